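#' Gamma-camera acquisition configuration
#'
#' Energy-window and geometry settings of the acquisition protocol.  The
#' defaults follow a Lu-177 whole-body protocol on a medium-energy
#' collimator system: photopeak window 208 keV +/- 20 %, lower scatter
#' window 187 keV +/- 15 %, planar pixel and (fused) SPECT voxel
#' 4.66 mm, whole-body scan speed 15 cm/min on days 1 and 2 and
#' 12 cm/min on day 4.
#'
#' `planar_sens_cps_per_MBq` and `spect_sens_cps_per_MBq` are the system
#' sensitivities used by the simulator; they cancel out of every
#' quantitative result because both pipelines are calibrated against a
#' known-activity source imaged with the same settings.
#'
#' @param photopeak_center_keV Photopeak window centre, keV.
#' @param photopeak_width_fraction Photopeak window width as a fraction
#'   of the centre energy (in (0, 1)).
#' @param scatter_center_keV Scatter window centre, keV.
#' @param scatter_width_fraction Scatter window fractional width.
#' @param planar_pixel_mm Planar pixel edge, mm.
#' @param spect_voxel_mm SPECT voxel edge after fusion, mm.
#' @param scan_speed_cm_min Whole-body scan speed per time point, cm/min;
#'   recycled to the number of time points when needed.
#' @param detector_length_cm Axial field of view of the detector; with a
#'   continuous-bed scan, dwell time per row is
#'   `detector_length_cm / scan_speed`.
#' @param planar_sens_cps_per_MBq Planar system sensitivity.
#' @param spect_sens_cps_per_MBq SPECT system sensitivity.
#' @return Object of class `camera_config`.
#' @export
camera_config <- function(photopeak_center_keV = 208,
                          photopeak_width_fraction = 0.20,
                          scatter_center_keV = 187,
                          scatter_width_fraction = 0.15,
                          planar_pixel_mm = 4.66,
                          spect_voxel_mm = 4.66,
                          scan_speed_cm_min = c(15, 15, 12),
                          detector_length_cm = 40,
                          planar_sens_cps_per_MBq = 10,
                          spect_sens_cps_per_MBq = 10) {
  stopifnot(photopeak_width_fraction > 0, photopeak_width_fraction < 1,
            scatter_width_fraction > 0, scatter_width_fraction < 1,
            planar_pixel_mm > 0, spect_voxel_mm > 0,
            all(scan_speed_cm_min > 0), detector_length_cm > 0,
            planar_sens_cps_per_MBq > 0, spect_sens_cps_per_MBq > 0)
  structure(list(
    photopeak_center_keV = photopeak_center_keV,
    photopeak_width_fraction = photopeak_width_fraction,
    scatter_center_keV = scatter_center_keV,
    scatter_width_fraction = scatter_width_fraction,
    planar_pixel_mm = planar_pixel_mm,
    spect_voxel_mm = spect_voxel_mm,
    scan_speed_cm_min = scan_speed_cm_min,
    detector_length_cm = detector_length_cm,
    planar_sens_cps_per_MBq = planar_sens_cps_per_MBq,
    spect_sens_cps_per_MBq = spect_sens_cps_per_MBq
  ), class = "camera_config")
}

#' Energy-window widths in keV
#'
#' @param camera A [camera_config()].
#' @return Named vector with elements `photopeak` and `scatter`, keV.
#' @export
window_widths_keV <- function(camera = camera_config()) {
  c(photopeak = camera$photopeak_center_keV * camera$photopeak_width_fraction,
    scatter = camera$scatter_center_keV * camera$scatter_width_fraction)
}

#' Recovery-coefficient table
#'
#' Volume-dependent recovery coefficients (measured-to-true activity
#' ratio of a hot sphere) used for partial-volume correction of SPECT
#' activity estimates.  Recovery must be non-decreasing with volume; for
#' volumes at or above `plateau_volume_ml` the plateau recovery is used.
#'
#' @param volume_ml Sphere volumes, ml, increasing.
#' @param recovery Recovery coefficients in (0, 1], non-decreasing.
#' @param plateau_volume_ml Volume at and beyond which the plateau
#'   recovery applies; defaults to the largest tabulated volume.
#' @return Object of class `rc_table`.
#' @seealso [rc_table_lu177()], [recovery_coefficient()],
#'   [measure_recovery_curve()]
#' @export
rc_table <- function(volume_ml, recovery,
                     plateau_volume_ml = max(volume_ml)) {
  stopifnot(length(volume_ml) == length(recovery),
            length(volume_ml) >= 1L,
            all(volume_ml > 0), !is.unsorted(volume_ml, strictly = TRUE),
            all(recovery > 0), all(recovery <= 1),
            !is.unsorted(recovery), plateau_volume_ml > 0)
  structure(list(volume_ml = as.numeric(volume_ml),
                 recovery = as.numeric(recovery),
                 plateau_volume_ml = plateau_volume_ml),
            class = "rc_table")
}

#' Published Lu-177 recovery coefficients
#'
#' The recovery-coefficient table of the clinical reconstruction setting
#' this package models: RC 0.85 for volumes >= 20 ml, falling to 0.79,
#' 0.67 and 0.59 for sphere volumes of approximately 13, 10 and 6 ml.
#'
#' @return An [rc_table()] with plateau at 20 ml.
#' @export
rc_table_lu177 <- function() {
  rc_table(volume_ml = c(6, 10, 13, 20),
           recovery = c(0.59, 0.67, 0.79, 0.85),
           plateau_volume_ml = 20)
}

#' Look up a recovery coefficient
#'
#' Tabulated volumes return the tabulated recovery exactly; volumes at or
#' above the plateau return the plateau recovery; intermediate volumes
#' are interpolated linearly in log(volume) (recovery curves are
#' approximately logarithmic in volume); volumes below the smallest
#' tabulated entry are clamped to the smallest tabulated recovery with a
#' warning (extrapolating a steep RC curve downwards risks gross
#' over-correction).
#'
#' @param volume_ml Object volume(s), ml.
#' @param table An [rc_table()].
#' @return Recovery coefficient(s) in (0, 1].
#' @examples
#' recovery_coefficient(25, rc_table_lu177())    # 0.85 (plateau)
#' recovery_coefficient(6, rc_table_lu177())     # 0.59
#' @export
recovery_coefficient <- function(volume_ml, table = rc_table_lu177()) {
  stopifnot(inherits(table, "rc_table"), all(volume_ml > 0))
  vols <- table$volume_ml
  recs <- table$recovery
  plateau_rec <- if (table$plateau_volume_ml <= max(vols)) {
    recs[findInterval(table$plateau_volume_ml, vols)]
  } else {
    recs[length(recs)]
  }
  out <- vapply(volume_ml, function(v) {
    if (v >= table$plateau_volume_ml) return(plateau_rec)
    if (v < vols[1L]) {
      warning("volume ", signif(v, 3), " ml below smallest tabulated RC ",
              "volume; clamping to RC(", vols[1L], " ml)")
      return(recs[1L])
    }
    i <- findInterval(v, vols)
    if (vols[i] == v) return(recs[i])
    # log-linear interpolation in volume
    w <- (log(v) - log(vols[i])) / (log(vols[i + 1L]) - log(vols[i]))
    recs[i] + w * (recs[i + 1L] - recs[i])
  }, numeric(1))
  out
}

#' @export
print.rc_table <- function(x, ...) {
  cat("Recovery-coefficient table (plateau at ",
      x$plateau_volume_ml, " ml)\n", sep = "")
  print(data.frame(volume_ml = x$volume_ml, recovery = x$recovery),
        row.names = FALSE)
  invisible(x)
}
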