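#' Planar calibration factor from a known-activity vial
#'
#' A vial with known Lu-177 activity is imaged alongside the patient
#' during each whole-body scan; the counts in a region of interest around
#' the vial divided by the (decay-corrected) vial activity give the
#' camera response in counts/MBq for that scan.  Because one factor is
#' derived per acquisition, differences in scan speed between time points
#' cancel automatically.
#'
#' @param image Planar count grid (matrix).
#' @param vial_roi Logical mask of the same dimension, or linear pixel
#'   indices, selecting the vial ROI.
#' @param vial_activity_MBq Vial activity at assay time, MBq (> 0).
#' @param assay_to_scan_h Hours elapsed between activity assay and scan
#'   start; the activity is decay-corrected with the physical decay
#'   constant over this interval.
#' @param lambda_phys Physical decay constant, 1/h.
#' @return Calibration factor in counts per MBq.
#' @export
planar_calibration_factor <- function(image, vial_roi, vial_activity_MBq,
                                      assay_to_scan_h = 0,
                                      lambda_phys = lu177_lambda()) {
  stopifnot(is.matrix(image), vial_activity_MBq > 0, assay_to_scan_h >= 0)
  idx <- .roi_index(image, vial_roi)
  if (length(idx) == 0L) stop("vial ROI is empty")
  counts <- sum(image[idx])
  if (counts <= 0) {
    stop("zero counts in vial ROI: acquisition or ROI placement failure")
  }
  activity_at_scan <- vial_activity_MBq * exp(-lambda_phys * assay_to_scan_h)
  counts / activity_at_scan
}

#' SPECT calibration factor from a uniform cylinder
#'
#' A large water cylinder (6595 ml by default in the simulator)
#' containing a well-calibrated Lu-177 source is scanned and
#' reconstructed with the clinical protocol; the calibration factor is
#' the known activity divided by the total reconstructed count rate, in
#' Bq per cps.
#'
#' @param volume_cps Reconstructed count-rate volume (3-D array, cps per
#'   voxel).
#' @param phantom_activity_Bq Known activity in the cylinder, Bq (> 0).
#' @param voi Optional logical mask or linear voxel indices restricting
#'   the sum; defaults to the whole volume so that spill-out counts are
#'   included.
#' @return Calibration factor in Bq per cps.
#' @export
spect_calibration_factor <- function(volume_cps, phantom_activity_Bq,
                                     voi = NULL) {
  stopifnot(is.array(volume_cps), phantom_activity_Bq > 0)
  idx <- if (is.null(voi)) seq_along(volume_cps) else .roi_index(volume_cps, voi)
  if (length(idx) == 0L) stop("calibration VOI is empty")
  total_cps <- sum(volume_cps[idx])
  if (total_cps <= 0) stop("zero count rate in calibration VOI")
  phantom_activity_Bq / total_cps
}
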