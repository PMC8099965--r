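#' Convert a count-rate volume to activity
#'
#' Voxelwise application of the SPECT calibration factor (Bq per cps),
#' returning voxel activities in MBq.
#'
#' @param volume_cps Count-rate volume, cps per voxel.
#' @param cf_Bq_per_cps Calibration factor from
#'   [spect_calibration_factor()].
#' @return Activity volume, MBq per voxel.
#' @export
counts_to_activity <- function(volume_cps, cf_Bq_per_cps) {
  stopifnot(cf_Bq_per_cps > 0)
  volume_cps * cf_Bq_per_cps / 1e6
}

#' Propagate a boundary VOI to another time point
#'
#' Rigid 3-D translation registration (peak of the normalised count
#' cross-correlation) of the target volume onto the reference volume,
#' after which the boundary VOI drawn on the reference is copied across.
#' An optional manual offset is added to the estimated shift (the
#' deterministic stand-in for interactive boundary adjustment).
#'
#' @param boundary Logical VOI drawn on the reference volume.
#' @param reference_volume,target_volume Same-dimension 3-D arrays.
#' @param manual_offset_vox Optional integer c(dx, dy, dz) added to the
#'   estimated shift.
#' @return List with the shifted `boundary` and the estimated
#'   `shift_vox`.
#' @export
propagate_voi <- function(boundary, reference_volume, target_volume,
                          manual_offset_vox = c(0L, 0L, 0L)) {
  stopifnot(identical(dim(boundary), dim(reference_volume)),
            identical(dim(reference_volume), dim(target_volume)))
  s <- estimate_shift(reference_volume, target_volume) +
    as.integer(manual_offset_vox)
  list(boundary = shift_array(boundary, s, fill = FALSE) > 0,
       shift_vox = s)
}

#' Adaptive-threshold VOI segmentation
#'
#' Automatic delineation inside a boundary VOI by iterated adaptive
#' thresholding: the threshold is `alpha` times the mean voxel value of
#' the current foreground, iterated to a fixed point.  This is a
#' deterministic automatic-segmentation stand-in with the same contract
#' as more elaborate classifiers (delineation within a boundary VOI);
#' it is pluggable via the `segment_fun` argument of
#' [spect_activity_series()].
#'
#' @param volume Activity (or count-rate) volume.
#' @param boundary Logical boundary VOI (or linear indices).
#' @param alpha Threshold fraction of the foreground mean, in (0, 1).
#' @param init Initial foreground: thresholding at `alpha` times the
#'   boundary mean (`"mean"`) or boundary maximum (`"max"`).
#' @param voxel_mm Voxel edge, mm, for the volume estimate.
#' @param max_iter Iteration limit (error when exceeded).
#' @return List with `segmented` (logical array), `volume_ml` and the
#'   number of iterations.
#' @export
segment_voi_adaptive <- function(volume, boundary, alpha = 0.5,
                                 init = c("mean", "max"),
                                 voxel_mm = 4.66, max_iter = 100L) {
  init <- match.arg(init)
  stopifnot(alpha > 0, alpha < 1)
  idx <- .roi_index(volume, boundary)
  if (length(idx) == 0L) stop("boundary VOI is empty")
  vals <- volume[idx]
  thr <- alpha * (if (init == "mean") mean(vals) else max(vals))
  fg <- vals >= thr
  if (!any(fg)) fg <- vals >= max(vals) * 0.99
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    thr <- alpha * mean(vals[fg])
    fg2 <- vals >= thr
    if (identical(fg2, fg)) { converged <- TRUE; break }
    fg <- fg2
  }
  if (!converged) {
    stop("adaptive segmentation did not converge in ", max_iter,
         " iterations")
  }
  seg <- array(FALSE, dim(volume))
  seg[idx[fg]] <- TRUE
  list(segmented = seg, volume_ml = sum(fg) * (voxel_mm / 10)^3,
       iterations = it)
}

#' Recovery-corrected VOI activity
#'
#' Sums the voxel activities in the segmented VOI and divides by the
#' recovery coefficient looked up at the segmented volume (sphere
#' volumes matching the object volume), the standard partial-volume
#' correction.
#'
#' @param volume_MBq Activity volume, MBq per voxel.
#' @param segmented Logical segmented voxel set (or linear indices).
#' @param rc A [rc_table()].
#' @param voxel_mm Voxel edge, mm.
#' @return List with `activity_raw_MBq`, `activity_MBq` (RC-corrected),
#'   `volume_ml` and the applied `recovery`.
#' @export
voi_activity <- function(volume_MBq, segmented, rc = rc_table_lu177(),
                         voxel_mm = 4.66) {
  idx <- .roi_index(volume_MBq, segmented)
  if (length(idx) == 0L) stop("segmented VOI is empty")
  vol_ml <- length(idx) * (voxel_mm / 10)^3
  raw <- sum(volume_MBq[idx])
  r <- recovery_coefficient(vol_ml, rc)
  list(activity_raw_MBq = raw, activity_MBq = raw / r,
       volume_ml = vol_ml, recovery = r)
}

#' Full 3D quantification chain for a SPECT study
#'
#' Per time point: calibration-factor conversion of the count-rate
#' volume to activity, propagation of the boundary VOIs from the first
#' acquisition by translation registration, adaptive-threshold
#' segmentation and recovery-corrected activity estimation.
#'
#' @param study A `spect_study`.
#' @param vois Boundary VOIs drawn on the first time point (named list of
#'   logical arrays), e.g. from [make_boundary_vois()].
#' @param rc An [rc_table()]; for synthetic studies the blur-matched
#'   curve from [measure_recovery_curve()] is the consistent choice.
#' @param alpha Threshold fraction of [segment_voi_adaptive()].
#' @param segment_fun Segmentation function with the signature of
#'   [segment_voi_adaptive()] (pluggable delineation algorithm).
#' @return Named list of [tac()] objects (method `"3D"`), each carrying
#'   the per-time estimated volumes as attribute `volumes_ml`.
#' @export
spect_activity_series <- function(study, vois = make_boundary_vois(study),
                                  rc = NULL, alpha = 0.5,
                                  segment_fun = segment_voi_adaptive) {
  stopifnot(inherits(study, "spect_study"))
  if (is.null(rc)) {
    rc <- measure_recovery_curve(psf_sigma_mm = study$psf_sigma_mm,
                                 voxel_mm = study$voxel_mm)
  }
  cf <- spect_calibration_factor(study$calibration$volume_cps,
                                 study$calibration$activity_Bq)
  nt <- length(study$times_h)
  ref <- study$volumes_cps[[1L]]
  # session-level registration: one rigid shift per time point, applied
  # to every boundary VOI
  shifts <- c(list(c(0L, 0L, 0L)),
              lapply(seq_len(nt)[-1L], function(k) {
                estimate_shift(ref, study$volumes_cps[[k]])
              }))
  acts_vols <- lapply(seq_len(nt), function(k) {
    act <- counts_to_activity(study$volumes_cps[[k]], cf)
    out_k <- lapply(names(vois), function(nm) {
      b <- if (all(shifts[[k]] == 0L)) vois[[nm]] else {
        shift_array(vois[[nm]], shifts[[k]], fill = FALSE) > 0
      }
      seg <- segment_fun(act, b, alpha = alpha,
                         voxel_mm = study$voxel_mm)
      va <- voi_activity(act, seg$segmented, rc, study$voxel_mm)
      c(va$activity_MBq, va$volume_ml)
    })
    names(out_k) <- names(vois)
    out_k
  })
  out <- list()
  for (nm in names(vois)) {
    acts <- vapply(acts_vols, function(x) x[[nm]][1L], numeric(1))
    vols <- vapply(acts_vols, function(x) x[[nm]][2L], numeric(1))
    tc <- tac(study$times_h, acts, method = "3D", region = nm)
    attr(tc, "volumes_ml") <- vols
    out[[nm]] <- tc
  }
  out
}
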