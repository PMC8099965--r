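#' Co-register a serial planar study
#'
#' Rigid 2-D translation alignment of every time point onto the first,
#' by the peak of the count cross-correlation of the anterior photopeak
#' images.  ROIs drawn on the reference scan are then valid at all time
#' points.  A warning is issued when the correlation peak sits at the
#' edge of the search window (possible registration failure).
#'
#' @param study A [simulate_planar_study()] result (needs >= 2 times).
#' @param reference Index of the reference time point.
#' @return The study with all emission images aligned to the reference
#'   and the estimated shifts stored in `$registration_shifts`.
#' @export
coregister_planar <- function(study, reference = 1L) {
  stopifnot(inherits(study, "planar_study"))
  nt <- length(study$times_h)
  if (nt < 2L) stop("co-registration needs at least two time points")
  ref <- study$photopeak_ant[[reference]]
  shifts <- vector("list", nt)
  for (k in seq_len(nt)) {
    if (k == reference) { shifts[[k]] <- c(0L, 0L); next }
    s <- estimate_shift(ref, study$photopeak_ant[[k]])
    shifts[[k]] <- s
    for (field in c("photopeak_ant", "photopeak_post",
                    "scatter_ant", "scatter_post")) {
      study[[field]][[k]] <- shift_array(study[[field]][[k]], -s)
    }
  }
  study$registration_shifts <- shifts
  study
}

#' Dual-energy-window scatter correction
#'
#' Estimates the scatter contribution in the photopeak window from the
#' lower scatter window scaled by the ratio of window widths, and
#' subtracts it pixelwise (floored at zero):
#' `C_primary = C_pk - C_sc * W_pk / W_sc`.  With the default windows
#' (208 keV +/- 20 %, 187 keV +/- 15 %) the width ratio is
#' 41.6 / 28.05 = 1.483.
#'
#' @param photopeak Photopeak count grid (matrix), non-negative.
#' @param scatter Scatter-window count grid, same dimension.
#' @param camera A [camera_config()] supplying the window widths.
#' @return Primary (scatter-corrected) count grid.
#' @export
scatter_correct <- function(photopeak, scatter, camera = camera_config()) {
  stopifnot(identical(dim(photopeak), dim(scatter)))
  if (any(photopeak < 0) || any(scatter < 0)) {
    stop("count grids must be non-negative")
  }
  ww <- window_widths_keV(camera)
  pmax(photopeak - scatter * ww[["photopeak"]] / ww[["scatter"]], 0)
}

#' Threshold segmentation inside a boundary ROI
#'
#' Delineates the organ within a (manually drawn, here fixture-supplied)
#' boundary ROI: pixels whose geometric mean of anterior and posterior
#' counts is at least `fraction` of the maximum geometric mean inside
#' the boundary.  Using the geometric mean makes the mask account for
#' both views at once and makes it depth-independent for conjugate
#' views.
#'
#' @param ant,post Scatter-corrected anterior/posterior count grids.
#' @param boundary Logical mask (or linear indices) of the boundary ROI.
#' @param fraction Threshold fraction in (0, 1); default 0.40 of the
#'   within-boundary maximum.
#' @return Logical organ mask.
#' @export
threshold_segment <- function(ant, post, boundary, fraction = 0.40) {
  stopifnot(fraction > 0, fraction < 1)
  idx <- .roi_index(ant, boundary)
  if (length(idx) == 0L) stop("boundary ROI is empty")
  gm <- sqrt(pmax(ant, 0) * pmax(post, 0))
  thr <- fraction * max(gm[idx])
  mask <- array(FALSE, dim(ant))
  mask[idx] <- gm[idx] >= thr
  if (!any(mask)) stop("threshold segmentation produced an empty mask")
  mask
}

#' Background correction of ROI counts
#'
#' Subtracts the background activity per pixel (from a background ROI
#' placed near the organ) scaled to the number of organ pixels:
#' `corrected = organ - bg / n_bg * n_organ`, floored at zero.
#'
#' @param organ_counts Summed counts in the organ ROI.
#' @param bg_counts Summed counts in the background ROI.
#' @param n_bg_pixels Number of background ROI pixels (> 0).
#' @param n_organ_pixels Number of organ ROI pixels.
#' @return Background-corrected counts.
#' @export
background_correct <- function(organ_counts, bg_counts, n_bg_pixels,
                               n_organ_pixels) {
  stopifnot(n_bg_pixels > 0)
  pmax(organ_counts - bg_counts / n_bg_pixels * n_organ_pixels, 0)
}

#' Conjugate-view activity estimate
#'
#' The geometric-mean method for opposed planar views: with anterior and
#' posterior counts `C_A`, `C_P`, the mean transmission factor `T` over
#' the organ (from the blank/transmission scan pair) and the source
#' self-attenuation factor `f = (mu t / 2) / sinh(mu t / 2)` for an
#' organ of thickness `t`, the activity is
#' `A = sqrt(C_A * C_P / T) * f / cf`, with `cf` the camera calibration
#' factor in counts/MBq.  The geometric mean makes the estimate
#' independent of the organ depth for a fixed total body thickness.
#'
#' @param ant_counts,post_counts Scatter- and background-corrected organ
#'   ROI counts.
#' @param transmission_mean Mean transmission factor `T` over the organ
#'   mask, in (0, 1].
#' @param organ_thickness_cm Organ thickness along the view axis, cm.
#' @param mu_cm Linear attenuation coefficient, 1/cm.
#' @param cf_counts_per_MBq Calibration factor for this scan.
#' @return Activity in MBq.
#' @examples
#' # no attenuation, thin source, unit calibration: A = sqrt(CA * CP)
#' conjugate_view_activity(100, 400, 1, 0, 0.11, 1)  # 200
#' @export
conjugate_view_activity <- function(ant_counts, post_counts,
                                    transmission_mean,
                                    organ_thickness_cm = 0,
                                    mu_cm = 0.11, cf_counts_per_MBq = 1) {
  if (any(transmission_mean <= 0)) {
    stop("mean transmission factor must be positive")
  }
  stopifnot(cf_counts_per_MBq > 0, organ_thickness_cm >= 0,
            ant_counts >= 0, post_counts >= 0)
  x <- mu_cm * organ_thickness_cm / 2
  f <- if (x == 0) 1 else x / sinh(x)
  sqrt(ant_counts * post_counts / transmission_mean) * f / cf_counts_per_MBq
}

#' Extrapolate counts from the visible organ fraction
#'
#' When an organ overlaps tissue of high uptake, only its non-overlapping
#' part is quantified and the counts are extrapolated to the entire
#' volume assuming homogeneous uptake: `counts / visible_fraction`.  For
#' paired kidneys with one kidney fully obscured, quantifying the
#' contralateral kidney and doubling corresponds to
#' `visible_fraction = 0.5` for the pair.
#'
#' @param counts_visible Counts from the visible organ part.
#' @param visible_fraction Fraction of the organ that is visible, (0, 1].
#' @return Extrapolated counts.
#' @export
partial_organ_extrapolate <- function(counts_visible, visible_fraction) {
  if (any(visible_fraction <= 0)) stop("visible_fraction must be > 0")
  stopifnot(all(visible_fraction <= 1))
  counts_visible / visible_fraction
}

#' Planar ROI set for a phantom
#'
#' Builds, from the phantom's CT-surrogate label map, the pixel sets the
#' 2D method needs per organ: the boundary ROI (projected footprint of
#' the *visible* organ part, dilated), a nearby background ROI (a ring
#' around the boundary restricted to body pixels free of any organ
#' footprint) and the visible fraction from the geometric contour
#' comparison of the projected organ and partner footprints.
#'
#' @param phantom A [build_phantom()] result.
#' @param boundary_margin_px Dilation margin of the boundary ROI.
#' @param bg_width_px Width of the background ring.
#' @return Named list per organ with elements `boundary`, `background`
#'   (logical matrices), `visible_fraction`, `thickness_cm`,
#'   `eligible_2d` (FALSE for bone metastases overlapping high-uptake
#'   tissue, which are excluded from planar analysis).
#' @export
make_planar_rois <- function(phantom, boundary_margin_px = 1L,
                             bg_width_px = 3L) {
  gd <- dim(phantom$labels)
  org <- phantom$organs
  fps <- lapply(seq_len(nrow(org)), function(i) {
    apply(phantom$labels == org$label[i], c(1L, 3L), any)
  })
  any_fp <- Reduce(`|`, fps)
  body_fp <- phantom$body_thickness_map > 0
  out <- vector("list", nrow(org))
  names(out) <- org$name
  for (i in seq_len(nrow(org))) {
    fp <- fps[[i]]
    visible <- fp
    for (j in seq_len(nrow(org))[-i]) visible <- visible & !fps[[j]]
    boundary <- dilate_mask(visible, boundary_margin_px)
    for (j in seq_len(nrow(org))[-i]) boundary <- boundary & !fps[[j]]
    ring <- dilate_mask(boundary, boundary_margin_px + bg_width_px) &
      !dilate_mask(boundary, boundary_margin_px + 1L)
    background <- ring & body_fp & !dilate_mask(any_fp, 1L)
    out[[i]] <- list(
      boundary = boundary, background = background,
      visible_fraction = org$visible_fraction[i],
      thickness_cm = org$thickness_cm[i],
      eligible_2d = !(org$region_class[i] == "bone_met" && org$overlapped[i])
    )
  }
  out
}

#' Full 2D quantification chain for a planar study
#'
#' Runs, per organ and time point: per-scan vial calibration,
#' dual-energy-window scatter correction, threshold segmentation within
#' the boundary ROI (on the reference scan, reused at all times),
#' background correction, conjugate-view activity estimation with
#' transmission-based attenuation correction and source self-attenuation,
#' and partial-organ extrapolation.  Organs flagged as ineligible (bone
#' metastases overlapping high-uptake tissue) are skipped.
#'
#' @param study A (co-registered) `planar_study`.
#' @param rois ROI set from [make_planar_rois()].
#' @param mu_cm Attenuation coefficient used for the self-attenuation
#'   factor, 1/cm.
#' @param segment_fraction Threshold fraction for [threshold_segment()].
#' @param per_pixel_transmission Use the per-pixel transmission under the
#'   organ mask instead of the ROI-mean factor.
#' @return Named list of [tac()] objects (method `"2D"`).
#' @export
planar_activity_series <- function(study, rois, mu_cm = 0.11,
                                   segment_fraction = 0.40,
                                   per_pixel_transmission = FALSE) {
  stopifnot(inherits(study, "planar_study"))
  nt <- length(study$times_h)
  tmap <- study$transmission / study$blank
  out <- list()
  for (nm in names(rois)) {
    roi <- rois[[nm]]
    if (!isTRUE(roi$eligible_2d)) next
    acts <- numeric(nt)
    mask <- NULL
    for (k in seq_len(nt)) {
      ant <- scatter_correct(study$photopeak_ant[[k]],
                             study$scatter_ant[[k]], study$camera)
      post <- scatter_correct(study$photopeak_post[[k]],
                              study$scatter_post[[k]], study$camera)
      if (is.null(mask)) {
        mask <- threshold_segment(ant, post, roi$boundary,
                                  segment_fraction)
      }
      cf <- planar_calibration_factor(ant, study$vial_roi,
                                      study$vial_activity_MBq,
                                      assay_to_scan_h = study$times_h[k])
      n_org <- sum(mask); n_bg <- sum(roi$background)
      ca <- background_correct(sum(ant[mask]), sum(ant[roi$background]),
                               n_bg, n_org)
      cp <- background_correct(sum(post[mask]), sum(post[roi$background]),
                               n_bg, n_org)
      # ROI-mean transmission by default; the per-pixel variant weights
      # each pixel by its own transmission (harmonic mean), equivalent to
      # correcting the conjugate product pixelwise for a uniform source
      tbar <- if (per_pixel_transmission) {
        1 / mean(1 / tmap[mask])
      } else {
        mean(tmap[mask])
      }
      a <- conjugate_view_activity(ca, cp, tbar, roi$thickness_cm, mu_cm,
                                   cf)
      acts[k] <- partial_organ_extrapolate(a, roi$visible_fraction)
    }
    out[[nm]] <- tac(study$times_h, acts, method = "2D", region = nm)
  }
  out
}
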