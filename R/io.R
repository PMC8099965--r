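# Configuration and study I/O.  Camera configuration, RC tables and
# dose-factor tables round-trip through YAML; TACs and dose tables
# through CSV; SPECT volumes and label maps can be exported to NIfTI
# when the RNifti package is installed.

#' Read and write configuration objects as YAML
#'
#' @param x A [camera_config()], [rc_table()] or [dose_factor_table()].
#' @param path File path.
#' @return `read_camera_config()` / `read_rc_table()` /
#'   `read_dose_factor_table()` return the corresponding object;
#'   the writers return `path` invisibly.
#' @export
write_config_yaml <- function(x, path) {
  obj <- if (inherits(x, "dose_factor_table")) {
    as.list(as.data.frame(x))
  } else {
    unclass(x)
  }
  obj$.class <- class(x)[1L]
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_camera_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$.class <- NULL
  do.call(camera_config, obj)
}

#' @rdname write_config_yaml
#' @export
read_rc_table <- function(path) {
  obj <- yaml::read_yaml(path)
  rc_table(unlist(obj$volume_ml), unlist(obj$recovery),
           obj$plateau_volume_ml)
}

#' @rdname write_config_yaml
#' @export
read_dose_factor_table <- function(path) {
  obj <- yaml::read_yaml(path)
  dose_factor_table(region = unlist(obj$region),
                    model = unlist(obj$model),
                    m_ref_g = unlist(obj$m_ref_g),
                    s_ref_Gy_per_MBqh = unlist(obj$s_ref_Gy_per_MBqh),
                    phi = unlist(obj$phi))
}

#' Write time-activity curves to CSV
#'
#' Long format with columns `region`, `method`, `time_h`,
#' `activity_MBq`.
#'
#' @param tacs A [tac()] or (possibly nested) list of TACs.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tacs_csv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  flat <- list()
  collect <- function(x) {
    if (inherits(x, "tac")) {
      flat[[length(flat) + 1L]] <<- data.frame(
        region = x$region, method = x$method, time_h = x$times_h,
        activity_MBq = x$activities_MBq, stringsAsFactors = FALSE)
    } else if (is.list(x)) {
      lapply(x, collect)
    }
    invisible(NULL)
  }
  collect(tacs)
  utils::write.csv(do.call(rbind, flat), path, row.names = FALSE)
  invisible(path)
}

#' Export a SPECT volume or label map to NIfTI
#'
#' Requires the RNifti package; voxel size is written into the header.
#'
#' @param volume 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel edge, mm.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel_mm = 4.66) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI requires the RNifti package")
  }
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
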