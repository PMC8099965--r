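# Internal array helpers: separable Gaussian blur via FFT (circular, with
# sources kept away from edges by construction), cross-correlation based
# translation estimation, and integer shifting with zero fill.

# 1-D Gaussian kernel aligned with the FFT origin (index 1), wrapped.
.kern1d <- function(n, sigma_mm, step_mm) {
  if (sigma_mm <= 0) {
    k <- numeric(n); k[1] <- 1; return(k)
  }
  half <- n %/% 2L
  x <- c(0:half, -((n - half - 1L):1L)) * step_mm
  k <- stats::dnorm(x, sd = sigma_mm)
  k / sum(k)
}

# Isotropic Gaussian blur of a 2-D or 3-D array; sigma in mm, grid step in
# mm.  FFT-based circular convolution: callers must keep activity away
# from the array edges (the phantom builder enforces a margin).
gauss_blur <- function(a, sigma_mm, step_mm) {
  if (sigma_mm <= 0) return(a)
  d <- dim(a)
  ks <- lapply(d, .kern1d, sigma_mm = sigma_mm, step_mm = step_mm)
  K <- ks[[1L]]
  for (i in seq_along(d)[-1L]) K <- outer(K, ks[[i]])
  dim(K) <- d
  out <- Re(stats::fft(stats::fft(a) * stats::fft(K), inverse = TRUE)) / prod(d)
  # clip FFT ringing at the numerical-noise level
  out[abs(out) < 1e-12 * max(abs(out))] <- 0
  out
}

# Integer translation of an array, filling vacated entries with `fill`.
# `shift` has one entry per dimension; positive values move content
# towards higher indices.
shift_array <- function(a, shift, fill = 0) {
  d <- dim(a)
  stopifnot(length(shift) == length(d))
  shift <- as.integer(round(shift))
  out <- array(fill, dim = d)
  src <- dst <- vector("list", length(d))
  for (i in seq_along(d)) {
    s <- shift[i]
    if (abs(s) >= d[i]) return(out)
    if (s >= 0) {
      dst[[i]] <- (1L + s):d[i]
      src[[i]] <- 1L:(d[i] - s)
    } else {
      dst[[i]] <- 1L:(d[i] + s)
      src[[i]] <- (1L - s):d[i]
    }
  }
  out_idx <- do.call(expand.grid, dst)
  if (length(d) == 2L) {
    out[dst[[1L]], dst[[2L]]] <- a[src[[1L]], src[[2L]]]
  } else if (length(d) == 3L) {
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  } else {
    stop("shift_array supports 2-D and 3-D arrays")
  }
  out
}

# Translation (integer-voxel) between two same-sized arrays estimated from
# the peak of their circular cross-correlation.  Returns the shift that
# maps `reference` onto `target` (target ~ shift_array(reference, shift)).
# Warns when the peak sits at the edge of the admissible search window.
estimate_shift <- function(reference, target, max_shift = NULL) {
  d <- dim(reference)
  stopifnot(identical(d, dim(target)))
  xc <- Re(stats::fft(stats::fft(target) * Conj(stats::fft(reference)),
                      inverse = TRUE))
  peak <- which.max(xc)
  idx <- arrayInd(peak, d) - 1L
  shift <- ifelse(idx > d / 2, idx - d, idx)
  if (is.null(max_shift)) max_shift <- floor(d / 4)
  if (any(abs(shift) >= max_shift)) {
    warning("correlation peak at the edge of the search window; ",
            "registration may have failed")
  }
  as.integer(shift)
}

# Binary dilation of a logical array by a chebyshev-ball of `r` voxels,
# via FFT convolution with a cube of ones (fast on large grids).
dilate_mask <- function(mask, r = 1L) {
  if (r <= 0) return(mask)
  d <- dim(mask)
  ks <- lapply(d, function(n) {
    k <- numeric(n)
    k[c(1:(r + 1L), (n - r + 1L):n)] <- 1
    k
  })
  K <- ks[[1L]]
  for (i in seq_along(d)[-1L]) K <- outer(K, ks[[i]])
  dim(K) <- d
  cnt <- Re(stats::fft(stats::fft(mask + 0) * stats::fft(K),
                       inverse = TRUE)) / prod(d)
  array(cnt > 0.5, dim = d)
}

# Resolve a region-of-interest given either a logical mask matching
# dim(image) or a vector of (1-based) linear indices.
.roi_index <- function(image, roi) {
  if (is.logical(roi)) {
    stopifnot(identical(dim(roi), dim(image)))
    which(roi)
  } else {
    as.integer(roi)
  }
}
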