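#' Time-activity curve
#'
#' Serial activity measurements of one source region by one method.
#'
#' @param times_h Measurement times, hours, strictly increasing, >= 2
#'   points for fitting and integration.
#' @param activities_MBq Measured activities, MBq, non-negative.
#' @param weights Positive fit weights; default `NULL` selects
#'   Poisson-like weights `1 / max(A_i, eps)` at fit time.
#' @param method One of `"2D"`, `"3D"`, `"hybrid"`.
#' @param region Region label.
#' @return Object of class `tac`.
#' @export
tac <- function(times_h, activities_MBq, weights = NULL,
                method = c("2D", "3D", "hybrid"), region = "region") {
  method <- match.arg(method)
  stopifnot(length(times_h) == length(activities_MBq),
            length(times_h) >= 1L,
            all(activities_MBq >= 0),
            !is.unsorted(times_h, strictly = TRUE), all(times_h > 0))
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(times_h), all(weights > 0))
  }
  structure(list(times_h = as.numeric(times_h),
                 activities_MBq = as.numeric(activities_MBq),
                 weights = weights, method = method, region = region),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat("TAC [", x$method, "] ", x$region, ": ", sep = "")
  cat(paste0(signif(x$activities_MBq, 4), " MBq @ ", x$times_h, " h"),
      sep = ", ")
  cat("\n")
  invisible(x)
}

#' Weighted mono-exponential fit of a time-activity curve
#'
#' Fits `A(t) = A0 * exp(-lambda * t)` by weighted least squares in
#' activity space, minimising `sum(w_i * (A_i - A0 exp(-lambda t_i))^2)`.
#' Default weights are Poisson-like, `w_i = 1 / max(A_i, eps)`.  With
#' exactly two positive points the fit is the exact interpolant.  A
#' fitted decay slower than physical decay (`lambda < lambda_phys`) is
#' biologically impossible as a washout and is flagged with a warning;
#' the fitted value is retained for diagnostics.
#'
#' @param x A [tac()] with at least two distinct positive activities.
#' @param weights `"poisson"` (default), `"uniform"`, or a numeric
#'   vector; ignored when the TAC carries its own weights.
#' @param lambda_phys Physical decay constant for the plausibility flag.
#' @return Object of class `monoexp_fit` with elements `A0_MBq`,
#'   `lambda_per_h`, `residual_norm`, `flag_slow_decay`.
#' @export
fit_monoexponential <- function(x, weights = c("poisson", "uniform"),
                                lambda_phys = lu177_lambda()) {
  stopifnot(inherits(x, "tac"))
  t <- x$times_h; a <- x$activities_MBq
  pos <- a > 0
  if (sum(pos) < 2L) {
    stop("mono-exponential fit needs at least two positive activities")
  }
  w <- if (!is.null(x$weights)) {
    x$weights
  } else if (is.numeric(weights)) {
    stopifnot(length(weights) == length(t), all(weights > 0))
    weights
  } else {
    weights <- match.arg(weights)
    if (weights == "poisson") 1 / pmax(a, 1e-9 * max(a)) else rep(1, length(t))
  }
  tp <- t[pos]; ap <- a[pos]; wp <- w[pos]
  if (sum(pos) == 2L) {
    lambda <- log(ap[1L] / ap[2L]) / (tp[2L] - tp[1L])
    a0 <- ap[1L] * exp(lambda * tp[1L])
  } else {
    # log-linear weighted start, then WLS refinement in activity space
    fit0 <- stats::lm.wfit(cbind(1, -tp), log(ap), wp * ap^2)
    start <- c(log_a0 = fit0$coefficients[[1L]],
               lambda = max(fit0$coefficients[[2L]], 1e-6))
    obj <- function(p) {
      sum(wp * (ap - exp(p[1L]) * exp(-p[2L] * tp))^2)
    }
    opt <- stats::nlminb(start, obj,
                         lower = c(-Inf, 1e-8), upper = c(Inf, 10),
                         control = list(rel.tol = 1e-14,
                                        iter.max = 500L))
    if (opt$objective > obj(start) + 1e-9 * (1 + abs(obj(start)))) {
      stop("mono-exponential fit did not converge: ", opt$message)
    }
    a0 <- exp(opt$par[[1L]]); lambda <- opt$par[[2L]]
  }
  if (lambda <= 0) stop("fitted decay constant is not positive")
  res <- a - a0 * exp(-lambda * t)
  flag <- lambda < lambda_phys * (1 - 1e-9)
  # warn only for clearly implausible values; quantification noise
  # routinely produces fits marginally below physical decay
  if (lambda < lambda_phys * 0.95) {
    warning("fitted lambda (", signif(lambda, 4),
            "/h) is slower than physical decay; accumulation beyond ",
            "physical decay is implausible for a washout phase")
  }
  structure(list(A0_MBq = a0, lambda_per_h = lambda,
                 residual_norm = sqrt(sum(w * res^2)),
                 flag_slow_decay = flag),
            class = "monoexp_fit")
}

#' Piecewise time-integrated activity
#'
#' Integrates a measured time-activity curve with the standard clinical
#' scheme: constant activity `A(t1)` is assumed between administration
#' and the first scan (a rectangle, i.e. a trapezoid with
#' `A(0) := A(t1)`); trapezoidal integration between the first and last
#' scans; and beyond the last scan a mono-exponential tail governed, by
#' default, by physical decay only: `A(tn) / lambda_phys`.
#'
#' The physical-decay tail is deliberately conservative: when the true
#' effective decay is faster than physical (biological clearance), it
#' overestimates the tail.  Set `tail = "fit"` to use the fitted decay
#' constant instead (floored at physical decay), and
#' `first_interval = "fit"` to replace the initial rectangle by a
#' trapezoid from the back-extrapolated `A0` of the fit.
#'
#' @param x A [tac()] with >= 2 points.
#' @param fit A [fit_monoexponential()] result; required for the `"fit"`
#'   options, otherwise only used for diagnostics.
#' @param decay A [physical_decay()].
#' @param tail `"physical"` (default) or `"fit"`.
#' @param first_interval `"constant"` (default) or `"fit"`.
#' @return Time-integrated activity, MBq h.
#' @export
integrate_tia <- function(x, fit = NULL, decay = physical_decay(),
                          tail = c("physical", "fit"),
                          first_interval = c("constant", "fit")) {
  tail <- match.arg(tail)
  first_interval <- match.arg(first_interval)
  stopifnot(inherits(x, "tac"), inherits(decay, "physical_decay"))
  t <- x$times_h; a <- x$activities_MBq
  if (length(t) < 2L) stop("TIA integration needs at least two points")
  if (all(a == 0)) return(0)
  a0_start <- if (first_interval == "fit") {
    if (is.null(fit)) stop("first_interval = 'fit' requires a fit")
    fit$A0_MBq
  } else {
    a[1L]
  }
  head_part <- (a0_start + a[1L]) / 2 * t[1L]
  trapz <- sum((a[-1L] + a[-length(a)]) / 2 * diff(t))
  lambda_tail <- if (tail == "fit") {
    if (is.null(fit)) stop("tail = 'fit' requires a fit")
    max(fit$lambda_per_h, decay$lambda_phys)
  } else {
    decay$lambda_phys
  }
  head_part + trapz + a[length(a)] / lambda_tail
}

#' Rescale a planar time-activity curve by one SPECT measurement
#'
#' The hybrid method: the shape of the kinetics comes from the serial
#' planar study, the absolute scale from a single quantitative SPECT.
#' Every planar activity is multiplied by
#' `s = spect_activity / planar_activity(t_anchor)`, so ratios between
#' time points — and hence the fitted decay constant — are unchanged.
#'
#' @param planar_tac A [tac()] with method `"2D"`.
#' @param spect_activity_MBq SPECT activity estimate at the anchor time.
#' @param t_anchor_h Anchor time; must match one of the planar times
#'   within `tol_h`.
#' @param tol_h Matching tolerance, hours.
#' @return A [tac()] with method `"hybrid"`.
#' @export
hybrid_rescale <- function(planar_tac, spect_activity_MBq, t_anchor_h,
                           tol_h = 2) {
  stopifnot(inherits(planar_tac, "tac"), spect_activity_MBq >= 0)
  d <- abs(planar_tac$times_h - t_anchor_h)
  i <- which.min(d)
  if (d[i] > tol_h) {
    stop("anchor time ", t_anchor_h, " h does not match any planar time ",
         "point within ", tol_h, " h")
  }
  if (planar_tac$activities_MBq[i] <= 0) {
    stop("planar activity at the anchor time is not positive")
  }
  s <- spect_activity_MBq / planar_tac$activities_MBq[i]
  tac(planar_tac$times_h, planar_tac$activities_MBq * s,
      weights = planar_tac$weights, method = "hybrid",
      region = planar_tac$region)
}

#' Time-integrated activity coefficient
#'
#' TIA normalised to the administered activity, expressed in hours:
#' `TIAC = TIA[MBq h] / (administered[GBq] * 1000)`.
#'
#' @param tia_MBqh Time-integrated activity, MBq h.
#' @param administered_GBq Administered activity, GBq (> 0).
#' @return TIAC in hours.
#' @examples
#' compute_tiac(6400, 6.4)  # 1 h
#' @export
compute_tiac <- function(tia_MBqh, administered_GBq) {
  stopifnot(administered_GBq > 0, all(tia_MBqh >= 0))
  tia_MBqh / (administered_GBq * 1000)
}
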