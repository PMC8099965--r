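#' Relative difference of a method pair
#'
#' The paired relative difference in percent, referred to the mean of
#' the two methods: `100 * (x - y) / ((x + y) / 2)`.  Pairs with zero
#' mean are undefined and returned as `NA` with a warning.
#'
#' @param x,y Paired dose estimates (e.g. Gy/GBq), same length.
#' @return Relative differences in percent.
#' @examples
#' relative_difference(0.9, 1.1)  # -20
#' @export
relative_difference <- function(x, y) {
  stopifnot(length(x) == length(y))
  m <- (x + y) / 2
  out <- 100 * (x - y) / m
  bad <- m == 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with zero mean excluded (undefined ",
            "relative difference)")
    out[bad] <- NA_real_
  }
  out
}

# Exact two-sided signed-rank p value by full enumeration of the 2^n
# sign assignments (ties handled by average ranks).
.signed_rank_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9))
  list(p_value = min(p, 1), statistic = w_obs)
}

# Normal approximation with tie and continuity correction.
.signed_rank_normal <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(p_value = min(2 * stats::pnorm(-abs(z)), 1), statistic = w)
}

#' Rank test on paired differences
#'
#' Two-sided test of the null of symmetric differences around zero.
#' The primary test is the paired Wilcoxon signed-rank test, matching
#' the paired structure of per-cycle dose estimates; the null
#' distribution is computed exactly by full enumeration of all sign
#' assignments for small samples and by the normal approximation with
#' tie and continuity correction otherwise.  An unpaired
#' Wilcoxon-Mann-Whitney rank-sum variant is available via
#' `type = "rank_sum"` (delegating to [stats::wilcox.test()]), in which
#' case `y` supplies the second sample.
#'
#' @param differences Paired differences (signed-rank test), or the
#'   first sample for the rank-sum variant.
#' @param y Second sample, rank-sum variant only.
#' @param type `"signed_rank"` (paired, default) or `"rank_sum"`.
#' @param exact_max Largest n (after zero removal) for exact
#'   enumeration.
#' @return List of class `rank_test` with `p_value`, `statistic`, `n`,
#'   `exact` and `type`.
#' @export
rank_test <- function(differences, y = NULL,
                      type = c("signed_rank", "rank_sum"),
                      exact_max = 12L) {
  type <- match.arg(type)
  if (type == "rank_sum") {
    stopifnot(!is.null(y))
    wt <- stats::wilcox.test(differences, y, exact = NULL)
    return(structure(list(p_value = wt$p.value,
                          statistic = unname(wt$statistic),
                          n = length(differences) + length(y),
                          exact = NA, type = type),
                     class = "rank_test"))
  }
  d <- differences[!is.na(differences)]
  nonzero <- d[d != 0]
  if (length(nonzero) == 0L) {
    warning("all differences are zero; p = 1")
    return(structure(list(p_value = 1, statistic = 0, n = 0L,
                          exact = TRUE, type = type),
                     class = "rank_test"))
  }
  res <- if (length(nonzero) <= exact_max) {
    c(.signed_rank_exact(nonzero), exact = TRUE)
  } else {
    c(.signed_rank_normal(nonzero), exact = FALSE)
  }
  structure(list(p_value = res$p_value, statistic = res$statistic,
                 n = length(nonzero), exact = res$exact, type = type),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(if (identical(x$type, "rank_sum")) "Wilcoxon rank-sum test"
      else "Wilcoxon signed-rank test",
      if (isTRUE(x$exact)) "(exact)" else "(normal approximation)",
      "\n  n =", x$n, " W =", x$statistic,
      " p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Computes per-pair relative differences (percent of the pair mean),
#' their mean and standard deviation, and the limits of agreement
#' `mean difference +/- 1.96 * SD`.  Also reported: the median absolute
#' difference (in the dose unit) and median percent difference, and the
#' signed-rank p value for a systematic difference.
#'
#' @param x,y Paired dose estimates (x = test method, y = reference).
#' @return Object of class `agreement_stats`: `n`, `mean_diff_pct`,
#'   `sd_diff_pct`, `loa_halfwidth_pct` (1.96 SD), `loa_lower_pct`,
#'   `loa_upper_pct`, `median_diff_abs`, `median_diff_pct`, `p_value`,
#'   plus the per-pair `pair_means` and `pair_diff_pct` for plotting.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("Bland-Altman analysis needs at least 2 pairs")
  d_pct <- relative_difference(x, y)
  keep <- !is.na(d_pct)
  d_pct <- d_pct[keep]
  m <- stats::sd(d_pct)
  mean_d <- mean(d_pct)
  structure(list(
    n = length(d_pct),
    mean_diff_pct = mean_d,
    sd_diff_pct = m,
    loa_halfwidth_pct = 1.96 * m,
    loa_lower_pct = mean_d - 1.96 * m,
    loa_upper_pct = mean_d + 1.96 * m,
    median_diff_abs = stats::median((x - y)[keep]),
    median_diff_pct = stats::median(d_pct),
    p_value = rank_test((x - y)[keep])$p_value,
    pair_means = ((x + y) / 2)[keep],
    pair_diff_pct = d_pct
  ), class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n",
      "  mean difference ", sprintf("%+.1f", x$mean_diff_pct), " % +/- ",
      sprintf("%.1f", x$loa_halfwidth_pct), " % (1.96 SD)\n",
      "  median difference ", sprintf("%+.1f", x$median_diff_pct),
      " %, p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Method-comparison summary table
#'
#' Paired comparison of the 2D and hybrid methods against the 3D
#' reference, per region class: median difference (dose units and
#' percent of the pair mean), signed-rank p value, and Bland-Altman mean
#' difference and limits of agreement.  Differences are signed as
#' (method - reference), so negative values mean underestimation
#' relative to 3D.  Instances missing one of the two methods of a
#' comparison are dropped (a message reports how many).
#'
#' @param doses Data frame with columns `region` (region class),
#'   `instance` (cycle-region identifier), `method` and
#'   `dose_Gy_per_GBq` (e.g. row-bound [absorbed_dose()] results).
#' @param reference Reference method label (default `"3D"`).
#' @param methods Methods compared against the reference.
#' @return Data frame of class `comparison_table` with one row per
#'   region class and comparison.
#' @export
comparison_table <- function(doses, reference = "3D",
                             methods = c("2D", "hybrid")) {
  stopifnot(all(c("region", "instance", "method", "dose_Gy_per_GBq")
                %in% names(doses)))
  rows <- list()
  dropped <- 0L
  for (cl in unique(doses$region)) {
    sub <- doses[doses$region == cl, ]
    ref <- sub[sub$method == reference, ]
    for (m in methods) {
      tst <- sub[sub$method == m, ]
      common <- intersect(tst$instance, ref$instance)
      dropped <- dropped + length(union(tst$instance, ref$instance)) -
        length(common)
      if (length(common) == 0L) next
      x <- tst$dose_Gy_per_GBq[match(common, tst$instance)]
      y <- ref$dose_Gy_per_GBq[match(common, ref$instance)]
      if (length(common) == 1L) {
        # a single pair has no spread: report its difference, no test
        rows[[length(rows) + 1L]] <- data.frame(
          region = cl, comparison = paste(m, "vs", reference), n = 1L,
          median_diff_Gy_per_GBq = x - y,
          median_diff_pct = relative_difference(x, y),
          p_value = NA_real_, mean_diff_pct = relative_difference(x, y),
          loa_halfwidth_pct = NA_real_, stringsAsFactors = FALSE)
        next
      }
      ba <- bland_altman(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        region = cl, comparison = paste(m, "vs", reference),
        n = ba$n,
        median_diff_Gy_per_GBq = ba$median_diff_abs,
        median_diff_pct = ba$median_diff_pct,
        p_value = ba$p_value,
        mean_diff_pct = ba$mean_diff_pct,
        loa_halfwidth_pct = ba$loa_halfwidth_pct,
        stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0L) {
    message(dropped, " unmatched instance(s) dropped from the comparison")
  }
  if (length(rows) == 0L) {
    stop("no region class with at least two matched instance pairs")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}
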