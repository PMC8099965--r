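#' Run the full dosimetry pipeline on a digital phantom
#'
#' Executes the requested dosimetry methods end to end: simulation of
#' the planar and/or SPECT studies, quantification (2D conjugate-view
#' chain, 3D VOI chain), region-class aggregation (e.g. both kidneys
#' into one `kidneys` region), mono-exponential fitting, piecewise TIA
#' integration and dose conversion, plus the analytic ground truth.
#' The 3D method uses all SPECT acquisitions; the hybrid method uses the
#' planar kinetics rescaled by the SPECT activity of the anchor day.
#'
#' @param x A [phantom_spec()] or [build_phantom()] result.
#' @param methods Subset of `c("2D", "3D", "hybrid")`.
#' @param times_h Acquisition times, hours.
#' @param anchor_day Index of the SPECT used by the hybrid method (1 or
#'   2).
#' @param camera A [camera_config()].
#' @param rc Recovery-coefficient table for the 3D chain; `NULL` uses
#'   the blur-matched [measure_recovery_curve()].
#' @param dose_factors A [dose_factor_table()].
#' @param noise Poisson counting noise in the simulated studies.
#' @param psf_sigma_mm SPECT PSF sigma, mm.
#' @param planar_study,spect_study Optional pre-simulated studies; `NULL`
#'   simulates from the phantom, `NA` marks the modality unavailable
#'   (an error if a requested method needs it).
#' @param tail,first_interval Passed to [integrate_tia()].
#' @param out_dir Optional output directory: dose and comparison tables
#'   are written as CSV together with a provenance log (YAML).
#' @return List of class `pipeline_result` with `doses` (data frame over
#'   regions and methods), `tacs`, `truth` ([true_absorbed_dose()]),
#'   `comparison` (per-region differences vs 3D when available) and
#'   `provenance`.
#' @export
run_pipeline <- function(x, methods = c("2D", "3D", "hybrid"),
                         times_h = c(24, 48, 96), anchor_day = 1L,
                         camera = camera_config(), rc = NULL,
                         dose_factors = dose_factor_table_default(),
                         noise = FALSE, psf_sigma_mm = 2.55,
                         planar_study = NULL, spect_study = NULL,
                         tail = "physical", first_interval = "constant",
                         out_dir = NULL) {
  stopifnot(all(methods %in% c("2D", "3D", "hybrid")),
            length(methods) >= 1L, anchor_day %in% c(1L, 2L))
  phantom <- if (inherits(x, "phantom_spec")) build_phantom(x) else x
  stopifnot(inherits(phantom, "phantom"))

  need_planar <- any(methods %in% c("2D", "hybrid"))
  need_spect <- any(methods %in% c("3D", "hybrid"))
  unavailable <- function(s) length(s) == 1L && !is.list(s) && is.na(s)
  if (need_planar && unavailable(planar_study)) {
    stop("methods ", paste(intersect(methods, c("2D", "hybrid")),
                           collapse = "/"),
         " require a planar study, but none is available")
  }
  if (need_spect && unavailable(spect_study)) {
    stop("methods ", paste(intersect(methods, c("3D", "hybrid")),
                           collapse = "/"),
         " require a SPECT study, but none is available")
  }
  if (need_planar && is.null(planar_study)) {
    planar_study <- simulate_planar_study(phantom, times_h, camera,
                                          noise = noise)
  }
  if (need_spect && is.null(spect_study)) {
    spect_study <- simulate_spect_study(phantom, times_h, psf_sigma_mm,
                                        camera, noise = noise)
  }

  org <- phantom$organs
  classes <- unique(org$region_class)
  decay <- physical_decay()
  aggregate_by_class <- function(tacs, method) {
    out <- list()
    for (cl in classes) {
      nms <- intersect(org$name[org$region_class == cl], names(tacs))
      if (length(nms) == 0L) next
      acts <- Reduce(`+`, lapply(tacs[nms],
                                 function(tc) tc$activities_MBq))
      # a partially measured pair (e.g. one excluded kidney) is
      # extrapolated via the CT-volume fraction, assuming homogeneous
      # uptake across the class (contralateral-kidney doubling rule)
      frac <- sum(org$volume_ml[org$name %in% nms]) /
        sum(org$volume_ml[org$region_class == cl])
      out[[cl]] <- tac(tacs[[nms[1L]]]$times_h, acts / frac,
                       method = method, region = cl)
    }
    out
  }

  tacs <- list()
  if (need_planar) {
    ps <- if (length(planar_study$times_h) > 1L) {
      coregister_planar(planar_study)
    } else {
      planar_study
    }
    rois <- make_planar_rois(phantom)
    tac_2d_organ <- planar_activity_series(ps, rois,
                                           mu_cm = phantom$mu_208_cm)
    tacs[["2D"]] <- aggregate_by_class(tac_2d_organ, "2D")
  }
  if (need_spect) {
    vois <- make_boundary_vois(spect_study)
    tac_3d_organ <- spect_activity_series(spect_study, vois, rc = rc)
    tacs[["3D"]] <- aggregate_by_class(tac_3d_organ, "3D")
  }
  if ("hybrid" %in% methods) {
    t_anchor <- times_h[anchor_day]
    tacs[["hybrid"]] <- lapply(
      intersect(names(tacs[["2D"]]), names(tacs[["3D"]])),
      function(cl) {
        anchor_act <- tacs[["3D"]][[cl]]$activities_MBq[anchor_day]
        hybrid_rescale(tacs[["2D"]][[cl]], anchor_act, t_anchor)
      })
    names(tacs[["hybrid"]]) <-
      intersect(names(tacs[["2D"]]), names(tacs[["3D"]]))
  }

  masses <- vapply(classes, function(cl) {
    sub <- org[org$region_class == cl, ]
    sum(organ_mass(sub$volume_ml, sub$density_g_ml))
  }, numeric(1))
  names(masses) <- classes

  dose_rows <- list()
  for (m in intersect(methods, names(tacs))) {
    for (cl in names(tacs[[m]])) {
      tc <- tacs[[m]][[cl]]
      fit <- fit_monoexponential(tc)
      tia <- integrate_tia(tc, fit, decay, tail = tail,
                           first_interval = first_interval)
      s <- mass_scaled_s_value(dose_factors, cl, masses[[cl]])
      dose_rows[[length(dose_rows) + 1L]] <-
        absorbed_dose(tia, s, phantom$administered_GBq, region = cl,
                      method = m, mass_g = masses[[cl]])
    }
  }
  doses <- do.call(rbind, dose_rows)

  # single-phantom comparison: per-region relative differences vs 3D
  # (cohort-level agreement statistics come from analyze_cohort)
  comparison <- NULL
  if ("3D" %in% methods && length(intersect(methods,
                                            c("2D", "hybrid"))) > 0L) {
    ref <- doses[doses$method == "3D", ]
    rows <- list()
    for (m in setdiff(methods, "3D")) {
      tst <- doses[doses$method == m, ]
      common <- intersect(tst$region, ref$region)
      if (length(common) == 0L) next
      x <- tst$dose_Gy_per_GBq[match(common, tst$region)]
      y <- ref$dose_Gy_per_GBq[match(common, ref$region)]
      rows[[length(rows) + 1L]] <- data.frame(
        region = common, comparison = paste(m, "vs 3D"),
        diff_pct = relative_difference(x, y), stringsAsFactors = FALSE)
    }
    comparison <- do.call(rbind, rows)
  }

  truth <- true_absorbed_dose(phantom, dose_factors)
  provenance <- list(
    package = "ludosim",
    version = as.character(utils::packageVersion("ludosim")),
    seed = phantom$seed, times_h = times_h, methods = methods,
    anchor_day = anchor_day, psf_sigma_mm = psf_sigma_mm,
    noise = noise, tail = tail, first_interval = first_interval,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- structure(list(doses = doses, tacs = tacs, truth = truth,
                           comparison = comparison,
                           provenance = provenance),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(doses, file.path(out_dir, "doses.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
    }
    yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Dosimetry pipeline result\n")
  print(x$doses[, c("region", "method", "tia_MBqh", "dose_Gy",
                    "dose_Gy_per_GBq")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Measurement-model parameters of the cohort emulator
#'
#' Defaults of the patient-cohort generator.  Planar quantification
#' carries, per cycle-region instance, a multiplicative bias (lognormal;
#' organ overlap and background mis-specification act multiplicatively
#' on conjugate-view estimates and persist across the time points of a
#' cycle) plus independent per-time-point noise; SPECT quantification is
#' unbiased with smaller per-time-point noise.  The hybrid method shares
#' the anchor-day SPECT with the 3D method, as in the clinical workflow.
#' Region-level uptake fractions, effective half-lives and volumes are
#' representative of Lu-177 PSMA therapy.
#'
#' @param planar_bias_log_mean Named per-class mean of the log planar
#'   bias (negative = underestimation).
#' @param planar_bias_log_sd SD of the log planar bias across instances.
#' @param planar_noise_log_sd Per-time-point planar log noise.
#' @param spect_noise_log_sd Per-time-point SPECT log noise.
#' @param teff_h Named per-class effective half-life medians, hours.
#' @param teff_log_sd Log SD of effective half-lives across patients.
#' @param uptake_frac Named per-class median uptake fraction of the
#'   administered activity at t = 0 (per instance).
#' @param uptake_log_sd Log SD of uptake fractions.
#' @param volume_ml Named per-class median region volumes, ml.
#' @param volume_log_sd Log SD of volumes.
#' @param lesion_ineligible_2d_prob Probability that a bone metastasis
#'   overlaps high-uptake tissue and is excluded from planar analysis.
#' @param administered_GBq_mean,administered_GBq_sd,administered_GBq_range
#'   Administered activity distribution per cycle (truncated normal).
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(
    planar_bias_log_mean = c(kidneys = -0.17, liver = -0.08,
                             parotid = -0.10, submandibular = -0.08,
                             bone_met = -0.10),
    planar_bias_log_sd = 0.20,
    planar_noise_log_sd = 0.04,
    spect_noise_log_sd = 0.05,
    teff_h = c(kidneys = 50, liver = 70, parotid = 40,
               submandibular = 40, bone_met = 70),
    teff_log_sd = 0.25,
    uptake_frac = c(kidneys = 0.02, liver = 0.025, parotid = 0.003,
                    submandibular = 0.0015, bone_met = 0.0015),
    uptake_log_sd = 0.4,
    volume_ml = c(kidneys = 300, liver = 1500, parotid = 25,
                  submandibular = 10, bone_met = 8),
    volume_log_sd = 0.25,
    lesion_ineligible_2d_prob = 0.2,
    administered_GBq_mean = 6.4, administered_GBq_sd = 1.6,
    administered_GBq_range = c(3, 10.9)) {
  structure(as.list(environment()), class = "cohort_params")
}

#' Generate a synthetic patient cohort
#'
#' Emulates the scale and structure of a clinical Lu-177 PSMA dosimetry
#' study: `n_patients` patients contributing `n_cycles` therapy cycles
#' (every patient at least one), split into two groups of approximately
#' equal size receiving either an abdominal SPECT (kidneys, liver) or a
#' head-and-neck SPECT (parotid and submandibular glands, one instance
#' per gland side) — each patient has exactly one SPECT region class
#' set.  Bone metastases (about 1.3 per cycle) are quantified in either
#' group; a fraction overlaps high-uptake tissue and is excluded from
#' planar analysis.
#'
#' Each cycle-region instance carries ground-truth mono-exponential
#' kinetics and measured time-activity curves for the 2D, 3D and hybrid
#' methods according to the [cohort_params()] measurement model.
#'
#' @param n_patients Number of patients.
#' @param n_cycles Total number of cycles (>= `n_patients`).
#' @param seed Integer seed.
#' @param times_h Acquisition times, hours.
#' @param anchor_day Anchor SPECT index for the hybrid method (1 or 2).
#' @param params A [cohort_params()].
#' @return Object of class `dosimetry_cohort`: list of instances with
#'   metadata, truth, and per-method [tac()]s.
#' @export
generate_fixture_cohort <- function(n_patients = 24L, n_cycles = 65L,
                                    seed = 1L, times_h = c(24, 48, 96),
                                    anchor_day = 1L,
                                    params = cohort_params()) {
  stopifnot(n_patients >= 1L, n_cycles >= n_patients,
            anchor_day %in% c(1L, 2L))
  set.seed(seed)
  p <- params
  lp <- lu177_lambda()

  groups <- rep(c("abdomen", "head_neck"), length.out = n_patients)
  groups <- sample(groups)
  extra <- if (n_cycles > n_patients) {
    table(factor(sample.int(n_patients, n_cycles - n_patients,
                            replace = TRUE), levels = seq_len(n_patients)))
  } else {
    rep(0L, n_patients)
  }
  cycles_per_patient <- 1L + as.integer(extra)

  rlnorm_med <- function(n, median, log_sd) {
    median * exp(stats::rnorm(n, 0, log_sd))
  }
  instances <- list()
  iid <- 0L
  for (pat in seq_len(n_patients)) {
    region_set <- if (groups[pat] == "abdomen") {
      c("kidneys", "liver")
    } else {
      c("parotid", "parotid", "submandibular", "submandibular")
    }
    n_mets <- 1L + stats::rbinom(1L, 1L, 0.3)
    region_set <- c(region_set, rep("bone_met", n_mets))
    # patient-level biology, shared across that patient's cycles
    teff <- rlnorm_med(length(region_set), p$teff_h[region_set],
                       p$teff_log_sd)
    vol <- rlnorm_med(length(region_set), p$volume_ml[region_set],
                      p$volume_log_sd)
    upt <- rlnorm_med(length(region_set), p$uptake_frac[region_set],
                      p$uptake_log_sd)
    ineligible <- region_set == "bone_met" &
      stats::runif(length(region_set)) < p$lesion_ineligible_2d_prob
    for (cy in seq_len(cycles_per_patient[pat])) {
      adm <- stats::rnorm(1L, p$administered_GBq_mean,
                          p$administered_GBq_sd)
      adm <- min(max(adm, p$administered_GBq_range[1L]),
                 p$administered_GBq_range[2L])
      for (r in seq_along(region_set)) {
        iid <- iid + 1L
        cl <- region_set[r]
        lambda_eff <- max(log(2) / teff[r], lp)
        a0 <- upt[r] * adm * 1000
        a_true <- a0 * exp(-lambda_eff * times_h)
        a_3d <- a_true * exp(stats::rnorm(length(times_h), 0,
                                          p$spect_noise_log_sd))
        bias <- stats::rnorm(1L, p$planar_bias_log_mean[[cl]],
                             p$planar_bias_log_sd)
        a_2d <- a_true * exp(bias + stats::rnorm(length(times_h), 0,
                                                 p$planar_noise_log_sd))
        tac_3d <- tac(times_h, a_3d, method = "3D", region = cl)
        tac_2d <- if (ineligible[r]) NULL else {
          tac(times_h, a_2d, method = "2D", region = cl)
        }
        tac_hy <- if (ineligible[r]) NULL else {
          hybrid_rescale(tac_2d, a_3d[anchor_day], times_h[anchor_day])
        }
        instances[[iid]] <- list(
          instance = iid, patient = pat, cycle = cy, group = groups[pat],
          region = cl, administered_GBq = adm, volume_ml = vol[r],
          A0_MBq = a0, lambda_eff = lambda_eff,
          tia_true_MBqh = a0 / lambda_eff,
          eligible_2d = !ineligible[r],
          tac_2d = tac_2d, tac_3d = tac_3d, tac_hybrid = tac_hy)
      }
    }
  }
  structure(list(instances = instances, n_patients = n_patients,
                 n_cycles = n_cycles, seed = seed, times_h = times_h,
                 anchor_day = anchor_day, params = p),
            class = "dosimetry_cohort")
}

#' @export
print.dosimetry_cohort <- function(x, ...) {
  regions <- vapply(x$instances, `[[`, character(1), "region")
  cat("Synthetic dosimetry cohort: ", x$n_patients, " patients, ",
      x$n_cycles, " cycles, ", length(x$instances),
      " region instances\n", sep = "")
  print(table(regions))
  invisible(x)
}

#' Dose estimation and method comparison on a synthetic cohort
#'
#' Runs the kinetics and dose chain (mono-exponential fit, piecewise TIA,
#' mass-scaled dose factors) per instance and method, then compares 2D
#' and hybrid against the 3D reference per region class.
#'
#' @param cohort A [generate_fixture_cohort()] result.
#' @param dose_factors A [dose_factor_table()].
#' @param tail,first_interval Passed to [integrate_tia()].
#' @return List of class `cohort_report` with `doses` (long data frame),
#'   `comparison` ([comparison_table()]) and `truth` (per-instance true
#'   dose).
#' @export
analyze_cohort <- function(cohort,
                           dose_factors = dose_factor_table_default(),
                           tail = "physical",
                           first_interval = "constant") {
  stopifnot(inherits(cohort, "dosimetry_cohort"))
  decay <- physical_decay()
  rows <- list()
  truth_rows <- list()
  for (inst in cohort$instances) {
    mass <- organ_mass(inst$volume_ml)
    s <- mass_scaled_s_value(dose_factors, inst$region, mass)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      instance = inst$instance, region = inst$region,
      dose_Gy_per_GBq = inst$tia_true_MBqh * s / inst$administered_GBq,
      stringsAsFactors = FALSE)
    for (m in c("2D", "3D", "hybrid")) {
      tc <- switch(m, "2D" = inst$tac_2d, "3D" = inst$tac_3d,
                   "hybrid" = inst$tac_hybrid)
      if (is.null(tc)) next
      fit <- fit_monoexponential(tc)
      tia <- integrate_tia(tc, fit, decay, tail = tail,
                           first_interval = first_interval)
      d <- absorbed_dose(tia, s, inst$administered_GBq,
                         region = inst$region, method = m, mass_g = mass)
      d$instance <- inst$instance
      rows[[length(rows) + 1L]] <- d
    }
  }
  doses <- do.call(rbind, rows)
  comparison <- comparison_table(doses)
  structure(list(doses = doses, comparison = comparison,
                 truth = do.call(rbind, truth_rows)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort method comparison (reference: 3D)\n")
  print(x$comparison, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Is hybrid dosimetry more consistent with 3D than planar dosimetry?
#'
#' Checks, per region class, whether the hybrid-vs-3D comparison shows a
#' strictly smaller absolute median percent difference and strictly
#' narrower limits of agreement than 2D-vs-3D.
#'
#' @param comparison A [comparison_table()] result.
#' @return Data frame with per-region logicals `median_smaller` and
#'   `loa_narrower`, plus attribute `all_regions` (TRUE when the
#'   ordering holds everywhere).
#' @export
hybrid_consistency <- function(comparison) {
  cls <- unique(comparison$region)
  rows <- lapply(cls, function(cl) {
    c2 <- comparison[comparison$region == cl &
                       comparison$comparison == "2D vs 3D", ]
    ch <- comparison[comparison$region == cl &
                       comparison$comparison == "hybrid vs 3D", ]
    if (nrow(c2) == 0L || nrow(ch) == 0L) return(NULL)
    data.frame(region = cl,
               median_smaller = abs(ch$median_diff_pct) <
                 abs(c2$median_diff_pct),
               loa_narrower = ch$loa_halfwidth_pct <
                 c2$loa_halfwidth_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_regions") <- all(out$median_smaller & out$loa_narrower)
  out
}
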