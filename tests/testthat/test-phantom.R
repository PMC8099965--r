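# Digital-phantom generator: geometry, kinetics, projections, blur.

test_that("voxelised organ volume matches the specification", {
  lam <- lu177_lambda()
  ph <- build_phantom(phantom_spec(
    organ_spec("kidney", 20, 100, lam, 5, 3, shape = "sphere"),
    grid_dim = c(48L, 48L, 48L)))
  vox_ml <- (ph$voxel_mm / 10)^3
  n_vox <- sum(ph$labels == 1L)
  expect_lt(abs(n_vox * vox_ml - 20), vox_ml + 1e-12)
  expect_equal(ph$organs$volume_ml, n_vox * vox_ml)
})

test_that("phantom construction is deterministic", {
  s <- reference_phantom_spec("physical", seed = 42L)
  expect_identical(build_phantom(s), build_phantom(s))
  st1 <- simulate_planar_study(build_phantom(s), noise = TRUE)
  st2 <- simulate_planar_study(build_phantom(s), noise = TRUE)
  expect_identical(st1, st2)
})

test_that("declared overlap produces the requested footprint sharing", {
  ph <- build_phantom(reference_phantom_spec("physical",
                                             overlap_fraction = 0.3))
  fp <- function(lab) apply(ph$labels == lab, c(1, 3), any)
  k <- ph$organs$label[ph$organs$name == "kidney_left"]
  l <- ph$organs$label[ph$organs$name == "liver"]
  shared <- sum(fp(k) & fp(l))
  frac <- shared / min(sum(fp(k)), sum(fp(l)))
  expect_lt(abs(frac - 0.3), 0.05)
  expect_equal(ph$organs$visible_fraction[ph$organs$name == "kidney_left"],
               1 - shared / sum(fp(k)))
})

test_that("undeclared footprint overlap raises a configuration error", {
  lam <- lu177_lambda()
  organs <- list(
    organ_spec("a", 50, 10, lam, 3, 2, center_xz_cm = c(0, 0)),
    organ_spec("b", 50, 10, lam, 10, 2, center_xz_cm = c(0, 0)))
  expect_error(build_phantom(phantom_spec(organs,
                                          grid_dim = c(48L, 48L, 48L))),
               "overlap_partner")
})

test_that("organ kinetics are conserved in total phantom activity", {
  ph <- build_phantom(reference_phantom_spec("biological"))
  for (t in c(0, 24, 96)) {
    expected <- sum(ph$organs$initial_uptake_MBq *
                      exp(-ph$organs$lambda_eff * t)) +
      ph$background_MBq_per_voxel *
      sum(ph$body & ph$labels == 0L) * exp(-ph$background_lambda_eff * t)
    expect_equal(sum(activity_at(ph, t)), expected, tolerance = 1e-12)
  }
})

test_that("anterior and posterior totals agree for a symmetric phantom", {
  # organ centred at mid-depth of the slab: both views see the same
  # attenuation path distribution
  lam <- lu177_lambda()
  org <- organ_spec("c", 20, 50, lam, depth_anterior_cm = 8.252,
                    thickness_cm = 4, shape = "sphere")
  ph <- build_phantom(phantom_spec(org, grid_dim = c(48L, 48L, 48L),
                                   body_thickness_cm = 20.504))
  st <- simulate_planar_study(ph, times_h = 24, vial_activity_MBq = 1e-9)
  expect_equal(sum(st$photopeak_ant[[1]]), sum(st$photopeak_post[[1]]),
               tolerance = 1e-2)
})

test_that("noiseless organ counts follow the decay law between scans", {
  # physical-decay phantom scanned at 24/48/96 h: counts ratio between
  # t1 and t3 equals exp(-lambda_phys * 72) after dwell normalisation
  st <- ref_planar_study()
  ph <- ref_phantom()
  fp <- apply(ph$labels ==
                ph$organs$label[ph$organs$name == "parotid_left"],
              c(1, 3), any)
  c1 <- sum(st$photopeak_ant[[1]][fp]) / st$dwell_s[1]
  c3 <- sum(st$photopeak_ant[[3]][fp]) / st$dwell_s[3]
  expect_equal(c3 / c1, exp(-lu177_lambda() * 72), tolerance = 1e-3)
})

test_that("conjugate product carries the slab attenuation factor", {
  # uniform slab of thickness d: sqrt(CA*CP) is reduced by exactly
  # exp(-mu*d/2) (up to source self-attenuation) relative to no
  # attenuation
  lam <- lu177_lambda()
  mk <- function(mu) {
    org <- organ_spec("s", 24.4, 10, lam, depth_anterior_cm = 3,
                      thickness_cm = 1.398, shape = "box")
    ph <- build_phantom(phantom_spec(org, grid_dim = c(48L, 48L, 48L),
                                     body_thickness_cm = 18.64,
                                     mu_208_cm = mu))
    st <- simulate_planar_study(ph, times_h = 24, scatter_fraction = 0)
    fp <- apply(ph$labels == 1L, c(1, 3), any)
    sqrt(sum(st$photopeak_ant[[1]][fp]) * sum(st$photopeak_post[[1]][fp]))
  }
  gm_mu <- mk(0.11)
  gm_0 <- mk(1e-9)
  d_cm <- 18.64
  t_cm <- 1.398
  x <- 0.11 * t_cm / 2
  expect_equal(gm_mu / gm_0, exp(-0.11 * d_cm / 2) * sinh(x) / x,
               tolerance = 1e-3)
})

test_that("geometric mean is proportional to activity without attenuation", {
  lam <- lu177_lambda()
  mk <- function(a0) {
    org <- organ_spec("s", 24.4, a0, lam, 3, 1.398, shape = "box")
    ph <- build_phantom(phantom_spec(org, grid_dim = c(48L, 48L, 48L),
                                     mu_208_cm = 1e-9))
    st <- simulate_planar_study(ph, times_h = 24, scatter_fraction = 0)
    fp <- apply(ph$labels == 1L, c(1, 3), any)
    sqrt(sum(st$photopeak_ant[[1]][fp]) * sum(st$photopeak_post[[1]][fp]))
  }
  expect_equal(mk(20) / mk(10), 2, tolerance = 1e-6)
})

test_that("SPECT blur preserves totals and is linear in activity", {
  st <- ref_spect_study()
  ph <- ref_phantom()
  # total counts conserved by the PSF convolution
  expect_equal(sum(st$volumes_cps[[1]]),
               sum(activity_at(ph, 24)) * st$camera$spect_sens_cps_per_MBq,
               tolerance = 1e-6)
  # doubling activity doubles VOI counts
  spec2 <- reference_phantom_spec("physical")
  spec2$organs <- lapply(spec2$organs, function(o) {
    o$initial_uptake_MBq <- 2 * o$initial_uptake_MBq; o
  })
  spec2$background_uptake_MBq_ml <- 2 * spec2$background_uptake_MBq_ml
  st2 <- simulate_spect_study(build_phantom(spec2), times_h = 24)
  voi <- ph$labels == ph$organs$label[ph$organs$name == "bone_met"]
  expect_equal(sum(st2$volumes_cps[[1]][voi]),
               2 * sum(st$volumes_cps[[1]][voi]), tolerance = 1e-9)
})

test_that("zero PSF gives unit recovery; calibrated PSF gives 0.85 at 20 ml", {
  sharp <- sphere_volume(20, sigma_mm = 0)
  expect_equal(sum(sharp$blurred[sharp$truth > 0]) / sum(sharp$truth), 1)
  sph <- sphere_volume(20)
  seg <- segment_voi_adaptive(sph$blurred, sph$boundary)
  rec <- sum(sph$blurred[seg$segmented]) / sum(sph$truth)
  expect_lt(abs(rec - 0.85), 0.03)
})

test_that("fixture blur reproduces the measured recovery curve", {
  rc <- ref_rc_curve()
  for (v in c(6, 10, 13, 20)) {
    sph <- sphere_volume(v)
    seg <- segment_voi_adaptive(sph$blurred, sph$boundary)
    rec <- sum(sph$blurred[seg$segmented]) / sum(sph$truth)
    expect_lt(abs(rec - recovery_coefficient(seg$volume_ml, rc)), 0.03)
  }
})

test_that("analytic ground truth follows TIA = A0 / lambda", {
  lam <- lu177_lambda()
  ph1 <- build_phantom(phantom_spec(
    organ_spec("m", 6, 100, 0.01, 5, 2.3, region_class = "bone_met",
               shape = "sphere"),
    grid_dim = c(32L, 48L, 32L)))
  gt <- true_absorbed_dose(ph1)
  expect_equal(gt$tia_MBqh, 100 / 0.01, tolerance = 1e-12)
  # pure physical decay: TIA = A0 * 230.15 h
  ph2 <- build_phantom(phantom_spec(
    organ_spec("m", 6, 100, lam, 5, 2.3, region_class = "bone_met",
               shape = "sphere"),
    grid_dim = c(32L, 48L, 32L)))
  expect_equal(true_absorbed_dose(ph2)$tia_MBqh, 100 / lam,
               tolerance = 1e-12)
  expect_equal(100 / lam, 100 * 230.1503, tolerance = 1e-6)
  # dose scales inversely with mass for fixed TIA (self-dose model)
  s6 <- mass_scaled_s_value(dose_factor_table_default(), "bone_met", 6)
  s12 <- mass_scaled_s_value(dose_factor_table_default(), "bone_met", 12)
  expect_equal(s6 / s12, 2)
})

test_that("empty or invalid acquisition times are rejected", {
  ph <- ref_phantom()
  expect_error(simulate_planar_study(ph, times_h = numeric(0)), "empty")
  expect_error(simulate_planar_study(ph, times_h = c(48, 24)),
               "increasing")
})
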