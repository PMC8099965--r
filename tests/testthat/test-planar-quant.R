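# 2D conjugate-view quantification chain.

test_that("co-registration recovers known shifts", {
  ph <- ref_phantom()
  shifts <- list(c(0L, 0L), c(3L, -2L), c(-4L, 5L))
  st <- simulate_planar_study(ph, shifts = shifts)
  reg <- coregister_planar(st)
  expect_identical(reg$registration_shifts[[1]], c(0L, 0L))
  expect_identical(reg$registration_shifts[[2]], c(3L, -2L))
  expect_identical(reg$registration_shifts[[3]], c(-4L, 5L))
  # with counting noise the shift is still recovered within one pixel
  stn <- simulate_planar_study(ph, noise = TRUE, shifts = shifts)
  regn <- coregister_planar(stn)
  expect_true(all(abs(regn$registration_shifts[[2]] - c(3L, -2L)) <= 1L))
})

test_that("dual-energy-window correction implements the width ratio", {
  pk <- matrix(1000, 1, 1); sc <- matrix(100, 1, 1)
  expect_equal(scatter_correct(pk, sc)[1, 1], 1000 - 100 * 41.6 / 28.05,
               tolerance = 1e-12)
  expect_equal(scatter_correct(pk, sc)[1, 1], 851.6934, tolerance = 1e-4)
  expect_equal(scatter_correct(pk, matrix(0, 1, 1)), pk)
  expect_error(scatter_correct(-pk, sc), "non-negative")
})

test_that("scatter correction restores scatter-free counts on fixtures", {
  ph <- ref_phantom()
  st <- simulate_planar_study(ph, scatter_fraction = 0.3)
  st0 <- simulate_planar_study(ph, scatter_fraction = 0)
  corr <- scatter_correct(st$photopeak_ant[[1]], st$scatter_ant[[1]])
  expect_lt(max(abs(corr - st0$photopeak_ant[[1]])) /
              max(st0$photopeak_ant[[1]]), 0.02)
})

test_that("threshold segmentation is exact for uniform organs and
           monotone in the threshold", {
  ant <- matrix(0, 20, 20); ant[5:10, 5:10] <- 100
  post <- ant
  boundary <- matrix(FALSE, 20, 20); boundary[3:12, 3:12] <- TRUE
  mask <- threshold_segment(ant, post, boundary, 0.5)
  expect_identical(which(mask), which(ant == 100))
  # shrinking with increasing fraction
  ant2 <- ant; ant2[5, 5:10] <- 30
  m_lo <- threshold_segment(ant2, ant2, boundary, 0.2)
  m_hi <- threshold_segment(ant2, ant2, boundary, 0.6)
  expect_true(all(which(m_hi) %in% which(m_lo)))
  expect_lt(sum(m_hi), sum(m_lo))
  expect_error(threshold_segment(ant, post, boundary & FALSE), "empty")
})

test_that("blurred disc segments to its true area within 10%", {
  n <- 64
  idx <- seq_len(n) - (n + 1) / 2
  d2 <- outer(idx^2, idx^2, `+`)
  disc <- 0 + (d2 <= 8^2)
  blurred <- ludosim:::gauss_blur(disc, 1.5, 1)
  boundary <- d2 <= 14^2
  mask <- threshold_segment(blurred, blurred, boundary, 0.5)
  expect_lt(abs(sum(mask) - sum(disc)) / sum(disc), 0.10)
})

test_that("background correction arithmetic and floor", {
  expect_equal(background_correct(10000, 50, 50, 100), 9900)
  expect_equal(background_correct(100, 0, 10, 50), 100)
  expect_equal(background_correct(10, 1000, 10, 50), 0)
})

test_that("conjugate-view formula limits and self-attenuation factor", {
  expect_equal(conjugate_view_activity(100, 400, 1, 0, 0.11, 1), 200)
  x <- 0.11 * 4 / 2
  f <- x / sinh(x)
  expect_equal(f, 0.991979, tolerance = 1e-6)
  expect_equal(conjugate_view_activity(100, 100, 1, 4, 0.11, 1), 100 * f)
  expect_error(conjugate_view_activity(1, 1, 0), "positive")
})

test_that("partial-organ extrapolation divides by the visible fraction", {
  expect_equal(partial_organ_extrapolate(4500, 0.75), 6000)
  expect_equal(partial_organ_extrapolate(123, 1), 123)
  expect_error(partial_organ_extrapolate(1, 0))
})

test_that("slab phantom activity is recovered within 1% at all times", {
  ph <- slab_phantom(background = 0)
  st <- simulate_planar_study(ph)
  tacs <- planar_activity_series(st, make_planar_rois(ph))
  lam <- lu177_lambda()
  for (nm in names(tacs)) {
    a0 <- ph$organs$initial_uptake_MBq[ph$organs$name == nm]
    truth <- a0 * exp(-lam * st$times_h)
    expect_lt(max(abs(tacs[[nm]]$activities_MBq / truth - 1)), 0.01)
  }
})

test_that("full 2D chain with background and scatter recovers within 2%", {
  ph <- slab_phantom(background = 0.003)
  st <- simulate_planar_study(ph)
  tacs <- planar_activity_series(st, make_planar_rois(ph))
  lam <- lu177_lambda()
  for (nm in names(tacs)) {
    a0 <- ph$organs$initial_uptake_MBq[ph$organs$name == nm]
    truth <- a0 * exp(-lam * st$times_h)
    expect_lt(max(abs(tacs[[nm]]$activities_MBq / truth - 1)), 0.02)
  }
})

test_that("conjugate-view estimate is invariant to organ depth", {
  lam <- lu177_lambda()
  est_at_depth <- function(depth) {
    org <- organ_spec("s", 119.0, 60, lam, depth_anterior_cm = depth,
                      thickness_cm = 2.796, shape = "box")
    ph <- build_phantom(phantom_spec(org, grid_dim = c(64L, 48L, 96L)))
    st <- simulate_planar_study(ph, times_h = 24)
    planar_activity_series(st, make_planar_rois(ph))$s$activities_MBq
  }
  shallow <- est_at_depth(3)
  deep <- est_at_depth(13)
  expect_lt(abs(shallow / deep - 1), 0.005)
})

test_that("overlapped organ is recovered by footprint extrapolation", {
  # box organs project uniformly, so the visible part is exactly
  # representative of the whole organ (the homogeneous-uptake premise of
  # the extrapolation rule)
  lam <- lu177_lambda()
  organs <- list(
    organ_spec("liver", 236.5, 100, lam, depth_anterior_cm = 4,
               thickness_cm = 5.592, region_class = "liver",
               center_xz_cm = c(0, -4), shape = "box"),
    organ_spec("kidney", 119.0, 60, lam, depth_anterior_cm = 12,
               thickness_cm = 2.796, region_class = "kidneys",
               center_xz_cm = c(0, 8), shape = "box",
               overlap_partner = "liver", overlap_fraction = 0.3))
  ph <- build_phantom(phantom_spec(organs, grid_dim = c(64L, 48L, 96L)))
  vis <- ph$organs$visible_fraction[ph$organs$name == "kidney"]
  expect_lt(abs((1 - vis) - 0.3), 0.05)
  st <- simulate_planar_study(ph)
  tacs <- planar_activity_series(st, make_planar_rois(ph))
  truth <- 60 * exp(-lam * st$times_h)
  expect_lt(max(abs(tacs$kidney$activities_MBq / truth - 1)), 0.05)
})

test_that("bone metastases overlapping high uptake are excluded from 2D", {
  lam <- lu177_lambda()
  organs <- list(
    organ_spec("liver", 236.5, 100, lam, 4, 5.592,
               region_class = "liver", center_xz_cm = c(0, 0),
               shape = "box"),
    organ_spec("met", 6, 5, lam, depth_anterior_cm = 12,
               thickness_cm = 2.3, region_class = "bone_met",
               center_xz_cm = c(0, 8), shape = "sphere",
               overlap_partner = "liver", overlap_fraction = 0.5))
  ph <- build_phantom(phantom_spec(organs, grid_dim = c(64L, 48L, 96L)))
  rois <- make_planar_rois(ph)
  expect_false(rois$met$eligible_2d)
  st <- simulate_planar_study(ph)
  tacs <- planar_activity_series(st, rois)
  expect_false("met" %in% names(tacs))
  expect_true("liver" %in% names(tacs))
})
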