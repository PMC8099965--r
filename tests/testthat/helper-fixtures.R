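# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# reference whole-body phantom with physical-decay kinetics (the digital
# analogue of a physical phantom measurement)
ref_phantom <- function() {
  fixture("ref_phantom",
          function() build_phantom(reference_phantom_spec("physical")))
}

ref_spect_study <- function() {
  fixture("ref_spect", function() simulate_spect_study(ref_phantom()))
}

ref_planar_study <- function() {
  fixture("ref_planar", function() simulate_planar_study(ref_phantom()))
}

# blur-matched recovery curve for the default PSF
ref_rc_curve <- function() {
  fixture("ref_rc", function() measure_recovery_curve())
}

# slab phantom: box organs project uniformly, so the conjugate-view
# chain has no segmentation edge loss; organ dimensions land on voxel
# multiples
slab_phantom <- function(background = 0, mu = 0.11) {
  lam <- lu177_lambda()
  organs <- list(
    organ_spec("slab_kidney", 119.0, 60, lam, depth_anterior_cm = 12,
               thickness_cm = 2.796, region_class = "kidneys",
               center_xz_cm = c(0, -12), shape = "box"),
    organ_spec("slab_liver", 236.5, 100, lam, depth_anterior_cm = 4,
               thickness_cm = 5.592, region_class = "liver",
               center_xz_cm = c(0, 0), shape = "box"),
    organ_spec("slab_met", 24.4, 12, lam, depth_anterior_cm = 9,
               thickness_cm = 1.398, region_class = "bone_met",
               center_xz_cm = c(0, 12), shape = "box"))
  build_phantom(phantom_spec(organs, grid_dim = c(64L, 48L, 96L),
                             background_uptake_MBq_ml = background,
                             mu_208_cm = mu))
}

# single blurred sphere on a small grid, for segmentation/RC fixtures
sphere_volume <- function(vol_ml, sigma_mm = 2.55, n = 40L,
                          voxel_mm = 4.66) {
  vox_ml <- (voxel_mm / 10)^3
  cx <- (n + 1) / 2
  idx <- (seq_len(n) - cx) * voxel_mm
  d2 <- outer(outer(idx^2, idx^2, `+`), idx^2, `+`)
  truth <- array(0, c(n, n, n))
  truth[order(d2)[seq_len(round(vol_ml / vox_ml))]] <- 1
  blurred <- if (sigma_mm > 0) {
    ludosim:::gauss_blur(truth, sigma_mm, voxel_mm)
  } else {
    truth
  }
  list(truth = truth, blurred = blurred,
       boundary = ludosim:::dilate_mask(truth > 0, 3L))
}
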