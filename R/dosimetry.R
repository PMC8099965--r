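#' Organ mass from volume and density
#'
#' @param volume_ml Volume delineated from CT, ml.
#' @param density_g_ml Tissue density, g/ml.
#' @return Mass in g.
#' @export
organ_mass <- function(volume_ml, density_g_ml = 1.05) {
  stopifnot(all(volume_ml > 0), all(density_g_ml > 0))
  volume_ml * density_g_ml
}

# S-value of the local-deposition sphere model at mass m (g):
# Delta_e [MeV] * 1.602e-13 J/MeV * 3.6e9 decays per MBq h / (m/1000 kg)
.s_local <- function(mass_g, delta_e_MeV = lu177_delta_electron_MeV()) {
  delta_e_MeV * 1.602e-13 * 3.6e9 / (mass_g / 1000)
}

#' Dose-factor table
#'
#' Per-region dose factors (S values, Gy per MBq h) at a reference mass,
#' with the model used for each region: `reference_organ` for organs with
#' phantom-based reference S values (kidneys, liver) and `sphere` for
#' tissues treated as unit-density spheres of their measured mass
#' (salivary glands, bone metastases).  Patient-specific mass adjustment
#' scales the electron self-dose as `m_ref / m`; with the default photon
#' self-dose fraction `phi = 0` (local electron deposition — appropriate
#' for the beta-dominated dose of Lu-177) the photon term vanishes and
#' the whole S value scales inversely with mass.
#'
#' The shipped default [dose_factor_table_default()] derives every
#' reference S value from the local-deposition model at the reference
#' mass; reference S values from phantom Monte-Carlo codes can be
#' supplied instead via this constructor.
#'
#' @param region Region-class labels.
#' @param model `"reference_organ"` or `"sphere"` per region.
#' @param m_ref_g Reference masses, g.
#' @param s_ref_Gy_per_MBqh Reference S values; default computes the
#'   local-deposition value at `m_ref_g`.
#' @param delta_e_MeV Mean electron energy per decay, MeV.
#' @param phi Photon self-dose fraction in [0, 1).
#' @return Object of class `dose_factor_table` (a data frame).
#' @export
dose_factor_table <- function(region, model, m_ref_g,
                              s_ref_Gy_per_MBqh = .s_local(m_ref_g,
                                                           delta_e_MeV),
                              delta_e_MeV = lu177_delta_electron_MeV(),
                              phi = 0) {
  stopifnot(length(region) == length(model),
            length(region) == length(m_ref_g),
            all(model %in% c("reference_organ", "sphere")),
            all(m_ref_g > 0), all(s_ref_Gy_per_MBqh > 0),
            all(phi >= 0), all(phi < 1))
  out <- data.frame(region = region, model = model, m_ref_g = m_ref_g,
                    s_ref_Gy_per_MBqh = s_ref_Gy_per_MBqh,
                    delta_e_MeV = delta_e_MeV,
                    phi = rep_len(phi, length(region)),
                    stringsAsFactors = FALSE)
  class(out) <- c("dose_factor_table", "data.frame")
  out
}

#' @rdname dose_factor_table
#' @export
dose_factor_table_default <- function() {
  dose_factor_table(
    region = c("kidneys", "liver", "parotid", "submandibular", "bone_met"),
    model = c("reference_organ", "reference_organ", "sphere", "sphere",
              "sphere"),
    m_ref_g = c(310, 1800, 25, 10, 6)
  )
}

#' Mass-scaled S value for a region
#'
#' The electron self-dose component of the reference S value scales with
#' the inverse of the patient-specific mass, `S_ref * m_ref / m`; the
#' photon component (fraction `phi` of the reference S value) scales the
#' same way under the local-deposition approximation used here.
#'
#' @param table A [dose_factor_table()].
#' @param region Region-class label (must be present in the table).
#' @param mass_g Patient-specific mass, g (> 0).
#' @return S value in Gy per MBq h.
#' @export
mass_scaled_s_value <- function(table, region, mass_g) {
  stopifnot(inherits(table, "dose_factor_table"), mass_g > 0)
  i <- match(region, table$region)
  if (is.na(i)) {
    stop("region '", region, "' not present in the dose-factor table")
  }
  table$s_ref_Gy_per_MBqh[i] * table$m_ref_g[i] / mass_g
}

#' Absorbed dose from time-integrated activity
#'
#' `D = TIA * S`; the dose per administered activity is `D` divided by
#' the administered activity in GBq.
#'
#' @param tia_MBqh Time-integrated activity, MBq h.
#' @param s_value_Gy_per_MBqh S value, Gy per MBq h.
#' @param administered_GBq Administered activity, GBq.
#' @param region,method Labels carried into the result.
#' @param mass_g Organ mass, g (reported).
#' @return One-row data frame of class `dose_result` with `dose_Gy` and
#'   `dose_Gy_per_GBq`.
#' @export
absorbed_dose <- function(tia_MBqh, s_value_Gy_per_MBqh, administered_GBq,
                          region = "region", method = "3D",
                          mass_g = NA_real_) {
  stopifnot(tia_MBqh >= 0, s_value_Gy_per_MBqh > 0, administered_GBq > 0)
  d <- tia_MBqh * s_value_Gy_per_MBqh
  out <- data.frame(region = region, method = method,
                    tia_MBqh = tia_MBqh,
                    tiac_h = compute_tiac(tia_MBqh, administered_GBq),
                    mass_g = mass_g, dose_Gy = d,
                    dose_Gy_per_GBq = d / administered_GBq,
                    stringsAsFactors = FALSE)
  class(out) <- c("dose_result", "data.frame")
  out
}
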