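#' Physical decay data for Lu-177
#'
#' Lu-177 decays with a physical half-life of 6.647 days.  All kinetics in
#' this package are expressed in hours, so the physical decay constant is
#' `log(2) / (6.647 * 24)` = 4.3446e-3 per hour.
#'
#' @return Decay constant in 1/h.
#' @examples
#' lu177_lambda()          # 0.004345 / h
#' 1 / lu177_lambda()      # 230.16 h: TIA per unit activity for pure
#'                         # physical decay
#' @export
lu177_lambda <- function() {
  log(2) / lu177_halflife_h()
}

#' @rdname lu177_lambda
#' @return `lu177_halflife_h()`: half-life in hours (159.528 h).
#' @export
lu177_halflife_h <- function() 6.647 * 24

#' Physical-decay descriptor
#'
#' Small container for the physical decay constant used in the tail term
#' of the time-integrated-activity integration.  Configurable so that
#' other nuclides can reuse the kinetics machinery.
#'
#' @param lambda_phys Physical decay constant, 1/h.
#' @return An object of class `physical_decay`.
#' @export
physical_decay <- function(lambda_phys = lu177_lambda()) {
  stopifnot(is.numeric(lambda_phys), length(lambda_phys) == 1L,
            is.finite(lambda_phys), lambda_phys > 0)
  structure(list(lambda_phys = lambda_phys), class = "physical_decay")
}

#' Mean energy emitted as electrons per decay of Lu-177
#'
#' Mean beta plus conversion/Auger electron energy per decay, used by the
#' local-deposition sphere dose model.  Value from standard nuclide decay
#' data compilations.
#'
#' @return Energy in MeV per decay.
#' @export
lu177_delta_electron_MeV <- function() 0.1479
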