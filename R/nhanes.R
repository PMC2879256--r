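#' Evaluate the NHANES-derived FFM polynomial
#'
#' Evaluates the fourth-order FFM-FM polynomial for the subject's
#' (race, sex) group at fat mass `fm_kg`, using the subject's age and
#' height as covariates:
#' `FFM = c1 + cF*F + cA*A + cH*H + cFA*F*A + cFH*F*H + cF2*F^2 +
#'  cF2A*F^2*A + cF3*F^3 + cF4*F^4 + cF2H*F^2*H + cF3H*F^3*H`.
#'
#' @param fm_kg fat mass in kg (>= 0); may be a vector.
#' @param cov a [subject_covariates()] object.
#' @param registry_variant coefficient registry variant; see
#'   [ffm_registry()].
#' @return predicted fat-free mass in kg, same length as `fm_kg`.
#' @examples
#' cov <- subject_covariates(30, 163, "F", "NAA")
#' nhanes_ffm(0, cov) # zero-fat intercept: 40.8 kg
#' @export
nhanes_ffm <- function(fm_kg, cov, registry_variant = "normalized") {
  cov <- as_covariates(cov)
  if (!is.numeric(fm_kg) || length(fm_kg) < 1L || any(!is.finite(fm_kg)))
    stop_validation("fm_kg", "must be finite numeric")
  if (any(fm_kg < 0))
    stop_validation("fm_kg", "must be >= 0")
  co <- ffm_registry(registry_variant)[[group_key(cov)]]
  drop(basis_monomials(fm_kg, cov$age_y, cov$height_cm) %*% co)
}

#' Analytic derivative of the FFM polynomial with respect to fat mass
#'
#' Closed-form partial derivative dFFM/dFM of [nhanes_ffm()] at the given
#' point; used by the energy-balance reduction and the inversion solver.
#'
#' @inheritParams nhanes_ffm
#' @return dimensionless slope (kg FFM per kg FM), same length as `fm_kg`.
#' @export
nhanes_dffm_dfm <- function(fm_kg, cov, registry_variant = "normalized") {
  cov <- as_covariates(cov)
  if (!is.numeric(fm_kg) || length(fm_kg) < 1L || any(!is.finite(fm_kg)))
    stop_validation("fm_kg", "must be finite numeric")
  if (any(fm_kg < 0))
    stop_validation("fm_kg", "must be >= 0")
  co <- ffm_registry(registry_variant)[[group_key(cov)]]
  A <- cov$age_y; H <- cov$height_cm; f <- fm_kg
  co[["F"]] + co[["FA"]] * A + co[["FH"]] * H +
    2 * co[["F2"]] * f + 2 * co[["F2A"]] * f * A + 3 * co[["F3"]] * f^2 +
    4 * co[["F4"]] * f^3 + 2 * co[["F2H"]] * f * H + 3 * co[["F3H"]] * f^2 * H
}
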