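# At FM = 0 the polynomial reduces to intercept + cA*A + cH*H, so the
# model implies a minimal ("zero-fat") BMI as a function of height and age:
# BMI_0(H) = FFM(0; A, H) / (H/100)^2.

#' BMI implied by the model at zero fat mass
#'
#' The theoretical lower bound of BMI for the subject's covariates:
#' `nhanes_ffm(0, cov) / (height/100)^2`. Only the intercept, age and
#' height terms of the polynomial contribute at FM = 0.
#'
#' @inheritParams nhanes_ffm
#' @return BMI in kg/m^2.
#' @examples
#' bmi_at_zero_fat(subject_covariates(30, 163, "F", "NAA")) # ~15.4
#' @export
bmi_at_zero_fat <- function(cov, registry_variant = "normalized") {
  cov <- as_covariates(cov)
  mass_index(nhanes_ffm(0, cov, registry_variant), cov$height_cm)
}

#' Zero-fat BMI versus height curve
#'
#' Samples [bmi_at_zero_fat()] along a height grid at fixed age, sex and
#' race, producing the level curve of minimal BMI versus height.
#'
#' @param age_y age in years.
#' @param sex `"M"` or `"F"`.
#' @param race `"AA"` or `"NAA"`.
#' @param height_grid strictly increasing heights in cm, within
#'   \[120, 220\].
#' @param registry_variant coefficient registry variant.
#' @return object of class `zero_fat_curve`: a data frame with columns
#'   `height_cm`, `bmi_kg_m2` and attributes `age_y`, `sex`, `race`.
#' @export
zero_fat_curve <- function(age_y, sex, race, height_grid,
                           registry_variant = "normalized") {
  if (!is.numeric(height_grid) || length(height_grid) < 1L ||
      any(!is.finite(height_grid)))
    stop_validation("height_grid", "must be finite numeric")
  if (is.unsorted(height_grid, strictly = TRUE))
    stop_validation("height_grid", "must be strictly increasing")
  if (min(height_grid) < HEIGHT_RANGE_CM[1] || max(height_grid) > HEIGHT_RANGE_CM[2])
    stop_validation("height_grid",
                    sprintf("heights must lie in [%g, %g] cm",
                            HEIGHT_RANGE_CM[1], HEIGHT_RANGE_CM[2]))
  bmi <- vapply(height_grid, function(h) {
    bmi_at_zero_fat(subject_covariates(age_y, h, sex, race), registry_variant)
  }, numeric(1))
  structure(data.frame(height_cm = height_grid, bmi_kg_m2 = bmi),
            age_y = age_y, sex = as_sex(sex), race = as_race(race),
            class = c("zero_fat_curve", "data.frame"))
}

#' Shape report for a zero-fat BMI curve
#'
#' Checks by finite differences whether the curve is strictly increasing
#' in height (all first differences > 0) and strictly concave down (all
#' second differences < 0). Zero differences count as violations, since
#' the claimed shape is strict. If either property fails, the first
#' violating height is reported.
#'
#' @param curve a [zero_fat_curve()] (or any data frame with strictly
#'   increasing `height_cm` and `bmi_kg_m2` columns), at least 3 samples.
#' @return list with logical `increasing`, `concave_down`, and
#'   `first_violation_height_cm` (`NA` if no violation).
#' @export
curve_shape_report <- function(curve) {
  if (!is.data.frame(curve) ||
      !all(c("height_cm", "bmi_kg_m2") %in% names(curve)))
    stop_validation("curve", "must have height_cm and bmi_kg_m2 columns")
  if (nrow(curve) < 3L)
    stop_validation("curve", "needs at least 3 samples")
  h <- curve$height_cm
  b <- curve$bmi_kg_m2
  d1 <- diff(b)
  d2 <- diff(b, differences = 2L)
  inc_viol <- which(d1 <= 0)          # step i covers (h[i], h[i+1])
  con_viol <- which(d2 >= 0)          # centred at h[i+1]
  viol_h <- c(h[inc_viol + 1L], h[con_viol + 1L])
  list(increasing = length(inc_viol) == 0L,
       concave_down = length(con_viol) == 0L,
       first_violation_height_cm = if (length(viol_h)) min(viol_h) else NA_real_)
}
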