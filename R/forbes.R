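# Forbes log-linear FFM-FM family. The classical female curve is
# FFM = 10.4 ln(FM) + 14.2; the male analogue (log-linear fit to
# average-stature men, 172-176 cm) is FFM = 13.8 ln(FM) + 16.9.
# An individual's longitudinal data travels a vertical translate of the
# curve, parameterised by the additive offset D.

FORBES_PARAMS <- list(
  F = c(slope = 10.4, intercept = 14.2),
  M = c(slope = 13.8, intercept = 16.9)
)

#' Construct a Forbes log-linear FFM-FM model
#'
#' `FFM = slope * ln(FM) + intercept + D`, with the classical sex-specific
#' slope and intercept (female: 10.4, 14.2; male: 13.8, 16.9) and a
#' vertical translate `D` (kg, default 0) selecting the member of the
#' parallel family an individual actually travels during weight change.
#'
#' @param sex `"M"` or `"F"`.
#' @param translate_d vertical offset D in kg.
#' @return object of class `forbes_model` with fields `slope`, `intercept`,
#'   `translate_d`, `sex`.
#' @examples
#' forbes_ffm(1, forbes_model("F")) # 14.2: the log term vanishes
#' @export
forbes_model <- function(sex = c("F", "M"), translate_d = 0) {
  sex <- as_sex(if (missing(sex)) "F" else sex[[1]])
  check_scalar_number(translate_d, "translate_d")
  p <- FORBES_PARAMS[[sex]]
  structure(list(slope = unname(p["slope"]), intercept = unname(p["intercept"]),
                 translate_d = translate_d, sex = sex),
            class = "forbes_model")
}

#' @export
print.forbes_model <- function(x, ...) {
  cat(sprintf("Forbes model (%s): FFM = %g ln(FM) + %g%s\n",
              if (x$sex == "F") "female" else "male", x$slope, x$intercept,
              if (x$translate_d != 0) sprintf(" + D (D = %g kg)", x$translate_d) else ""))
  invisible(x)
}

as_forbes <- function(model) {
  if (inherits(model, "forbes_model")) return(model)
  if (is.character(model)) return(forbes_model(model))
  stop_validation("model", "must be a forbes_model object or a sex label")
}

#' Forbes-predicted fat-free mass
#'
#' @param fm_kg fat mass in kg (> 0; the logarithm is undefined at 0); may
#'   be a vector.
#' @param model a [forbes_model()] (or a sex label, taken with D = 0).
#' @return predicted FFM in kg.
#' @export
forbes_ffm <- function(fm_kg, model) {
  model <- as_forbes(model)
  if (!is.numeric(fm_kg) || any(!is.finite(fm_kg)) || any(fm_kg <= 0))
    stop_domain("forbes_ffm requires fm_kg > 0 (logarithm undefined otherwise)")
  model$slope * log(fm_kg) + model$intercept + model$translate_d
}

#' Tangent slope of the Forbes curve
#'
#' dFFM/dFM = slope / FM; independent of the translate D, which is why all
#' members of the parallel family predict the same FFM change for a given
#' FM change.
#'
#' @inheritParams forbes_ffm
#' @return dimensionless slope (kg FFM per kg FM).
#' @export
forbes_slope <- function(fm_kg, model) {
  model <- as_forbes(model)
  if (!is.numeric(fm_kg) || any(!is.finite(fm_kg)) || any(fm_kg <= 0))
    stop_domain("forbes_slope requires fm_kg > 0")
  model$slope / fm_kg
}

#' Calibrate the Forbes translate D to a baseline composition
#'
#' Returns the vertical offset `D = FFM_b - slope * ln(FM_b) - intercept`
#' that makes the translated Forbes curve pass exactly through the
#' individual's baseline (FM, FFM) point.
#'
#' @param fm_baseline_kg baseline fat mass, kg (> 0).
#' @param ffm_baseline_kg baseline fat-free mass, kg.
#' @param sex `"M"` or `"F"`.
#' @return translate D in kg.
#' @export
calibrate_forbes_d <- function(fm_baseline_kg, ffm_baseline_kg, sex) {
  if (!is.numeric(fm_baseline_kg) || length(fm_baseline_kg) != 1L ||
      !is.finite(fm_baseline_kg) || fm_baseline_kg <= 0)
    stop_domain("calibrate_forbes_d requires fm_baseline_kg > 0")
  check_scalar_number(ffm_baseline_kg, "ffm_baseline_kg")
  m <- forbes_model(sex)
  ffm_baseline_kg - m$slope * log(fm_baseline_kg) - m$intercept
}
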