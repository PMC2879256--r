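# One-dimensional energy-balance coupling. Writing FFM as the polynomial
# phi(FM) reduces the paired FM/FFM balance to a single state equation by
# the chain rule:
#   (c_f + c_l * phi'(FM)) dFM/dt = I(t) - E(FM, phi(FM))
# where c_l and c_f are the energy conversion constants (kcal per kg of
# FFM and FM) and E is the expenditure rate in kcal/d. No default values
# are supplied for c_l and c_f: they are user configuration.

#' Energy conversion constants
#'
#' @param c_l kcal per kg of fat-free mass (> 0).
#' @param c_f kcal per kg of fat mass (> 0, and greater than `c_l`: fat is
#'   the denser energy store).
#' @return object of class `energy_params`.
#' @export
energy_params <- function(c_l, c_f) {
  check_scalar_number(c_l, "c_l", 0, strict_lower = TRUE)
  check_scalar_number(c_f, "c_f", 0, strict_lower = TRUE)
  if (c_f <= c_l)
    stop_validation("c_f", sprintf("must exceed c_l (%g kcal/kg)", c_l))
  structure(list(c_l = c_l, c_f = c_f), class = "energy_params")
}

#' Linear reference expenditure function
#'
#' A simple pluggable expenditure model
#' `E(FM, FFM) = intercept + per_kg_ffm * FFM + per_kg_fm * FM` (kcal/d),
#' shipped for testing and illustration; all constants are user-supplied.
#' Any function of `(fm_kg, ffm_kg)` returning kcal/d can be used in its
#' place.
#'
#' @param intercept_kcal_d baseline kcal/d.
#' @param per_kg_ffm kcal/d per kg FFM.
#' @param per_kg_fm kcal/d per kg FM.
#' @return function of `(fm_kg, ffm_kg)`.
#' @export
linear_expenditure <- function(intercept_kcal_d, per_kg_ffm = 0, per_kg_fm = 0) {
  check_scalar_number(intercept_kcal_d, "intercept_kcal_d")
  check_scalar_number(per_kg_ffm, "per_kg_ffm")
  check_scalar_number(per_kg_fm, "per_kg_fm")
  function(fm_kg, ffm_kg) intercept_kcal_d + per_kg_ffm * ffm_kg + per_kg_fm * fm_kg
}

#' Fat-mass rate of change under energy imbalance
#'
#' Evaluates `dFM/dt = (I - E(FM, FFM)) / (c_f + c_l * dFFM/dFM)` at the
#' given state, with FFM and its derivative taken from the polynomial
#' model.
#'
#' @param fm_kg current fat mass, kg.
#' @param cov a [subject_covariates()] object.
#' @param intake_kcal_d energy intake rate, kcal/d.
#' @param expenditure function of `(fm_kg, ffm_kg)` returning kcal/d.
#' @param params an [energy_params()] object.
#' @param registry_variant coefficient registry variant.
#' @return rate in kg/day.
#' @export
dfm_dt <- function(fm_kg, cov, intake_kcal_d, expenditure, params,
                   registry_variant = "normalized") {
  cov <- as_covariates(cov)
  if (!inherits(params, "energy_params"))
    stop_validation("params", "must be an energy_params object")
  if (!is.function(expenditure))
    stop_validation("expenditure", "must be a function of (fm_kg, ffm_kg)")
  check_scalar_number(intake_kcal_d, "intake_kcal_d")
  ffm <- nhanes_ffm(fm_kg, cov, registry_variant)
  slope <- nhanes_dffm_dfm(fm_kg, cov, registry_variant)
  denom <- params$c_f + params$c_l * slope
  if (denom <= 0)
    bc_stop(sprintf(paste0("energy density denominator c_f + c_l*dFFM/dFM = ",
                           "%.6g <= 0 at FM = %.4g kg; the one-dimensional ",
                           "reduction is not valid at this state"),
                    denom, fm_kg),
            "bodycomp_model_error")
  (intake_kcal_d - expenditure(fm_kg, ffm)) / denom
}

FM_SIM_MAX_KG <- 120

#' Simulate a weight trajectory under an intake schedule
#'
#' Integrates the one-dimensional energy-balance equation with the
#' classical fixed-step fourth-order Runge-Kutta scheme. The initial fat
#' mass is recovered from the initial total mass by [solve_fm()]; at every
#' step FFM is recomputed from the polynomial model, so the trajectory
#' stays exactly on the subject's FFM-FM curve. A cumulative net-energy
#' state (the integral of intake minus expenditure) is integrated
#' alongside, so the energy-partition identity
#' `c_f * dFM + c_l * dFFM = integral of (I - E) dt`
#' can be checked on the output. If fat mass leaves \[0, 120\] kg the
#' integration is truncated at the crossing step with a warning.
#'
#' @param initial_total_kg initial total body mass, kg.
#' @param cov a [subject_covariates()] object.
#' @param intake_kcal_d constant intake (scalar kcal/d) or a function of
#'   time in days returning kcal/d.
#' @param expenditure function of `(fm_kg, ffm_kg)` returning kcal/d.
#' @param params an [energy_params()] object.
#' @param duration_d simulated duration, days.
#' @param dt_d fixed step size, days (default 1).
#' @param registry_variant coefficient registry variant.
#' @return object of class `bc_trajectory`: data frame with columns `day`,
#'   `fm_kg`, `ffm_kg`, `total_kg`, `net_kcal` (cumulative intake minus
#'   expenditure).
#' @export
simulate_trajectory <- function(initial_total_kg, cov, intake_kcal_d,
                                expenditure, params, duration_d, dt_d = 1,
                                registry_variant = "normalized") {
  cov <- as_covariates(cov)
  check_scalar_number(duration_d, "duration_d", 0, strict_lower = TRUE)
  check_scalar_number(dt_d, "dt_d", 0, strict_lower = TRUE)
  intake <- if (is.function(intake_kcal_d)) intake_kcal_d
            else { check_scalar_number(intake_kcal_d, "intake_kcal_d")
                   function(t) intake_kcal_d }
  f0 <- solve_fm(initial_total_kg, cov, registry_variant)
  n_steps <- ceiling(duration_d / dt_d - 1e-9)
  deriv <- function(t, f) {
    c(dfm_dt(f[1], cov, intake(t), expenditure, params, registry_variant),
      intake(t) - expenditure(f[1], nhanes_ffm(f[1], cov, registry_variant)))
  }
  day <- numeric(n_steps + 1L); fm <- numeric(n_steps + 1L)
  net <- numeric(n_steps + 1L)
  day[1] <- 0; fm[1] <- f0; net[1] <- 0
  kept <- n_steps + 1L
  for (k in seq_len(n_steps)) {
    t <- day[k]; y <- c(fm[k], net[k])
    h <- min(dt_d, duration_d - t)
    # a stage evaluation outside [0, max] also counts as a boundary crossing
    y1 <- tryCatch({
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 2, y + h / 2 * k1)
      k3 <- deriv(t + h / 2, y + h / 2 * k2)
      k4 <- deriv(t + h, y + h * k3)
      y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }, bodycomp_validation_error = function(e) NA_real_)
    if (anyNA(y1) || !is.finite(y1[1]) || y1[1] < 0 || y1[1] > FM_SIM_MAX_KG) {
      warning(sprintf(paste0("fat mass left [0, %g] kg at day %.4g; ",
                             "trajectory truncated at the crossing step"),
                      FM_SIM_MAX_KG, t + h), call. = FALSE)
      kept <- k
      break
    }
    day[k + 1L] <- t + h; fm[k + 1L] <- y1[1]; net[k + 1L] <- y1[2]
  }
  idx <- seq_len(kept)
  ffm <- nhanes_ffm(fm[idx], cov, registry_variant)
  out <- data.frame(day = day[idx], fm_kg = fm[idx], ffm_kg = ffm,
                    total_kg = fm[idx] + ffm, net_kcal = net[idx])
  structure(out, cov = cov, params = params,
            registry_variant = registry_variant,
            class = c("bc_trajectory", "data.frame"))
}

#' @export
print.bc_trajectory <- function(x, ...) {
  cat(sprintf("energy-balance trajectory: %d samples over %g d\n",
              nrow(x), x$day[nrow(x)]))
  cat(sprintf("  start: FM %.3f kg, FFM %.3f kg, total %.3f kg\n",
              x$fm_kg[1], x$ffm_kg[1], x$total_kg[1]))
  n <- nrow(x)
  cat(sprintf("  end:   FM %.3f kg, FFM %.3f kg, total %.3f kg (net %.0f kcal)\n",
              x$fm_kg[n], x$ffm_kg[n], x$total_kg[n], x$net_kcal[n]))
  invisible(x)
}
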