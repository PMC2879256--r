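# Inversion of the mass-balance identity W = FM + FFM(FM; covariates).
# g(F) = F + FFM(F) - W is scanned on [0, W] for sign changes; in the
# physiological band g is strictly increasing and the root is unique, but
# the quartic tails can turn over for extreme covariates, so multiple
# bracketed roots are detected and reported rather than silently resolved.

SOLVE_TOL_KG <- 1e-8
SCAN_POINTS <- 512L
FM_MODEL_MAX_KG <- 100  # upper edge of the fat-mass band the model covers

stop_infeasible <- function(total_kg, ffm0) {
  bc_stop(sprintf(paste0("total mass %.6g kg is at or below the zero-fat ",
                         "fat-free mass bound %.6g kg for these covariates; ",
                         "no non-negative fat solution exists"),
                  total_kg, ffm0),
          "bodycomp_infeasible_error", total_kg = total_kg, zero_fat_bound = ffm0)
}

#' Solve fat mass from total body mass
#'
#' Inverts the mass-balance identity `W = FM + FFM(FM; A, H, sex, race)`
#' for FM by bracketed root finding on \[0, min(W, 100)\] kg (absolute
#' tolerance 1e-8 kg); the search stops at 100 kg fat mass, the upper edge
#' of the band the polynomial class covers, beyond which the quartic tail
#' is not meaningful. The solution exists and is unique when `W` exceeds
#' the zero-fat fat-free mass `FFM(0)` and the total-mass function is
#' increasing over the bracket; if several roots are bracketed (possible
#' for extreme covariates where the quartic tail turns over) an ambiguity
#' error lists them all.
#'
#' @param total_kg total body mass in kg.
#' @param cov a [subject_covariates()] object.
#' @param registry_variant coefficient registry variant; see
#'   [ffm_registry()].
#' @return fat mass in kg.
#' @examples
#' cov <- subject_covariates(34, 165, "F", "AA")
#' solve_fm(75, cov, registry_variant = "corrected") # 27.75 kg
#' @export
solve_fm <- function(total_kg, cov, registry_variant = "normalized") {
  cov <- as_covariates(cov)
  check_scalar_number(total_kg, "total_kg", 0, strict_lower = TRUE)
  ffm0 <- nhanes_ffm(0, cov, registry_variant)
  if (total_kg <= ffm0) stop_infeasible(total_kg, ffm0)
  g <- function(f) f + nhanes_ffm(f, cov, registry_variant) - total_kg
  # the search stops at the edge of the model's fat-mass band: beyond it the
  # quartic tail can turn over and produce spurious crossings
  upper <- min(total_kg, FM_MODEL_MAX_KG)
  grid <- seq(0, upper, length.out = SCAN_POINTS + 1L)
  gv <- grid + nhanes_ffm(grid, cov, registry_variant) - total_kg
  sgn <- sign(gv)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(gv == 0)
  roots <- grid[exact]
  for (i in cross) {
    r <- stats::uniroot(g, lower = grid[i], upper = grid[i + 1L],
                        tol = SOLVE_TOL_KG / 10)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (length(roots) == 0L)
    bc_stop(sprintf(paste0("no fat-mass root found in [0, %g] kg; total mass ",
                           "%g kg has no composition within the model's ",
                           "fat-mass band for these covariates"),
                    upper, total_kg),
            "bodycomp_infeasible_error")
  if (length(roots) > 1L)
    bc_stop(sprintf(paste0("total-mass function is non-monotone on [0, %g]: ",
                           "%d fat-mass roots found (%s kg); covariates are ",
                           "outside the band where inversion is unique"),
                    total_kg, length(roots),
                    paste(sprintf("%.4f", roots), collapse = ", ")),
            "bodycomp_ambiguity_error", roots = roots)
  roots
}

composition_change <- function(fm_b, ffm_b, fm_f, ffm_f, method) {
  structure(list(
    fm_baseline_kg = fm_b, ffm_baseline_kg = ffm_b,
    fm_final_kg = fm_f, ffm_final_kg = ffm_f,
    delta_fm_kg = fm_f - fm_b, delta_ffm_kg = ffm_f - ffm_b,
    delta_total_kg = (fm_f + ffm_f) - (fm_b + ffm_b), method = method),
    class = "composition_change")
}

#' @export
print.composition_change <- function(x, ...) {
  cat(sprintf("composition change (%s model)\n", x$method))
  cat(sprintf("  baseline: FM %8.3f kg  FFM %8.3f kg  total %8.3f kg\n",
              x$fm_baseline_kg, x$ffm_baseline_kg,
              x$fm_baseline_kg + x$ffm_baseline_kg))
  cat(sprintf("  final:    FM %8.3f kg  FFM %8.3f kg  total %8.3f kg\n",
              x$fm_final_kg, x$ffm_final_kg, x$fm_final_kg + x$ffm_final_kg))
  cat(sprintf("  change:   FM %+8.3f kg  FFM %+8.3f kg  total %+8.3f kg\n",
              x$delta_fm_kg, x$delta_ffm_kg, x$delta_total_kg))
  invisible(x)
}

#' Longitudinal FFM change under weight change (polynomial model)
#'
#' Solves body composition at the baseline and final total mass with
#' identical covariates (age and height are frozen at baseline over the
#' study interval) and returns the implied composition change. By mass
#' balance, `delta_ffm = delta_total - delta_fm`.
#'
#' @param baseline_total_kg baseline total body mass, kg.
#' @param delta_total_kg change in total mass, kg (negative = loss).
#' @param cov a [subject_covariates()] object.
#' @param registry_variant coefficient registry variant.
#' @return object of class `composition_change`.
#' @examples
#' cov <- subject_covariates(34, 165, "F", "AA")
#' delta_ffm_nhanes(75, -10, cov, registry_variant = "corrected")
#' @export
delta_ffm_nhanes <- function(baseline_total_kg, delta_total_kg, cov,
                             registry_variant = "normalized") {
  cov <- as_covariates(cov)
  check_scalar_number(baseline_total_kg, "baseline_total_kg", 0, strict_lower = TRUE)
  check_scalar_number(delta_total_kg, "delta_total_kg")
  final_total <- baseline_total_kg + delta_total_kg
  if (final_total <= 0)
    stop_validation("delta_total_kg", "final total mass must be positive")
  fm_b <- solve_fm(baseline_total_kg, cov, registry_variant)
  fm_f <- solve_fm(final_total, cov, registry_variant)
  composition_change(fm_b, baseline_total_kg - fm_b,
                     fm_f, final_total - fm_f, method = "nhanes")
}

#' Longitudinal FFM change under weight change (translated Forbes curve)
#'
#' Calibrates the Forbes translate D so the curve passes through the
#' individual's measured baseline (FM, FFM), then solves the final fat
#' mass from `FM + slope*ln(FM) + intercept + D = W_final` by bracketed
#' root finding. The FFM change `slope*(ln FM_final - ln FM_baseline)` is
#' independent of D: all members of the parallel family predict the same
#' change.
#'
#' @param fm_baseline_kg baseline fat mass, kg (> 0).
#' @param ffm_baseline_kg baseline fat-free mass, kg.
#' @param delta_total_kg change in total mass, kg (negative = loss).
#' @param sex `"M"` or `"F"`.
#' @return object of class `composition_change`.
#' @export
delta_ffm_forbes <- function(fm_baseline_kg, ffm_baseline_kg, delta_total_kg, sex) {
  d <- calibrate_forbes_d(fm_baseline_kg, ffm_baseline_kg, sex)
  check_scalar_number(delta_total_kg, "delta_total_kg")
  model <- forbes_model(sex, translate_d = d)
  w_final <- fm_baseline_kg + ffm_baseline_kg + delta_total_kg
  g <- function(f) f + forbes_ffm(f, model) - w_final
  # g is strictly increasing on (0, Inf) and -> -Inf as F -> 0+
  lower <- 1e-12
  upper <- max(w_final, fm_baseline_kg)
  if (g(upper) < 0) upper <- upper + abs(model$translate_d) + model$slope * 10 + 100
  if (g(upper) < 0)
    bc_stop(sprintf("no positive fat-mass root at final mass %.6g kg", w_final),
            "bodycomp_infeasible_error")
  fm_f <- stats::uniroot(g, lower = lower, upper = upper,
                         tol = SOLVE_TOL_KG / 10)$root
  composition_change(fm_baseline_kg, ffm_baseline_kg,
                     fm_f, forbes_ffm(fm_f, model), method = "forbes")
}

#' Summarise prediction errors (mean +/- SD)
#'
#' Errors are `predicted - measured`; the summary reports their mean and
#' sample standard deviation (n - 1 denominator). The SD is `NA` for a
#' single pair.
#'
#' @param measured numeric vector of measured values, kg.
#' @param predicted numeric vector of predicted values, kg (same length).
#' @return object of class `error_summary`: list with `mean_error_kg`,
#'   `sd_error_kg`, `n`.
#' @export
summarize_errors <- function(measured, predicted) {
  if (!is.numeric(measured) || !is.numeric(predicted))
    stop_validation("measured", "measured and predicted must be numeric")
  if (length(measured) == 0L)
    stop_validation("measured", "must be non-empty")
  if (length(measured) != length(predicted))
    stop_validation("predicted",
                    sprintf("length %d does not match measured length %d",
                            length(predicted), length(measured)))
  if (any(!is.finite(measured)) || any(!is.finite(predicted)))
    stop_validation("measured", "values must be finite")
  err <- predicted - measured
  structure(list(mean_error_kg = mean(err),
                 sd_error_kg = if (length(err) > 1L) stats::sd(err) else NA_real_,
                 n = length(err)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("prediction error (predicted - measured): %.3f +/- %.3f kg (n = %d)\n",
              x$mean_error_kg, x$sd_error_kg, x$n))
  invisible(x)
}
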