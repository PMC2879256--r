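# Classed conditions so callers (and the CLI) can distinguish bad input from
# genuine model failures.
bc_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "bodycomp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_validation <- function(field, msg) {
  bc_stop(sprintf("invalid `%s`: %s", field, msg),
          "bodycomp_validation_error", field = field)
}

stop_domain <- function(msg) bc_stop(msg, "bodycomp_domain_error")

stop_config <- function(msg) bc_stop(msg, "bodycomp_config_error")

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_validation(field, sprintf("must be > %g (got %g)", lower, x))
  if (!strict_lower && x < lower)
    stop_validation(field, sprintf("must be >= %g (got %g)", lower, x))
  if (x > upper)
    stop_validation(field, sprintf("must be <= %g (got %g)", upper, x))
  invisible(x)
}

# Valid covariate band: brackets the NHANES DXA sample (ages 8y and older)
# with margin. Out-of-range is an error, not a warning, because the quartic
# polynomials extrapolate badly.
AGE_RANGE_Y <- c(8, 110)
HEIGHT_RANGE_CM <- c(120, 220)

#' Canonicalise a sex label
#'
#' Accepts `"M"`/`"F"` (case-insensitive) and the spellings `"male"`,
#' `"female"`; returns the canonical `"M"` or `"F"`.
#'
#' @param x character scalar.
#' @return `"M"` or `"F"`.
#' @export
as_sex <- function(x) {
  if (length(x) != 1L || is.na(x)) stop_validation("sex", "must be a single non-missing label")
  s <- toupper(trimws(as.character(x)))
  if (s %in% c("M", "MALE")) return("M")
  if (s %in% c("F", "FEMALE")) return("F")
  stop_validation("sex", sprintf("unrecognised label %s (expected M or F)", dQuote(x)))
}

#' Canonicalise a race-group label
#'
#' The model distinguishes two groups: African American (`"AA"`) and
#' non-African American (`"NAA"`, all other ethnic groups). Any label other
#' than `"AA"` (or spellings of African American) is coerced to `"NAA"`;
#' labels not recognised as either group trigger a warning before coercion.
#'
#' @param x character scalar.
#' @return `"AA"` or `"NAA"`.
#' @export
as_race <- function(x) {
  if (length(x) != 1L || is.na(x)) stop_validation("race", "must be a single non-missing label")
  r <- toupper(trimws(as.character(x)))
  if (r %in% c("AA", "AFRICAN AMERICAN", "AFRICAN-AMERICAN", "BLACK")) return("AA")
  if (r %in% c("NAA", "NON-AFRICAN AMERICAN", "NON-AA", "WHITE", "HISPANIC", "ASIAN", "OTHER")) {
    return("NAA")
  }
  warning(sprintf("race label %s not recognised; coercing to NAA", dQuote(x)),
          call. = FALSE)
  "NAA"
}

#' Subject covariates for the FFM polynomial models
#'
#' Bundles the covariates entering every polynomial evaluation: age `A`
#' (years), height `H` (cm), sex and race group. Age must lie in
#' \[8, 110\] years and height in \[120, 220\] cm; values outside these
#' bands are rejected rather than extrapolated.
#'
#' @param age_y age in years.
#' @param height_cm height in centimetres.
#' @param sex `"M"` or `"F"` (see [as_sex()]).
#' @param race `"AA"` or `"NAA"` (see [as_race()]).
#' @return An object of class `subject_covariates`.
#' @examples
#' subject_covariates(34, 165, "F", "AA")
#' @export
subject_covariates <- function(age_y, height_cm, sex, race) {
  check_scalar_number(age_y, "age_y", AGE_RANGE_Y[1], AGE_RANGE_Y[2])
  check_scalar_number(height_cm, "height_cm", HEIGHT_RANGE_CM[1], HEIGHT_RANGE_CM[2])
  structure(
    list(age_y = as.numeric(age_y), height_cm = as.numeric(height_cm),
         sex = as_sex(sex), race = as_race(race)),
    class = "subject_covariates"
  )
}

#' @export
print.subject_covariates <- function(x, ...) {
  cat(sprintf("subject: %s %s, age %g y, height %g cm\n",
              x$race, x$sex, x$age_y, x$height_cm))
  invisible(x)
}

as_covariates <- function(cov) {
  if (inherits(cov, "subject_covariates")) return(cov)
  if (is.list(cov) && all(c("age_y", "height_cm", "sex", "race") %in% names(cov)))
    return(subject_covariates(cov$age_y, cov$height_cm, cov$sex, cov$race))
  stop_validation("cov", "must be a subject_covariates object")
}

#' Paired fat mass / fat-free mass state
#'
#' A body-composition state (FM, FFM) in kg; total mass is their sum by the
#' mass-balance identity.
#'
#' @param fm_kg fat mass, kg (>= 0).
#' @param ffm_kg fat-free mass, kg (> 0).
#' @return An object of class `body_state` with fields `fm_kg`, `ffm_kg`
#'   and the derived `total_kg`.
#' @export
body_state <- function(fm_kg, ffm_kg) {
  check_scalar_number(fm_kg, "fm_kg", 0)
  check_scalar_number(ffm_kg, "ffm_kg", 0, strict_lower = TRUE)
  structure(list(fm_kg = fm_kg, ffm_kg = ffm_kg, total_kg = fm_kg + ffm_kg),
            class = "body_state")
}

#' Height-normalised mass index (FFMI / FMI / BMI)
#'
#' Expresses a mass as an index to height squared, `mass / (height/100)^2`,
#' in kg/m^2. Used for the fat-free mass index (FFMI), fat mass index (FMI)
#' and BMI alike.
#'
#' @param mass_kg mass in kg (>= 0); may be a vector.
#' @param height_cm height in cm (> 0).
#' @return index in kg/m^2.
#' @examples
#' mass_index(25, 100) # 25 kg over 1 m^2
#' @export
mass_index <- function(mass_kg, height_cm) {
  if (!is.numeric(mass_kg) || any(!is.finite(mass_kg)) || any(mass_kg < 0))
    stop_validation("mass_kg", "must be finite and >= 0")
  if (!is.numeric(height_cm) || length(height_cm) != 1L ||
      !is.finite(height_cm) || height_cm <= 0)
    stop_validation("height_cm", "must be a single positive number")
  mass_kg / (height_cm / 100)^2
}
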