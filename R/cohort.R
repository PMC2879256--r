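# Synthetic cross-sectional cohorts with the statistical structure the
# polynomial regression assumes: per (race, sex) group, age uniform,
# height normal (truncated to the valid covariate band), fat mass gamma
# (right-skewed, positive, moment-matched to the reference population),
# and FFM = polynomial(FM; covariates) + Gaussian noise.

# Reference moments (kg / cm): FM mean/SD 24.2/10.4 (M), 30.6/12.3 (F);
# height mean/SD 174.3/7.9 (M), 160.6/7.2 (F).
DEFAULT_FM_MOMENTS <- list(M = c(mean = 24.2, sd = 10.4),
                           F = c(mean = 30.6, sd = 12.3))
DEFAULT_HEIGHT_MOMENTS <- list(M = c(mean = 174.3, sd = 7.9),
                               F = c(mean = 160.6, sd = 7.2))

# Run code with a deterministic RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic cross-sectional cohort
#'
#' Defaults emulate the adult reference population the polynomial class
#' was developed from: age uniform on \[18, 85\] y; height normal with
#' sex-specific mean/SD (174.3 +/- 7.9 cm male, 160.6 +/- 7.2 cm female),
#' truncated to the valid covariate band; fat mass gamma with sex-specific
#' moments (24.2 +/- 10.4 kg male, 30.6 +/- 12.3 kg female) via moment
#' matching; additive Gaussian FFM noise with SD 3 kg, the residual spread
#' implied by an R^2 of about 0.86 at a population FFM SD of about 8 kg.
#'
#' @param n_per_group records per (race, sex) group (>= 12, more rows than
#'   basis terms).
#' @param age_range_y length-2 numeric, uniform age range in years.
#' @param height_mean_sd named list (`M`, `F`) of c(mean, sd) heights, cm.
#' @param fm_mean_sd named list (`M`, `F`) of c(mean, sd) fat mass, kg.
#' @param noise_sd_kg SD of additive Gaussian FFM noise, kg (>= 0).
#' @param seed integer seed; generation is reproducible for a fixed spec.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 1000L,
                        age_range_y = c(18, 85),
                        height_mean_sd = DEFAULT_HEIGHT_MOMENTS,
                        fm_mean_sd = DEFAULT_FM_MOMENTS,
                        noise_sd_kg = 3,
                        seed = 1L) {
  check_scalar_number(n_per_group, "n_per_group", 12)
  if (!is.numeric(age_range_y) || length(age_range_y) != 2L ||
      age_range_y[1] >= age_range_y[2] ||
      age_range_y[1] < AGE_RANGE_Y[1] || age_range_y[2] > AGE_RANGE_Y[2])
    stop_validation("age_range_y",
                    sprintf("must be an increasing pair within [%g, %g]",
                            AGE_RANGE_Y[1], AGE_RANGE_Y[2]))
  for (s in c("M", "F")) {
    for (fld in c("height_mean_sd", "fm_mean_sd")) {
      v <- get(fld)[[s]]
      if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || v[2] <= 0)
        stop_validation(fld, sprintf("entry %s must be c(mean, sd) with sd > 0", s))
    }
  }
  check_scalar_number(noise_sd_kg, "noise_sd_kg", 0)
  check_scalar_number(seed, "seed")
  structure(list(n_per_group = as.integer(n_per_group),
                 age_range_y = as.numeric(age_range_y),
                 height_mean_sd = height_mean_sd, fm_mean_sd = fm_mean_sd,
                 noise_sd_kg = noise_sd_kg, seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_truncated <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic cross-sectional cohort
#'
#' Draws `n_per_group` records for each of the four (race, sex) groups per
#' the spec and sets `ffm_kg = nhanes_ffm(fm_kg, cov) + N(0, noise_sd_kg)`.
#'
#' @param spec a [cohort_spec()].
#' @param registry_variant coefficient registry variant used as the
#'   generating truth. Defaults to `"corrected"`, the only variant whose
#'   AA-female row is physically plausible across the height range (the
#'   transcribed row implies negative fat-free mass at zero fat for most
#'   statures); see [ffm_registry()].
#' @return data frame with columns `id`, `sex`, `race`, `age_y`,
#'   `height_cm`, `fm_kg`, `ffm_kg`.
#' @export
generate_cohort <- function(spec = cohort_spec(), registry_variant = "corrected") {
  if (!inherits(spec, "cohort_spec")) stop_validation("spec", "must be a cohort_spec")
  groups <- expand.grid(sex = c("F", "M"), race = c("AA", "NAA"),
                        stringsAsFactors = FALSE)
  with_seed(spec$seed, {
    out <- lapply(seq_len(nrow(groups)), function(i) {
      sex <- groups$sex[i]; race <- groups$race[i]
      n <- spec$n_per_group
      age <- stats::runif(n, spec$age_range_y[1], spec$age_range_y[2])
      hm <- spec$height_mean_sd[[sex]]
      height <- rnorm_truncated(n, hm[1], hm[2],
                                HEIGHT_RANGE_CM[1], HEIGHT_RANGE_CM[2])
      fmom <- spec$fm_mean_sd[[sex]]
      shape <- (fmom[1] / fmom[2])^2
      scale <- fmom[2]^2 / fmom[1]
      fm <- stats::rgamma(n, shape = shape, scale = scale)
      co <- ffm_registry(registry_variant)[[paste(race, sex, sep = ".")]]
      X <- cbind(1, fm, age, height, fm * age, fm * height, fm^2,
                 fm^2 * age, fm^3, fm^4, fm^2 * height, fm^3 * height)
      ffm <- drop(X %*% co) + stats::rnorm(n, 0, spec$noise_sd_kg)
      data.frame(id = sprintf("%s%s%05d", race, sex, seq_len(n)),
                 sex = sex, race = race, age_y = age, height_cm = height,
                 fm_kg = fm, ffm_kg = ffm, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Design matrix over the 12-term polynomial basis
#'
#' Expands the records of a single (race, sex) group into the n x 12
#' design matrix with columns `{1, F, A, H, FA, FH, F2, F2A, F3, F4, F2H,
#' F3H}` (see [ffm_basis_terms()]). Groups are fitted separately, so mixed
#' groups are rejected.
#'
#' @param records cohort data frame (columns `sex`, `race`, `age_y`,
#'   `height_cm`, `fm_kg`).
#' @return numeric matrix, `nrow(records)` x 12.
#' @export
build_design_matrix <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_validation("records", "must be a non-empty data frame")
  needed <- c("sex", "race", "age_y", "height_cm", "fm_kg")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop_validation("records", paste("missing columns:", paste(miss, collapse = ", ")))
  if (length(unique(records$sex)) > 1L || length(unique(records$race)) > 1L)
    stop_validation("records",
                    "records mix (race, sex) groups; fit each group separately")
  f <- records$fm_kg; a <- records$age_y; h <- records$height_cm
  cbind(`1` = rep(1, nrow(records)), F = f, A = a, H = h, FA = f * a,
        FH = f * h, F2 = f^2, F2A = f^2 * a, F3 = f^3, F4 = f^4,
        F2H = f^2 * h, F3H = f^3 * h)
}

#' Ordinary least squares fit of the FFM polynomial for one group
#'
#' Regresses FFM on the 12-term basis for a single (race, sex) group.
#' Columns are rescaled internally to unit maximum absolute value before
#' the fit (the raw quartic basis is badly conditioned); coefficients and
#' standard errors are returned on the original scale, and p-values are
#' unaffected by the scaling. R^2 is computed as `1 - RSS/TSS` about the
#' mean.
#'
#' @param records cohort data frame for one group, with `ffm_kg`; needs
#'   more than 12 rows.
#' @param terms basis terms to include (default all 12).
#' @return object of class `ffm_fit`: list with `group`, `coefficients`,
#'   `standard_errors`, `p_values` (all keyed by term), `r_squared`,
#'   `sigma`, `n`.
#' @export
fit_group <- function(records, terms = ffm_basis_terms()) {
  X <- build_design_matrix(records)
  if (!all(terms %in% ffm_basis_terms()))
    stop_validation("terms", "unknown basis terms")
  X <- X[, terms, drop = FALSE]
  if (!"ffm_kg" %in% names(records))
    stop_validation("records", "missing columns: ffm_kg")
  y <- records$ffm_kg
  if (nrow(X) <= ncol(X))
    stop_validation("records",
                    sprintf("need more rows (%d) than basis terms (%d)",
                            nrow(X), ncol(X)))
  scal <- apply(abs(X), 2, max)
  scal[scal == 0] <- 1
  Xs <- sweep(X, 2, scal, "/")
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    dep <- colnames(Xs)[qrX$pivot[(qrX$rank + 1L):ncol(Xs)]]
    bc_stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                    paste(dep, collapse = ", ")),
            "bodycomp_fit_error")
  }
  fit <- stats::lm.fit(Xs, y)
  rss <- sum(fit$residuals^2)
  df <- nrow(Xs) - ncol(Xs)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se_s <- sqrt(diag(xtx_inv) * sigma2)
  beta <- fit$coefficients / scal
  se <- se_s / scal
  tval <- fit$coefficients / se_s
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  names(beta) <- names(se) <- names(pval) <- colnames(X)
  tss <- sum((y - mean(y))^2)
  structure(list(group = c(race = records$race[1], sex = records$sex[1]),
                 coefficients = beta, standard_errors = se, p_values = pval,
                 r_squared = 1 - rss / tss, sigma = sqrt(sigma2), n = nrow(Xs)),
            class = "ffm_fit")
}

#' @export
print.ffm_fit <- function(x, ...) {
  cat(sprintf("FFM polynomial fit: %s %s (n = %d, R^2 = %.4f, sigma = %.3f kg)\n",
              x$group["race"], x$group["sex"], x$n, x$r_squared, x$sigma))
  tab <- data.frame(estimate = x$coefficients, std_error = x$standard_errors,
                    p_value = x$p_values)
  print(format(tab, digits = 4))
  invisible(x)
}

#' Fit the FFM polynomial to every (race, sex) group in a cohort
#'
#' @param records cohort data frame (possibly mixed groups).
#' @return named list of [fit_group()] results, keyed `"AA.F"` etc.
#' @export
fit_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop_validation("records", "must be a non-empty data frame")
  key <- paste(records$race, records$sex, sep = ".")
  lapply(split(records, key), fit_group)
}

#' Significance screening of fitted terms
#'
#' Returns the basis terms whose two-sided p-value falls below `alpha`
#' (default 0.001, the selection threshold used to reduce the model).
#'
#' @param fit an [fit_group()] result.
#' @param alpha significance level.
#' @return character vector of retained term names.
#' @export
screen_terms <- function(fit, alpha = 0.001) {
  if (!inherits(fit, "ffm_fit")) stop_validation("fit", "must be an ffm_fit")
  check_scalar_number(alpha, "alpha", 0, 1)
  names(fit$p_values)[fit$p_values < alpha]
}

#' Backward-eliminated polynomial fit
#'
#' Starting from the full 12-term basis, repeatedly drops the least
#' significant term (largest p-value at or above `alpha`; the intercept is
#' always kept) and refits, until every remaining term is significant at
#' `alpha`.
#'
#' @inheritParams fit_group
#' @param alpha significance level for retention.
#' @return an `ffm_fit` over the retained terms.
#' @export
fit_screened <- function(records, alpha = 0.001) {
  terms <- ffm_basis_terms()
  repeat {
    fit <- fit_group(records, terms)
    p <- fit$p_values
    p["1"] <- 0  # intercept is structural
    worst <- which.max(p)
    if (p[worst] < alpha || length(terms) <= 1L) return(fit)
    terms <- setdiff(terms, names(p)[worst])
  }
}
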