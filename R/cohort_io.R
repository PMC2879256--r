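# Cohort CSV schema: comma-separated, header required, UTF-8, "." decimal.
# Required columns: id, sex, race, age_y, height_cm, fm_kg, ffm_kg.
# Optional follow-up columns for longitudinal records: fm_final_kg,
# ffm_final_kg.

COHORT_COLUMNS <- c("id", "sex", "race", "age_y", "height_cm", "fm_kg", "ffm_kg")
COHORT_FOLLOWUP <- c("fm_final_kg", "ffm_final_kg")

#' Read a cohort CSV
#'
#' Validates the schema and every row (sex/race labels case-insensitive,
#' covariates within the valid band, fat mass >= 0, fat-free mass > 0).
#' Row-level problems are collected and reported together with their line
#' numbers.
#'
#' @param path CSV path.
#' @return validated cohort data frame (canonical `M`/`F`, `AA`/`NAA`
#'   labels), with the optional follow-up columns if present.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_validation("path", sprintf("no such file: %s", path))
  # id/sex/race must never be type-guessed: a column of "F" values would
  # otherwise parse as logical
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(id = "character", sex = "character",
                                       race = "character"))
  miss <- setdiff(COHORT_COLUMNS, names(df))
  if (length(miss))
    bc_stop(sprintf("cohort CSV is missing column(s): %s",
                    paste(miss, collapse = ", ")),
            "bodycomp_schema_error")
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    id <- df$id[i]
    note <- function(field, msg) {
      problems[[length(problems) + 1L]] <<-
        sprintf("line %d (id %s): %s %s", line, id, field, msg)
    }
    df$sex[i] <- tryCatch(as_sex(df$sex[i]),
                          error = function(e) { note("sex", "is invalid"); NA })
    df$race[i] <- tryCatch(suppressWarnings(as_race(df$race[i])),
                           error = function(e) { note("race", "is invalid"); NA })
    num_ok <- function(x) is.numeric(x) && is.finite(x)
    if (!num_ok(df$age_y[i]) || df$age_y[i] < AGE_RANGE_Y[1] ||
        df$age_y[i] > AGE_RANGE_Y[2])
      note("age_y", sprintf("out of range [%g, %g]", AGE_RANGE_Y[1], AGE_RANGE_Y[2]))
    if (!num_ok(df$height_cm[i]) || df$height_cm[i] < HEIGHT_RANGE_CM[1] ||
        df$height_cm[i] > HEIGHT_RANGE_CM[2])
      note("height_cm", sprintf("out of range [%g, %g]",
                                HEIGHT_RANGE_CM[1], HEIGHT_RANGE_CM[2]))
    if (!num_ok(df$fm_kg[i]) || df$fm_kg[i] < 0) note("fm_kg", "must be >= 0")
    if (!num_ok(df$ffm_kg[i]) || df$ffm_kg[i] <= 0) note("ffm_kg", "must be > 0")
    for (col in intersect(COHORT_FOLLOWUP, names(df))) {
      v <- df[[col]][i]
      if (!is.na(v) && (!num_ok(v) || v < 0)) note(col, "must be >= 0")
    }
  }
  if (length(problems))
    bc_stop(paste0("cohort CSV has invalid rows:\n  ",
                   paste(problems, collapse = "\n  ")),
            "bodycomp_validation_error")
  df
}

#' Write a cohort CSV
#'
#' @param records cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  miss <- setdiff(COHORT_COLUMNS, names(records))
  if (length(miss))
    stop_validation("records", paste("missing columns:", paste(miss, collapse = ", ")))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Evaluate model predictions against measured longitudinal compositions
#'
#' For each longitudinal record (baseline and final FM/FFM measured),
#' predicts body composition with both model families and summarises
#' prediction errors (predicted - measured, mean +/- sample SD):
#' \itemize{
#'   \item polynomial model: baseline and final FM from inverting the
#'     mass-balance identity at the measured baseline and final weights;
#'     FFM change by subtraction.
#'   \item Forbes: baseline and final FM by the same inversion on the
#'     original (untranslated) sex-specific curve; FFM change from the
#'     translate calibrated through the measured baseline composition.
#' }
#' Records whose weights are infeasible for a model are dropped from that
#' model's summary (with a warning).
#'
#' @param records longitudinal cohort data frame (cohort columns plus
#'   `fm_final_kg`, `ffm_final_kg`).
#' @param registry_variant coefficient registry variant.
#' @return data frame with columns `model`, `quantity` (`fm_baseline`,
#'   `fm_final`, `delta_ffm`), `mean_error_kg`, `sd_error_kg`, `n`.
#' @export
evaluate_cohort <- function(records, registry_variant = "normalized") {
  if (!all(COHORT_FOLLOWUP %in% names(records)))
    stop_validation("records",
                    paste("longitudinal evaluation needs columns:",
                          paste(COHORT_FOLLOWUP, collapse = ", ")))
  n <- nrow(records)
  meas <- list(fm_baseline = records$fm_kg, fm_final = records$fm_final_kg,
               delta_ffm = records$ffm_final_kg - records$ffm_kg)
  pred <- list(
    nhanes = list(fm_baseline = rep(NA_real_, n), fm_final = rep(NA_real_, n),
                  delta_ffm = rep(NA_real_, n)),
    forbes = list(fm_baseline = rep(NA_real_, n), fm_final = rep(NA_real_, n),
                  delta_ffm = rep(NA_real_, n)))
  n_dropped <- 0L
  for (i in seq_len(n)) {
    cov <- subject_covariates(records$age_y[i], records$height_cm[i],
                              records$sex[i], records$race[i])
    w_b <- records$fm_kg[i] + records$ffm_kg[i]
    w_f <- records$fm_final_kg[i] + records$ffm_final_kg[i]
    nh <- tryCatch(delta_ffm_nhanes(w_b, w_f - w_b, cov, registry_variant),
                   bodycomp_error = function(e) NULL)
    if (!is.null(nh)) {
      pred$nhanes$fm_baseline[i] <- nh$fm_baseline_kg
      pred$nhanes$fm_final[i] <- nh$fm_final_kg
      pred$nhanes$delta_ffm[i] <- nh$delta_ffm_kg
    } else n_dropped <- n_dropped + 1L
    fb <- tryCatch({
      m <- forbes_model(records$sex[i])
      g <- function(f, w) f + forbes_ffm(f, m) - w
      fm_b <- stats::uniroot(g, c(1e-12, w_b), w = w_b, tol = 1e-9)$root
      fm_f <- stats::uniroot(g, c(1e-12, w_f), w = w_f, tol = 1e-9)$root
      dc <- delta_ffm_forbes(records$fm_kg[i], records$ffm_kg[i], w_f - w_b,
                             records$sex[i])
      list(fm_b = fm_b, fm_f = fm_f, dffm = dc$delta_ffm_kg)
    }, error = function(e) NULL)
    if (!is.null(fb)) {
      pred$forbes$fm_baseline[i] <- fb$fm_b
      pred$forbes$fm_final[i] <- fb$fm_f
      pred$forbes$delta_ffm[i] <- fb$dffm
    } else n_dropped <- n_dropped + 1L
  }
  if (n_dropped > 0L)
    warning(sprintf("%d record/model combinations were infeasible and dropped",
                    n_dropped), call. = FALSE)
  rows <- list()
  for (model in names(pred)) {
    for (q in names(meas)) {
      ok <- is.finite(pred[[model]][[q]])
      s <- summarize_errors(meas[[q]][ok], pred[[model]][[q]][ok])
      rows[[length(rows) + 1L]] <-
        data.frame(model = model, quantity = q, mean_error_kg = s$mean_error_kg,
                   sd_error_kg = s$sd_error_kg, n = s$n)
    }
  }
  do.call(rbind, rows)
}
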