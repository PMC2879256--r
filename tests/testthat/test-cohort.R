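test_that("cohort generation is reproducible and respects the spec", {
  spec <- cohort_spec(n_per_group = 50, seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 200L)
  expect_setequal(unique(paste(a$race, a$sex)), c("AA F", "AA M", "NAA F", "NAA M"))
  expect_true(all(a$age_y >= 18 & a$age_y <= 85))
  expect_true(all(a$height_cm >= 120 & a$height_cm <= 220))
  expect_true(all(a$fm_kg > 0))
  expect_error(cohort_spec(n_per_group = 5), class = "bodycomp_validation_error")
  expect_error(cohort_spec(noise_sd_kg = -1), class = "bodycomp_validation_error")
})

test_that("noiseless cohorts sit exactly on the generating polynomial", {
  spec <- cohort_spec(n_per_group = 30, noise_sd_kg = 0, seed = 9)
  cohort <- generate_cohort(spec)
  for (i in seq_len(nrow(cohort))) {
    cov <- cov_of(cohort, i)
    expect_equal(cohort$ffm_kg[i],
                 nhanes_ffm(cohort$fm_kg[i], cov, "corrected"),
                 tolerance = 1e-10)
  }
})

test_that("residual spread matches the requested noise level", {
  spec <- cohort_spec(n_per_group = 2000, noise_sd_kg = 1, seed = 77)
  cohort <- generate_cohort(spec)
  key <- paste(cohort$race, cohort$sex, sep = ".")
  for (g in unique(key)) {
    sub <- cohort[key == g, ]
    resid <- vapply(seq_len(nrow(sub)), function(i) {
      sub$ffm_kg[i] - nhanes_ffm(sub$fm_kg[i], cov_of(sub, i), "corrected")
    }, numeric(1))
    expect_equal(sd(resid), 1, tolerance = 0.05)
  }
})

test_that("design matrix columns are the twelve basis monomials", {
  rec <- data.frame(id = "x", sex = "F", race = "AA", age_y = 1,
                    height_cm = 150, fm_kg = 0, ffm_kg = 40)
  X <- build_design_matrix(rec)
  expect_identical(colnames(X), ffm_basis_terms())
  f_cols <- c("F", "FA", "FH", "F2", "F2A", "F3", "F4", "F2H", "F3H")
  expect_true(all(X[1, f_cols] == 0))
  set.seed(3)
  rec2 <- data.frame(id = "y", sex = "M", race = "NAA", age_y = runif(1, 20, 80),
                     height_cm = runif(1, 150, 190), fm_kg = runif(1, 5, 50),
                     ffm_kg = 60)
  X2 <- build_design_matrix(rec2)
  expect_equal(unname(X2[1, "F3H"]), rec2$fm_kg^3 * rec2$height_cm)
  expect_equal(unname(X2[1, "F2A"]), rec2$fm_kg^2 * rec2$age_y)
  mixed <- rbind(rec, transform(rec2, height_cm = 180))
  expect_error(build_design_matrix(mixed), class = "bodycomp_validation_error")
})

test_that("noiseless fits recover the generating coefficients essentially exactly", {
  spec <- cohort_spec(n_per_group = 400, noise_sd_kg = 0, seed = 42)
  cohort <- generate_cohort(spec)
  reg <- ffm_registry("corrected")
  fits <- fit_cohort(cohort)
  for (g in names(fits)) {
    truth <- reg[[g]]
    est <- fits[[g]]$coefficients
    expect_equal(unname(est[truth != 0] / truth[truth != 0]),
                 rep(1, sum(truth != 0)), tolerance = 1e-6)
    expect_equal(fits[[g]]$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("fit residuals have zero mean and R-squared decreases with noise", {
  r2 <- vapply(c(0, 1, 3, 5), function(noise) {
    spec <- cohort_spec(n_per_group = 600, noise_sd_kg = noise, seed = 10)
    cohort <- generate_cohort(spec)
    fit <- fit_group(cohort[cohort$race == "NAA" & cohort$sex == "F", ])
    pred <- drop(build_design_matrix(cohort[cohort$race == "NAA" & cohort$sex == "F", ]) %*%
                   fit$coefficients)
    resid <- cohort$ffm_kg[cohort$race == "NAA" & cohort$sex == "F"] - pred
    expect_lt(abs(mean(resid)), 1e-8)
    fit$r_squared
  }, numeric(1))
  expect_true(all(diff(r2) < 0))
  expect_gt(r2[2], 0.95)  # 1 kg noise barely dents the signal variance
})

test_that("refitting a fit's own predictions reproduces the fit", {
  spec <- cohort_spec(n_per_group = 300, noise_sd_kg = 2, seed = 8)
  cohort <- generate_cohort(spec)
  sub <- cohort[cohort$race == "AA" & cohort$sex == "M", ]
  fit1 <- fit_group(sub)
  sub$ffm_kg <- drop(build_design_matrix(sub) %*% fit1$coefficients)
  fit2 <- fit_group(sub)
  expect_equal(fit2$coefficients, fit1$coefficients, tolerance = 1e-6)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-10)
})

test_that("rank-deficient designs are reported with the collinear columns", {
  spec <- cohort_spec(n_per_group = 50, seed = 4)
  cohort <- generate_cohort(spec)
  sub <- cohort[cohort$race == "AA" & cohort$sex == "F", ]
  sub$age_y <- 30  # constant age makes A collinear with the intercept
  err <- tryCatch(fit_group(sub), condition = function(e) e)
  expect_s3_class(err, "bodycomp_fit_error")
  expect_match(conditionMessage(err), "collinear")
})

test_that("significance screening retains terms below alpha", {
  spec <- cohort_spec(n_per_group = 4000, noise_sd_kg = 1, seed = 21)
  cohort <- generate_cohort(spec)
  fit <- fit_group(cohort[cohort$race == "NAA" & cohort$sex == "M", ])
  expect_identical(screen_terms(fit, alpha = 1), ffm_basis_terms())
  retained <- screen_terms(fit, alpha = 0.001)
  # the strong main effects always survive at this sample size; the
  # near-collinear high-order interactions need not
  expect_true(all(c("1", "F", "A", "H") %in% retained))
  expect_true(all(fit$p_values[retained] < 0.001))
  expect_true(all(fit$p_values[setdiff(ffm_basis_terms(), retained)] >= 0.001))
})

test_that("a null coefficient is retained at about the type-I rate", {
  # generate from a truth with the F4 term removed, fit the full basis,
  # and screen at alpha = 0.05: F4 should survive in roughly 5% of runs
  set.seed(314)
  reg <- ffm_registry("normalized")
  truth <- reg$NAA.F
  truth["F4"] <- 0
  hits <- 0L
  n_reps <- 200L
  for (rep in seq_len(n_reps)) {
    n <- 400L
    age <- runif(n, 18, 85)
    height <- runif(n, 145, 180)
    fm <- rgamma(n, shape = (30.6 / 12.3)^2, scale = 12.3^2 / 30.6)
    rec <- data.frame(id = as.character(seq_len(n)), sex = "F", race = "NAA",
                      age_y = age, height_cm = height, fm_kg = fm,
                      ffm_kg = NA_real_)
    X <- build_design_matrix(rec)
    rec$ffm_kg <- drop(X %*% truth) + rnorm(n, 0, 2)
    fit <- fit_group(rec)
    if ("F4" %in% screen_terms(fit, alpha = 0.05)) hits <- hits + 1L
  }
  # binomial(200, 0.05): central 99.9% range is roughly [1, 22]
  expect_gte(hits, 1L)
  expect_lte(hits, 25L)
})

test_that("backward elimination keeps only significant terms plus the intercept", {
  spec <- cohort_spec(n_per_group = 2000, noise_sd_kg = 3, seed = 55)
  cohort <- generate_cohort(spec)
  fit <- fit_screened(cohort[cohort$race == "NAA" & cohort$sex == "F", ],
                      alpha = 0.001)
  terms <- names(fit$coefficients)
  expect_true("1" %in% terms)
  others <- setdiff(terms, "1")
  expect_true(all(fit$p_values[others] < 0.001))
})
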