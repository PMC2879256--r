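test_that("mass-balance inversion round-trips and agrees with bisection", {
  set.seed(11)
  d <- random_covariates(200)
  for (i in seq_len(200)) {
    cov <- cov_of(d, i)
    fm <- runif(1, 0.5, 80)
    total <- fm + nhanes_ffm(fm, cov, "corrected")
    solved <- tryCatch(solve_fm(total, cov, "corrected"),
                       bodycomp_ambiguity_error = function(e) e)
    if (inherits(solved, "condition")) {
      expect_true(any(abs(solved$roots - fm) < 1e-6))
      next
    }
    expect_equal(solved, fm, tolerance = 1e-6)
    oracle <- bisect_root(
      function(f) f + nhanes_ffm(f, cov, "corrected") - total,
      0, min(total, 100))  # same fat-mass band as the solver
    expect_equal(solved, oracle, tolerance = 1e-6)
  }
})

test_that("near the zero-fat bound the solved fat mass shrinks to first order", {
  cov <- subject_covariates(40, 170, "F", "NAA")
  eps <- 1e-3
  total <- nhanes_ffm(0, cov) + eps
  fm <- solve_fm(total, cov)
  # g(F) ~ (1 + phi'(0)) F near zero, so F ~ eps / (1 + phi'(0))
  expect_equal(fm, eps / (1 + nhanes_dffm_dfm(0, cov)), tolerance = 1e-3)
  oracle <- bisect_root(function(f) f + nhanes_ffm(f, cov) - total, 0, total)
  expect_equal(fm, oracle, tolerance = 1e-8)
})

test_that("infeasible totals report the zero-fat bound", {
  cov <- subject_covariates(34, 165, "F", "AA")
  err <- tryCatch(solve_fm(10, cov, "corrected"), condition = function(e) e)
  expect_s3_class(err, "bodycomp_infeasible_error")
  expect_match(conditionMessage(err), "zero-fat")
  # a total below any achievable composition fails whatever the intercept
  err2 <- tryCatch(solve_fm(10, cov), condition = function(e) e)
  expect_s3_class(err2, "bodycomp_infeasible_error")
})

test_that("longitudinal polynomial prediction conserves mass and is null at zero change", {
  set.seed(23)
  d <- random_covariates(100)
  for (i in seq_len(100)) {
    cov <- cov_of(d, i)
    fm <- runif(1, 5, 60)
    w <- fm + nhanes_ffm(fm, cov, "corrected")
    dw <- runif(1, -12, 12)
    ch <- tryCatch(delta_ffm_nhanes(w, dw, cov, "corrected"),
                   bodycomp_error = function(e) NULL)
    if (is.null(ch)) next  # large loss can cross the zero-fat bound
    expect_equal(ch$delta_fm_kg + ch$delta_ffm_kg, dw, tolerance = 1e-6)
    expect_equal(ch$fm_baseline_kg + ch$ffm_baseline_kg, w, tolerance = 1e-8)
  }
  cov <- subject_covariates(34, 165, "F", "AA")
  ch0 <- delta_ffm_nhanes(75, 0, cov)
  expect_equal(ch0$delta_fm_kg, 0, tolerance = 1e-8)
  expect_equal(ch0$delta_ffm_kg, 0, tolerance = 1e-8)
})

test_that("Forbes translate calibration passes through the baseline point", {
  # a point on the original female curve calibrates to D = 0
  expect_equal(calibrate_forbes_d(10, 10.4 * log(10) + 14.2, "F"), 0,
               tolerance = 1e-12)
  expect_equal(calibrate_forbes_d(30, 50, "F"), 50 - 10.4 * log(30) - 14.2,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:50) {
    fm <- runif(1, 0.5, 80)
    ffm <- runif(1, 20, 80)
    sex <- sample(c("M", "F"), 1)
    d <- calibrate_forbes_d(fm, ffm, sex)
    expect_equal(forbes_ffm(fm, forbes_model(sex, d)), ffm, tolerance = 1e-10)
  }
  expect_error(calibrate_forbes_d(0, 50, "F"), class = "bodycomp_domain_error")
})

test_that("Forbes weight-change prediction matches a bisection oracle", {
  # female, baseline (FM 30, FFM 50), 10 kg loss: solve
  # F + 10.4 ln F + 14.2 + D = 70 with D = 50 - 10.4 ln 30 - 14.2
  d <- calibrate_forbes_d(30, 50, "F")
  f_final <- bisect_root(function(f) f + 10.4 * log(f) + 14.2 + d - 70, 1e-9, 70)
  ch <- delta_ffm_forbes(30, 50, -10, "F")
  expect_equal(ch$fm_final_kg, f_final, tolerance = 1e-7)
  expect_equal(ch$delta_ffm_kg, 10.4 * (log(f_final) - log(30)),
               tolerance = 1e-7)
  ch0 <- delta_ffm_forbes(30, 50, 0, "F")
  expect_equal(ch0$delta_ffm_kg, 0, tolerance = 1e-9)
})

test_that("Forbes FFM change is invariant to vertical shifts of the baseline", {
  set.seed(99)
  for (i in 1:200) {
    fm_b <- runif(1, 2, 70)
    ffm_b <- runif(1, 25, 75)
    dw <- runif(1, -10, 10)
    sex <- sample(c("M", "F"), 1)
    a <- delta_ffm_forbes(fm_b, ffm_b, dw, sex)
    b <- delta_ffm_forbes(fm_b, ffm_b + 5, dw, sex)
    expect_lt(abs(a$delta_ffm_kg - b$delta_ffm_kg), 1e-8)
    expect_lt(abs(a$fm_final_kg - b$fm_final_kg), 1e-8)
  }
})

test_that("polynomial and Forbes predictions share sign for moderate scenarios", {
  set.seed(31)
  d <- random_covariates(60)
  for (i in seq_len(60)) {
    cov <- cov_of(d, i)
    fm <- runif(1, 15, 45)
    ffm <- nhanes_ffm(fm, cov, "corrected")
    w <- fm + ffm
    dw <- sample(c(-8, -4, 4, 8), 1)
    nh <- tryCatch(delta_ffm_nhanes(w, dw, cov, "corrected"),
                   bodycomp_error = function(e) NULL)
    if (is.null(nh)) next
    fo <- delta_ffm_forbes(fm, ffm, dw, cov$sex)
    expect_identical(sign(nh$delta_ffm_kg), sign(fo$delta_ffm_kg))
  }
})

test_that("error summaries use predicted minus measured with sample SD", {
  s <- summarize_errors(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$mean_error_kg, 0)
  expect_equal(s$sd_error_kg, 0)
  s <- summarize_errors(c(0, 0), c(1, -1))
  expect_equal(s$mean_error_kg, 0)
  expect_equal(s$sd_error_kg, sqrt(2), tolerance = 1e-12)
  s <- summarize_errors(c(0, 0, 0), c(1, 2, 3))
  expect_equal(s$mean_error_kg, 2)
  expect_equal(s$sd_error_kg, 1)
  expect_equal(s$n, 3L)
  expect_error(summarize_errors(numeric(0), numeric(0)),
               class = "bodycomp_validation_error")
  expect_error(summarize_errors(1:3, 1:2), class = "bodycomp_validation_error")
})
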