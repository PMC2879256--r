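# Independent oracles used across the suite; these deliberately avoid the
# code paths they check.

# Term-by-term polynomial evaluation: explicit monomial list summed with a
# plain loop (vs the evaluator's basis-matrix product).
oracle_ffm <- function(co, fm, age, height) {
  mono <- c(1, fm, age, height, fm * age, fm * height, fm^2, fm^2 * age,
            fm^3, fm^4, fm^2 * height, fm^3 * height)
  total <- 0
  for (i in seq_along(mono)) total <- total + co[[i]] * mono[[i]]
  total
}

# Plain bisection on a monotone-bracketed function; 200 iterations gives
# bracket width below 1e-55 * span, far tighter than any tolerance used.
bisect_root <- function(f, lower, upper, iterations = 200L) {
  fl <- f(lower)
  for (i in seq_len(iterations)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (sign(fm) == sign(fl)) {
      lower <- mid
      fl <- fm
    } else {
      upper <- mid
    }
  }
  (lower + upper) / 2
}

# Central finite difference for dFFM/dFM.
fd_slope <- function(fun, x, h = 1e-4) (fun(x + h) - fun(x - h)) / (2 * h)

random_covariates <- function(n) {
  data.frame(age_y = runif(n, 18, 85), height_cm = runif(n, 140, 200),
             sex = sample(c("M", "F"), n, replace = TRUE),
             race = sample(c("AA", "NAA"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

cov_of <- function(d, i) {
  subject_covariates(d$age_y[i], d$height_cm[i], d$sex[i], d$race[i])
}
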