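---
title: "Fat-free mass models, mass-balance inversion, and energy-balance coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fat-free mass models, mass-balance inversion, and energy-balance coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodycomp)
```

## The model

Body weight `W` splits into fat mass (`FM`, the energy store) and fat-free
mass (`FFM`, everything else). Cross-sectionally the two are strongly
related: lean people carry proportionally more FFM per kg of weight change
than obese people. The classical description is the Forbes log-linear
curve,

    FFM = s * ln(FM) + b,

with `s = 10.4`, `b = 14.2` kg for women and `s = 13.8`, `b = 16.9` kg for
men (the male curve is a log-linear fit to average-stature men, heights
172--176 cm). An individual undergoing weight change does not travel the
cross-sectional curve itself but a vertical translate of it,
`FFM = s*ln(FM) + b + D`; because all translates are parallel, the
predicted *change* in FFM for a given change in FM is independent of `D`,
which is why the Forbes curve predicts composition change well even where
it misplaces the composition itself. `calibrate_forbes_d()` fixes `D`
through a measured baseline `(FM, FFM)` point, and `delta_ffm_forbes()`
solves the final composition on the calibrated translate.

The Forbes curve has two limitations when coupled to an energy-balance
differential equation: `D` must be recalibrated per individual or study
population, and `FFM -> -Inf` as `FM -> 0`, which is biologically wrong —
starvation data show low but positive FFM at near-zero fat. The polynomial
class implemented here addresses both. For each of four groups — African
American (AA) and non-African American (NAA, all other ethnic groups),
female and male — FFM is a quartic polynomial in FM with age `A` (years)
and height `H` (cm) as covariates over the fixed 12-term basis

    {1, F, A, H, F*A, F*H, F^2, F^2*A, F^3, F^4, F^2*H, F^3*H}.

The covariates replace the per-study calibration: age, height, sex and
race select the individual's curve directly, and the intercept at `FM = 0`
is finite and positive, so the model implies a minimal ("zero-fat") BMI as
a function of height and age.

## The coefficient registry and its variants

The coefficients are shipped as data — a versioned plain-text table in
`inst/extdata/ffm_coefficients.tsv` — not as constants in code, so any
coefficient question is a data question. Three variants are provided
(`ffm_registry(variant)`):

* **printed** transcribes the published coefficient table literally. Two
  of its entries break the otherwise identical row pattern: the NAA-female
  row carries a bare `-0.002*A` where every other row has `-0.002*F*A`,
  and the AA-male row ends in `-0.000002*F*H` where every other row has
  `-0.000002*F^3*H`. The printed variant reads both literally.
* **normalized** (the default) replaces those two anomalous terms with
  their pattern-consistent `F*A` and `F^3*H` forms. This is the only
  reading consistent with the declared 12-term basis, and the change is
  numerically tiny.
* **corrected** additionally repairs the AA-female row, which is defective
  as printed in three mutually consistent ways. First, its height
  coefficient is 0.3 where the other three rows have 0.7; with 0.3 the
  zero-fat intercept `-69 - 0.04*A + 0.3*H` is *negative* for any height
  below about 235 cm, contradicting the model's own headline property of a
  non-negative intercept, so it is set to the pattern-consistent 0.7.
  Second, even with that repair the row does not reproduce the published
  reference compositions for an AA female aged 34, height 165 cm —
  `FFM = 47.25` kg at `FM = 27.75` kg and `FFM = 44.26` kg at
  `FM = 20.74` kg. No single-coefficient change can fix both points (the
  required ratio of corrections matches no basis monomial), so the two
  row parameters least constrained by the row pattern — the intercept and
  the linear-`F` coefficient — are recalibrated by solving the 2x2 linear
  system that makes the row interpolate both reference points exactly.
  The resulting row (intercept −79.9196, `F` coefficient 2.1814) has a
  positive zero-fat intercept across the full covariate band and a
  strictly increasing total-mass function over the physiological fat-mass
  range.

The corrected variant is the recommended surface for AA-female subjects
and is the default truth for the synthetic-cohort generator; the other
three rows are identical between `normalized` and `corrected`. The
repair is deliberately confined to one row of the data table; the
evaluator, solver and fitting code are identical across variants.

```{r}
cov <- subject_covariates(age_y = 34, height_cm = 165, sex = "F", race = "AA")
solve_fm(75, cov, registry_variant = "corrected")
```

## Inverting the mass-balance identity

`solve_fm()` recovers composition from weight by solving
`g(F) = F + FFM(F; A, H) - W = 0`. The solver brackets on
`[0, min(W, 100)]` kg and refines with `stats::uniroot()` to an absolute
tolerance of 1e-8 kg — tight enough that values reported to two decimals
are independent of the solver path. Three numerical choices matter:

* **Feasibility.** If `W <= FFM(0)` no non-negative-fat solution exists
  and the solver reports the zero-fat bound rather than returning a
  boundary value.
* **The 100 kg cap.** The quartic tails are not meaningful beyond the
  fat-mass band the model was built on; for extreme covariates (very tall,
  young subjects) they turn over and can generate a spurious second root
  at very high fat mass. The search therefore stops at 100 kg fat mass
  rather than extending to `W`.
* **Ambiguity detection.** `g` is sampled at 512 points across the
  bracket; if more than one sign change is found, all bracketed roots are
  refined and reported in an ambiguity error instead of silently picking
  one. Uniqueness is a property of the physiological band (the derivative
  `1 + dFFM/dFM` stays positive for fat mass up to 80 kg across the whole
  covariate grid, verified in the test suite), not of the whole domain.

Longitudinal prediction (`delta_ffm_nhanes()`) solves the identity at the
baseline and final weights with *identical* covariates: age and height
are frozen at baseline over the study interval, matching how the
reference calculation uses a single age for both solves. By mass balance
the FFM change is `dW - dFM` exactly.

## Zero-fat BMI curves

At `FM = 0` only the intercept, `A` and `H` terms survive, so
`bmi_at_zero_fat()` is `(c1 + cA*A + cH*H) / (H/100)^2`. The claimed
shape — BMI increasing in height and concave down — is checked by finite
differences on a 1-cm grid (`curve_shape_report()`) rather than
symbolically: for this rational-function form the sign pattern at 1-cm
resolution is decisive, and the numeric check also covers any future
registry edits. Zero first or second differences count as violations,
since the claim is strict monotonicity and strict concavity. Ageing
lowers the zero-fat FFM by exactly `0.04 * dA` kg at every height; on the
BMI scale the vertical offset is `0.04 * dA / (H/100)^2`, constant only
after rescaling by height squared.

## The synthetic cohort generator

No reference individual-level data ship with the package, so
`generate_cohort()` emulates the cross-sectional structure the regression
assumes, per group: age uniform on [18, 85] y; height normal, truncated
to the valid band, with sex-specific moments 174.3 ± 7.9 cm (men) and
160.6 ± 7.2 cm (women); fat mass gamma — right-skewed and positive — with
moments matched to 24.2 ± 10.4 kg (men) and 30.6 ± 12.3 kg (women); and
`FFM = polynomial(FM; A, H) + N(0, sd)` with a default noise SD of 3 kg,
the residual spread implied by a coefficient of determination near 0.86
at a population FFM SD of about 8 kg. All draws flow through one seed.

What the generator does *not* emulate: survey design weights, the joint
dependence of fat mass on age and height in real populations,
measurement error in the covariates, and non-Gaussian residual structure.
Passing recovery tests therefore demonstrate that the fitting machinery
is correct and well-conditioned, not that the shipped coefficients would
be recovered from real survey data.

## Refitting and screening

`fit_group()` is ordinary least squares of FFM on the 12-term basis, one
fit per (race, sex) group — the four rows are treated as independent
models because any shared-coefficient structure across groups is not
recoverable from the published table alone. The raw quartic basis spans
eight orders of magnitude, so columns are rescaled to unit maximum
absolute value before the QR solve and the coefficients and standard
errors are mapped back afterwards; p-values are invariant to this.
`screen_terms()` applies the selection threshold `P < 0.001` in a single
pass; `fit_screened()` adds a conventional backward-elimination loop
(drop the worst term at or above the threshold, refit, repeat; the
intercept is structural and never dropped). A full best-subset search
over all covariate interactions is out of scope.

## Energy-balance coupling

Writing `FFM = phi(FM)` collapses the paired FM/FFM energy balance to one
state equation by the chain rule:

    (c_f + c_l * phi'(FM)) dFM/dt = I(t) - E(FM, phi(FM)),

where `c_l` and `c_f` are the energy conversion constants (kcal per kg of
FFM and FM) and `E` is the expenditure rate in kcal/d. The package takes
**no default values** for `c_l` and `c_f` and ships no specific
expenditure model: both are user configuration (a linear reference form
`E = E0 + g1*FFM + g2*FM` is provided for testing and illustration). The
derivative `phi'` is the closed-form polynomial derivative
(`nhanes_dffm_dfm()`), not a finite difference.

`simulate_trajectory()` integrates with the classical fixed-step
fourth-order Runge-Kutta scheme (default step 1 day). Fixed stepping was
chosen over adaptive control because the dynamics are smooth, slow and
one-dimensional, and bit-reproducibility across runs matters more than
step-count economy here. A second state, the running integral of
`I - E`, is integrated alongside so that the defining energy-partition
identity `c_f*dFM + c_l*dFFM = integral(I - E) dt` can be verified on any
output to integration accuracy. If fat mass leaves [0, 120] kg (or a
Runge-Kutta stage evaluates outside the model's domain) the trajectory is
truncated at the crossing step with a warning rather than extrapolated.

## Problem sizes and tolerances used in the test suite

The suite verifies, among other properties: evaluator agreement with a
term-by-term oracle at 1e-9 relative over 1000 random states; inversion
round-trips and agreement with a 200-iteration bisection oracle at 1e-6
kg over 500 random feasible states; Forbes secant invariance at 1e-8 kg
over 200 scenario pairs; shape of all twelve zero-fat curves (four
groups, ages 20/30/40) over 145--195 cm; coefficient recovery within ±4
standard errors in at least 95 of 100 replicates at 5000 records per
group and 1 kg noise, with noiseless fits exact to 1e-6 relative; and
energy conservation within 0.1% of cumulative flux on a 100-day
constant-deficit trajectory, with step-halving confirming at least
third-order observed convergence. These sizes were chosen to make the
statistical assertions sharp while keeping the default test run fast.

## Known limitations

* The corrected AA-female row is a repair calibrated to two published
  reference compositions, not a refit to survey data; its out-of-sample
  behaviour between and beyond those points inherits the printed row's
  higher-order terms.
* Covariates are frozen during longitudinal prediction; multi-year
  interventions in which ageing matters are outside the intended use.
* The polynomial class is valid for adults within the covariate band
  (age 8--110 y enforced, fitted band 18--85 y; height 120--220 cm; fat
  mass up to ~100 kg); the evaluator refuses rather than extrapolates.
* Predicted compositions are cross-sectional expectations; subjects far
  off the population band (e.g. after massive surgical weight loss)
  deviate systematically, which is precisely what the error-summary
  machinery (`evaluate_cohort()`) is for.
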