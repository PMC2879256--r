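# bodycomp

Body-composition modelling for energy-balance work: who carries how much
fat-free mass (FFM) at a given fat mass (FM), and how FFM changes when
weight changes.

Total body mass obeys the mass-balance identity `W = FM + FFM`. Given a
cross-sectional model `FFM = phi(FM; covariates)`, that identity can be
inverted to recover body composition from weight alone, longitudinal FFM
change can be predicted from weight change, and the pair can be coupled
to a one-dimensional energy-balance differential equation

    (c_f + c_l * phi'(FM)) dFM/dt = I - E(FM, FFM)

for weight-trajectory simulation. The package implements two model
families:

* the **Forbes log-linear curves** `FFM = s*ln(FM) + b` (female:
  `10.4 ln FM + 14.2`; male: `13.8 ln FM + 16.9`) and their vertically
  translated family `+ D`, with `D` calibrated through an individual's
  baseline composition; and
* a **class of fourth-order FFM–FM polynomials** over the basis
  `{1, F, A, H, FA, FH, F², F²A, F³, F⁴, F²H, F³H}` with age `A` (y),
  height `H` (cm), sex and race group (African American vs all others)
  as covariates, developed from the NHANES 1999–2004 DXA reference
  population. The polynomial intercepts are positive at `FM = 0`, giving
  a minimal ("zero-fat") BMI as a function of height and age.

Around the two families the package provides: bracketed root-finding
inversion of the mass-balance identity (`solve_fm()`), longitudinal
composition-change prediction for both families (`delta_ffm_nhanes()`,
`delta_ffm_forbes()`), zero-fat BMI curves and shape verification
(`zero_fat_curve()`, `curve_shape_report()`), a synthetic-cohort
generator and OLS refitting of the polynomial class with significance
screening (`generate_cohort()`, `fit_group()`, `screen_terms()`), Table-4
style error summaries against measured longitudinal data
(`evaluate_cohort()`), an energy-balance integrator
(`simulate_trajectory()`), and a command-line interface (`exec/bodycomp`
or `run_command()`).

The polynomial coefficients ship as a versioned plain-text registry with
three variants — `printed` (literal transcription of the published
table), `normalized` (default; two typographically anomalous terms
replaced by their pattern-consistent forms) and `corrected` (the
AA-female row repaired and recalibrated against the published reference
compositions). See `?ffm_registry` and the vignette
`vignettes/ffm-models.Rmd` for why the repair is needed and how it was
derived.

## Worked example

An African American woman, age 34, height 165 cm, baseline weight 75 kg,
loses 10 kg. What happened to her body composition?

```r
library(bodycomp)
cov <- subject_covariates(age_y = 34, height_cm = 165, sex = "F", race = "AA")
solve_fm(75, cov, registry_variant = "corrected")
#> [1] 27.75
delta_ffm_nhanes(75, -10, cov, registry_variant = "corrected")
#> composition change (nhanes model)
#>   baseline: FM   27.750 kg  FFM   47.250 kg  total   75.000 kg
#>   final:    FM   20.740 kg  FFM   44.260 kg  total   65.000 kg
#>   change:   FM   -7.010 kg  FFM   -2.990 kg  total  -10.000 kg
```

Of 75 kg, 27.75 kg is fat; after the 10 kg loss the model attributes
7.01 kg to fat and 2.99 kg to fat-free mass. The same prediction from a
Forbes translate calibrated through her baseline composition:

```r
delta_ffm_forbes(27.75, 47.25, -10, sex = "F")$delta_ffm_kg
#> [1] -3.015437
```

The minimal BMI her covariates imply at zero fat, and the same from the
command line:

```r
bmi_at_zero_fat(cov, registry_variant = "corrected")
#> [1] 12.56947
```

```sh
bodycomp solve --weight 75 --age 34 --height 165 --sex F --race AA --variant corrected
# FM (kg):  27.75
# FFM (kg): 47.25
# FFMI (kg/m^2): 17.35537
# FMI (kg/m^2):  10.19284
```

Subcommands: `eval`, `solve`, `delta`, `zerofat`, `simulate`, `fit`,
`evaluate`, `ode`; run with no arguments for usage.

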