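# baclopk

Population and noncompartmental pharmacokinetics of oral baclofen under
herbal pretreatment.

Baclofen is the reference drug for spasticity; herbal preparations such
as Oyaksungisan (OY) and *Achyranthes bidentata* radix extract (AB) are
commonly co-used for the same indication, raising the question of
pharmacokinetic interaction. A rat study compared a single 1 mg/kg oral
baclofen dose after 7 days of pretreatment with water (control, n = 6),
OY (n = 4) or AB (n = 5) and concluded that OY roughly halves the
absorption rate constant without changing the extent of absorption. The
raw animal data were never deposited — only summary tables — so this
package rebuilds the entire analysis chain as testable code.

## What it implements

* **Structural model** — two-compartment disposition with first-order
  oral absorption and a urinary elimination pathway:

  ```
  dXgut/dt = -Ka·Xgut                                  Xgut(0) = F·Dose
  dX1/dt   =  Ka·Xgut - (K12 + Kel,ur + Kel)·X1 + K21·X2
  dX2/dt   =  K12·X1 - K21·X2
  dXu/dt   =  Kel,ur·X1
  ```

  with Cp = X1/Vc. Solved exactly (tri-exponential / matrix
  exponential; `pk_profile()`) with a stiff ODE integrator as an
  independent oracle (`pk_profile_ode()`), plus derived kinetics
  (`macro_constants()`: absorption and terminal half-lives, hybrid
  exponents α and β, clearance, urinary recovery, flip-flop flag).
* **Virtual studies** — `population_model()` + `study_design()` +
  `simulate_study()` generate long-format datasets at the published
  design with log-normal between-subject variability and combined
  additive/proportional residual error.
* **NCA** — `run_nca()` / `nca_summary()`: Cmax, Tmax, λz with
  automatic terminal-window selection, t½, linear-up/log-down AUC,
  CL/F, Vz/F, urinary recovery and absolute bioavailability against a
  dose-normalized IV reference.
* **Population fit** — `fit_mcpem()`: importance-sampling Monte Carlo
  parametric EM with arm-specific Ka and F, log/logit parameterisation,
  adaptive per-subject proposals, periodic direct-likelihood polish,
  an IV-clearance identifiability anchor, and BHHH relative standard
  errors. `tidy()`/`glance()` return the estimates table and fit
  summary; `vpc()`, `npde()`, `profile_objective()` and
  `compare_groups()` cover the diagnostic battery; `autoplot()` methods
  draw the standard figures.
* **Pipeline** — `reproduce_study()` chains
  simulate → NCA → fit → VPC/NPDE → statistics → derived quantities
  from one (YAML-able) configuration and writes CSV/JSON results with
  an embedded config hash.

## Worked example

```r
library(baclopk)

pop <- population_model()     # published estimates as the generating truth
dat <- simulate_study(pop, study_design(), seed = 1)

nca <- run_nca(dat, iv_auc_ref = baclofen_iv_auc_reference())
dplyr::filter(nca_summary(nca), parameter == "cmax")
#> # A tibble: 3 × 5
#>   group   parameter     n  mean    sd
#>   <chr>   <chr>     <int> <dbl> <dbl>
#> 1 AB      cmax          5  757. 112.
#> 2 OY      cmax          4  344.  48.3
#> 3 control cmax          6  591. 222.
```

The OY arm's mean Cmax is clearly depressed relative to control and AB
— the direct signature of slower absorption at matched exposure. The
population fit quantifies it:

```r
fit <- fit_mcpem(dat, fit_config(seed = 2, compute_rse = FALSE))
dplyr::filter(tidy(fit), startsWith(parameter, "ka"))
#> # A tibble: 3 × 5
#>   parameter  estimate rse_pct bsv_cv_pct bsv_rse_pct
#>   <chr>         <dbl>   <dbl>      <dbl>       <dbl>
#> 1 ka_AB         1.42       NA       1.70          NA
#> 2 ka_control    1.15       NA      56.9           NA
#> 3 ka_OY         0.470      NA       9.69          NA

log(2) / 0.470   # absorption half-life in the OY arm, hr
#> [1] 1.48
```

Even at the published study size (15 rats) the fitted Ka ordering
OY ≪ control < AB reproduces the interaction: absorption under OY takes
more than twice as long (generating values: half-lives 0.54 hr control
vs 1.33 hr OY). `vpc(fit, dat)` and `npde(fit, dat)` check the fit;
`compare_groups(nca)` runs the t-test/ANOVA + Scheffé battery.

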