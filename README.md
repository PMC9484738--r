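# stpe: short-time ultrasound poroelastography

Poroelastography estimates the Young's modulus (E), Poisson's ratio (nu)
and vascular permeability (Lp) of a tumor embedded in normal tissue from
time series of axial and lateral strain images acquired under sustained
(creep) compression. Classical protocols wait for the strains to reach
steady state, which takes minutes; **short-time poroelastography (STPE)**
fits the first-order creep model

    s(t) = eta + (alpha - eta) * exp(-t / tau)

to a truncated *window of observation* (WoO), predicts the steady state
`eta` and the strain time constant `tau`, and reconstructs from those:

* the background moduli from the far-field steady state
  (`E_b = sigma0 / |eta_zz|`, `nu_b = |eta_rr / eta_zz|`);
* the inclusion `E_i`, `nu_i` by minimising the mismatch between the
  geometric and material expressions of the Eshelby interior eigenstrain;
* the vascular permeability from `tau = 1 / (H_A * Lp * S/V)` with
  `H_A = E (1 - nu) / ((1 - 2 nu)(1 + nu))` the aggregate modulus and
  `S/V` the capillary surface-to-volume ratio.

The package is aimed at elastography researchers: it contains the analytic
phantom generator (Eshelby interior strains + exponential relaxation), a
convolution-model RF ultrasound simulator, a two-step speckle tracker
(integer dynamic programming followed by Horn-Schunck refinement), EOF
(truncated SVD) denoising, variable-projection curve fitting, the elastic
inversion, the transport conversions (force-sensor stress, tumor-volume
S/V regression), and an evaluation harness that quantifies the estimation
error as the window shrinks to multiples of the time constant.

## Worked example

Generate a phantom with a 7.5 mm spherical tumor (E = 60 kPa, nu = 0.4,
tau = 10 s) in a 30 kPa background under 1 kPa creep, fit the full record,
then refit a two-time-constant window:

```r
library(stpe)
ser  <- generate_strain_series(stpe_scenarios(grid_mm = 0.5)$A)
fit  <- stpe_fit(ser)
print(fit)
#> Short-time poroelastography fit
#>
#> Call:  stpe_fit(series = ser)
#>
#> Window of observation: 60 s (601 frames)
#> Coefficients:
#>       E_i      nu_i       E_b      nu_b     tau_s        Lp
#> 6.000e+04 4.000e-01 3.000e+04 3.000e-01 1.000e+01 3.889e-11

short <- stpe_fit(ser, window_s = 20)
round(100 * abs(coef(short) - coef(fit)) / coef(fit), 4)
#>   E_i  nu_i   E_b  nu_b tau_s    Lp
#> 0e+00 0e+00 0e+00 0e+00 1e-04 1e-04
```

`E_i`/`nu_i`/`E_b`/`nu_b` are Pa and dimensionless, `tau_s` seconds, `Lp`
m/(Pa s). On noise-free phantom data the model is exact, so a 2-TC window
reproduces the full-record estimates to optimizer precision; with noise
(`add_strain_noise()`, or the full RF chain via `simulate_rf_series()` +
`track_rf_series()`) the window dependence becomes visible:

```r
rep <- run_stpe_experiment(list(scenario = "A", condition = "strain-noise",
                                snr_db = 40, woo_multiples = c(0.5, 1, 2),
                                grid_mm = 0.8, n_reps = 1, seed = 2))
rep$pre       # percent relative error vs the full record, per window
```

A thin command-line front end is installed under
`system.file("scripts", "stpe", package = "stpe")` with `simulate`, `fit`
and `evaluate` subcommands.

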