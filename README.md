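# spmekin

Second-order kinetic modeling of flavor release measured by headspace
solid-phase microextraction (HS-SPME).

Extraction-time profiles of small flavor esters — GC peak area versus
SPME exposure time — often rise past their eventual plateau and then
decay (an overshoot), because adsorption onto the fiber and release
back into the headspace run in parallel on different time scales.
`spmekin` is for analytical chemists who want reproducible *parameters*
out of such profiles rather than noisy point measurements. It models
the amount on the fiber as

```
C(t) = k1 (1 - exp(-t/tau1)) - k2 (1 - exp(-t/tau2)),   k1 > k2, tau1 < tau2
```

with plateau `C_inf = k1 - k2`, peak time
`t_max = tau1 tau2 / (tau2 - tau1) * ln(k1 tau2 / (k2 tau1))`, and peak
height `C_max = C(t_max)`, and fits triplicate profiles with a two-loop
procedure:

* **inner loop** — per replicate, bound-constrained weighted least
  squares for `(k1, k2, tau1, tau2)`, with weight `W` on the observed
  peak sample and tabulated starting rules for the time constants;
* **outer loop** — one shared `W` per compound, chosen to minimize
  `F`, the summed relative standard deviation (RSD) of the four
  parameters across the triplicate.

A synthetic-profile generator (per-replicate parameter jitter plus
multiplicative lognormal noise, with presets for 24 published
compound/matrix/temperature combinations) makes the whole pipeline
testable without any instrument data, and a hold-out validator predicts
one withheld late-time point per replicate.

## Worked example

Simulate a triplicate from the ethyl octanoate 40 °C preset
(normalized amplitudes 174.2/173.2, time constants 58.30/59.08 min),
fit it, and validate at the withheld 300-minute point:

```r
library(spmekin)

scenario <- preset_scenarios(seed = 1)[["ethyl_octanoate_40C"]]
set <- normalize_set(generate_replicates(scenario))
fit <- optimize_W(set, fit_config(seed = 1))
fit
#> compound_fit: ethyl octanoate / alcoholic beverage 40 C
#>   W = 1.00, F = 2.18%, total RMSE = 0.076
#>   means: k1 = 100, k2 = 99.03, tau1 = 60, tau2 = 60.21
#>   RSD%:  k1 = 0.00, k2 = 0.00, tau1 = 1.09, tau2 = 1.09

held <- select_validation_point(
  normalize_set(generate_replicates(scenario)), 300
)
vfit <- optimize_W(held, fit_config(seed = 1))
validate_holdout(vfit, held)
#>          compound               condition replicate t_holdout observed predicted discrepancy_percent
#> 1 ethyl octanoate alcoholic beverage 40 C         1       300        1 0.9882476           -1.175237
#> 2 ethyl octanoate alcoholic beverage 40 C         2       300        1 0.9555850           -4.441504
#> 3 ethyl octanoate alcoholic beverage 40 C         3       300        1 0.9128946           -8.710538
#> max |discrepancy| = 8.71%
```

Reading the output: `F = 2.18%` is the summed RSD of the four fitted
parameters across the three replicates — each parameter reproduces to
about 1 % despite 3 % measurement noise, which is the method's point.
`total RMSE = 0.076` sums the three per-replicate fit errors on the
normalized scale (each curve fits to ~0.025). The validation block
predicts each replicate's withheld 300-minute observation from
parameters fitted without it; discrepancies stay inside the ±10 % band
expected for profiles that reach equilibrium within the sampling
window. The peak algebra is available directly too:

```r
p <- kinetic_params(k1 = 2, k2 = 1, tau1 = 10, tau2 = 20)
c(peak_time(p), peak_conc(p), equilibrium_conc(p))
#> [1] 27.72589  1.12500  1.00000
```

File-based workflows use `cmd_simulate()` / `cmd_fit()` /
`cmd_validate()` (CSV in, CSV + JSON manifest out), or the equivalent
`inst/cli/spmekin.R` script with `fit`, `simulate`, and `validate`
subcommands.

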