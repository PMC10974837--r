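# dhfsim

Design-stage simulation and uncertainty analysis for **dual-heat-flux (DHF)
core body temperature probes** — the skin-mounted sensors used in wearable
thermometry for sports, occupational-safety and medical monitoring.

A DHF probe carries two adjacent channels of thermally resistive material
with different resistances. At steady state, each channel obeys the
single-flux relation `CBT = T_ss + q/h_t`; combining the two channels
eliminates the unknown skin heat-transfer coefficient `h_t`:

```
CBT_HT = T_ss1 + q1 (T_ss1 − T_ss2) / (q2 − q1)                    (flux-based)
CBT_TT = T_ss1 + ΔT_s1 ΔT_ss / (k ΔT_s2 − ΔT_s1),  k = h_s2/h_s1   (temperature-only)
```

The package provides, for probe designers:

* a lumped steady-state forward model of the blood–skin–sensor–air stack
  (`dhf_forward()`), producing error-free readings for any geometry;
* the six estimator variants — `HT`, `TT`, their paired-sensor forms
  `HTp`, `TTp` (calibrated differential measurements), and multi-equation
  averaged forms `HTpm`, `TTpm` (`estimate_cbt()`);
* a per-variant Gaussian measurement-noise model (`dhf_noise()`,
  `sample_measured_set()`);
* Monte Carlo uncertainty propagation with repeatability estimates
  (`estimate_uncertainty()`: mean `mu_cbt` and spread `su_cbt` of per-trial
  error SDs);
* first-order Taylor uncertainty budgets with per-component shares
  (`combined_uncertainty()`), backed by a finite-difference oracle;
* parameter sweeps over ambient temperature, CBT, channel coefficients,
  coefficient ratio and convection (`run_sweep()`, `dhf_experiment()`),
  with CSV/JSON-manifest output and two-panel figures.

## Worked example

```r
library(dhfsim)

probe <- dhf_probe()          # PDMS 15/30 mm channels, 2.5 mm skin, h_sa = 6.1
dhf_forward(probe, cbt = 37, t_amb = 25)
#> Error-free DHF readings (CBT = 37, T_amb = 25 deg C)
#>  quantity channel   value  unit
#>         q       1 44.3300 W/m^2
#>         q       2 32.3700 W/m^2
#>      T_ss       1 36.7000  degC
#>      T_ss       2 36.7800  degC
#>      T_sa       1 32.2700  degC
#>      T_sa       2 30.3100  degC
#>     dT_ss      NA -0.0808  degC
#>     dT_s1       1  4.4330  degC
#>     dT_s2       2  6.4740  degC
```

Channel 1 (thinner, `h_s1 = 10`) passes more heat than channel 2
(`h_s2 = 5`), so its skin-side surface is slightly cooler — that 0.08 °C
contrast is the signal the dual-flux estimators live on.

```r
estimate_uncertainty("TTp", n_reps = 2000, n_trials = 10, seed = 3)
#> Monte Carlo CBT uncertainty (TTp): mu_cbt = 0.058286, su_cbt = 0.00058 deg C
#>   2000 reps x 10 trials; 0 non-finite estimates

combined_uncertainty("TT")
#> Taylor uncertainty budget (TT): u_combined = 0.2556 deg C
#>  component sensitivity   u_x     share
#>      T_ss1    -2.89000 0.053 0.3591000
#>      T_ss2     3.83200 0.053 0.6315000
#>      T_sa1     0.18290 0.053 0.0014390
#>      T_sa2    -0.12520 0.053 0.0006744
#>       h_s1    -0.08108 0.120 0.0014490
#>       h_s2     0.16220 0.120 0.0057970
```

The paired variant reaches ~0.058 °C where the unpaired temperature-only
variant sits at ~0.26 °C — pairing the skin sensors removes the dominant
absolute-temperature contribution (here ~99 % of the TT budget). Sweeps
and figures:

```r
tab <- run_sweep(dhf_experiment("e1"), n_reps = 2000, n_trials = 20, seed = 1)
write_results(tab, "e1.csv", config = dhf_config())   # CSV + JSON manifest
render_sweep_figure(tab, "e1.png")                    # mu_cbt / su_cbt panels
```

or from a shell, via the thin CLI:

```sh
Rscript inst/cli/dhf.R forward --cbt 37 --tamb 25
Rscript inst/cli/dhf.R sweep --experiment e4 --reps 2000 --trials 20 \
        --seed 1 --out e4.csv --fig e4.png
Rscript inst/cli/dhf.R reproduce --fast --outdir results   # all five sweeps, ~1 min
```

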