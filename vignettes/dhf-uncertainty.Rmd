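---
title: "Uncertainty analysis of dual-heat-flux core temperature probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty analysis of dual-heat-flux core temperature probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhfsim)
```

## The physical model

A dual-heat-flux (DHF) probe sits on the skin and carries two adjacent
channels of thermally resistive material with deliberately different
resistances. Heat flows from the blood (at core body temperature, CBT)
through the skin, through each channel, and into the air by convection. At
steady state each layer is a thermal resistance, and with
$h = k/d$ (conductivity over thickness, W/(m²·K)) the overall coefficient of
channel $i$ is the series combination

$$\frac{1}{h_i} = \frac{1}{h_t} + \frac{1}{h_{si}} + \frac{1}{h_{sa}},$$

so that the channel flux and surface temperatures are

$$q_i = h_i\,(\mathrm{CBT} - T_{amb}), \qquad
T_{ssi} = \mathrm{CBT} - q_i/h_t, \qquad
T_{sai} = T_{ssi} - q_i/h_{si}.$$

Everything is algebraic and affine in the driving gradient
$\mathrm{CBT}-T_{amb}$: there is no thermal capacitance, no transient, and
Celsius temperatures are safe throughout. The default probe is two PDMS
channels ($k = 0.15$ W/(m·K), 15 and 30 mm thick, so $h_{s1}=10$,
$h_{s2}=5$ W/(m²·K)) over 2.5 mm of skin ($k_t = 0.37$, $h_t = 148$) under
natural convection ($h_{sa} = 6.1$, one value applied to both channels).

```{r}
dhf_forward(dhf_probe(), cbt = 37, t_amb = 25)
```

## The six estimators

A single channel gives $\mathrm{CBT} = T_{ss} + q/h_t$, which requires the
skin coefficient $h_t$ — unknown and highly variable across people and
sites. Two channels eliminate it: equating the two single-channel equations
gives $h_t = (q_1-q_2)/(T_{ss2}-T_{ss1})$ and, substituting back,

$$\mathrm{CBT}_{HT} = T_{ss1} + \frac{q_1\,(T_{ss1}-T_{ss2})}{q_2-q_1}.$$

Replacing each flux by $h_{si}$ times the temperature drop across the
channel turns this into the temperature-only form

$$\mathrm{CBT}_{TT} = T_{ss1} +
\frac{(T_{ss1}-T_{sa1})(T_{ss1}-T_{ss2})}{k\,(T_{ss2}-T_{sa2})-(T_{ss1}-T_{sa1})},$$

where $k = h_{s2}/h_{s1}$ is the only probe property that survives — the
characteristic parameter. Two refinements give six variants in total:

* **pairing ("p")**: a temperature-sensor pair whose mutual bias has been
  calibrated out (e.g. in an oil bath) measures a *differential*
  ($\Delta T_{ss}$, $\Delta T_{s1}$, $\Delta T_{s2}$) with an uncertainty two
  orders of magnitude below an absolute reading;
* **multi-equation averaging ("m")**: the estimator can be re-based on any
  of the measured temperatures; averaging the two (HT) or four (TT)
  re-expressions of the same measurement event cancels part of the absolute
  sensor noise.

On error-free readings all six variants return CBT exactly, for any
non-degenerate probe ($h_{s1} \neq h_{s2}$) and any $T_{amb} \neq$ CBT; the
test suite asserts this to $10^{-9}$ °C over a grid of operating points.

## The noise model

Each measured quantity is the true value plus independent zero-mean Gaussian
error, with one standard deviation per kind of reading
(defaults in parentheses): absolute temperature `u_t` (0.053 °C, LMT70-class
sensor), paired differential `u_dt` (0.0006 °C), heat flux `u_q`
(1.3 W/m², PHFS-01-class sensor) and channel coefficient `u_h`
(0.12 W/(m²·K), from ±0.1 mm thickness and 1 % conductivity tolerances).
The measured characteristic parameter is the ratio of independently
perturbed coefficients, $k_{meas} = (h_{s2}+e_2)/(h_{s1}+e_1)$; a
non-positive coefficient draw is redrawn and counted. All TT-family
variants perturb the coefficients by default (`h_noise = FALSE` restores a
strict temperature-only error model).

Two modelling decisions deserve note:

* **Averaging variants share one realisation** of the differentials, fluxes
  and $k$ across their constituent equations, while each absolute base
  temperature gets its own draw. The re-expressions describe a single
  physical measurement event, but each base sensor is a distinct device —
  and this is precisely why averaging reduces variance.
* `ut_interpretation = "uniform_bound"` divides all four values by
  $\sqrt 3$ before use, for users who read datasheet limits as uniform
  bounds rather than Gaussian SDs. The default is `gaussian_sd`.

## Monte Carlo procedure

One *trial* simulates the truth, draws `n_reps` noisy measured sets,
applies the estimator, and takes the sample SD (with $n-1$) of the
estimation errors. `estimate_uncertainty()` repeats this `n_trials` times:
`mu_cbt` is the mean of the per-trial SDs (the predicted standard
uncertainty) and `su_cbt` their SD (the repeatability of the Monte Carlo
itself). Defaults are 10 000 repetitions × 100 trials; the master seed
draws one 31-bit child seed per trial, so results are reproducible
bit-for-bit and trials are independent.

Non-finite estimates (an exactly zero denominator) are never dropped: they
propagate into the trial SD and are counted, because the explosive
behaviour near singular operating points is part of the findings. No
epsilon clipping is applied to denominators for the same reason.

Five sweep experiments cover the design space (`dhf_experiment()`):
ambient temperature −15…+45 °C in 0.5 °C steps (plus a 36.95…37.05 °C
sweep at 0.001 °C to resolve the very thin unstable band of TTp/TTpm), CBT
35…45 °C in 0.25 °C steps, the common channel conductivity 0.01…100
W/(m·K) (60 log-spaced points, ratio fixed at 2), the coefficient ratio
1.25…10 000 (60 log-spaced points, channel 1 fixed, channel 2 thickened),
and convection 6…104 W/(m²·K) in steps of 2. Grid resolutions are the
package's own choice — fine enough to resolve the reported features at
desk-scale cost. The test suite runs reduced sizes (typically 2 000–10 000
repetitions × 10–20 trials), which resolve the stable-region values to
about 1 % relative.

## First-order budget

`combined_uncertainty()` evaluates closed-form sensitivity coefficients
$c_x = \partial \mathrm{CBT}_e/\partial x$ at the error-free operating point
(coefficient sensitivities via the chain rule through $k$), combines them as
$u^2 = \sum (c_x u_x)^2$ and reports shares
$ru(x) = (c_x u_x)^2/u^2$. A central finite-difference oracle
(`numeric_partials()`) is kept in the test suite and agrees with the closed
forms to $10^{-6}$ relative.

Two structural facts are worth knowing:

* All temperature and flux sensitivities are **scale-invariant in the
  gradient** — numerators and denominators shrink together as
  $T_{amb} \to \mathrm{CBT}$, so the first-order budget does *not* flag the
  approach to the singularity. The blow-up there is a beyond-first-order
  effect that only the Monte Carlo captures.
* The first-order budget slightly understates the Monte Carlo dispersion
  for the flux-based variants at the default point: the flux difference
  $q_2-q_1$ in the denominator has a 15 % coefficient of variation at
  $u_q = 1.3$, and the resulting second-order excess is about 4 % (HTp) to
  6 % (HTpm) of the total — visible in the test suite as a one-sided gap.

```{r}
combined_uncertainty("TTp")
```

## Degenerate and singular inputs

A symmetric probe ($h_{s1} = h_{s2}$) is representable — the forward model
is well-defined — but every dual-flux estimator is singular on its
error-free readings, and the budget functions raise a domain error naming
the vanishing denominator. At $T_{amb} = \mathrm{CBT}$ all fluxes and
differentials are zero: with zero noise the estimators return 0/0, which is
reported as a counted non-finite, not an exception.

## Design choices made where the design was open

* **Noise on $k$** is realised through the two coefficients separately
  (matching the published share table, which lists $h_{s1}$ and $h_{s2}$
  columns with the exact 4:1 share ratio the chain rule predicts), rather
  than as a single dispersion applied to $k$ itself.
* **The published share percentages are not targeted.** The printed rows
  are mutually inconsistent with the stated default noise levels: the
  flux-based rows imply an effective $u_q \approx 2.4$ W/m² and the
  temperature-only row an effective $u_h \approx 0.22$ W/(m²·K).
  `dhf_compat_noise()` exposes those inferred values for side-by-side
  comparison; the package asserts only the normalisation and the structural
  ratios (1.875 for HT's two skin sensors, 4.0 for TT's two coefficients).
* **Ratio-sweep shape.** Under the separate-coefficient noise realisation
  the first-order uncertainty of TTp/TTpm decreases monotonically with the
  coefficient ratio towards the absolute-sensor floor
  $\sqrt{u_t^2 + (c_k u_h/h_{s1})^2}$; the pronounced interior minimum near
  ratio 30 reported for this design is not reproduced by this realisation,
  and reported figure-level values in general are treated as qualitative.
* **Paired variants at the exact singular point.** HTp's numerator
  $q_1 \Delta T_{ss}$ vanishes together with its denominator at
  $T_{amb} = \mathrm{CBT}$ and the differential noise is tiny, so its
  uncertainty stays near $u_t$ there instead of exploding; the singular
  blow-up of the paired variants is strongest on a ring *around* the
  singular ambient, not at the exact point. The unpaired variants (HT, TT)
  blow up at the point itself by well over an order of magnitude.

## What the simulator does and does not emulate

The generator emulates steady-state, laterally infinite layers with a
constant blood temperature, identical convection over both channels, and
white Gaussian sensor noise. It does not emulate transients, lateral heat
leakage, perfusion or thermoregulatory dynamics, correlated or drifting
sensor errors, quantisation, or contact-resistance variability. Passing
tests therefore validate the estimator algebra and the uncertainty
propagation machinery — not the field accuracy of a physical probe, for
which the model is a theoretical lower bound.
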