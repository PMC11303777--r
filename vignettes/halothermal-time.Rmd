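---
title: "Halothermal-time models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Halothermal-time models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halott)
```

## The model

A dish of seeds under temperature $T$ (°C) and osmotic potential
$\psi \le 0$ (MPa, from NaCl via the Van't Hoff relation
$\psi = -c\,i\,R\,(T + 273.15)$, $R = 0.008314$ MPa L mol$^{-1}$
K$^{-1}$, $i = 2$ for NaCl) is scored repeatedly for cumulative
germination. The halothermal-time model treats the population as
heterogeneous in a single trait, the base water potential $\psi_b$,
normally distributed with median $\psi_b(50)$ and spread
$\sigma_{\psi b}$. Seed $i$ germinates when its accumulated halothermal
time reaches a shared constant $\theta_{HaloTT}$ (MPa °C h):

$$ (\psi - \psi_{b,i})\,(T - T_b)\, t_i \;=\; \theta_{HaloTT}, $$

so the cumulative germinated fraction at time $t$ is a probit in the
"implied base potential" $b(t) = \psi - \theta_{HaloTT}/((T - T_b)t)$:

$$ g(t) \;=\; \Phi\!\left[\,\big(b(t) - \psi_b(50;T)\big)\,/\,
   \sigma_{\psi b}\,\right]. $$

Assumptions worth keeping in mind: the threshold draw is the *only*
source of between-seed variation (no separate timing noise); thresholds
do not change during incubation (no priming or dormancy induction); and
sub-optimal temperatures act only through the thermal-time factor
$(T - T_b)$. Above the optimum $T_o$ the median threshold rises linearly,
$\psi_b(50;T) = \psi_b(50) + k_T\,(T - T_o)$, which reproduces the
observed suppression of both rate and final percentage at supra-optimal
temperatures. Below $T_b$ no thermal time accumulates and
`predict_fraction()` returns 0 rather than an error.

The printed form of this percentile relation in parts of the applied
literature is often typeset with unbalanced brackets; the package
implements the standard form above, with NaCl molarity unified onto the
MPa scale before fitting, so molarity-based and potential-based designs
share one code path.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| `psi_b50` | MPa | −0.87 | median base water potential |
| `sigma_psib` | MPa | 0.30 | population spread of $\psi_b$ |
| `theta_halott` | MPa °C h | 56.29 | halothermal time constant |
| `t_base` | °C | 20 | base temperature $T_b$ |
| `t_opt` | °C | 33 | optimum temperature $T_o$ |
| `t_ceil` | °C | 45 | ceiling temperature $T_c$ |
| `k_t` | MPa/°C | 0.104 | supra-optimal shift of $\psi_b(50)$ |

These defaults are a published maize (NaCl stress) parameterization and
double as the generating truth of the simulator, so that a simulated
experiment represents realistic effect sizes, not a convenient toy.
Reported cardinal temperatures for maize vary between sources (base
temperatures of 15–20 °C are both in circulation, and published derived
tables are sometimes internally consistent only with the lower value);
`derive_cells()` therefore takes `t_base` and `t_ceil` as explicit inputs
through its `params` argument rather than hard-wiring any value.

## Estimation: repeated probit regression

`halott()` recovers the parameters by the field's "repeated probit"
procedure, implemented as a fully deterministic search:

* **Regression points.** Replicate dishes are pooled by summing counts at
  shared scoring times; each treatment × time with cumulative fraction
  strictly between 0 and 1 contributes one point $(b, \mathrm{probit}(g))$.
  Fractions are of seeds *sown* by default (`fraction_of = "germinated"`
  rescales to the final germinated count). Exact 0s and 1s carry infinite
  probits and are dropped; the optional `(g + 0.5)/(n + 1)` continuity
  correction (`continuity = TRUE`) retains them instead.
* **Weighting.** Points are weighted by the classical probit working
  weight $n\,\phi(\mathrm{probit}(g))^2 / (g(1-g))$ — the inverse
  binomial sampling variance of the probit-transformed fraction. Extreme
  percentiles are noisy on the probit scale and otherwise dominate the
  search through leverage; in simulation the weighted fit roughly halves
  the spread of the recovered $\theta$. `weights = "none"` restores
  ordinary least squares.
* **Search.** A grid over $T_b$ (0.5 °C steps from 0 to one degree below
  the coolest temperature with germination) × $\theta$ (201 log-spaced
  points on $[1, 5000]$ MPa °C h), maximizing the regression $R^2$; ties
  break to the smaller $\theta$ (the first grid maximum). The best cell is
  refined by three rounds of alternating golden-section searches in
  $\theta$ (±10% bracket) and $T_b$ (±0.75 °C bracket). A maximum on the
  grid boundary is reported with a warning, not silently moved.
* **Back-transformation.** With slope $m$ and intercept $a$ of the probit
  line, $\sigma_{\psi b} = 1/m$ and $\psi_b(50) = -a/m$. A non-positive
  slope (no coherent threshold ordering) warns and invalidates the fit.
* **Supra-optimal side.** Only observations below $T_o$ enter the global
  regression. Each temperature above $T_o$ is fitted separately by the
  single-temperature halotime analogue (`fit_halo_temperature()`, search
  over $\theta_{Halo}$ only), and $k_T$ is the least-squares slope of the
  per-temperature $\psi_b(50)$ estimates against $T$. With fewer than two
  usable supra-optimal temperatures $k_T$ is `NA`, flagged by a warning.

`t_opt` classifies observations as sub- or supra-optimal. Left `NULL`, it
is estimated from the $\psi = 0$ rate profile by
`cardinal_temperatures()`; when the design is scored too coarsely for a
trustworthy profile (see *Limitations*), supply it explicitly —
`parameter_recovery()` passes the generating value for exactly this
reason, since it measures recovery of the threshold-distribution
parameters, not of $T_o$.

## Cardinal temperatures

`cardinal_temperatures()` fits the classical two-segment description of
the rate profile $GR(T)$ at $\psi = 0$: one rising line from $T_b$ to
$T_o$, one falling line down to $T_c$. Zero rates are censored
observations ("no germination"), not measurements of zero speed, and are
excluded — this also makes the estimate invariant to padding the profile
with temperatures wholly outside the germination window. Every admissible
split of the (temperature-ordered) positive-rate points into a left and a
right segment sharing the split point is tried; the split minimizing the
pooled residual sum of squares wins. $T_b$ and $T_c$ are the segments'
x-intercepts, $T_o$ the abscissa of their intersection. A profile with no
valid split (monotone rates) yields a one-sided answer with the missing
cardinals `NA` and a warning.

`gr_profile()` generates noise-free $GR(g)$ profiles from a parameter
set. Above $T_o$ two constructions are offered: `"cardinal"` (default), a
linear decline to zero at $T_c$, matching the two-segment description the
estimator assumes and the linearity actually reported for rate data; and
`"kT"`, the decline implied by the shifted threshold
$\psi_b(g) + k_T(T - T_o)$, which is quadratic in $T$ and reaches zero at
$T_o - \psi_b(g)/k_T$ — under the default parameters ≈ 41.4 °C, *not*
$T_c = 45$. The two constructions coincide only if
$k_T = -\psi_b(g)/(T_c - T_o)$; the default parameter set does not
satisfy this, a tension inherited from the applied literature and left
visible rather than resolved. The closed-loop check (profile → estimator
→ cardinals) uses the `"cardinal"` construction.

## The simulator

`simulate_germination()` draws one $\psi_{b,i}$ per seed, computes exact
germination times from the threshold identity, and bins them onto the
scoring grid; seeds with $\psi_{b,i} \ge \psi$ (or $T \le T_b$) never
germinate and are visible only as the shortfall in the counts. The
default design (`sim_design()`) is 5 temperatures (20–40 °C) × 5
potentials (0 to −0.8 MPa) × 3 dishes of 30 seeds, scored every 24 h for
480 h — the structure of the emulated assay; the 480 h horizon covers the
slowest interpolated times implied by published derived tables (~95 h)
with a wide margin, and the scoring interval is a declared assumption
(the emulated protocol states only "regular intervals"). Each dish gets
an independent child seed derived from the root seed by a fixed stride,
so datasets are reproducible and replicates independent. An optional
lognormal timing jitter (`jitter_sdlog`) exists for robustness
experiments and is off by default — it is *not* part of the model.

What the simulator does **not** emulate: partial seed viability (real
lots germinate at ≤ ~90% even unstressed), counting error, dish effects,
threshold drift during incubation, and solute-specific (ionic) toxicity
beyond the osmotic term. Passing recovery tests therefore demonstrates
the estimator inverts the model, not that the model captures every
feature of real assay data.

## Numerical choices and degenerate inputs

* Times are hours internally; the reader converts days on request
  (`time_unit = "d"`). Day-indexed indices bin hours as
  $\lceil h/24 \rceil$, crediting a seed to the first scoring day it was
  seen.
* Interpolated percentile times (`time_to_fraction()`) are linear between
  bracketing observations, starting from the origin $(0, 0)$; a target
  exactly at an observation returns that time; tied brackets return the
  earlier time; unreached targets are `NA`, never an error, and propagate
  as flags.
* Zero-germination courses: extent indices are 0; timing indices (MGT,
  MGR, CVG, T50) are `NA` with the course flagged.
* $\sigma_{\psi b} = 0$ is admitted everywhere as the degenerate
  population: prediction becomes a step function and simulation a single
  shared germination time. Probit *fitting* of truly degenerate data is
  impossible (every fraction is 0 or 1), so the estimator's behaviour is
  verified in the $\sigma \to 0$ limit instead: with
  $\sigma_{\psi b} = 0.02$ and hourly scoring the regression $R^2$
  exceeds 0.99 and $\hat\sigma$ collapses toward 0.
* Report tables round to 6 significant digits (2 decimals behind
  `paper_rounding`), keeping pipeline reruns byte-identical.

## Problem sizes in the checks

The recovery experiment simulates 20 replicate datasets of the full
5 × 5 design at 1000 seeds per treatment and refits each — about 15 s on
one core — chosen so the Monte-Carlo error of the reported medians is
well inside the tolerances being checked (±0.05 MPa on location/spread,
±10% on $\theta$, ±20% on $k_T$). The cardinal-temperature closed loop
runs on a 1 °C profile grid from 15 to 50 °C. Property checks (monotone
predictions, binomial consistency of simulated final fractions within 3
standard errors at 3000 seeds) use single treatments.

## Limitations

* **Coarse scoring biases interpolated rates.** With 24 h scoring and
  median germination times of a few hours, `gr_from_timecourse()`
  linearizes a convex curve across the first interval and underestimates
  fast rates; a cardinal-temperature estimate from such data is
  unreliable (hence the explicit `t_opt` escape hatch). Rate-based
  cardinal estimation wants scoring intervals comparable to the fastest
  median times.
* **$T_b$–$\theta$ ridge.** With only two informative sub-optimal
  temperatures the likelihood surface has a long diagonal ridge; single-
  dataset estimates of $T_b$ and $\theta$ co-vary strongly (the worked
  example in the README shows it), while their ratio-determined
  combination — and the medians across replicate fits — are stable.
* **One threshold trait.** Variation in $\theta$ or $T_b$ across seeds,
  dormancy loss, or ion accumulation over long incubations are outside
  the model family.
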