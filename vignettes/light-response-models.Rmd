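---
title: "Light-response models and electron-flow partitioning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-response models and electron-flow partitioning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcpart)
```

## The problem

A leaf's photosynthetic light response is measured by stepping incident
irradiance $I$ (µmol photons m⁻² s⁻¹) downward from saturating to zero
while logging net CO₂ assimilation $A_n$ and, with a combined
fluorometer, the effective PSII quantum yield $\Phi_{PSII}$. Four curves
summarise the leaf: $A_n$–$I$, total PSII electron transport $J$–$I$,
and the allocation of that electron flow to RuBP carboxylation
($J_C$–$I$) and RuBP oxygenation, i.e. photorespiration ($J_O$–$I$).
The quantities practitioners carry forward — the curve maximum, the
saturation irradiance at which it occurs, the light compensation point
$I_c$, dark respiration $R_d$ — are read off a fitted model, so the
model's functional form matters.

Two families are implemented:

**Non-rectangular hyperbola (NH).** The lower root of
$\theta y^2 - (\alpha I + y_{max})y + \alpha I\,y_{max} = 0$ (minus
$R_d$ for net curves), with initial slope $\alpha$, convexity
$\theta \in (0, 1]$ and asymptote $y_{max}$. For $\theta < 1$ the curve
approaches $y_{max}$ only as $I \to \infty$: the reported "maximum" lies
above every value the leaf can actually reach within (or beyond) the
measured range, and no saturation irradiance exists. This is the
mechanism behind the widely reported overestimation of $A_{n\,max}$ and
$J_{max}$ by asymptotic fits, which the package quantifies directly with
`nh_asymptote_gap()`.

**Nonasymptotic (Ye) model.**
$$y(I) = \alpha\,\frac{1-\beta I}{1+\gamma I}\,I - R_d,$$
with photoinhibition coefficient $\beta \ge 0$ and light-saturation
coefficient $\gamma$. The numerator's $1-\beta I$ factor gives the curve
a genuine interior maximum and a mild post-saturation decline, so both
the maximum and its saturation irradiance have closed forms:
$$I_{sat}=\frac{\sqrt{(\beta+\gamma)/\beta}-1}{\gamma},\qquad
  y_{max}=\alpha\left(\frac{\sqrt{\beta+\gamma}-\sqrt{\beta}}
  {\gamma}\right)^2 - R_d.$$
The light compensation point is the smaller positive root of
$\alpha\beta I^2-(\alpha-R_d\gamma)I+R_d=0$ (that root, not the larger
one, is the physiological crossing below saturation); no closed form
for $I_c$ is in common circulation, so the quadratic derivation is
documented here and cross-checked against root bracketing in the tests.

## Electron-flow estimation and partitioning

Total linear electron flow is estimated from fluorescence as
$J = \Phi_{PSII} \cdot I \cdot 0.5 \cdot 0.84$; the PSII fraction (0.5)
and leaf absorptance (0.84) are the conventional C3 values but are
species-dependent, so `compute_j()` exposes both. With day respiration
$R_{day} = 0.5\,R_d$ (an adopted convention, overridable in
`respiration_spec()`), the flow splits as
$$J_C = \tfrac{1}{3}\left[J + 8(A_n + R_{day})\right], \qquad
  J_O = \tfrac{2}{3}\left[J - 4(A_n + R_{day})\right],$$
which sum to $J$ identically — the package tests this conservation to
1e-9 on random inputs. The split assumes electron sinks other than
carboxylation and oxygenation are negligible or constant; when inputs
violate that (low $J$ relative to assimilation), $J_O$ goes negative and
is deliberately *reported, not clipped*, because a negative component is
the diagnostic for the violated assumption.

## Numerical choices

* **Degenerate parameter regions.** The closed forms are evaluated by
  analytic limits when a parameter sits within 1e-10 of a removable
  singularity rather than by naive evaluation: $\gamma \to 0$ gives the
  parabola limit $I_{sat} = 1/(2\beta)$, $y_{max} = \alpha/(4\beta) -
  R_d$; $\beta = 0$ gives a saturating hyperbola whose maximum is only
  an asymptote (flagged `asymptotic`); $\theta \to 0$ gives the
  rectangular hyperbola; and $\theta = 1$ is evaluated as the exact
  Blackman form $\min(\alpha I, y_{max})$. Continuity across the
  switches is tested at $\gamma = \pm 10^{-12}$.
* **Negative $\gamma$.** Fitted $J$–$I$ and $J_O$–$I$ curves can have
  $\gamma < 0$ (the soybean reference values do). All closed forms
  remain valid while $\beta + \gamma > 0$; prediction enforces the
  validity window $I < -1/\gamma$, and the fit bounds
  $\gamma \ge -1/(1.05\,I_{max})$ keep the denominator positive over
  any dataset being fitted.
* **Optimisation.** `fit_lrc()` minimises unweighted least squares with
  Levenberg–Marquardt under box bounds ($\alpha \in (0,1]$,
  $\beta \in [0, 0.02]$, $\theta \in (10^{-6}, 1]$, $R_d \in [0, 20]$,
  $y_{max}$ up to 10× the observed maximum), tolerances 1e-10 and a
  10 000-evaluation budget per start. Both families have shallow,
  multi-modal cost surfaces, so the fit multi-starts deterministically
  over a grid of initial values: $\gamma_0 \in \{-10^{-4}, 10^{-5},
  5\times10^{-4}, 2\times10^{-3}\}$ (or $\theta_0 \in \{0.5, 0.9\}$)
  crossed with three initial-slope candidates — the secant of the two
  dimmest steps (exact on clean data) and two gross-maximum-based
  guesses that survive noise in those steps. There is no random restart,
  so fits are reproducible without a seed.
* **Respiration.** Whether the published fits treated $R_d$ as free or
  as the measured $I=0$ exchange is not stated; the package defaults to
  a free parameter for $A_n$ curves and offers `fix_rd` to pin it.
  Electron-flow curves pass through the origin and carry no offset.

## What the synthetic-data generator emulates — and what it does not

`simulate_an_curves()` reproduces the measurement design of the
two-species field study the reference values come from: descending
steps 2000, 1800, …, 50, 0 µmol m⁻² s⁻¹ (15 levels; capped at 1800 for
the wheat design), $n = 3$ leaf replicates, curves with a linear rise,
saturation and mild post-saturation decline. Measurement error is
homoscedastic Gaussian with sd defaulting to 2% of the curve maximum —
a standard assumption for steady-state gas exchange; no error model was
published, so this is a stated choice, with an absolute-sd option.
Between-leaf variation is multiplicative lognormal on the parameters
(keeping them in their valid ranges naturally), default 0.
`simulate_fluorescence()` inverts $J = \Phi_{PSII}\cdot I\cdot 0.42$ to
generate yields consistent with a $J$–$I$ truth, so the partition
pipeline closes algebraically at zero noise.

The generator does **not** emulate instrument drift, heteroscedastic or
autocorrelated noise along the descending sequence, stomatal dynamics
between steps, or alternative electron sinks. Passing recovery tests on
these simulations therefore demonstrates correctness of the estimation
machinery under the stated error model, not robustness to every
pathology of field data.

The reference parameter catalog (`fixture_table1()`) carries the
replicate-mean fitted coefficients for both species and all four curve
families, with one deliberate omission: the wheat $J$–$I$ coefficients
are internally inconsistent as published (the printed photoinhibition
coefficient $\beta_e = 2.42\times10^{-3}$ would force $J < 0$ above
$I \approx 413$, yet $J$ was measured positive to 1800, and the printed
$J_{max}$ is unreachable from those coefficients — most plausibly a
power-of-ten typo). They are therefore excluded from the catalog and
from all numerical checks. Similarly, the published $I_{O\text{-}sat}$
expression carries a stray $\alpha_O$ prefactor relative to the other
saturation-irradiance forms; dimensional analysis and the printed
soybean $J_O$–$I$ values (computed 1845 vs printed 1861 ± 34 without
the prefactor, ~161 with it) identify it as typographical, and the
package uses the consistent form.

## Problem sizes used in the checks

The test suite exercises: 1000 random parameter draws for the
closed-form-vs-grid-search equivalence (0.1 µmol m⁻² s⁻¹ grid);
10⁴ random partition inputs for conservation; 100 random noiseless
truths (half soybean, half wheat design, split across the two families)
for parameter recovery to 1e-4 relative; and 200 simulated three-replicate
datasets at 2% noise for the overestimation headline — chosen as the
smallest sizes at which the stochastic properties are stable.

## Known limitations

* Single-curve, per-replicate fitting only: no hierarchical pooling
  across leaves, no bootstrap or asymptotic standard errors on
  parameters (replicate scatter is the uncertainty unit, as in the
  source study's tables).
* No temperature or CO₂ response surface, no FvCB coupling, no
  mesophyll conductance, and no Laisk/Kok estimation of $R_{day}$.
* The observed light compensation point is obtained by linear
  interpolation between the two steps bracketing $A_n = 0$, and the
  observed saturation irradiance is the irradiance of the largest
  measured step — simple, stated conventions for quantities whose
  published extraction method is unspecified.
* Tukey HSD at $\alpha = 0.05$ supplies the homogeneous-subset letters;
  the published tables print letters without naming a post-hoc
  procedure, and Tukey is the standard companion to one-way ANOVA.
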