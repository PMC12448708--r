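---
title: "Methods: from A/Ci curves to treatment inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from A/Ci curves to treatment inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acitherm)
```

`acitherm` implements the analysis chain used in growth-CO2 by
growth-temperature experiments on C3 plants: estimate apparent photosynthetic
capacity from CO2-response curves, model its short-term temperature response,
and test treatment effects with mixed-model ANOVA. Because campaigns of this
kind rarely deposit raw instrument tables, the package also ships a synthetic
study generator with known ground truth, so every stage can be validated end
to end.

## The biochemical model

Net CO2 assimilation in C3 leaves is the minimum of two limiting processes.
When Rubisco activity limits,

$$A_c = V_{cmax}\,\frac{C_i - \Gamma^*}{C_i + K_c\,(1 + O/K_o)} - R_L,$$

and when RuBP regeneration (electron transport) limits,

$$A_j = \frac{J}{4}\,\frac{C_i - \Gamma^*}{C_i + 2\Gamma^*} - R_L,
\qquad \theta J^2 - J(\alpha Q + J_{max}) + \alpha Q J_{max} = 0,$$

with $J$ the lower root of the quadratic. $A_{net} = \min(A_c, A_j)$ — the
strict minimum, with no hyperbolic smoothing between limitations: it is the
simplest faithful reading of the model and matches the default of the fitting
tools practitioners use. Triose-phosphate limitation is deliberately not
modelled; it matters only under combinations of conditions (very high CO2,
low temperature, high light) outside the scope of this design, and is
likewise left out of the large-scale models these parameters feed.

Fixed constants: the light-response curvature $\theta = 0.85$ and quantum
yield $\alpha = 0.24$ mol electrons mol$^{-1}$ photons (typical conifer
values), irradiance $Q = 1800$ µmol photons m$^{-2}$ s$^{-1}$ (saturating),
and the O2 mole fraction $O = 210000$ µmol mol$^{-1}$ (21%), all overridable.
Because $C_i$ stands in for chloroplastic CO2 (mesophyll conductance is not
modelled), the estimates are *apparent* $V_{cmax}$ and $J_{max}$.

Rubisco constants ($K_c$, $K_o$, $\Gamma^*$) and their exponential Arrhenius
temperature sensitivities ship as a plain-text preset table. The `"tobacco"`
set carries the standard in-vivo tobacco constants the field defaults to.
No authoritative constants are bundled for the alternative species sets:
`"rice"` and `"potato"` are clearly-labelled synthetic stand-ins
(representative deviations from tobacco) intended only for the sensitivity
analysis, which asks whether *rankings and treatment contrasts* survive a
kinetics swap, not for absolute parity. For the same reason no re-derivation
of any published study's absolute capacity values is possible from this
package: the shipped constants are a documented convention.

## Fitting one curve

`fitACi()` minimises the sum of squared residuals of $A_{net}$ over the
curve's points by bounded Levenberg–Marquardt, with kinetic constants
evaluated at the curve's mean leaf temperature. Choices that matter:

* **Multi-start.** Five deterministic starts: one analytic (Vcmax inverted
  from the low-$C_i$ points, Jmax from the top step) and four log-spaced
  along the capacity diagonal. High $J_{max}/V_{cmax}$ ratios otherwise trap
  a single-start optimizer in a local minimum. Ties break by lowest SSR,
  then lowest $V_{cmax}$. No RNG is involved, so fits are reproducible.
* **Respiration.** Two supported readings: estimate $R_L$ jointly (bounded
  in $[0, 10]$; the single-curve default) or fix it at the preset's basal
  rate, Arrhenius-adjusted to the curve temperature. At study scale the
  fixed mode is the default: on cold (10 °C) curves the signal is a few
  µmol m$^{-2}$ s$^{-1}$ and a free $R_L$ trades off against $V_{cmax}$ —
  on the default synthetic study this inflated per-treatment activation
  energy errors to tens of percent and boundary-flagged a quarter of the
  thermal fits, while the fixed mode recovers optima to a few tenths of a
  degree. The residual bias from an imperfect assumed $R_L$ (±10% of ~1
  µmol m$^{-2}$ s$^{-1}$) is negligible for the capacities.
* **Identifiability.** A capacity is only constrained by points it limits at
  $C_i > \Gamma^*$ (below the compensation point the branches swap roles and
  carry no practical information). Fits with fewer than two such points for
  a parameter are flagged `jmax_unidentifiable` / `vcmax_unidentifiable`
  rather than rejected.

## Curve quality control

Visual curve inspection is not reproducible, so QC is a fixed rule set:
reject a curve if (i) any raw $C_i$ point is negative, (ii) $V_{cmax}$ or
$J_{max}$ falls outside $[10, 500]$ µmol m$^{-2}$ s$^{-1}$, (iii) the
optimizer did not converge, or (iv) the fit is poor — $R^2 < 0.90$, or the
residuals form fewer than 3 sign runs on curves of at least 8 points with
non-negligible residual variance (a systematic-misfit signature). Reasons
are enumerated, verdicts are idempotent and independent of row order (points
are put in measurement order before fitting). On the default synthetic study
about 2% of curves are rejected, essentially all cold curves of warm-grown
trees whose true $V_{cmax}$ approaches the lower QC bound — the same
mechanism the rule exists for in real campaigns.

## Operating point and thermal responses

`extractOperatingPoint()` reads $A_{growth}$, $g_s$ and $C_i/C_a$ at the
step nearest the growth CO2: 400 µmol mol$^{-1}$ for ambient-grown, 800 for
elevated-grown plants (the nearest step to the 750 growth level). The 400
step occurs twice in the standard sequence; the later, post-recovery
occurrence is used.

Per tree and year, the temperature response of each capacity across the
four curve temperatures is fit with the peaked Arrhenius function

$$f(T_l) = k_{opt}\,
\frac{H_d \exp\!\big(\tfrac{E_a (T_l - T_{opt})}{T_l R T_{opt}}\big)}
{H_d - E_a\big(1 - \exp\!\big(\tfrac{H_d (T_l - T_{opt})}{T_l R T_{opt}}\big)\big)},$$

with $H_d$ fixed at 200000 J mol$^{-1}$ to avoid over-parameterization,
leaving $k_{opt}$, $T_{opt}$ and $E_a$ free. The optimisation parameterises
$T_{opt}$ directly (bounds 273.15–333.15 K, $E_a \in (0, 199999]$): with
four points and a fixed $H_d$ this is identifiable and avoids the
transformed-parameter forms. Monotone data yield a boundary optimum and are
flagged `topt_extrapolated` (also when the optimum sits more than 15 °C
outside the measured range); flat data are flagged `degenerate_flat`.
Fitting is per tree, not per treatment mean, so the derived parameters can
feed tree-level ANOVA; a pooled fit is a one-line aggregation away but is
not the default. $A_{growth}(T_l)$ uses an ordinary quadratic with the
closed-form optimum $T_{optA} = -b/2a$; temperatures are °C for the
quadratic and K inside the peaked form (conversion constant 273.15).
Standardised rates at 20 °C ($V_{cmax20}$, $J_{max20}$, their ratio) come
from evaluating the fitted curves at 293.15 K. Standard errors for derived
parameters, when wanted, come from a seeded nonparametric bootstrap over
temperature points (default 500 resamples).

## Treatment inference

Two layers mirror the design of such experiments. Gas-exchange responses
(per species and year) use linear mixed models with individual trees as
random intercepts — each tree is measured at four leaf temperatures, which
is the repeated measure — with leaf temperature as a continuous covariate
alongside the growth-temperature and growth-CO2 factors. Derived
thermal-response parameters (per species) use ordinary linear models with
year, growth temperature and growth CO2: seedling cohorts differ between
years, so each tree contributes one row per year and there is no
within-tree replication to absorb.

Fixed effects are selected by AICc,
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, over every
marginality-respecting submodel of the factorial (interactions only enter
with their main effects), fit by ML; ties go to the smaller model and the
chosen structure is refit by REML for reporting. Terms dropped by selection
are reported as blank cells rather than zeros. F tests are marginal, with
nlme's between-within containment denominator degrees of freedom — a fixed,
documented convention. Factors are coded with sum-to-zero contrasts and
covariates centered, so marginal main-effect tests refer to average effects
rather than to an arbitrary reference cell (with treatment coding the
warming main effect would be evaluated at a leaf temperature of 0 °C
whenever an interaction is retained). A singular or failing mixed fit falls
back to a fixed-effects model with a warning; a constant response reports
F = 0, p = 1. Tukey-adjusted pairwise comparisons among the six treatment
cells (via emmeans) trigger when a growth-temperature or interaction term is
significant at 0.05; the compact letter display assigns letters to maximal
cliques of the not-significantly-different graph, ordered by decreasing
mean, so groups sharing no letter differ at the chosen level.

## The synthetic study

The generator emulates the study design end to end: two years (independent
seedling cohorts), five boreal species, 0T/+4 °C/+8 °C warming crossed with
410/750 ppm growth CO2, five trees per cell, A/Ci curves at 10/20/30/40 °C
over the standard 12-step sequence at saturating light. Ground truth per
tree: species-baseline peaked-Arrhenius parameters for both capacities
(optimal rates 80–110 µmol m$^{-2}$ s$^{-1}$ for $V_{cmax}$, 120–165 for
$J_{max}$, optima at 35/31 °C, activation energies 60/43 kJ mol$^{-1}$ —
typical boreal-seedling magnitudes, chosen so that even 10 °C curves of
warmed trees sit clear of the QC floor), a shared lognormal tree intercept
(10% SD), small jitter on optima and energies, and basal respiration near
1 µmol m$^{-2}$ s$^{-1}$.

Injected treatment effects are deliberately sparse: warming multiplies the
capacity optima (0.90 at +4 °C, 0.70 at +8 °C); growth CO2 leaves
capacities untouched. Everything else is emergent: elevated-CO2 plants
operate at higher $C_a$, so their measured $A_{growth}$ is stimulated and —
because photorespiration weighs less at high $C_i$ — their $A_{growth}$
thermal optimum sits higher (about +3 °C on the default study), without any
$T_{opt}$ shift being coded in. An optional knob adds a warming shift of
the capacity optima (default off, matching the weak and inconsistent
warming responses of those optima in this kind of experiment).

The stomatal closure is a fixed ratio, $C_i = 0.72\,C_a$, the near-constant
operating ratio such campaigns report, with $g_s$ back-computed from the
CO2 gradient via the 1.6 diffusivity ratio. Measurement noise is additive
Gaussian (SD 0.5 µmol m$^{-2}$ s$^{-1}$) on $A_{net}$ only. What the
generator does *not* emulate: VPD-driven stomatal dynamics (a cosmetic
`vpd` column exists), leaf-trait physiology (`lma`/`narea` are simple
treatment-mean draws so trait ANOVAs can be exercised), instrument drift,
autocorrelated within-curve noise, and mesophyll conductance. Passing
recovery tests on these data therefore demonstrates correctness of the
estimation machinery under the stated noise model, not robustness to every
pathology of field data.

Whole-curve dropout (`injectMissingness()`) and negative-$C_i$ corruption
of a seeded fraction of curves exercise the unbalanced designs and the QC
path; corruption is constructed so the negative-$C_i$ rejections identify
exactly the corrupted curves.

## Problem sizes and reproducibility

All randomness flows from one integer seed per configuration; identical
configurations reproduce byte-identical CSVs. The validation suite uses the
full default study (1200 curves per seed) for the end-to-end pattern check
across 20 seeds, 200 noisy curves and 500 noisy thermal replicates for
stochastic recovery, 1000 null replicates for type-I calibration and 200
for power — sizes at which the Monte-Carlo error of each checked quantity
is well below its acceptance band.

## Known limitations

Apparent capacities inherit all mesophyll-conductance caveats; the
cuticular correction implements the standard algebra (cuticular water loss
removed from stomatal conductance before the CO2 conversion) but real
cuticular conductance varies with temperature and species; the rice/potato
presets are stand-ins; AICc selection among small candidate sets can retain
a null term about 15–20% of the time (the familiar cost of
information-criterion selection); and containment df are approximate for
severely unbalanced designs — Kenward–Roger alternatives are out of scope.
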