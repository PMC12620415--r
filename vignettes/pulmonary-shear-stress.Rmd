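---
title: "Modelling proximal pulmonary artery wall shear stress as a biomarker of chronic thromboembolic disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling proximal pulmonary artery wall shear stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic thromboembolic pulmonary hypertension (CTEPH) and its
normotensive precursor, chronic thromboembolic disease with
ventilation/perfusion (V/Q) mismatch (CTEPD), obstruct and remodel the
distal pulmonary vasculature. The increased downstream impedance and the
dilation of the proximal arteries both depress the wall shear stress
(WSS) exerted by blood on the proximal pulmonary artery wall, which makes
cycle-averaged WSS — the time-averaged wall shear stress, TAWSS — a
candidate noninvasive biomarker for thromboembolic burden. `pawss`
implements a desk-scale version of this analysis chain: a reduced
arterial-tree representation of the proximal pulmonary anatomy,
three-element Windkessel (RCR) outflow boundary conditions tuned to
right-heart-catheter (RHC) targets, a pulsatile lumped-parameter (0D)
circulation solve, TAWSS and oscillatory shear index (OSI) computation,
a calibrated synthetic three-group cohort generator, and the
nonparametric diagnostics used to evaluate the biomarker
(Kruskal–Wallis, Dunn–Bonferroni, Spearman, ROC with Youden cutoff).

```{r setup}
library(pawss)
```

## The hemodynamic model

### Arterial tree

The proximal anatomy (MPA, LPA, RPA and descendants) is reduced to a
rooted binary tree of straight segments, each carrying only a length and
a lumen diameter. Bifurcations obey a Murray-type diameter power law,
$D_p^\gamma = D_1^\gamma + D_2^\gamma$. The exponent $\gamma$ defaults to
2.25 — the same exponent used to apportion outlet resistance, which
accounts for microcirculatory elements — but is configurable (the classic
anatomical value is 3.0). By default trees have 3 bifurcation
generations (8 outlets): how far "proximal" extends is a modelling
choice, and 3 generations covers the main, lobar and first segmental
branches. Segment length defaults to 3 diameters, a typical proximal
pulmonary proportion. Disease remodeling rescales the tree to a
patient's MPA diameter and, in the disease groups, halves the diameter
of a seeded random subset of outlet segments (default fractions: 3/8 of
outlets for CTEPH, 1/4 for CTEPD) as a simple surrogate for chronic
distal obstruction.

### Windkessel boundary conditions and tuning

Each outlet terminates in a three-element Windkessel: proximal
resistance $R_p$ in series with a parallel compliance $C$ / distal
resistance $R_d$ pair referenced to a distal pressure. Outlet
resistances are inversely proportional to $D^{2.25}$ and recombine in
parallel to the patient's total pulmonary vascular resistance
$(\mathrm{mPAP} - \mathrm{PAWP})/\mathrm{CO}$; compliances are
proportional to $D^2$ and sum to the total. Design choices the source
material leaves open, each exposed in the configuration:

* **$R_p$ : $R_d$ split** — 10% proximal, a common impedance-matching
  heuristic.
* **Distal reference pressure** — the wedge pressure PAWP, the
  physiological outflow pressure of the pulmonary circuit.
* **Initial total compliance** — stroke volume / pulse pressure; when
  systolic/diastolic pressures are unavailable, the value giving an RC
  time constant of 0.5 s.
* **Tuning targets** — mean pressure (via a resistance scale) and pulse
  pressure (via a compliance scale). Cardiac output is matched by
  construction because the inflow waveform is imposed, and PVR then
  follows from mPAP and PAWP.

Tuning is a damped fixed-point iteration: after each solve the total
resistance is rescaled by
$(\mathrm{mPAP}_t - \mathrm{PAWP})/(\mathrm{mPAP}_s - \mathrm{PAWP})$
and the total compliance by the ratio of simulated to target pulse
pressure. Both maps are nearly linear in their scale factors, so plain
iteration converges in a handful of steps; the damping exponent starts
at 1 and is halved whenever an update overshoots and reverses direction.
Convergence demands both relative errors below 2% (configurable) within
20 iterations.

### The 0D solver

Full 3D finite-element simulation is out of scope here; the package
solves the pulsatile lumped-parameter network that image-based CFD
pipelines themselves use for boundary-condition tuning. Segments carry
Poiseuille resistances $8\mu L/(\pi r^4)$; all compliance is lumped at
the outlets. Blood is Newtonian with viscosity 0.0035 Pa·s and density
1060 kg/m³ (density is carried but unused — the resistive network is
inertia-free). The imposed root inflow is a half-sine systolic ejection
(systolic fraction 0.35 of the cycle, configurable) scaled so its cycle
mean equals the catheter cardiac output.

Because the resistive network is linear, every nodal pressure and
segment flow is an affine function of the imposed inflow and the vector
of capacitor pressures; the package precomputes this affine map once per
solve by a Thevenin-style tree collapse, then advances the Windkessel
capacitors by unconditionally stable implicit Euler at $\Delta t$ = 1 ms.
Cycles repeat until the cycle-mean root pressure changes by less than
0.5% (relative) between consecutive cycles, with at least six cycles run
— six is kept as a floor, and the explicit periodicity criterion is added
because none is stated in the source analysis. A note on the source
description: it says "steady-state" equations while describing six
pulsatile cardiac cycles; the pulsatile reading is implemented, since
cycle-resolved TAWSS and OSI are undefined for steady flow.

Numerical behaviour is property-tested: the DC limit is exact, a
sinusoidally driven Windkessel matches the analytic impedance modulus
within 1%, cycle-mean inflow and outlet flows agree within 0.5% at
periodicity, and halving the time step changes the mean pressure by
less than 0.2%.

### Shear metrics

Wall shear stress uses the quasi-steady Poiseuille relation
$\tau(t) = 4\mu Q(t)/(\pi r^3)$, signed with the flow; a Womersley
amplitude correction is deliberately not applied (the signed 1D $\tau$
stands in for the 3D WSS vector, and absolute 3D magnitudes are not
reproducible from a 0D model in any case). Then

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\tau(t)|\,dt, \qquad
  \mathrm{OSI} = \frac{1}{2}\left(1 -
  \frac{|\int_0^T \tau\,dt|}{\int_0^T |\tau|\,dt}\right),$$

with OSI defined as 0 in the degenerate no-flow case. A patient-level
value is the luminal-area-weighted mean (weight $\pi D L$) over the MPA,
LPA and RPA — the aggregation rule is a package decision, as published
patient-level values do not state one.

## The synthetic cohort generator

No patient data are available, so the generator defines the study
conditions: three groups of 30 patients (CTEPH, CTEPD, control), in two
modes.

**Statistical mode** is the calibrated substrate for the diagnostic
statistics. Patient TAWSS is drawn from a lognormal quantile-matched to
each group's published median and quartiles: $\mu = \ln(\mathrm{median})$
and $\sigma$ = the mean of the two one-sided log-quartile distances
divided by $z_{0.75} = 0.6745$. The lognormal family is a choice — the
summaries are positive and right-skewed, and only median/IQR are
published; because a single $\sigma$ symmetrises a log-asymmetric IQR,
the printed medians are reproduced exactly (large-sample) while printed
quartiles are reproduced to within about 5% in the worst group. OSI is
drawn as $0.5\,\mathrm{Beta}(2, 8)$ with identical parameters in all
groups, since the published OSI comparison shows no group effect.
V/Q mismatch scores for the two disease groups come from the same
quantile-matched fit to their published summaries.

**Mechanistic mode** exercises the full modelling chain per patient:
MPA diameter sampled from the group summary, disease remodeling, RCR
tuning to the patient's sampled RHC record, 0D solve, shear
aggregation. Its purpose is ordinal fidelity, not absolute magnitudes:
group median TAWSS must order CTEPH < CTEPD < control with a
CTEPH:control ratio near the Poiseuille prediction
$(Q_\mathrm{CTEPH}/Q_\mathrm{ctrl})(r_\mathrm{ctrl}/r_\mathrm{CTEPH})^3
\approx 0.43$, consistent with the published ratio $16.5/42 \approx
0.39$.

RHC records are sampled per field from quantile-matched lognormals,
with the pressure fields coupled through a shared standard-normal
severity factor (loadings 0.85 on sPAP/dPAP/mPAP, 0.7 on PAWP). The
coupling leaves every marginal exactly quantile-matched but makes a
patient's pressures rise and fall together, as they do physiologically;
independent draws occasionally produce records whose pulse pressure
exceeds what any outlet compliance can deliver at the sampled
transpulmonary gradient (the zero-compliance bound for a half-sine
inflow is $\pi/(2 \times 0.35) \approx 4.5$ times the mean gradient).
Records are then made fully coherent: the (dPAP, mPAP, sPAP) triple is
sorted, PAWP is capped at 70% of mPAP (keeping records precapillary),
and PVR is recomputed as $(\mathrm{mPAP}-\mathrm{PAWP})/\mathrm{CO}$.
Heart rate is never published and is uniform on 60–90 beats/min. The
rare residual infeasible record (about 0.3%, concentrated in the
normotensive CTEPD group) fails tuning and is excluded from mechanistic
cohorts with a logged count rather than imputed.

What passing tests on these cohorts do **not** show: the generator
emulates published group summaries, not real joint distributions —
covariances between TAWSS and individual hemodynamics within a group,
measurement error in catheter data, and the 3D flow features behind
absolute TAWSS magnitudes (secondary flows, near-wall gradients,
curvature) are all outside it. Statistical-mode results certify the
diagnostic machinery under the published marginals; they are not
evidence about new patients.

## Diagnostics

The statistical stage mirrors the published analysis: tie-corrected
Kruskal–Wallis across the three groups (via `stats::kruskal.test`),
Dunn's rank-based pairwise tests with Bonferroni correction (number of
pairs, capped at 1), tie-safe Spearman correlation, and an empirical ROC
of TAWSS for predicting mismatch. Orientation is **lower TAWSS =
positive call** — required to make a specificity of 100% *above* the
published cutoff coherent. Thresholds are midpoints between adjacent
distinct scores plus infinite sentinels; the AUC uses the Mann–Whitney
identity with ties counted one half, which equals the trapezoidal area
under the empirical curve (cross-checked at 1e-12 in tests, and against
an independent ROC implementation). The Youden-optimal cutoff maximises
sensitivity + specificity − 1, with ties broken toward higher
specificity and then toward the lower threshold. Proportion confidence
intervals are Wilson score intervals (the published analysis reports
intervals without naming a method). The binary mismatch indicator is
used for the Spearman correlation, since scores are unavailable for
controls.

Two published values are knowingly not reproduced: the NPV (60.5%) is
arithmetically inconsistent with the published sensitivity/specificity
at 60 positives / 30 negatives (which give 62.5%), and the group-table
pairwise p-values conflict with the accompanying prose; the package
reports what it computes and targets neither.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; identical
configurations produce byte-identical cohort exports. The replicate
harness (`replicate_study()`) uses 500 seeded cohorts of 90 patients,
which takes under a minute on one CPU and gives Monte-Carlo standard
errors around 0.001–0.002 on the replicate means. Mechanistic-mode
checks use 12–30 patients per group: each patient costs a few tuning
iterations of a ~10 ms solve, so a 36-patient cohort runs in a few
seconds. The large-sample calibration checks use $10^5$ draws.

```{r replicate, eval = FALSE}
res <- replicate_study(n_replicates = 500, base_seed = 1)
res$summary
#>   metric         mean   mc_se n_replicates
#> 1 auc           0.931 0.00109          500
#> 2 rho          -0.704 0.00179          500
#> 3 sensitivity   0.709 0.00227          500
#> 4 specificity   0.953 0.00167          500
```

## Known limitations

* The 0D network has no wave propagation, inertance or nonlinear
  resistance; pressures are cycle-coherent but carry no transit delays.
* Quasi-steady Poiseuille WSS underestimates pulsatile amplitude effects
  (no Womersley correction) and cannot reproduce absolute 3D TAWSS
  levels; mechanistic mode is therefore validated ordinally only.
* The lognormal family and the severity-factor coupling are modelling
  choices over published summaries, not fitted joint distributions (a
  gamma alternative was considered; conclusions are insensitive to the
  family at the published effect sizes, since group separations are
  several within-group spreads wide).
* Segment compliance is lumped entirely at the outlets, matching the
  outlet-distribution scheme of the boundary conditions.
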