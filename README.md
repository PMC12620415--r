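# pawss

Proximal pulmonary artery wall shear stress as a biomarker of chronic
thromboembolic disease — a desk-scale, fully seeded modelling and
evaluation pipeline in R.

## What it does, and for whom

Chronic thromboembolic pulmonary hypertension (CTEPH) and its
normotensive precursor (CTEPD, chronic thromboembolic disease with
ventilation/perfusion mismatch) raise the impedance of the distal
pulmonary vasculature and dilate the proximal arteries. Both effects
depress the time-averaged wall shear stress (TAWSS) on the proximal
pulmonary artery wall, making TAWSS a candidate noninvasive screening
biomarker. `pawss` is for researchers in computational hemodynamics and
cardiopulmonary physiology who want a reproducible, testable version of
that analysis without patient imaging data:

* **Arterial trees** — Murray-law binary trees (`D_p^γ = D_1^γ + D_2^γ`)
  standing in for the segmented MPA/LPA/RPA anatomy, with
  disease remodeling (MPA dilation, seeded outlet stenosis).
* **Windkessel boundary conditions** — total resistance apportioned over
  outlets as `R_i ∝ 1/D_i^2.25`, compliance as `C_i ∝ D_i²`, split into
  three-element RCR models and tuned by damped fixed-point iteration
  until simulated mPAP and pulse pressure match a right-heart-catheter
  record.
* **Pulsatile 0D hemodynamics** — Poiseuille segment resistances with
  RCR outlets, implicit-Euler capacitor updates, at least six cardiac
  cycles to periodic convergence.
* **Shear metrics** — signed Poiseuille WSS `τ = 4μQ/(πr³)`, with
  `TAWSS = (1/T)∫|τ|dt` and `OSI = ½(1 − |∫τdt|/∫|τ|dt)`, aggregated to
  one patient value by luminal-area weighting over MPA+LPA+RPA.
* **Synthetic cohorts** — three groups of 30 patients calibrated to
  published clinical summaries (lognormal quantile matching of median +
  IQR), in a *statistical* mode carrying the quantitative calibration
  and a *mechanistic* mode that exercises the whole modelling chain.
* **Diagnostics** — tie-corrected Kruskal–Wallis, Dunn–Bonferroni
  pairwise tests, tie-safe Spearman correlation, empirical ROC with
  Mann–Whitney AUC, Youden-optimal cutoff, and Wilson confidence
  intervals for sensitivity/specificity/PPV/NPV.

Everything is tibble-in/tibble-out and pipe-friendly, with
`tidy()`/`glance()` methods and `autoplot()` figures for the main result
types.

## Worked example

Tune a CTEPH-range patient and inspect the shear field:

```r
library(pawss)

tree <- generate_tree(root_diameter = 3.0, n_generations = 3, seed = 1)
rhc  <- rhc_record(mPAP = 38, sPAP = 63, dPAP = 17, PAWP = 9, CO = 5.15, HR = 75)
fit  <- tune_rcr(tree, rhc)
fit$report
#>   iterations achieved_mPAP achieved_pulse_pressure rel_err_mPAP rel_err_pulse_pressure converged
#> 1          3          38.0                    45.3   0.00000121                 0.0157 TRUE

compute_shear(fit$solution, tree) |> aggregate_proximal(tree)
#>   TAWSS_proximal OSI_proximal
#> 1           1.29     5.09e-15
```

Three tuning iterations reach the catheter targets within tolerance
(mPAP error ~1e-6, pulse pressure 1.6%). The proximal TAWSS of 1.29
dyn/cm² is an *ordinal* 0D quantity — absolute published magnitudes come
from 3D near-wall gradients, which is why group-level questions use the
calibrated cohort below; OSI ≈ 0 because the solved proximal flow never
reverses.

Generate a calibrated cohort and run the full diagnostic stage:

```r
cohort <- generate_cohort("statistical", seed = 1)
diag   <- diagnose_cohort(cohort, threshold = 27)
glance(diag)
#>   H_tawss  p_tawss H_osi p_osi    rho   auc optimal_cutoff sensitivity_at_threshold specificity_at_threshold
#> 1    57.7 2.96e-13 0.569 0.752 -0.634 0.888           27.9                      0.7                      0.9
```

At this single seed: TAWSS separates the three groups strongly
(Kruskal–Wallis H = 57.7), OSI does not (p = 0.75, by construction —
the generator carries no group effect in OSI), TAWSS correlates
negatively with mismatch status (ρ = −0.63), and the 27 dyn/cm²
threshold detects 70% of mismatch-positive patients. `autoplot(diag$roc)`
draws the ROC curve, `autoplot(cohort)` the group boxplots.

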