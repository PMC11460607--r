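# fnirspipe

An R package for end-to-end analysis of block-design functional
near-infrared spectroscopy (fNIRS) recordings, built around a
three-group clinical comparison (type-2 diabetes with comorbid
depression, type-2 diabetes alone, healthy controls) performing a
motor task on a 40-channel prefrontal/motor montage.

It is aimed at researchers who have (or want to simulate) raw
two-wavelength optical intensity time series and need the full chain:

1. **Hemoglobin recovery** — optical density against the pre-task
   baseline, spline-based motion correction, and inversion of the
   modified Beer–Lambert law
   `ΔOD(λ) = [ε_HbO₂(λ)·ΔHbO₂ + ε_Hb(λ)·ΔHb]·d·DPF(λ)`
   (d = 2.5 cm; DPF 6/5 at 760/850 nm), then a zero-phase Butterworth
   band-pass to the 0.01–0.1 Hz hemodynamic band.
2. **Activation** — per-channel GLM `β` of ΔHbO₂ on a canonical
   double-gamma HRF regressor; one-sample t per group, three-group
   one-way ANOVA per channel with Benjamini–Hochberg FDR over the
   40-channel family, Welch post hocs, ROI summaries.
3. **Laterality** — `LI = (L − R)/(L + R)` of mean task-window ΔHbO₂
   per region; `LI ≥ 0.1` left, `≤ −0.1` right, else symmetric;
   group comparison of LI with FDR.
4. **Connectivity** — instantaneous phase via the analytic signal and
   the phase-locking value `PLV = |mean exp(i(φ_a − φ_b))|` over all
   780 channel pairs; pairwise group ANOVA with FDR over the pair
   family.
5. **Clinical statistics** — one-way ANOVA and two-sample t computed
   from published means ± sd alone, chi-square tests,
   normality-gated Pearson/Spearman correlation, outlier rules, and a
   demographic summary table.
6. **Synthetic cohorts** — a generator with known ground truth
   (group/ROI evoked amplitudes, hemispheric asymmetry, phase-coupling
   blocks, physiological noise, motion artifacts, clinical scores), so
   every stage has a closed-loop recovery test.

See `vignettes/fnirs-pipeline-methods.Rmd` for the models, defaults,
and design decisions.

## Worked example

Simulate a cohort of 20 subjects per group and run the full chain:

```r
library(fnirspipe)

spec   <- cohort_spec(n_per_group = 20, seed = 42)
cohort <- simulate_cohort(spec)
res    <- analyze_cohort(cohort$recordings)

# group-mean activation in the dorsolateral prefrontal cortex
lay <- probe_layout()
b <- res$betas; b$roi <- lay$channels$roi[b$channel_id]
aggregate(beta ~ group + roi, b[b$roi == "DLPFC", ], mean)
#>      group   roi      beta
#> 1  HEALTHY DLPFC 0.9633534
#> 2     T2DM DLPFC 0.6950047
#> 3 T2DM_MDD DLPFC 0.4074352
```

The estimated group means track the generator's configured evoked
amplitudes (1.0 / 0.7 / 0.4 µmol/L) and keep their ordering. Channel
and pair level inference:

```r
ca <- channel_anova(res$betas)
sum(ca$omnibus$significant)          # channels with group effect, FDR < .05
#> [1] 26

pc <- pairwise_group_compare(res$plv)
sum(pc$omnibus$significant)          # PLV pairs with group effect
#> [1] 11
head(pc$omnibus[pc$omnibus$significant, c("ch_i", "ch_j", "F", "q")], 4)
#>   ch_i ch_j        F            q
#> 1    1    2 12.52878 2.410728e-03
#> 2    1    3 25.63714 9.915487e-07
#> 3    1    4 28.67236 3.142087e-07
#> 4    1    5 48.41715 2.006701e-10
```

The significant pairs concentrate in channels 1–5 — exactly the block
whose coupling the generator reduces by 0.4 in the depressed group.
Laterality proportions show the configured right-shift of the
depressed group (prefrontal region):

```r
lr <- lateralization_ratio(res$laterality)
lr[lr$region == "prefrontal", c("group", "left", "right", "symmetric")]
#>      group left right symmetric
#> 4  HEALTHY 0.50   0.1      0.40
#> 5     T2DM 0.30   0.3      0.40
#> 6 T2DM_MDD 0.35   0.5      0.15
```

And the clinical table reproduces the expected significance pattern
(depression scale separates the groups, cognition does not):

```r
tab <- demographic_table(cohort$clinical)
tab[tab$variable %in% c("HAMD24", "MOCA"), c("variable", "statistic", "p")]
#>   variable statistic        p
#> 4   HAMD24    563.29 2.86e-38
#> 6     MOCA      1.85 1.66e-01
```

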