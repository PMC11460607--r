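---
title: "Models and methods behind fnirspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fnirspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirspipe)
```

## The measurement and the montage

`fnirspipe` analyses continuous-wave fNIRS recordings from a 16-source,
16-detector montage with 40 measurement channels over the prefrontal
cortex and motor areas, sampled at 5 Hz at two wavelengths (760 and
850 nm) with 2.5 cm source-detector separation. Twenty channels
(CH1-CH9, CH11, CH31-CH40) lie over the left hemisphere and twenty
(CH10, CH12-CH30) over the right. The block paradigm is 30 s of rest,
four consecutive 15 s task blocks, and 60 s of post-task rest: 750
samples, with the task window at samples [150, 450).

Channel-to-anatomy assignment is configuration, not measurement: the
shipped default map (`default_roi_map()`) places the four prefrontal
ROI labels (DLPFC, FPA, Broca, OA) on channels 1-20 and the six motor
labels (FEF, SMA, PMC, PSC, STG, Wernicke) on channels 21-40, in
contiguous blocks mirrored across the hemispheric split so every ROI is
bilateral. No public channel-to-coordinate table exists for this
montage, so the default is a documented stand-in; any study with a real
optode digitisation should pass its own `roi_map` to `probe_layout()`.

## From photons to hemoglobin

Optical density change is computed against the mean intensity of the
30 s pre-task rest, the only stimulus-free period before the task:
$\Delta OD(t) = -\log_{10}(I(t)/\bar I_0)$.

The modified Beer-Lambert law links OD change at wavelength
$\lambda$ to chromophore concentration changes (in µmol/L):

$$\Delta OD(\lambda) = \left[\varepsilon_{HbO_2}(\lambda)\,\Delta HbO_2
 + \varepsilon_{Hb}(\lambda)\,\Delta Hb\right] d \cdot DPF(\lambda)$$

with $d$ the separation (2.5 cm) and $DPF$ the differential pathlength
factor. The inverse is a per-sample 2x2 solve. Defaults:

* **Extinction coefficients**: the standard compiled molar extinction
  values (Prahl/OMLC tabulation) for HbO2 and Hb at 760/850 nm, shipped
  in `default_extinction()`.
* **DPF**: 6 at 760 nm and 5 at 850 nm. The source protocol states only
  "5 and 6"; the assignment follows the physiology (DPF decreases with
  wavelength in adult head tissue) and is configurable.

`dpf_sensitivity()` quantifies what a wrong DPF does. Because the DPF
enters multiplicatively, inverting with DPF 5 where the truth is 6
scales the recovered concentrations by 6/5: a maximum error of 20%.
The function reports both this scaling bound and the empirical maximum
relative concentration error on a concrete series, because the phrase
"maximum percentage error in the DPFs of 20%" admits either reading
(error in the DPF values themselves, or in the recovered
concentrations); with a common scalar DPF error the two coincide.

## Motion correction

Artifacts are detected on each OD trace as runs where the moving
standard deviation (2 s window) of the first difference exceeds 3 times
a robust reference, the 90th percentile of that statistic over the
numerically non-flat part of the trace. The percentile reference was
chosen over the median after observing that a perfectly noiseless
synthetic trace concentrates most of its moving-sd mass near zero
(rest periods), which would turn ordinary block transitions into
false positives; the 90th percentile tolerates up to roughly 10%
contaminated samples while leaving physiological transitions alone.

Correction operates in the derivative domain: inside a flagged run the
derivative is replaced by a natural cubic spline through windowed means
of the neighbouring clean derivative, and the trace is re-integrated.
This removes transient spikes in place and, because integration carries
the corrected increment forward, re-levels baseline steps for the rest
of the record. An earlier variant that subtracted a smoothing spline
inside the segment and re-aligned segment means performed visibly worse
at junctions on oscillatory signals; the derivative-bridge form
implements the same contract (spline-modelled excursion subtracted,
later samples re-levelled) with exact level bookkeeping. Clean traces
pass through bit-identically.

Limits: a step occurring inside a flagged run can only be re-levelled
up to the uncertainty of the clean increment across the gap, which for
white noise of sd $\sigma$ grows as $\sigma\sqrt{\text{gap}}$ — a floor
every re-levelling method shares. The first sample is assumed clean
(it anchors the re-integration).

## Band-pass filtering and its consequences

Hemodynamics are isolated with a zero-phase (forward-backward)
Butterworth band-pass, order 3, 0.01-0.1 Hz, rejecting drift below
0.01 Hz and respiratory (~0.25 Hz) / cardiac (~1 Hz) components. DC is
removed exactly; the passband ripple at 0.05 Hz is under 5%.

Two numerical notes. First, an order-3 Butterworth at 0.004 of Nyquist
is close to the conditioning limit of the forward-backward recursion:
linearity holds to about 1e-7 relative, not machine precision. Second —
and scientifically more important — the 0.01 Hz high-pass necessarily
removes the sustained component of a 60 s task block on a 150 s record.
The filtered evoked response correlates only ~0.82 with the unfiltered
one over the task window, *for any* implementation of this band. The
pipeline therefore passes the GLM task regressor through the same
filter as the data, which restores unbiased amplitude estimation
(closed-loop recovery of a noiseless subject is then exact to 1e-6),
and recovery tests compare against the band-passed evoked trace, the
quantity the chain is actually designed to estimate.

## Activation GLM

The design matrix has a task regressor (boxcar over the task blocks
convolved with the canonical double-gamma HRF: peak 6 s, undershoot
16 s, ratio 1/6, normalised to unit peak), an intercept, and a centred
linear drift. The toolkit named in the source protocol does not state
its HRF; the double-gamma is the convention such GLMs assume, and the
parameters are arguments. Whether the 60 s task should be one regressor
or four block regressors is equally unstated; the single regressor is
the default (`blocks = "single"`) with the four-block form available,
in which case the reported beta is the mean of the block coefficients.

Estimation is ordinary least squares; AR(1) prewhitening
(Cochrane-Orcutt) is available behind `prewhiten = TRUE` but off by
default, keeping estimates exactly reproducible by a hand-rolled
regression. Group inference per channel: one-sample t against zero per
group; one-way ANOVA across the three groups with Benjamini-Hochberg
correction over the 40-channel family; Welch pairwise t tests only for
channels whose omnibus survives, corrected within channel over the
three contrasts. ROI summaries average channel t statistics within ROI.

## Laterality

$LI = (L - R)/(L + R)$ of the mean band-passed task-window
$\Delta HbO_2$ over left vs right channels, per region (prefrontal,
motor). $LI \ge 0.1$ is left-lateralised, $LI \le -0.1$ right,
otherwise symmetric. Concentration *changes* can be negative and the
source formula is silent about that case: when $L + R \le$ 1e-3 µmol/L
(including all negative denominators) the index is recorded as
undefined and excluded from group statistics rather than reported with
a flipped sign. Group comparison mirrors the channel ANOVA, applied to
the defined LIs per region.

## Phase-locking connectivity

Each channel's band-passed $\Delta HbO_2$ is converted to an
instantaneous phase via the analytic signal (frequency-domain
construction; the band-pass guarantees the narrowband input a
meaningful phase needs). Phases are computed on the full record to
keep transform edge effects away from the window of interest; the PLV
of a pair is the magnitude of the time-averaged unit phasor of the
phase difference over the task window with the first and last 10% of
its samples trimmed:

$$PLV = \left|\frac{1}{N}\sum_t e^{i(\phi_a(t) - \phi_b(t))}\right|$$

For 40 channels this yields 780 unique pairs; group comparison is a
one-way ANOVA per pair, BH-corrected over the 780-pair family, with
Welch post hocs within surviving pairs.

A caution the tests make explicit: a 0.01-0.1 Hz signal observed for
48 s (the trimmed window) contains only a handful of independent
phase samples, so single-subject PLVs are extremely noisy — the
independent-phase floor for N = 300 samples is
$\sqrt{\pi}/(2\sqrt{300}) \approx 0.05$ only for *white* phase noise,
and far higher for narrowband signals. All conclusions the package
draws from PLV are at the group level, where averaging across subjects
restores power.

## The synthetic cohort generator

No recordings from the motivating study were deposited, so the
generator is the package's test bed: it must produce data whose
*known* structure each stage can be asked to recover.

Forward model per subject: evoked $\Delta HbO_2$ = task regressor
(identical construction to the GLM design) x amplitude(group, ROI) x
hemispheric factor x subject gain; $\Delta Hb = -0.3\,\Delta HbO_2$;
concentrations map through the MBLL forward model to OD and intensity
$I_0 10^{-\Delta OD}$ with $I_0 = 1$ detector unit. Defaults, chosen
once as physiologically plausible magnitudes:

* **Effect amplitudes** (µmol/L peak): healthy 1.0, T2DM 0.7,
  T2DM+MDD 0.4 in the six ROIs where the motivating study reports
  group differences (FPA, DLPFC, Broca, PMC, STG, SMA); 0.5 elsewhere.
* **Laterality ratios** (left/right): 1.2 healthy, 1.1 T2DM, 0.8
  depressed — the depressed group is right-dominant, so its true LI is
  $(f_L - f_R)/(f_L + f_R) = -0.11$.
* **Coupling**: channels 1-5 share a band-limited oscillator mixed at
  strength 0.9 (healthy, T2DM) vs 0.5 (depressed): the 0.4 coupling
  loss the connectivity stage must detect. Channels 21-25 form a weak
  control block at 0.1. Mixing is amplitude-preserving:
  $m\,c + \sqrt{1-m^2}\,e$.
* **Noise** (µmol/L): cardiac 0.2 at 1 Hz, respiratory 0.15 at
  0.25 Hz, Mayer 0.1 at 0.1 Hz (random phase per channel), white
  sd 0.1, linear drift 0.2 per record with random sign, in-band
  oscillation sd 0.4, between-subject amplitude gain sd 15%.
* **Artifacts**: Poisson-timed at 0.5/min; spikes (one sample,
  10 trace-sd, 70% of events) and baseline steps (5 trace-sd, to the
  end of record). The source protocol gives no artifact model; these
  are the two shapes the corrector targets.
* **Clinical scores**: per-group truncated normals calibrated to the
  published cohort table (`table1_reference()`); sex as Bernoulli with
  the published proportions. The published table's frequency rows are
  internally consistent with n = 20 per group although the narrative
  reports 30 enrolled; the package keeps 20 as the reproduction fixture
  size and leaves `n_per_group` free.

What the generator does **not** emulate: photon transport through
layered tissue, scalp/systemic physiology shared across channels
(short-separation regression is out of scope), spatially correlated
noise, or serial correlation beyond what the narrowband components
induce. Passing recovery tests therefore demonstrate the estimators'
correctness under the modelled conditions, not robustness to every
failure mode of real scalp optics.

## Group sizes, replicates and runtimes

The recovery suites run 20 replicate cohorts at n = 30 per group
(the enrolled size in the motivating study) under default noise: the
configured amplitude ordering must be recovered in every graded ROI,
the depressed group's median LI must be negative, and at least one
within-block PLV pair must survive FDR over 780 pairs, each in at
least 90% of replicates. Twenty replicates keep the suite within a few
minutes; each replicate is an independent draw of the same generative
model, so rates at the 100-replicate scale are expected to match
(binomial SE at a true rate of 0.97 and 20 replicates is ~4%). The
permutation-null calibration uses 200 label permutations of one
n = 30 cohort and requires the mean fraction of FDR-significant
channels (40-family) and pairs (780-family) to stay at or below 0.05.

## Statistics from printed summaries

`anova_from_summary()`, `t_from_summary()` and `chi_square_test()`
recompute test statistics from group moments or counts alone, which is
what makes published mean±sd tables checkable without raw data: at
n = 20 per group the published F statistics for age, height, weight,
HAMD-24, SDSS, MOCA and the movement score, and the pooled t for
diabetes duration, are reproduced to within the rounding of the
printed inputs. `cor_p_value()` maps a correlation and sample size to
the two-sided p of its t transform; `correlate_gated()` picks Pearson
vs Spearman by Shapiro-Wilk at α = 0.05 on both variables, and
`exclude_outliers()` implements a pluggable outlier rule (default:
|studentised residual| > 3; the motivating study excluded three
outliers without stating its rule).

## Known limitations

* The channel-to-ROI map is a stand-in; ROI-level conclusions on real
  data require the montage's own digitisation.
* OLS with optional AR(1) is simpler than precoloring schemes used by
  some toolkits; with the 0.01-0.1 Hz band the residual spectrum is
  already heavily shaped, and the default keeps estimates auditable.
* PLV on 60 s of 0.01-0.1 Hz signal is noisy at the single-subject
  level by information-theoretic necessity; interpret only group-level
  contrasts.
* The CSV long format is the interchange dialect; no HDF5-based I/O is
  provided.
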