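---
title: "Plateau-time analysis of cuff-occlusion optical recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plateau-time analysis of cuff-occlusion optical recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvospt)
```

## The clinical problem and the measurement

Patients with peripheral arterial disease (PAD) who present with lower-limb
ulcers often undergo endovascular revascularization, but roughly a third need
a second intervention within a year because the wound does not heal. The
question this package's analysis addresses is whether a bedside optical
measurement taken around the three-week follow-up can predict, patient by
patient, whether the ulcer will go on to heal.

The measurement is dynamic vascular optical spectroscopy (DVOS): up to four
adhesive patches, each carrying laser diodes at 670, 780, 808 and 850 nm and
two silicon photodiodes at 1.6 and 2.5 cm from the sources, are placed on the
foot angiosomes of interest (peroneal, posterior tibial, anterior tibial,
dorsalis pedis, lateral plantar, medial plantar). A thigh cuff is then
inflated in a five-phase protocol — baseline, inflate-and-hold at 60 mmHg,
recovery, inflate-and-hold at 100 mmHg, recovery. Sub-arterial cuff pressures
occlude venous return while barely affecting arterial inflow, so blood pools
distally and total hemoglobin (HbT) in the foot rises until the venous bed
saturates; on deflation it drains back to baseline.

In `build_protocol()` each hold lasts 60 s and is preceded by a 10 s
inflation ramp, with 60 s baseline and recovery phases, giving a 320 s
session. Acquisition is multiplexed across patches: with 1–4 patches in use
every patch records at 10.24, 5.12, 3.41 or 2.56 frames per second
(`patch_frame_rate()`).

## From detector voltages to hemoglobin: the modified Beer–Lambert model

The device reports raw detector voltages \(V(\lambda, t)\). We convert them
to chromophore concentration changes with the modified Beer–Lambert law.
Relative to a baseline reference intensity \(V_0(\lambda)\),

\[
\Delta OD(\lambda, t) = -\log_{10}\frac{V(\lambda,t)}{V_0(\lambda)}
  = \left[\varepsilon_{HbO_2}(\lambda)\,\Delta HbO_2(t)
        + \varepsilon_{Hb}(\lambda)\,\Delta Hb(t)\right] d\,\mathrm{DPF}(\lambda),
\]

with \(d\) the source–detector distance, DPF the differential pathlength
factor, and \(\varepsilon\) the molar extinction coefficients. Per frame this
is an overdetermined linear system (four wavelengths, two unknowns) solved by
least squares (`unmix()`); \(\Delta HbT = \Delta HbO_2 + \Delta Hb\).

Choices behind this module:

* **Reconstruction model.** The original instrument's reconstruction is a
  diffusion-model-based multispectral inversion. The plateau-time statistic
  analysed here depends on the *shape* of the HbT time course, not on
  absolute quantitation, so this package uses the standard modified
  Beer–Lambert unmixing throughout: it is linear, exactly invertible on its
  own forward model, and sufficient for every downstream statistic. Absolute
  concentrations, scattering and oxygen-saturation estimation are out of
  scope.
* **Extinction table.** Bundled coefficients (`hb_extinction()`, per-mM
  per-cm) follow the standard published compilation of hemoglobin spectra:
  670 nm is strongly deoxy-weighted, 808 nm near-isosbestic, 850 nm
  oxy-weighted, which keeps the \(4\times 2\) system well conditioned
  (condition number ≈ 4).
* **DPF.** Default 4, identical across wavelengths, configurable per
  wavelength. Since the same \(d\cdot\mathrm{DPF}\) scales the forward and
  inverse model, its value cancels in round trips and only rescales real
  data; the scale contract (doubling \(d\cdot\mathrm{DPF}\) halves recovered
  concentrations) is tested.
* **Detector.** The far detector (2.5 cm) is the default — the deeper
  sampling volume is the one of clinical interest — with the near detector
  available by configuration. How the original system fused the two is not
  specified, so the choice is isolated in `optical_config()`.
* **Baseline reference.** \(V_0\) is the *geometric* mean voltage over the
  central 40 s of the baseline phase, which makes \(\Delta OD\) average
  exactly zero over that window (an arithmetic mean would leave a
  second-order residual under multiplicative noise).

## The plateau time and its aggregation

The classification feature is the plateau time (PT): on each inflation
trial's HbT curve, the time between the two crossings of 90% of the realized
maximum (`extract_trial_features()`). Crossing times are linearly
interpolated between bracketing frames (the sampling rule of the original
analysis is unstated; interpolation makes the statistic sub-frame accurate
and resampling-stable, which is tested). The curve is referenced to its level
at inflation onset — estimated from the last few raw frames at or before the
window start, so the smoothing window never straddles the onset kink — which
makes PT invariant under positive affine rescaling of the curve. A centered
moving average (default 5 frames, configurable) suppresses detector noise
before thresholding.

Two declared edge rules:

* **Right censoring.** If the curve is still at or above the threshold when
  the trial window ends, the trailing crossing is clamped to the window end
  and a `censored` flag is set. Patients who fail to reach saturation at
  follow-up are the hallmark of the non-healing group, so those trials must
  not be discarded; the flag preserves both readings of the ambiguity.
* **Flat curves.** A non-positive HbT excursion yields explicitly undefined
  features with a diagnostic reason, never a silent zero.

Per patch and time point, PT is the mean of the 60 mmHg and 100 mmHg trials
(if only one trial is defined, that one is used, with a warning). Per patient
the *Gen* feature is the mean over all patches; the *Loc* feature follows the
arterial tree (`angiosome_tree()`: anterior tibial → dorsalis pedis;
posterior tibial → medial and lateral plantar) in preferential order — patch
on the ulcer's angiosome, else mean of patches below the affected artery,
else the patch above it. Differences across the three acquisition time points
(pre-, post-intervention, first follow-up) give the six features
`postpre/fu1pre/fu1post × gen/loc`; `fu1post = fu1pre − postpre` exactly for
complete data.

## The synthetic cohort generator

No individual patient recordings are published, so the package generates
cohorts whose statistical structure matches the reported study
(`cohort_spec()`, `generate_cohort()`), and every analysis is exercised on
raw simulated voltages end to end.

* **Curve family.** Each trial response is a saturating-exponential rise
  toward the plateau with an exponential return to baseline after deflation
  (the published example curve has exactly this character). Given a target
  PT, the rise time constant — and, for short plateaus, an onset delay — is
  solved numerically so the interval above 90% of the realized maximum has
  exactly the target length; non-saturating curves (still rising at
  deflation) realize short PTs by construction. The second trial superposes
  on the first trial's residual decay, as real curves would.
* **Outcome structure.** The follow-up-minus-post difference `fu1post_gen`
  is the quantity with published group statistics, so it is generated
  directly: positive-outcome patients draw it from N(6.7, 9.3²) s and
  negative-outcome patients from N(−7.1, 4.3²) s, with 9 and 5 patients per
  group by default.
* **PT levels.** The published per-time-point PT values are not printed, so
  levels are fixed defaults chosen once as physiologically sensible for the
  320 s protocol: pre-intervention 15 ± 4 s (uniformly poor vasculature
  before treatment), post-intervention 35 ± 5 s (positive) and 45 ± 5 s
  (negative — the non-healing group showed the larger immediate
  post-intervention jump), and follow-up equal to post plus the drawn
  difference. Patient-level targets are clamped to the curve family's
  realizable range [2, 69] s; at these defaults the clamp touches ≈2% of
  follow-up draws and biases the realized group mean by ≈0.02 s.
* **Patch heterogeneity.** Each patch carries a persistent offset
  (N(0, 1.5 s)) applied at *all* time points, so patch-mean differences equal
  the patient-level drawn difference exactly — which is what makes the
  generator's difference distribution interpretable.
* **Optics and noise.** Plateau amplitude 10 µM (a typical venous-occlusion
  HbT excursion at these wavelengths), venous oxy-fraction 0.7, baseline
  voltage 1 V, and 1% multiplicative Gaussian detector noise; the paper is
  silent on noise, so the default is declared, not inferred.
* **Comparison modalities.** Ankle-brachial (ABI) pressure ratios and duplex
  peak-systolic-velocity (PSV) ratios are drawn with only a weak outcome
  association (neither modality was statistically associated with healing)
  and with missingness matching the reported availability: pre/follow-up ABI
  in 5/10 of 14 patients, duplex in 9/11. Missingness is explicit (`NA`),
  whole-modality per visit, never a sentinel value.
* **Determinism.** One cohort-level seed; per-patient streams are derived
  deterministically from it, and the modality panel is drawn before the
  optical noise stream so that a recordings-free run (`recordings = FALSE`)
  draws identical targets and panels. A fixed seed reproduces byte-identical
  serialized cohorts.

What the generator does *not* emulate: motion artifacts, drift, probe
decoupling, arterial pulsation, inter-wavelength noise correlation, or any
dependence of curve shape on demographics. Passing tests therefore show that
the pipeline recovers what the model family encodes, not that the instrument
behaves this way in vivo.

## Statistical layer

`analyze_features()` reproduces the study's statistics on any feature table:

* **Redundancy screen.** Pairwise Spearman rank correlations
  (pairwise-complete); pairs with ρ > 0.75 are flagged redundant. The rule
  is one-sided by design — it mirrors the original screen — and constant
  features report `NA` rather than disappearing.
* **Group comparison.** Welch's unequal-variance t-test with
  Welch–Satterthwaite degrees of freedom, computable from raw values or from
  published `(mean, SD, n)` summaries. The statistic is oriented
  negative-minus-positive group, matching the sign convention of the
  published t = −3.78 with 11.8 df; the fractional df is what forces Welch
  rather than a pooled test. p values are Bonferroni-adjusted with m = 3
  (the three Gen difference features); with m = 3 the printed P = 0.008
  follows from the raw Welch p ≈ 0.0027, which is how the unstated
  multiplier was pinned down. The study's abstract quotes p < 0.001 for the
  same comparison; the section-level value is the one reproduced here.
* **ROC and cutoff.** Thresholds at midpoints between adjacent distinct
  scores plus ±∞; AUC as the Mann–Whitney probability with ties counting
  one half (identical to trapezoidal integration of this curve, which is
  tested); operating cutoff by maximum Youden index J = Se + Sp − 1, ties
  broken by distance to the (0,1) corner and then by the larger cutoff. On
  14-patient instances every quantity is also checked against exhaustive
  enumeration.
* **Diagnostic accuracy.** Confusion counts and Se/Sp/PPV/NPV as proportions
  and as percentages rounded half-up (8/9 → 89%). Zero denominators yield
  `NA`, not 0.
* **Sample size.** Two-group normal-approximation size for a standardized
  difference: \(n = \lceil 2 (z_{1-\alpha/2} + z_{1-\beta})^2 / \Delta^2 \rceil\)
  per group. The published estimate of 56 total patients corresponds to
  α = 0.05, β = 0.04 and a one-SD effect; the sentence defining it is
  ambiguous, and this formula is the declared interpretation because it
  reproduces the printed number exactly.

## Modality comparison

`assign_outcome()` maps each modality to a predicted outcome through an
explicit `cutoff_rule()`: optical difference below −1.3 s, ABI below 0.9, or
PSV ratio above 2.4 predicts non-healing; inequalities are strict, so a
reading exactly at the cutoff is assigned the healing outcome. The direction
conventions for ABI and duplex follow the standard abnormality directions in
vascular practice (the published table states the cutoffs but not the
mapping), and they live in configuration so they can be flipped. The bundled
`inst/extdata/clinical_truth_table.csv` transcribes the published 14-patient
comparison (with `X` as missing); `fixture_report()` scores it without any
simulation. The reported duplex Se = 86%/Sp = 50% at follow-up is *not*
reproducible from that table at the 2.4 cutoff — it evidently used the
continuous PSV values, which are unpublished — and is deliberately out of
scope.

## Numerical choices and problem sizes

Crossing solvers use `uniroot` at 1e−12 tolerance on bracketing intervals
that are provably monotone for this curve family. Feature extraction treats
excursions below 1e−6 µM as flat. Youden-index ties are detected in exact
integer arithmetic (comparing `TP·n_neg + TN·n_pos` rather than floating
`Se + Sp − 1`), since mathematically equal indices can otherwise differ by
an ulp and scramble the declared tie-break order. The test suite's Monte-Carlo checks use
500 seeded cohorts (full pipeline: simulate, reconstruct, featurize, test)
for the effect-size and cutoff recovery, and 2000 generator-level cohorts
for the unbiasedness of the realized group difference; these sizes put the
Monte-Carlo standard errors comfortably inside the asserted bounds while
keeping a full check run to a few minutes on a laptop.

## Known limitations

* The Beer–Lambert substitution recovers the forward model exactly but is
  not the original diffusion-based reconstruction; absolute concentrations
  from real hardware would differ (the PT statistic would not).
* Plateau times below ≈8 s are realized with a delayed-onset rise; at the
  extremes of the realizable range (below ~5 s or above ~68 s) the
  deflation-kink interacts with smoothing and the realized PT can err by a
  few tenths of a second at the coarsest frame rate. The cohort defaults
  keep targets away from those extremes.
* The generator draws the key feature difference directly from the printed
  group distributions; it cannot validate the physiological claim, only the
  pipeline's ability to recover parameters under the stated conditions.
* Sampled cutoffs on 14-patient cohorts are highly variable (the 90%
  interval spans several seconds); a fixed published cutoff like −1.3 s
  should be read as one draw from that distribution.
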