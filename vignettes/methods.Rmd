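---
title: "Models and methods behind aliSmoke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aliSmoke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aliSmoke)
```

`aliSmoke` implements the statistical and image-analysis workflow of a
smoke-exposure study on small-airway epithelial cells differentiated at the
air-liquid interface (ALI), plus the transfer of the resulting expression
signature to an independent in vivo cohort. This vignette is the package's
own account of the models, the tunable parameters, the synthetic-data
design, and the choices made where the procedure was genuinely open.

## Per-pixel ciliary beat-frequency mapping

A recording is a grayscale stack `T x H x W` with frame rate `fps`. Each
pixel is treated independently (no spatial smoothing): its trace is
detrended — mean removal by default, least-squares linear detrend as an
option — optionally Hann-windowed, and transformed to a one-sided power
spectrum `|X_k|^2 / T^2` at resolution `fps / T`. The zero-frequency bin is
always excluded; for even and odd `T` alike the spectrum has
`floor(T/2) + 1` bins.

A pixel is called *actively beating* when the in-band peak power is at
least `snr_threshold` times the median in-band power (inclusive at the
threshold, and requiring strictly positive peak power so that constant
traces are inactive). The criterion is deliberately simple and fully
tunable, because published descriptions of "meaningful frequency" rules
rarely pin down the decision statistic. Its null behaviour is measured, not
assumed: in the package tests, Monte-Carlo white-noise traces establish the
per-pixel false-positive rate.

Three numeric choices matter:

* **Analysis band, default 2–20 Hz.** Brackets the 7–10 Hz physiological
  CBF range of differentiated cultures with margin. The band must stay
  below Nyquist (`band_high < fps/2`); for 30 fps material this means
  narrowing it (the package examples use 2–14 Hz), and
  `compute_frequency_map()` rejects violations rather than clipping
  silently.
* **`snr_threshold`, default 30.** A peak-to-median statistic over `m`
  in-band bins has null exceedance probability roughly
  `m * exp(-0.69 * k)` for threshold `k`; with hundreds of bins (T = 512),
  thresholds below ~15 let white noise pass frequently, while 30 keeps the
  null rate far below 1e-4 yet costs no power: a sinusoid of amplitude `a`
  in noise of SD `sigma` has expected peak-to-median ratio of order
  `T * a^2 / (2.8 * sigma^2)`, i.e. hundreds even at `a = sigma`.
* **Detrending, default mean removal.** Makes the map invariant to constant
  offsets (and, with the linear option, to slow drift), which also makes
  8-bit vs 16-bit acquisition offsets irrelevant.

The map reports each active pixel's argmax-power frequency; the summary is
the percentage of analysed pixels active and the mean CBF over them. The
false-color rendering maps the band linearly onto a temperature-style
lookup table with black reserved for inactive pixels.

## Adjusted AUC and the repeated-measures model

Longitudinal endpoints (TEER in Ω·cm², qPCR delta-Ct defined as
`Ct_target - Ct_control`) are collapsed per series to the *adjusted AUC*:
trapezoidal area over the day grid divided by the spanned interval — the
time-average of the interpolated curve, in the endpoint's own units and
invariant to affine changes of the day axis. The trapezoid rule is a
documented, swappable choice; any quadrature exact for piecewise-linear
interpolants gives the same value. Where an endpoint is analysed on the log
scale (TEER, active-cilia area), the natural logarithm is applied to the
adjusted AUC value itself, not pointwise; test results are base-invariant.

Because both treatments are applied to cells of each donor, the two AUCs of
one donor are correlated. The model has fixed cell means `mu[i, j]` for
group `i` (HC/COPD) and treatment `j` (Air/CS) — equivalently group,
treatment and interaction effects — and a compound-symmetry covariance:
equal variance `sigma^2`, within-donor correlation `rho`. Residual degrees
of freedom are partitioned into between-subject and within-subject halves
(`N - G` each for `N` donors in `G` groups); effects that change within a
donor (treatment, interaction) are tested on within-subject df, the group
effect on between-subject df.

Estimation uses the closed-form balanced-design solution: per-donor
treatment differences estimate `2 sigma^2 (1 - rho)`, per-donor means
estimate `sigma^2 (1 + rho) / 2`. On this balanced two-treatment design
these moment estimators coincide with REML — the package tests verify
agreement with `nlme::lme` — while remaining well-defined at zero residual
variance, where iterative REML fails. The treatment contrast within a group
is then a t statistic on within-subject df; when the model is fit to a
single group's data it reproduces that group's paired t-test exactly (to
more than ten significant figures in the tests). With two groups the
within-subject variance is pooled across groups, which is the model's
intended behaviour and differs from running two separate paired t-tests.

One-sided hypotheses come from an endpoint registry mirroring the study
design: a *decrease* under smoke is expected for log AUC of active-cilia
area, AUC of CBF, log AUC of TEER, and the delta-Ct AUCs of KRT5, KRT14 and
MUC5AC (lower delta-Ct = induction); an *increase* for the delta-Ct AUCs of
SCGB1A1 and FOXJ1. P-values are deliberately not adjusted for multiplicity.
Comparative-Ct fold changes between treatment arms are
`2^|AUC_air - AUC_smoke|`, directed by which arm has the lower delta-Ct.

## Differential expression

Expression input is assumed normalized and log-scale; upstream read
processing is out of scope. Each transcript is fit by OLS with the design
`~ 0 + condition + donor` (donor covariates only in paired designs), the
condition contrast is tested two-sided on the residual df, and
Benjamini–Hochberg step-up q-values are computed across transcripts.
Moderated (empirical-Bayes) variance shrinkage is intentionally not
implemented: the downstream consumers — signature membership, direction of
deregulation, ranking — depend on contrast estimates and their ordering,
which the ordinary model preserves; an optional pooled-variance mode is
available for very small designs. Rank-deficient designs are rejected with
the confounded columns named. Signatures are transcripts with `q < q_cut`
(default 0.05), ordered by q.

## Signature transfer

Each dataset is min–max normalized per transcript to `[0, 1]`
*independently*; constant rows map to zero with a warning. Independent
normalization is what makes a cross-platform join meaningful: any additive
per-transcript platform offset between cohorts cancels exactly. Joining
keeps transcripts significant in *both* comparisons at `q < q_cut` with no
directionality filter, concatenates samples, and clusters columns by UPGMA
(average linkage) on correlation distance `d = 1 - r` (range `[0, 2]`;
zero-variance leaves get `r = 0`, hence `d = 1`, with a warning). Tie-breaks
follow `hclust`'s deterministic convention; the tests verify merge structure
against an exhaustive small-instance oracle via cophenetic distances.

Classification uses a random forest (100 trees, 10 candidate features per
split) under stratified k-fold cross-validation, 50 folds by default,
degrading to leave-one-out with a message when the smaller class has fewer
members than folds. Out-of-fold vote fractions are pooled into the ROC/AUC;
the confusion matrix thresholds votes at 0.5. Robustness is probed by
removing the `k` features (default 10) with the highest absolute Pearson
correlation to the 0/1 label; the ranking is computed once on the full
dataset before cross-validation — a two-stage scheme with a known optimistic
bias, kept because it mirrors the attribute-ranking-then-classify workflow
this package models, and documented rather than hidden. Every stochastic
operation requires an explicit seed and records it in its report.

Direction consistency between two DE results counts, among transcripts
significant in both, those with the same sign of log fold change; a zero
log fold change matches only another zero. With nothing shared, the
fraction is flagged undefined rather than fabricated.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

* **Videos** model beating as an additive per-pixel sinusoid
  (`background + a * sin(2 pi f t / fps + phase)`) with Gaussian noise;
  per-pixel phases drawn from `N(0, jitter_sd)` model imperfect metachrony.
  Defaults (30 fps, 512 frames) are package choices for plausible
  recordings. A convenience preset (`healthy_culture_video_spec()`)
  scatters patches covering roughly 7–16% of the field at 7.2–9.8 Hz with
  amplitude/noise = 5, and its analysis lands inside the 5–20% area and
  7–10 Hz CBF plausibility bands expected of healthy differentiated
  cultures.
* **Longitudinal tables** use the paired design (3 donors per group, days
  7/14/21/28 by default), a donor random intercept shared by both arms, and
  equicorrelated residuals across days implementing compound symmetry.
* **Expression cohorts** share a deregulated signature (random sign per
  transcript, shift `effect_size` in exposed samples) between a paired
  in vitro cohort and an unpaired in vivo cohort; a per-transcript Gaussian
  cohort offset models the platform shift, and a configurable fraction of
  the signature flips direction in vivo. All draws are Gaussian; seeds are
  explicit parameters, never global state.

What passing tests on these data show is that the *computational* pipeline
is correct and calibrated: frequencies are recovered to one spectral bin,
type-I error of the one-sided contrast matches its nominal level, BH and
UPGMA match independent oracles, classification behaves correctly on
separable, null, redundant and concentrated constructions, and direction
overlap recovers a planted discordance rate. They do not certify behaviour
on real recordings or sequencing data, which add optics, non-sinusoidal
beat waveforms, count noise, library-size effects and batch structure that
these generators deliberately omit.

## Problem sizes and numerical conventions

The shipped tests run on deliberately modest sizes — videos up to
50 x 50 x 512, 10,000-replicate null simulations for type-I calibration,
forests of 100 trees under 5–10-fold CV — chosen so the whole suite
validates every property in a few minutes on one core. Degenerate inputs
are defined, not exceptional: constant traces give all-zero spectra;
all-inactive maps summarize with an undefined (NA) mean CBF; zero residual
variance gives exact cell means with infinite t for non-zero contrasts and
an undefined p for zero ones; subjects missing a treatment arm, reversed
day grids, rank-deficient designs and empty signature intersections are
rejected with named offenders. Video TIFFs store intensities affine-scaled
to `[0, 1]` as 32-bit float with a sidecar JSON carrying the frame rate and
original range (round-trips are exact to single precision); frequency maps
are written as TSV with NA marking inactive pixels.

## Known limitations

Per-pixel independence ignores spatial coherence of ciliary fields; the
optional activity criterion is a package-defined stand-in, not a validated
clinical rule. The repeated-measures implementation requires the balanced
paired design it was built for and does not impute missing arms. The DE
model's per-transcript variances are noisy at n = 3 donors per group —
exactly the regime where moderated methods shine — so absolute significance
calls on tiny designs should be read cautiously even though directions and
rankings are stable. Feature ranking on the full data inflates reduced-set
AUCs slightly; comparisons between full and reduced signatures remain
internally consistent.
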