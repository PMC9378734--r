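---
title: "Decoding the attentional spotlight and latent behavioral states from prefrontal population activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the attentional spotlight and latent behavioral states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`attnstate` implements an analysis chain for multi-unit activity (MUA)
recorded from prefrontal cortex (frontal eye fields, FEF) during a
100%-valid cued luminance-change detection task, together with a
synthetic-session generator that plants the latent structure the chain
is designed to detect. The scientific question the chain addresses is
whether behavioral errors in an attention task reflect misallocated
spatial attention, latent task-independent behavioral states, or both.
Its stages:

1. **Attentional-spotlight decoding** (`fit_regole()`,
   `rolling_decode()`): a regularized optimal linear estimator — ridge
   regression of the cued location's quadrant code on pre-target
   population responses — decodes a continuous (x, y) locus of covert
   attention per trial. The distance from that locus to the expected
   target, TA, is binned (close 0–6°, medium 6–12°, far 12–18°) and
   related to detection accuracy (`hit_rate_by_ta()`).
2. **Unit selectivity** (`unit_selectivity()`): per-unit modulation
   indices MI = (FR1 − FR2)/(FR1 + FR2) for attention (TA close vs far,
   correct trials) and behavioral outcome (hit vs miss), with Wilcoxon
   significance and pure/mixed classification.
3. **Noise correlations** (`noise_corr_by_outcome()`): pairwise Pearson
   correlations of z-scored 200-ms pre-stimulus responses, summarized
   over positive significant pairs, split by trial type (hit / miss /
   false alarm), on pre-target and pre-cue epochs, with an optional
   control that matches TA distributions across types.
4. **Demixed PCA** (`marginalize()`, `fit_dpca()`,
   `decode_with_axis()`, `axis_overlap()`,
   `remove_component_backproject()`): a from-scratch implementation of
   demixed principal component analysis. The trial-averaged
   condition tensor (units × conditions × time) is split into factorial
   marginalizations (parameter main effects with their time
   interactions folded in, the parameter interaction, and
   condition-independent activity); each marginalization is approximated
   by a reduced-rank regularized regression onto the full data, giving
   paired decoder/encoder axes. Axes serve as linear classifiers with
   permutation chance (maximum accuracy over 100 label shuffles), can be
   compared by their normalized dot product (non-orthogonality tested
   against a Monte-Carlo null of random directions), and can be removed
   from the data by a rank-one back-projection filter.
5. **Multi-session pipeline** (`analyze_session()`, `run_study()`):
   orchestration, per-session summaries (behavioral gain, component
   overlap, axis accuracies, noise-correlation summaries), and
   across-session statistics (demixing cost, overlap-versus-gain rank
   correlation, cross-trial state persistence, component-removal
   contrasts).

The monkey recordings the chain was designed around are not publicly
available, so all quantitative claims in this package are made — and
tested — on the synthetic generator, which plants known ground truth.

# The generative model

`simulate_session()` draws, per trial \(t\) and unit \(i\):

* **Task**: one of four landmarks (corners of a square with 28°
  diagonal, ~14° eccentricity) is cued with 100% validity; the true
  attentional spotlight is the cued landmark plus isotropic Gaussian
  jitter (default SD 8.5°, giving a realistic spread of true TA across
  the 0–18° analysis range).
* **Latent states**: two independent stationary AR(1) series.
  \(s_1\) ("optimality") relates to outcome in a U-shaped way: its
  positive tail raises miss odds (distractibility), its negative tail
  raises false-alarm odds (impulsivity). \(s_2\) ("responsiveness")
  orders outcomes linearly (miss vs false alarm). The AR coefficient
  (default 0.7, i.e. a correlation length of roughly 3 trials) was
  chosen as the slowest drift at which a single 800-trial session still
  contains enough independent state excursions for per-session
  conditional statistics to be estimable; slower drifts leave per-type
  state moments dominated by a handful of excursions.
* **Outcomes**: a multinomial logistic model with linear predictors
  \(\eta_{hit} = b_h - \beta_{TA}\,TA\),
  \(\eta_{miss} = b_m + \beta_{m}\max(s_1,0) + \beta_{s2}s_2\),
  \(\eta_{fa} = b_f + \beta_{f}\max(-s_1,0) - \beta_{s2}s_2\).
  Defaults give roughly 65% hits, 15% misses, 20% false alarms and a
  close-to-far hit-rate drop of ~10–15 percentage points, comparable to
  published cued-detection behavior.
* **Rates**:
  \[
  r_{it} = \max\Big\{0,\;(b_i + w^{s2}_i s_{2,t})\,
    \big(1 + g_i K_{rf}\big)\big(1 + f_i K_{focus}(TA_t)\big)\,
    \big(1 + w^{s1}_i(|s_{1,t}| - E|s_1|) + v_i\,|s_{1,t}|\,\epsilon_t\big)\Big\}
  \]
  with Gaussian spatial kernels \(K\), baseline rates \(b_i\) log-normal
  around 30 spikes/s, and counts conditionally Poisson in 10-ms bins.
  Three design choices deserve comment, because the published
  description of the phenomena leaves the generative mechanism open:

  * **Attentional-focus gain** \(f_i K_{focus}(TA_t)\). A receptive-field
    kernel alone cannot reproduce the population-wide finding that units
    fire more when attention is *near the expected target*, wherever
    that target is: pooled across the four cue positions, RF-based
    modulation averages out. The focus gain — shared by tuned units and
    driven by the true spotlight-to-target distance — is the generative
    counterpart of that population-level attentional-focus modulation.
  * **U-shaped mean footprint with negative loadings.** The optimality
    state enters through its centred magnitude \(|s_1| - E|s_1|\) with
    negative loadings \(w^{s1}_i\), so error trials (large \(|s_1|\))
    *lower* the rates of loaded units while hits sit apart: this gives
    the trial-type tensor a U-shaped condition pattern and makes the
    state pathway push the hit-vs-miss rate contrast in the same
    direction as the behavioral TA-outcome coupling (hits above misses),
    so the two sources reinforce rather than cancel in mixed units.
    A gain linear in \(s_1\) would instead produce a purely monotone
    mean pattern and no U-shaped component.
  * **State-modulated shared volatility** \(v_i |s_{1,t}| \epsilon_t\),
    with \(\epsilon_t\) a fast trial-wise standard normal factor common
    to the population. Trial-type differences in noise correlations are
    carried by the conditional second moment \(E[s_1^2 \mid type]\)
    (hit < false alarm < miss by construction of the outcome model),
    which is estimable from conditional means and therefore far more
    stable per session than conditional variances. This is what makes
    the ordering hit < fa < miss reproducible at 18 × 800-trial scale.

* **Population structure**: 48 units; 55% attention-tuned, 45%
  state-loaded, with the tuned/loaded intersection controlled by a
  copula-correlation parameter (`overlap`) whose expected membership
  counts are planted exactly. State-loaded units carry the optimality
  (gain) and/or responsiveness (additive) loading. In the
  `vary_overlap` study arm, `overlap` ramps across sessions from −0.8
  (state loadings pushed onto untuned units) to +0.9 (state loadings
  concentrated on tuned units) while \(\beta_{TA}\) ramps downward, so
  that a larger attention/outcome population overlap co-occurs with a
  smaller behavioral gain of attention — the across-session coupling the
  pipeline is asked to recover as a negative Spearman correlation.

## What the generator does and does not emulate

It emulates: the task geometry and timing, slow task-independent state
drift with U-shaped/linear outcome coupling, mixed selectivity,
TA-dependent behavior, trial-type noise-correlation structure, and an
across-session overlap-gain relation. It does not emulate: within-trial
attentional exploration dynamics (one static spotlight sample per
trial), eye movements, raw-voltage or spike-sorting artifacts,
correct-rejection subtypes, evoked-response dynamics beyond a minimal
post-stimulus transient, or non-Poisson spiking statistics. Passing
tests therefore certify the analysis chain's behavior under this
generative family, not under real recordings.

# Numerical and statistical choices

* **Ridge decoder.** The bias is handled by mean-centring responses and
  refitting an intercept (equivalent to the weights-times-(response plus
  bias) parameterization up to reparameterization). The penalty defaults
  to generalized cross-validation over a 13-point log grid scaled by the
  mean squared response; it is selected on the first training window of
  a session and then held fixed across retrainings. Decoder readouts are
  mapped to degrees by an affine calibration fit on the training cue
  positions. Trials seen before the 200-correct-trial warm-up are
  excluded from all TA analyses. TA of 18° or more is labelled
  `out_of_range` and excluded from binned summaries (no clipping).
* **Selectivity.** MIs are computed on raw median rates (z-scored rates
  can be negative, which makes the index unbounded); the analysis window
  is the [−250, −50] ms pre-target epoch. Rank-sum tests at α = 0.05;
  a unit is `mixed` if both indices are significant.
* **Noise correlations.** Per-pair significance is the two-sided t-test
  on the Pearson coefficient; summaries are the mean (and median) over
  pairs with r > 0 and p < 0.05. The pre-cue epoch is the 200 ms before
  cue onset. TA equalization matches, per trial type, the TA-bin profile
  of the scarcest type, keeping as many trials as the profile allows;
  matching counts exactly per bin instead discards so many trials that
  the truncated-pair summary becomes uninformative at this session
  length.
* **Demixed PCA.** Regularization defaults to \(10^{-6}\) of the total
  signal variance. Time interactions are folded into their parameter's
  marginalization. Condition averaging is near-balanced: cells are
  subsampled to the larger of the smallest cell count and 8 trials, so a
  single sparse cell cannot reduce the whole fit to a handful of trials.
  Units are soft-normalized by 1/(mean rate + 5); without this,
  log-normal rate spread lets a few high-rate units dominate every
  population axis. Component signs are fixed (largest-magnitude decoder
  element positive) so fits are bit-reproducible. Axis decoding holds
  out one trial per class per repeat and classifies by nearest
  class-mean projection; chance is the maximum time-averaged accuracy
  over 100 label shuffles. The non-orthogonality threshold is the 97.5th
  percentile of |dot| over 10,000 random unit-vector pairs in the
  ambient dimension (the threshold depends on unit count, so no fixed
  number is hard-coded). Component removal rescales the decoder row by
  \(1/(D_k F_k)\) so the removed axis is exactly annihilated.
* **Trial-type analyses.** The trial-type tensors are TA-equalized by
  default (the standard control for attentional confounds in trial-type
  contrasts) and unbalanced, so every retained trial keeps its
  chronological neighbor for the lag-1 persistence analysis, which uses
  consecutive-trial pairs only. The U-shaped versus linear component
  labels are assigned by decomposing both axes' condition profiles onto
  the canonical U and linear contrasts and taking the pairing that
  explains the most contrast. Ground-truth state recovery is evaluated
  on the pre-cue trial-type model, where the planted states are isolated
  from attention-related variance by construction (attention is not yet
  deployed before the cue); the pre-target model is used for axis
  decoding and component removal.
* **Session overlap.** The per-session overlap between attention and
  outcome components is the median |dot| of the first encoder axes over
  six refits on resampled, TA-matched condition averages: a single fit's
  estimate is dominated by small-cell noise, and without TA matching the
  residual within-bin TA differences between hits and misses leak
  attention-unit weight into the outcome axis.
* **Open questions resolved.** The training/testing window mismatch
  ([−220, +30] vs the 150 ms pre-target average) is kept as configured
  defaults, both exposed. Both pooled and single-session trial-type
  dPCA modes are available (`run_study()` operates per session). The
  hit/miss equalized and unequalized behavioral-gain variants are both
  reported.

# Scale of the shipped analyses

The packaged tests and the acceptance script run two 18-session ×
800-trial study arms (one at constant population overlap for parameter
recovery, one with the planted overlap-gain ramp), 48 units per
session. These sizes reproduce all planted qualitative structure while
keeping a full run in the single-digit minutes on one CPU; the
calibration studies (type-I error of the selectivity tests and of the
shuffle-based decoding threshold) use 200 null replicates.

# Known limitations

* The planted-role recovery rate of the selectivity classification is
  bounded (~80–85%) by a real ambiguity: with a TA-dependent outcome
  model, attention-tuned units genuinely carry hit-vs-miss information,
  so "attention-only" units show outcome selectivity at better than
  chance rates.
* The estimated U-shaped axis aligns imperfectly with the planted gain
  direction (cos ≈ 0.7–0.9); component removal therefore attenuates
  rather than perfectly abolishes the noise-correlation contrast, and
  the removal analysis is asserted as a paired across-session double
  dissociation.
* Session-level overlap estimates remain noisy even after resampling;
  the overlap-gain correlation is a study-level statistic and individual
  sessions scatter widely around the planted ramp, as they do in real
  data.
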