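---
title: "Population analysis of trial-aligned calcium imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of trial-aligned calcium imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalpop)
```

`thalpop` implements the population-analysis stages used to study how
sensory-thalamus (MGB) ensembles reorganise during cross-modal Go/Nogo
reversal learning: behavioural performance, trace conditioning, per-cell
responsiveness, functional clustering, trial-by-trial population-vector
correlation (PVC), weighted co-activity network metrics, off-task sensory
mapping analyses, and linear population decoding. A synthetic-data
generator with planted ground truth stands in for real recordings, so
every stage is testable end to end without any data download.

This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic tests do and do not establish
about real data.

## Task structure and behavioural model

A session has 140 trials: 30% Go, 35% Nogo, 35% catch (allocation is
deterministic: `floor` for Go and Nogo, remainder to catch, giving
42/49/49). Each trial is a 2 s stimulus (or blank), a 2 s silent delay,
and a 1.5 s response window, separated by 6-13 s inter-trial intervals.
Spout contacts within 200 ms of the response-window onset are treated as
accidental and ignored.

Performance is the discriminability index

$$d' = Z(\text{hit ratio}) - Z(\text{false-alarm ratio}),$$

with Nogo and catch trials pooled into the false-alarm ratio (their
performance develops similarly) and $Z$ the standard-normal inverse CDF.
Ratios of exactly 0 or 1 are adjusted to $1/(2N)$ and $1 - 1/(2N)$
before the inverse normal; the $1/(2N)$ rule is the standard
log-linear correction, adopted because no single adjustment convention
is universal and the choice must be explicit for d-prime to be
reproducible. Animals are experts once $d' > 1.5$ on
three consecutive sessions; the naive phase is the first two-to-three
sessions that are themselves below threshold.

The synthetic learning curve makes the *expected* d-prime follow a
logistic in session index with its midpoint at the configured expert
session and asymptote 3.0, so the deterministic trajectory crosses 1.5
exactly at the midpoint; hit and false-alarm probabilities are derived
symmetrically ($p_{hit} = \Phi(d'/2)$, $p_{fa} = \Phi(-d'/2)$) and
binomially sampled.

## Signal model of the generator

Fluorescence is built additively, per cell, in z units:

* **Stimulus transients.** A difference-of-exponentials kernel (rise
  0.07 s, decay 1.7 s, unit peak) is placed at stimulus onsets.
  Kinetics are conventional GCaMP7s-like values and configurable; the
  default planted amplitude is 1.5 z with ±20% per-event jitter.
  Classes: `stable_go` (constant across learning), `learning_enhanced`
  (weak naive, full expert), `learning_inhibited` (the reverse),
  `nogo_responsive`.
* **Delay ramps.** `ramp_up` / `ramp_down` cells receive a linear ramp
  across the delay period of Hit trials only, with an exponential tail.
* **Delay coherence.** In expert phases all cells share a latent
  delay-period signal on Hit trials — a per-trial amplitude times a
  smooth within-trial waveform — scaled per cell by a positive loading
  drawn once per session (uniform on [0.5, 1.5]) and globally by the
  per-phase `delay_coherence` (default 0 naive, 0.4 expert). Positive
  loadings mean no anticorrelation is planted; the negative-edge network
  regime should stay flat.
* **Behavioural coupling.** `behavior_coupled` cells add a scaled copy
  of the z-scored locomotion trace.
* **Nuisance.** I.i.d. Gaussian frame noise (SD 1.0 z), a per-cell
  linear drift (to make detrending consequential), and a slow shared
  neuropil background whose 0.7-scaled copy contaminates the raw trace,
  so neuropil correction exactly recovers the cell signal.

The lick policy is phase-dependent Bernoulli per trial (naive: 0.50 /
0.45 / 0.45 lick probability for Go/Nogo/catch, giving d-prime near 0;
expert: 0.95 / 0.10 / 0.10, d-prime near 2.9), with anticipatory licks
during the delay drawn from a Poisson rate on a fraction of licked
trials so the anticipatory-licking analyses are exercisable.

What the generator does *not* emulate: biophysical spiking, motion or
bleaching artifacts beyond linear drift, non-Gaussian noise, and any
real between-animal heterogeneity (animals are statistically
exchangeable). Passing tests therefore demonstrate the *analysis logic*
— recovery of planted effects, correct nulls, oracle agreement — not
performance on real recordings.

## Preprocessing

The pipeline order is fixed and recorded in a provenance attribute:
neuropil correction (`F - 0.7 F_{neu}`) → linear detrend → zero-phase
4th-order Butterworth low-pass at 5 Hz → (optional per-cell z-scoring
over the whole session) → trial epoching with an explicit baseline
convention. Calling stages out of order is an error. The Butterworth
order and the linearity of the detrend are choices (only the filter
family and cutoff are fixed by the design); both are configurable.

The 5 Hz low-pass is applied for the PVC, co-activity-network and
decoder analyses only. Responsiveness classification runs on detrended,
*unfiltered* z-scores (`condition_trace(..., cutoff_hz = NA)`): after
low-passing, z-renormalisation leaves window-mean noise strongly
autocorrelated, which inflates the sampling variance of short-window
medians and with it the false-positive rate of the ±0.2 z threshold.

Zero-phase filtering subtracts each row's mean (the DC component passes
a unit-gain low-pass exactly), extends the series by odd reflection at
both ends, and runs the forward-backward pass vectorised across cells.
This avoids the start-up transients of zero-padded implementations; a
constant trace passes through unchanged.

Windows are half-open `[onset, onset + round(duration * rate))` in
0-based frames. Four baseline conventions are tagged on every epoch
tensor — 0.5 s pre-stimulus (per-cell heatmaps, responsiveness), 2 s
pre-stimulus (PVC and network analyses), 1 s pre-stimulus (decoder
features), 150 ms pre-delay (anticipatory-licking traces) — and each
downstream analysis refuses tensors carrying the wrong tag.

## Responsiveness classification

Per cell and trial type, the per-trial mean stimulus-window z-scores
(no per-trial baseline: the z-score already references the session
mean) enter a two-step call: (1) a two-sided Wilcoxon signed-rank test against
zero at $\alpha = 0.05$ (per cell, uncorrected); (2) a median threshold
$|\tilde{x}| > 0.2$ z for `excited`/`inhibited`. Auditory trials are
additionally tested on the 0.3 s onset window to catch fast-adapting
cells; either window suffices. The exact signed-rank null is computed by
dynamic programming over doubled midranks, which reproduces full
$2^n$ sign-flip enumeration and stays exact under ties (20 identical
positive responses give $p = 2 \cdot 2^{-20}$); beyond 50 retained
observations a tie-corrected normal approximation with continuity
correction takes over. Zero differences are dropped.

## Functional clustering

Matched-cell trial-averaged traces (stimulus + delay) are concatenated
across phases; initial and reversal learning contribute independent
rows. PCA retains components explaining 90% of variance (a choice; the
dimensionality is not pinned down by the design), and spherical k-means
(cosine distance, k = 30, 20 restarts, best inertia kept) clusters the
rows. Empty clusters are re-seeded from distinct farthest points.

Functional subgrouping of this kind is typically finished by merging
similar clusters *by eye*; a subjective step cannot be reproduced, so
the package substitutes average-linkage
agglomeration of centroid traces by Pearson correlation with an exposed
threshold (default r > 0.8), followed by semantic labelling via
template correlation (delay ramps, stimulus boxcars; minimum r 0.5,
else `other`). Ramp-labelled cells feed the removal controls of the PVC
and network stages.

## Population-vector correlation

Per trial, the population vector is the per-cell mean response in one
epoch (stimulus or delay), from the 2 s pre-stimulus-baselined tensor;
the session summary is the mean of the strictly-upper-triangle entries
of the trial-by-trial Pearson matrix. Cells with missing data are
dropped; trial pairs with an undefined correlation (a vector constant
across cells) are excluded from the mean rather than silently zeroed.

Phase comparisons use a random-intercept linear mixed model,
`value ~ phase + (1 | mouse)`, fitted by REML. Inference uses
Satterthwaite degrees of freedom (via lmerTest) rather than a
large-sample Wald z: with eight animals the Wald approximation is
anticonservative, and the Satterthwaite correction keeps the null
rejection rate near nominal (verified at 500 null replicates in the
acceptance suite). Singular fits (zero between-mouse variance is common
in synthetic data, which plants none) still yield valid fixed-effect
inference; if the mixed fit fails outright the function falls back to
OLS and labels the result.

## Co-activity networks

The adjacency is the cells × cells Pearson matrix of within-window time
series concatenated across the filtered trials. Positive and negative
edges are analysed as separate regimes (negative edges weighted by
$|r|$). Three metrics:

* **Hubness** $H_i$: mean edge weight of node *i* to the others. A
  literal sum over all *m* nodes would include the unit self-term
  $r_{ii} = 1$; since the quantity is meant to measure correlation "to
  all the others", the default divides by $m - 1$ with the self-term
  excluded, and `include_self = TRUE` gives the literal form.
* **Geodesics** $L_{ij}$: Dijkstra all-pairs shortest paths on edge
  lengths $1/r_{ij}$ (igraph). Unreachable pairs are excluded from the
  mean and counted — consistent with reporting path lengths over a
  finite subset of pairs.
* **Triad clustering coefficient** $C_i = \frac{1}{k_i(k_i-1)}
  \sum_{j \ne k}(\hat{w}_{ij}\hat{w}_{ik}\hat{w}_{jk})^{1/3}$ with
  weights max-normalised over the whole adjacency; computed via the
  elementwise cube-root matrix cubed. For uniform weights this reduces
  to the binary clustering coefficient.

Condition contrasts are bootstrap deltas (3000 resamples, percentile
95% CIs), resampling nodes for hubness/$C_i$ and pairs for $L_{ij}$ —
the resampling unit is an explicit design choice.
Removal controls recompute all metrics after deleting a target cell set
and after 30 random same-size deletions.

## Sensory mapping

The mapping catalog enumerates 29 stimulus types (5 tone frequencies, 4
grating directions, 20 combinations) × 8 repetitions = 232 trials in
pseudo-random order. (A nominal 240-trial session would imply a 30th
stimulus type, which the enumerable catalog does not contain; the
generator uses the 29 enumerable types and leaves the count discrepancy
unexplained.) Responsiveness in mapping sessions splits the 2 s
stimulus window into halves, doubling the data points per trial before
the same two-step classifier. Tuning curves use the cells × 20 feature
layout (pre/post × multi/uni × 5 frequencies) with correlation-distance
k-means (k = 8 by default; the cluster count is a free choice exposed in
the interface). The multisensory index is
$|A_fV| / |A_f + V|$ per cell and frequency, with exclusions for
double-nonsignificant cells, sign conflicts ($A_fV\cdot(A_f+V) < 0$) and
zero denominators; 1 indicates linear integration. Pre/post
distributions are compared with a two-dimensional two-sample KS test
(Fasano-Franceschini statistic over the four quadrants at every
observed point, permutation p-value); the 2-D sample is (index value,
frequency), matching the per-frequency framing of the index.

## Decoding

Linear SVMs (cost 1, features standardised on the training fold only)
decode stimulus modality or tone frequency from stimulus-period
activity baselined to 1 s pre-stimulus and down-sampled to 3 Hz (6 bins
per 2 s window). Modality decoding equalises classes to the smallest
class before a 70/30 split (floor on the per-class test count: the
standard session gives 27 test trials); frequency decoding keeps all
200 frequency-labelled trials (140/60). Accuracies average over 50
resampled iterations.

Chance is estimated by circular permutation. Two units are
implemented because they answer different questions. Shifting the
*trial sequence* relative to the labels destroys the feature-label
correspondence while preserving session structure, and is the default
chance estimate (expected accuracy = class frequency). Rotating *time
bins within each trial* (coherently across cells) removes only temporal
coding: a time-invariant population pattern remains decodable by a
position-invariant readout, so this unit tests whether information is
carried by response timing, and its "chance" is not the class-frequency
level whenever spatial patterns differ between classes.

## Problem sizes used by the test and acceptance suites

All stochastic suites run at sizes chosen for a single CPU: the
PVC/LMM recovery suite uses 20 replicates of 8 mice × 3 sessions per
phase × 100 cells with 20-trial sessions and 3-5 s inter-trial
intervals (the planted delay-coherence contrast of 0.4 vs 0 is large,
so short sessions retain essentially full power); the network suite
uses 50 meta-repeats at 50 cells; classifier recovery uses 20
full-length (140-trial) sessions at 100 cells; decoding uses 25-cell
mapping sessions with reduced shuffle counts. The type-I calibration of
the mixed model simulates session-level summaries directly (500
replicates, between-mouse SD 0.05, residual SD 0.05). The
dissociation suites plant a class mix whose stimulus-window amplitudes
are phase-stable, so the only planted difference between naive and
expert sessions is the delay coherence; with learning-modulated
stimulus classes included, the stimulus-epoch PVC shifts for a real
reason (the stimulus-pattern signal-to-noise changes), which is the
generator working as intended but would confound the dissociation
being tested.

## Known limitations

* The manual cluster-merge surrogate is a deliberate, documented
  replacement for a subjective step; its threshold is exposed rather
  than presented as equivalent to any particular by-eye grouping.
* Between-animal variability is not modelled, so mixed-model fits on
  synthetic data are frequently singular (handled, but real data will
  exercise the random intercept more).
* The geometric ("fitcircle") pupil fit is replaced by the algebraic
  Kåsa least-squares fit; at pupil-tracking noise levels the difference
  is below reporting precision.
* Satterthwaite rather than Wald inference for the LMM, and the
  trial-sequence unit for decoder chance, are the package's own
  resolutions of underdetermined design points; both are documented
  above and switchable where meaningful.
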