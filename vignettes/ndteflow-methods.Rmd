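---
title: "Directed information flow, rich-club hubs and entrainment: methods and design choices"
author: "ndteflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed information flow, rich-club hubs and entrainment: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndteflow)
```

# The scientific problem

When the timing of a sensory event is predictable, the brain prepares for
it: reaction times shorten and large-scale cortical networks reorganize.
`ndteflow` implements an analysis pipeline for asking *where* directed
information converges during such temporal prediction. The experimental
design it targets is a cued auditory target-detection task: a 100 ms cue
tone is followed, after a cue-target interval of 1200 ms (early) or
2400 ms (late), by a target tone. One cue predicts an early target with
80% probability; the other is uninformative (50%). Comparing the two cue
conditions isolates the effect of temporal predictability.

The pipeline estimates, from epoched region-level time series, a directed
functional connectivity graph (normalized directed transfer entropy, NDTE),
tests every ordered region pair against circular-shift surrogates, detects
a *functional rich club* (FRIC) of high-inflow hub regions, runs a
spatiotemporal cluster permutation test on evoked responses, quantifies
low-frequency entrainment (Welch bandpower, Morlet intertrial phase
clustering, Hilbert phase-locking value), and correlates the strongest
inflow connections with per-participant reaction-time effects.

Because real source-localized EEG is not required to validate any of the
statistics, the package ships a first-class synthetic-data module that
simulates the full design with known ground truth, and every downstream
stage is tested against it.

# The NDTE estimator

For a source series $X$ and target series $Y$, the NDTE flow is

$$F_{X\to Y} \;=\;
  \frac{I\!\left(Y_t;\, X^{past} \mid Y^{past}\right)}
       {I\!\left(Y_t;\, X^{past}, Y^{past}\right)},$$

the information the source past adds about the one-sample future of the
target beyond the target's own past, normalized by everything the joint
past knows about that future. The normalization bounds $F$ in $[0, 1]$ and
makes flows comparable across pairs. All entropies are Gaussian,
evaluated from the empirical covariance of the lag-embedded data
($H = \tfrac{n}{2}\ln 2\pi e + \tfrac12 \ln\det\Sigma$), which is exact
for linear-Gaussian dynamics and is the assumption the synthetic VAR
generator deliberately matches.

Numerical choices:

* **Embedding.** Both pasts use the same length $T$ (the model order);
  the future horizon is one sample. $T$ is estimated as the rounded mean,
  over regions, trials, conditions and participants, of the first local
  minimum of the sample autocorrelation function (first $\tau$ with
  $\mathrm{ACF}(\tau) < \mathrm{ACF}(\tau+1)$), with a $1/e$-crossing
  fallback when no local minimum occurs before `maxLag`. The ACF uses the
  unbiased $1/(n-\tau)$ normalization so the triangular taper of the
  biased estimator does not shift minima of oscillatory signals. Even so,
  the sample ACF of a finite windowed oscillation is not exactly its
  population ACF, so first-minimum estimates can sit one sample off the
  idealized value; tests allow that.
* **Covariance.** Per trial, over time, with $1/n$ normalization; a
  relative jitter of $10^{-10}\times\overline{\mathrm{diag}}$ is added
  before Cholesky factorization because 400-sample windows are short.
* **Degeneracy.** If the denominator falls below $10^{-12}$ (e.g. a
  white-noise target), $F$ is defined as 0; the ratio is clipped to
  $[0,1]$.
* **Units.** Natural logarithms throughout; the normalization cancels the
  unit.

# Surrogate inference

Directed flows have no analytic null here, so each ordered pair in each
trial is compared against `nSurrogates` recomputations in which the
*source* series is circularly rotated by a random offset in $[L/4, 3L/4]$.
Rotating the source preserves both marginal spectra exactly while
destroying cross-signal alignment, and leaves the target's future
untouched; offsets are kept away from $0$ and $L$ so surrogates are never
near-identical. Per-trial p-values use the add-one permutation rule
$p = (1 + \#\{F^{surr} \ge F\})/(n_{surr}+1)$, which can never be zero.

P-values are aggregated with Stouffer's method (one-sided: strong flow
means small $p$), first across trials within a participant, then across
participants, and a single Benjamini–Hochberg mask at level $q$ over all
$R(R-1)$ ordered pairs is shared by all participants — post-cue and
post-target analyses are masked separately. Flows are standardized per
trial against their own surrogate distribution,
$z = (F - \mu_{surr})/\sigma_{surr}$, retained on masked pairs, averaged
over trials and then participants. Aggregated p-values of exactly 1 (an
observed flow below every surrogate) are clipped to $1-10^{-15}$ before
the normal-quantile transform, with a warning; this makes the null
slightly conservative, which is the safe direction for a mask.

# Functional rich-club detection

With the package's orientation (entry $[i,j]$ = flow from $j$ into $i$),
a region's total inflow is its row sum. Regions are ranked by inflow and
nested prefix clubs are scored by the FRIC value: within-club flow, plus
inflow from non-members, minus outflow to non-members. For club size $k$,
surrogate clubs keep the first $k-1$ members and swap the $k$-th for a
random non-member; the Monte-Carlo p-value is again add-one. Because a
surrogate's value depends only on which member is drawn, candidate values
are precomputed and the 100,000-draw default costs almost nothing.

Two design points deserve emphasis:

* **Largest significant club.** The detector tests every size
  $k = 2,\dots,R-1$ and returns the *largest* prefix whose value is
  significantly larger than its surrogates. Stopping at the first
  non-significant size instead would make detection of an exchangeable
  planted club impossible: at $k=2$ the surrogate pool still contains the
  remaining planted members, whose clubs tie the observed value, so the
  $k=2$ test is not expected to pass even when a genuine 3-region club
  exists and is cleanly significant at $k=3$. All tested sizes and their
  p-values are reported so the growth path can be audited.
* **Calibration caveat.** The observed club at size $k$ is *selected* as
  the top-$k$ by inflow, and inflow correlates with the FRIC value. On
  unstructured (i.i.d.) matrices this selection makes the surrogate
  comparison anti-conservative — simulation shows far more than
  $\alpha$ "significant" first sizes under an i.i.d. null. The test is a
  detection heuristic for strongly structured matrices, not a calibrated
  null test on arbitrary ones. This is also why the synthetic club
  generator plants *exact* weight ties by default (`jitterScale = 0`):
  entry-level noise in an exchangeable structure is read by the
  comparison as genuine heterogeneity. Ranking ties are broken
  deterministically by label order and recorded.

# Cluster permutation, entrainment, behavior

The ERP comparison is the standard paired cluster permutation test:
elementwise paired $t$ maps over channels × time, a cluster-forming
threshold at the two-sided $t$ quantile for $p=0.05$ (the threshold is a
tuning parameter of sensitivity, not the error rate), clusters connected
through channel adjacency at a common time sample or temporal contiguity
on a channel, cluster mass = sum of $t$, and a max-|mass| sign-flip null
with add-one p-values — the family-wise error is controlled by the
maximum statistic regardless of the threshold choice. Channels with fewer
layout neighbors than `minNeighbors` are excluded from cluster formation.
Spatial adjacency is built from channel coordinates with a distance
threshold chosen so the median neighborhood has at least four channels.

Entrainment measures follow their textbook definitions. Welch bandpower
uses Hann segments with 50% overlap; a nominal 0.12 Hz bin spacing on a
~1.2 s window exceeds the true spectral resolution, so it is implemented
as zero-padded bin spacing with the segment length equal to the available
window, and documented as such. PSD scaling satisfies Parseval (integral
= variance), and band power is baseline-normalized per channel. ITPC
convolves complex Morlet wavelets (7 cycles by default, log-spaced center
frequencies) and reports $|\,\overline{e^{i\phi}}\,|$ across trials;
samples within 3 wavelet SDs of an epoch edge are set to `NA`. PLV uses
FFT-based analytic-signal phases after band-pass filtering (0.85–4 Hz
default, matching the 1.2 s post-cue window); 10% of samples at each
epoch edge are discarded before averaging because the finite-window
analytic signal is unreliable there. Scalar condition contrasts use
paired sign-flip permutation tests (exact enumeration when
$n_{perm} \ge 2^n - 1$). Filtering everywhere is zero-phase FIR
(Hamming-window design, forward–backward application) with odd-reflection
padding; the default order is three cycles of the lowest cutoff period,
capped by the data length.

The behavior link takes, per participant, the mean reaction-time
difference (non-predictive minus predictive, responses slower than
1000 ms excluded), extracts the `k` strongest masked inflow connections
(ties broken by target then source label), and correlates each
connection's per-participant trial-mean $z$ with the RT differences
(Pearson, two-sided $t$ p-values, BH-corrected per analysis window). The
per-subject connection summary is the trial-averaged standardized flow —
the only per-subject quantity the inference stage defines.

# The synthetic-data generator

The generator emulates the statistical skeleton of the study, not its
electrophysiology:

* **Design.** Two conditions × 3 blocks × 50 trials per participant by
  default (300 target trials, 150 per condition), early-target
  probabilities 0.8/0.5, 100 ms cue, cue-target intervals of 1200/2400 ms
  measured cue offset to target onset (the only reading under which a
  100–500 ms post-target window sits 1400–1800 ms after cue onset), ITI
  uniform in 200–1000 ms.
* **Signals.** Stationary vector-autoregressive networks (companion
  spectral radius checked < 1, with a 100-sample burn-in) with Gaussian
  innovations — deliberately matched to NDTE's Gaussian-entropy
  estimator, so estimator bias and model mismatch are separated. The
  condition effect is a *coupling* change confined to a configurable
  window in predictive-condition trials, because a directed-flow
  difference is exactly what NDTE on difference waveforms is meant to
  detect; amplitude effects are deliberately not modeled.
* **Reaction times.** Participant offset (between-SD 20 ms) + condition
  mean (330 ms predictive / 360 ms non-predictive) + trial noise
  (within-SD 40 ms), truncated at 50 ms rather than resampled (the
  truncated mass is negligible at these parameters). The defaults give a
  paired condition effect of realistic size for this kind of task.
* **What is not emulated.** No volume conduction or electrode mixing, no
  1/f background, no artifacts beyond what the amplitude-rejection test
  constructs for itself, no forward/inverse modeling. Passing tests
  therefore demonstrate that the *statistics* behave as specified on data
  satisfying their assumptions — not that source-localized EEG satisfies
  those assumptions.

Difference waveforms are built by seeded random pairing of the two
condition's epochs (each trial used at most once, counts equalized first
by seeded subsampling of the larger condition), with the sign fixed as
non-predictive minus predictive. Windows are half-open $[start, end)$ on
the sample grid, so a 900–1300 ms window at 1 kHz holds exactly 400
samples, and the matching high-pass cutoff is $1/0.4\,\mathrm{s} =
2.5$ Hz. Amplitude rejection reads "amplitude change" as per-region
peak-to-peak within the epoch (the joint-across-regions reading is
available via `perRegion = FALSE`).

# Problem sizes and reproducibility

Every random stage takes an explicit seed, and the end-to-end driver
(`runAll`) derives all stage seeds from one master seed, writing a
manifest from which any artifact can be regenerated. Desk-scale defaults
(8 regions, 10 participants, 20 trials per condition, 50 surrogates,
1000 Monte-Carlo club draws, 500 permutations) keep a full run in the
tens of seconds; the study-scale values (62 regions, 100 surrogates,
1000 permutations, 100,000 Monte-Carlo draws) are plain config entries.
The validation suite uses: 100 detection runs for club recovery; 10
participants × 20 trials × 50 surrogates for directed-effect recovery;
500 null datasets (5 channels × 20 samples × 10 participants, 300
permutations) for cluster family-wise calibration — at least 10
participants are needed here because max-|mass| is invariant to a global
sign flip, so the effective sign-flip space is $2^{n-1}$ and with very
few participants the attainable family-wise level is quantized well
below 5%; 500 null pair-trials
for surrogate-p uniformity; and 20 null datasets for the FDR mask. These
sizes are the package's chosen validation scale: large enough that the
binomial noise of each rate sits well inside the asserted bounds.

# Known limitations

* Gaussian entropies are exact only for linear-Gaussian dynamics;
  nonlinear coupling is seen only through its second-order footprint. No
  binned or nearest-neighbor entropy estimators are provided.
* The FRIC surrogate comparison is anti-conservative on unstructured
  matrices (see above); interpret detected clubs on real data as ranked
  structure, not calibrated inference.
* One-sample future horizon; spectrally resolved transfer entropy is out
  of scope.
* The wrapped-Gaussian phase model gives
  $\mathrm{ITPC} \to e^{-\sigma^2/2}$ for phase-jitter SD $\sigma$; the
  ITPC estimator has the usual positive small-sample bias, so
  comparisons should keep trial counts equal (the pipeline equalizes
  them anyway).
* Very low wavelet frequencies on short epochs are entirely edge — after
  3-SD trimming nothing remains; choose `fMin` against the epoch length.
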