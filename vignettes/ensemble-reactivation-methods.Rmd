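---
title: "Decoding and reactivation analysis of event-aligned CA1 ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and reactivation analysis of event-aligned CA1 ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reverb)
library(dplyr)
```

# The analysis problem

Brief, startling episodic events — a loud sound, an air blow, an elevator
drop, a cage shake — evoke transient firing-rate changes in hippocampal CA1
ensembles. `reverb` implements the analysis chain used to characterize such
recordings: normalize per-unit responses, assign a unit taxonomy
(responsive / selectivity / intensity dependence), classify the ensemble
pattern of each event with a regularized multi-class discriminant model,
scan the rest of the recording for spontaneous reduced-amplitude
re-expressions of those patterns ("reactivations"), and corroborate the
reactivations with pairwise-correlation and explained-variance statistics.
Because such data sets are rarely public, the package ships a spike-train
generator that reproduces the population structure these analyses assume, so
every stage can be validated against ground truth.

# Response normalization and the unit taxonomy

Event responses are measured as firing frequencies in two 500-ms bins
immediately after each event onset (all windows are half-open,
`[start, end)`, times in seconds). Per unit and event type the mean
event-window rate $f_{\text{startle}}$ is compared with the unit baseline
$f_0$ (mean rate outside the 3 s after every event) through

$$R = \frac{f_{\text{startle}} - f_0}{g_0 + f_0},\qquad T = \log(1 + R),$$

with $g_0$ the population-average baseline. The denominator makes the score
proportional to the *absolute* rate change for low-baseline units
($f_0 \ll g_0$) and to the *relative* change for high-baseline units; the
natural logarithm compresses large increases. $T$ is undefined for
$R \le -1$, which cannot occur for nonnegative rates.

A unit counts as responsive to a type when $|T| \ge 0.2$ *and* its
per-trial event rates differ from matched 1-s pre-event baselines in a
two-sample Wilcoxon test at $\alpha = 0.05$. Analyses of this kind often leave the exact cutoff unstated; the combined
rule fixes both a
practical effect-size floor and a false-positive rate (about 5% per unit
across four types, concentrated in the two non-parametric types where only
7 trials are available). Selectivity is then the count of qualifying types:
general (all four), subgeneral (two or three), specific (one).

Intensity dependence is assessed on the unit's most responsive parametric
type (drop heights 5/13/30 cm; air-blow durations 200/400/800 ms) by the
least-squares slope of per-trial rate on intensity rank, with a
1000-permutation p-value at $\alpha = 0.05$: a significant positive slope is
`sensitive-up`, negative `sensitive-down`, otherwise `invariant`. The
permutation test was chosen because trial counts are small (7 per level) and
the trial-rate distribution is strongly non-Gaussian at low baselines.

Putative cell classes use rate thresholds (< 5 Hz pyramidal, > 8 Hz
interneuron, else unknown, minimum 100 spikes) — the waveform information
that usually supports this split is not part of the package's inputs. The
complex spike index is the percentage of spikes with a 2–15 ms first-lag
inter-spike interval whose second spike has smaller amplitude.

# Hierarchical clustering of response profiles

`cluster_responses()` agglomerates per-unit $T$-vectors with Euclidean
distance and *recomputed-mean* (centroid) linkage, merging the two closest
clusters at each step; ties take the lexicographically smallest pair of
cluster ids, making the sequence deterministic. Centroid linkage can invert
merge heights; no monotonicity is asserted. For display,
`order_leaves()` orients the two subtrees at every merge so that the
adjacent boundary leaves are closest, a best-matching-endpoints rule that
sorts well-separated one-dimensional data. Clustering operates on all
responsive units; the heatmap convention keeps only positively responding
units.

# Regularized multiple discriminant analysis

Each event contributes one pattern vector: the concatenation of every
unit's two 500-ms bin rates ($2N_u$ features — concatenation rather than
averaging retains the transient structure of the response). Rest patterns
are drawn from randomly placed baseline windows of the same width. With
class means $m_i$, global mean $m$ and class sizes $n_i$,

$$S_B = \sum_i n_i (m_i - m)(m_i - m)^t, \qquad
  S_W = \sum_i \sum_{x \in D_i} (x - m_i)(x - m_i)^t.$$

Because units far outnumber trials, $S_W$ is singular; each class
covariance $\Omega_i = S_{W,i}/n_i$ is shrunk,
$\Omega_i' = (1-\lambda)\,\Omega_i + \lambda\, c_i I$ with
$\lambda \in [0,1]$, and $S_W' = \sum_i n_i \Omega_i'$ (this weighting
reproduces $S_W$ exactly at $\lambda = 0$). By default the identity is
scaled by $c_i$, the mean diagonal of $\Omega_i$, so that shrinkage is
unit-aware when rates span orders of magnitude; `shrink_scale = "identity"`
gives the plain-identity variant. The discriminant basis consists of the
top eigenvectors of $S_W'^{-1} S_B$ — at most $N-1$ for $N$ classes,
limited by the rank of $S_B$ — solved in symmetrized form through the
Cholesky factor of $S_W'$; the contract (tested) is agreement with the
naive dense decomposition to $10^{-8}$ relative. $\lambda$ can be chosen by
cross-validated grid search (`select_lambda()`, smallest-$\lambda$ tie
rule); the default 0.5 is a robust mid-grid value for the rank-deficient
regimes the package targets.

Classes are modelled as Gaussians in the subspace (covariances shrunk the
same way), classification is by smallest Mahalanobis distance with ties to
the lowest class index, and cross-validation repeatedly holds out one
sample per class. Cluster separations are summarized as the Mahalanobis
distance of each class centroid from the rest centroid under the
rest-cluster covariance — "distance in rest SDs".

# Sliding-window trajectories and reactivation detection

`sliding_projection()` projects the two-bin rate vector at every 10-ms step
with the fitted basis; the window covering `[t, t+0.5)` and `[t+0.5, t+1)`
is stamped `t` (window alignment is a convention; no look-ahead beyond
`t + 1` is tested as an invariant). Each sample carries its Mahalanobis
distance from the rest centroid and a *coverage-calibrated* score
$(D - \mu_D)/\sigma_D$, where $\mu_D, \sigma_D$ describe the null
distribution of that distance. Two calibration details matter:

* The training rest samples understate the null — the basis itself was
  fitted on them — so `calibrate_rest()` re-estimates $\mu_D, \sigma_D$
  from freshly drawn baseline windows (with a leave-one-out fallback inside
  `fit_mda()`). Without this, a nominal 2-SD boundary excludes ~20% of
  genuine baseline samples.
* The boundary is defined on the distance scale, not as the Mahalanobis
  contour $D = 2$: in a $d$-dimensional subspace baseline distances
  concentrate around $\sqrt{d}$, so the raw contour would misclassify most
  baseline activity for $d \ge 4$. With the calibrated score, stationary
  baseline activity falls below 2 about 97% of the time, matching the
  intuition of a "2σ rest ellipsoid".

`detect_reactivations()` flags epochs with score $\ge \theta$ (default 2)
for at least 50 ms outside the event windows, merging gaps under 100 ms.
Each epoch is assigned the nearest *approached* non-rest class — among the
classes whose distance decreased from the start of the epoch to its peak,
the one nearest at the peak; epochs approaching no class are discarded.
(Assigning the globally nearest class instead rejects many genuine
reactivations in crowded subspaces, where a weakly separated foreign
cluster can sit marginally closer than the approached one.)

A caveat the detector cannot remove: the two-bin window decorrelates in
about one second, so an hour-long scan contains thousands of effectively
independent baseline samples, and a 2-SD threshold necessarily yields on
the order of one threshold excursion per minute from noise alone. Duration
and directionality filters thin these excursions but cannot push the false
rate much below that order of magnitude at $\theta = 2$; analyses that need
clean reactivation windows should either raise $\theta$ or, in simulation
studies, use the injected ground-truth times (as the package's own
validation does for the subpopulation and correlation statistics below).

Subpopulation analyses (`subpopulation_projection()`) refit the model on
the intensity-invariant or intensity-sensitive responsive units only and
compare reactivation-window peak distances against *matched baseline
windows of the same length* (`reactivation_magnitude_stats()`,
Mann–Whitney): maxima grow with window length, so single-sample baselines
would overstate significance.

# Shuffle controls

Two nulls are implemented. The *unit-identity* shuffle permutes which unit
owns which spike train: the global form (whole trains, one permutation)
preserves the population rate function exactly and is the right input for a
*previously fitted* model, but a single global permutation is merely a
column relabeling for a freshly fitted classifier — cross-validated accuracy
is provably unchanged. Demonstrating classification collapse therefore
requires the per-window form (`windows =` argument; an independent
permutation inside each analysis window) or its pattern-space equivalent
`shuffle_pattern_units()`. The collapse benchmark additionally uses
zero-sum, equal-norm class means (`simulate_labelled_patterns()`), because
classes that differ in summed population rate stay partly separable under
any unit shuffle — with matched sums, shuffled accuracy is chance by
symmetry.

The *temporal* shuffle permutes 10-ms bins of each unit's spikes within a
4-s window around a reactivation (50-ms bins available via `bin =`; both
binnings are in circulation for this control). It conserves each unit's
window rate exactly while destroying the within-window coincidence
structure, returning the projected trajectory to the rest cluster.

# Correlations and explained variance

`pair_correlations()` bins each unit's activity at 50 ms inside equal-length
repetition windows, concatenates the per-repetition frequency vectors, and
computes Pearson correlations for all pairs (a per-repetition-averaged
variant sits behind `per_repetition = TRUE`). Zero-variance vectors yield
flagged `NA`s. Pairs can be thresholded on their non-basal `|r|`
(`filter_pairs()`, conventional thresholds 0.05 and 0.1) and displayed as
the top 10/20/30 pairs of the specific/subgeneral/general groups
(`select_top_pairs()`).

Period comparisons use pre-event baselines, 1-s event windows, ±2-s windows
around reactivations, and matched post-event non-reactivation controls
(`make_period_windows()`). One statistical choice deserves emphasis: the
periods contain very different numbers of bins, and the null width of a
Pearson coefficient scales as $1/\sqrt{n_{\text{bins}}}$, so comparing raw
`|r|` across periods confounds signal with sample size.
`period_correlation_stats()` therefore tests Fisher-z standardized
magnitudes $|\mathrm{atanh}\,r|\sqrt{n_{\text{bins}}-3}$ (paired one-sided
Wilcoxon vs the basal period) while still reporting mean `|r|`
descriptively.

Explained variance is the squared partial correlation

$$\mathrm{EV} = \left(
  \frac{r_{\text{ep,post}} - r_{\text{ep,pre}}\; r_{\text{pre,post}}}
       {\sqrt{(1-r_{\text{ep,pre}}^2)(1-r_{\text{pre,post}}^2)}}\right)^2
  \in [0, 1],$$

computed across pairs between the period-wise correlation vectors; the
reversed control swaps the roles of pre and post and should stay near zero
when the post-period similarity is genuinely event-derived.

# The synthetic-data generator

`simulation_config()` fixes the study conditions; they are defaults, not
dials. Four event types are delivered in one session per (type, intensity),
seven repetitions each, at randomized 1–3 min intervals. 36% of units are
responsive, split 1:1 invariant:sensitive, with selectivity fractions
54/26/20% (invariant) and 45/25/30% (sensitive) across
general/subgeneral/specific. Rates follow a piecewise-constant
inhomogeneous Poisson model — the simplest model consistent with 500-ms-bin
analyses — with pyramidal baselines 0.2–3 Hz (85% of units) and interneuron
baselines 8–30 Hz. Event windows last 1 s (the two analysis bins).
Additive gains are 8 Hz for invariant units at every level and 4/8/16 Hz
(the 1:2:4 ratio) for sensitive-up units; sensitive-down units (20% of
sensitive) are suppressed to 50/25/5% of baseline. Additive gains in Hz
rather than baseline multiples keep low-baseline pyramidal responses
detectable at 7 trials — the "strong effect" regime the recovery benchmarks
assume. A shared log-normal per-trial gain jitter within each selectivity
group (sd 0.35/0.25/0.15) creates the event-period co-variability the
correlation analyses measure.

Reactivations are injected 5–120 s after each event (1–3 per event, uniform; reactivation timing in vivo is only loosely
characterized, on the order of seconds to minutes), lasting
1 s, at amplitude 0.4 of the event gain. Participation follows a shared
Bernoulli gate per (injection, selectivity group) with probabilities
0.9/0.65/0.45 and amplitude weights 1/0.7/0.45 for
general/subgeneral/specific invariant units; sensitive units join with
per-unit probability 0.02 — "near zero", so that the modulated subspace
shows no statistically resolvable reactivation, as the analyses assume. The gate probabilities and weights were chosen
together so that (a) the general clique participates near-obligately,
making injected reactivations reliably expressed, and (b) the pair-level
shared variance $w_g^2\,p_g(1-p_g)$ times the probability that both pair
members respond to the reactivated type (≈ 1/0.39/0.25 for
general/subgeneral/specific pairs) stays ordered
general (0.090) > subgeneral (0.043) > specific (0.013) — the ordering the
correlation analyses are designed to resolve. Category counts follow
largest-remainder rounding, so configured fractions are met exactly; all
randomness is seeded and reproducible.

What the generator does *not* emulate: burst/theta ISI structure beyond
Poisson, slow non-stationarities of baseline rate, waveform or LFP signals,
place or locomotion covariates, and temporally ordered (sequential) replay.
Passing recovery benchmarks on this generator therefore demonstrates the
correctness and calibration of the estimators under the stated rate model,
not robustness to every structure present in vivo.

# Problem sizes and numerical choices

The recovery benchmarks use 500 units for the taxonomy (one session set),
150 units (a typical per-animal population) over 100 seeded runs for
the monotone intensity trend, and 280
units (≈ 50 invariant) over 20 seeded runs for the reactivation and
correlation studies; classifier benchmarks use 5 Gaussian classes at
6σ separation with 12 samples per class. Tolerances: eigensolver agreement
$10^{-8}$ relative; generalized-eigenpair residuals $10^{-6}$ relative;
distances and scores are plain double precision. Degenerate inputs are
errors with typed conditions (`reverb_invalid_config`, `reverb_bad_input`,
`reverb_range_error`, ...), not silent fallbacks; ties everywhere break
deterministically (lowest index / smallest value), so fixed seeds give
byte-identical outputs.

# Known limitations

* At the default detection threshold ($\theta = 2$) the false-alarm rate is
  noise-floor-limited to roughly one excursion per minute, as derived
  above; treat the detector's output as candidate epochs, not a final
  catalogue.
* The pyramidal/interneuron split by rate alone mislabels fast-firing
  pyramidal cells and quiet interneurons; it is a stand-in for
  waveform-based sorting information the package does not ingest.
* Subgeneral/specific correlation ordering rests on small absolute
  correlation values (|r| of order 0.01 at 50-ms bins); resolving it needs
  the full pair count of a ~50-unit invariant population and many
  reactivation windows.
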