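---
title: "Characterizing neuron and ion-channel models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing neuron and ion-channel models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neurochar)
```

Model databases accumulate hundreds to thousands of published neuron and
ion-channel models, written against heterogeneous conventions and rarely
accompanied by comparable measurements. `neurochar` implements a
characterization pipeline that makes such collections comparable: a standard
current-clamp protocol battery, a fixed 42-property electrophysiology feature
set, a variable-timestep computational-complexity estimate, nested
dimensionality-reduction/clustering of cell models, likelihood-based scoring
and clustering of channel voltage-clamp responses, and the integration of
somatic conductance densities into normalized channel densities (NCDs) that
link channel clusters to cell-model clusters. Because published model
databases cannot be redistributed, the package ships a synthetic-data
generator with exact ground truth for every stage; the test suite exercises
the pipeline end to end on that synthetic data.

Units are fixed throughout: milliseconds, nanoamps, millivolts, conductance
densities in mS/cm². Stimulus intervals are half-open, `[onset, onset +
duration)`.

## Stimulus protocols

`build_protocol()` samples the six current-clamp stimulus kinds used for
characterization: `square` and `long_square` steps, a `ramp` whose slope is
expressed in rheobase units per second, `pink_noise` (1/f-spectrum noise,
spectrally shaped from seeded white noise), a brief `short_square` pulse and
`short_square_triple` (three pulses spaced at `1000 / frequency` ms). The
exact pulse widths of the short-square variants are not standardized across
laboratories; the defaults here (2 ms pulses at twice rheobase, nine pulse
frequencies evenly spaced on 29–143 Hz) are configuration, not science, and
every consumer takes them as arguments.

The computational-complexity benchmark uses a 13-amplitude series
(`complexity_current_series()`): 0 nA, the largest known sub-rheobase
current, and 11 evenly spaced amplitudes spanning rheobase to 1.5× rheobase
inclusive. The sub-rheobase entry is defined as the lower bracket left by
the rheobase bisection — the highest current actually probed that produced
no spike.

## Electrophysiology features

Spike detection is an upward crossing of a fixed voltage threshold (default
0 mV) with 2 ms refractory merging. Traces whose median potential is at or
above that threshold — abstract integrate-and-fire-style models that rest at
0 mV — fall back to a derivative detector (default 20 mV/ms), since a level
threshold cannot be meaningful there.

Rheobase is found by bracketed bisection on 1 s square pulses (geometric
scan upward for the first spiking amplitude, then bisection to 1% relative
tolerance, at most 30 iterations). Models that spike with no stimulation are
flagged *non-positive rheobase* and excluded from rheobase-relative
protocols; models that never spike up to the configured maximum current are
an error.

The feature vector has exactly 42 entries: 19 action-potential and
spike-train measures evaluated at both 1.5× ("normal") and 3.0× ("strong")
rheobase square injections — spike count, first/second spike latencies,
firing rate, ISI mean/median/CV/first/last, steady-state and per-interval
accommodation, first/second/mean spike amplitude, amplitude adaptation,
first/mean half-width, mean after-hyperpolarization depth, and an
early/late adaptation index — plus four properties: the resting
action-potential count, the time to the first spike under a 1 rheobase/s
ramp, and the two inflection frequencies of a bi-sigmoidal ("hat") fit to
triple-pulse spike counts (the pass-above and pass-below frequency-filter
parameters). Steady-state accommodation is defined as the percent change of
the mean ISI among intervals ending in the last 25% of the stimulus window
relative to the first ISI; this window is an interpretation we fixed once
and document here. Anything that cannot be computed (a second spike that
never happened, a flat frequency profile) is `NA` — flagged missing, never
silently zero.

The hat fit uses a product of two opposed logistic sigmoids with a shared
slope, fitted by Levenberg–Marquardt least squares with box constraints and
data-driven starts; a fit whose inflections come out unordered is treated
as not converged.

### Preparing features for clustering

The order is fill → bi-symmetric log → z-score, and it matters: fills must
happen on the raw scale, and z-scores must summarize the transformed values.
Missing entries are filled per feature by a declared policy table
(`default_fill_policies()`): latency-like features fill with the observed
column maximum (an unobserved spike is later than any observed one),
count-like features with the column minimum, everything else with the
cross-model mean. We use observed column extrema rather than theoretical
bounds because the feature set has no natural a-priori ranges.

The bi-symmetric log transform is `sign(x) * log10(1 + |x|/C)` — odd, smooth
through zero, logarithmic in the tails. The default `C = 1/ln 10` makes the
slope at the origin exactly 1, so values in (−1, 1) are left essentially
untouched; `C` is configurable. Z-scoring uses the population (1/n)
standard deviation; zero-variance columns map to zero with a warning.

## Variable-timestep complexity

Variable-step integrators take a baseline number of steps per simulated
second plus a roughly constant number of extra steps per action potential.
The package fits

    steps/sec = steps_base + steps_AP * APs

by ordinary least squares over the 13-current step-count table (all rows,
unweighted; a negative slope is clamped to zero with a warning). Absolute
complexity at a target rate of 10 APs/s is

    omega_abs = (steps_base + steps_AP * 10) * runtime_step

where `runtime_step` — mean wall-clock seconds per integration step — is an
*input measurement*, not something this package computes, so estimates stay
hardware-explicit. Relative complexity divides a model's `omega_abs` by a
reference model's; the reference therefore sits at exactly 1, and the ratio
is invariant to a shared `runtime_step`. The fixed 10 APs/s target is a
simplifying assumption: models whose step cost is strongly rate-dependent
are summarized by a single operating point.

## Nested cell-model clustering

The standardized feature matrix is reduced by PCA retaining the smallest
number of components that explain 95% of variance. Clustering is nested and
three levels deep:

1. density clustering (HDBSCAN, minimum cluster size 10) on the PCA scores
   of all models;
2. a **fresh** PCA and density clustering restricted to the designated
   level-1 cluster (by default the largest; an override selects by label);
3. a fresh PCA and K-means on the designated level-2 cluster, with the
   cluster count chosen by the largest mean silhouette over k = 2–10
   (seeded initialization, multiple restarts).

PCA is refit at every level deliberately: within-subset variation is
invisible in the parent's retained components whenever the parent scale
dominates, and the test suite asserts that subset scores are not slices of
parent scores. Points HDBSCAN flags as noise are reassigned to the cluster
whose geometric center (arithmetic mean of member scores) is nearest in
Euclidean distance, ties to the lowest cluster index; after reassignment
every model carries a leaf label. Recursion stops early when a level finds
one cluster.

No HDBSCAN implementation exists in this package's R dependency set, so
`hdbscan()` is implemented here from the standard construction: core
distances (distance to the `min_samples`-th neighbor, the point itself
counted first), the mutual-reachability minimum spanning tree, the
single-linkage hierarchy, the condensed tree at the minimum cluster size,
and excess-of-mass cluster selection. Two defaults deserve note:
`min_samples = min_cluster_size` (the conventional default), and
`allow_single_cluster = TRUE`, so a dataset whose hierarchy never truly
splits comes back as one cluster with no noise rather than all noise. A
dataset smaller than the minimum cluster size is all noise by definition.

Interpretive cluster names (e.g. a non-positive-rheobase group) are attached
by an explicit rule table (`attach_cluster_labels()`), never learned —
naming clusters is a post-hoc act.

## Channel-model scoring and clustering

Voltage-clamp responses under three protocols (activation, deactivation,
inactivation) are condensed per protocol: each voltage step's current trace
is linearly resampled onto a fixed grid (default 512 points per step), the
steps are concatenated in ascending step-voltage order, and each model's
vector is normalized by its maximum absolute value so the representation
carries kinetic shape, not magnitude. The grid makes condensation invariant
to the original sampling rate.

For each protocol a probabilistic-PCA model is fitted to the condensed
matrix at 99% explained variance, and every model is scored by its marginal
log-likelihood under that fit; the three scores form the model's channel
family score. Two numerical choices matter in the samples ≪ dimensions
regime: the residual variance is the mean of the discarded *observed*
(nonzero) eigenvalues — averaging over all discarded dimensions would drive
it to zero and make the likelihood degenerate — and residuals are computed
by direct reconstruction rather than by subtracting squared norms, which
cancels catastrophically for near-duplicate models.

The score matrix is reduced by a second PCA (99%), clustered by Ward-linkage
agglomerative clustering, and cut with an adaptive tree cut in which
singletons are allowed: a merge is cut when its height exceeds `cut_ratio`
(default 3) times the tallest internal merge height of its child subtrees,
floored at the median merge height (a leaf child has no internal scale) and
at a numeric-noise floor of 10⁻⁶ of the tallest merge; any subtree
containing a cut is implicitly split. The default ratio was chosen by
validating the cut on canonical scenarios — a single Gaussian cloud must
stay whole, two well-separated groups must split, a far outlier may become
a singleton, identical data must stay one cluster — before the planted-data
tests were written.

A property of this scoring worth understanding: the log-likelihood is a
*typicality* coordinate. For archetypes whose members carry independent
kinetic jitter, the within-archetype spread of the score is a whitened
chi-square whose scale does not shrink with the jitter, so the score cannot
resolve archetypes of jittered models. It resolves sub-types that exist as
groups of (near-)exact duplicates with distinct prevalences — which is how
sub-types actually arise in model databases, through reuse of published
channel models. The synthetic archetype generator therefore populates
archetypes with exact copies and distinct member counts by default
(`jitter_mv = 0`); jitter is available, but recovering jittered archetypes
is explicitly outside what this method can promise.

## Normalized channel densities

`parse_somatic_densities()` reads the `channelDensity` elements of
NeuroML-subset XML. "Somatic" means the element's segment group matches a
configurable pattern (default: any group name containing "soma") — the
matching rule is ours, since naming conventions vary across models.
Recognized units are S/cm², mS/cm² and S/m², all converted to mS/cm². A
channel requested but absent from a file is exactly zero; several somatic
elements for one channel are averaged without area weighting (area
information is not part of the density elements; an area-weighted mean is
the natural alternative where morphologies are available).

Each channel column is divided by its maximum across cells (all-zero
columns are left alone), mapping densities onto [0, 1] while preserving
each column's relative structure. Scaled densities of co-clustered channels
are then summed per cell, giving the NCD matrix: cells × channel clusters,
non-negative, unitless. Per cell-cluster summaries are means with seeded
percentile-bootstrap 95% confidence intervals (default 10,000 resamples of
cells with replacement). A |z| < 3 inlier filter is available for plotting
low-dimensional property spaces; it never touches the summary statistics.

## The synthetic-data generator

The generator exists so that every stage has inputs with exact ground
truth:

* **Voltage responses** are phenomenological: stylized action potentials
  (instantaneous rise, linear fall over twice the half-width, a linear AHP
  notch) are inserted at analytically computed spike times on top of a
  passive response, plus optional Gaussian noise. The first spike under a
  square stimulus of amplitude I occurs at `delay * (1.5 * rheobase / I)`
  after onset; intervals follow `isi_base * (1.5 * rheobase / I) *
  accommodation_rate^k`. The 1.5× point is the reference because the
  feature battery measures there. Ramp responses spike when the
  instantaneous current reaches rheobase; pulse triples trigger per-pulse
  spikes, with an optional frequency band outside which only the first
  pulse fires (a band-pass cell). Intrinsic spikers fire regardless of
  stimulus.
* **Step-count tables** are exactly linear, optionally with Poisson
  counting noise around the linear mean.
* **Channel responses** follow closed-form first-order Boltzmann gating
  (piecewise-exponential relaxation under piecewise-constant commands),
  with per-family default kinetics for Kv, Nav, Cav, KCa and Ih.
* **Conductance files** are NeuroML-subset XML with somatic and optional
  dendritic density elements; absent channels are genuinely absent from the
  file.
* **Planted clustering inputs**: flat Gaussian mixtures with a controlled
  center separation, and a three-level 4 → 2 → 6 hierarchy in which each
  level's separation lives in its own feature subspace at geometrically
  decreasing variance scales, so a 95%-variance PCA at each level sees only
  that level's structure — our model of how nested structure appears in
  heterogeneous feature data, fixed once in the generator defaults.

What the generator does **not** emulate: conductance-based spike dynamics
(no depolarization block, no bursting), measurement artifacts, correlated
feature noise, and the long-tailed feature distributions of real model
collections. Passing tests therefore demonstrate that the pipeline's
machinery is correct and recovers planted structure under the stated
conditions; they do not certify cluster counts or effect sizes on any real
database.

## Problem sizes and determinism

The shipped tests run the nested clustering on 480–600-point hierarchies
(10 seeds), channel characterization on 15–27-model families (10 seeds),
100 Poisson step tables, and 10,000-resample bootstraps — sizes chosen so
the whole suite completes in a few minutes on one CPU while keeping every
statistical check meaningful. All randomness flows through explicit integer
seeds (`withr::with_seed`); there is no global random state, and
`run_pipeline()` writes a JSON manifest (config snapshot, seeds, output
hashes) with byte-identical tables across reruns of the same config.

## Known limitations

* The 19-property Druckmann-style set is this package's fixed
  interpretation of the classic interneuron measure catalogue; published
  variants differ in windowing details.
* The complexity summary assumes one operating point (10 APs/s) and a
  linear steps-vs-spikes relationship.
* The likelihood-based channel scores resolve duplicate-based sub-types,
  not jittered kinetic continua (see above).
* The NeuroML parser targets density elements only; morphology-aware area
  weighting and non-somatic analyses are out of scope.
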