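---
title: "Dual embeddings of multichannel dynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual embeddings of multichannel dynamics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opntda)
```

This vignette explains the science implemented by `opntda`, the
assumptions behind each stage, every tunable parameter that matters,
and the design decisions taken where more than one defensible choice
existed. The package analyses short multichannel recordings (a
channels-by-samples matrix `M` with sampling rate `fs`) through two
complementary embeddings: a continuous point-cloud representation
analysed topologically, and a discrete per-channel state-transition
network analysed information-theoretically.

## Preprocessing

Field recordings carry mains interference and slow drifts, so a
segment is conditioned before analysis: band limiting, mains notches,
edge trimming, and global z-scoring, in that order.

- **FIR design.** All filters are windowed-sinc (Hamming) FIRs applied
  forwards and backwards, so the net phase response is zero and
  temporal features are not displaced. The two-pass application is
  computed in the frequency domain (multiplication by |H(f)|², which
  is real), with odd-reflection padding of one kernel length per side
  to suppress wrap-around transients. Transition bandwidth is
  `max(0.25 × band edge, 2 Hz)` and the Hamming order rule is
  `ceil(3.3 · fs / transition)`.
- **High-pass path.** A genuine FIR high-pass at the default 0.1 Hz
  edge would need a kernel far longer than a ten-second segment, so
  edges below 1 Hz are implemented as per-channel mean removal; the
  path taken is recorded in the `"highpass_path"` attribute. At edges
  of 1 Hz and above a true FIR high-pass is used.
- **Notches.** Band-stop filters of half-width 2 Hz at the mains
  frequency and every harmonic up to `notch_max` (default 50–250 Hz in
  50 Hz steps), each harmonic below Nyquist. After the two passes the
  mains attenuation is far beyond the 40 dB the analysis requires
  (verified on a 50 Hz unit sine in the test suite).
- **Trimming.** `trim_edges()` removes `round(trim_ms · fs / 1000)`
  samples (default 50 ms) from each end, where filter transients
  concentrate; a 10 s segment at 1000 Hz becomes 9900 samples.
- **Global z-scoring.** One mean and one SD over the entire C × T
  matrix. A per-channel transform would equalize channel amplitudes
  and destroy exactly the between-channel structure the point-cloud
  branch measures; the pooled transform preserves relative amplitudes.
  Constant segments are rejected (zero pooled SD).

## The embedded point cloud and its topology

Each of the T columns of the z-scored segment is a point in
C-dimensional state space, in recording order. The dissimilarity
convention is cosine (`1 − cosine similarity`, range [0, 2]) by
default: it compares activity *patterns* across the array rather than
their magnitudes. Euclidean distance is available. Zero-norm states
make the cosine undefined; `state_velocity()` flags such transitions as
`NA` and `pairwise_dissimilarity()` rejects them with their indices.

**Vietoris–Rips persistence.** Spheres of growing radius around each
point induce a nested family of simplicial complexes; the package
tracks connected components (H0) and cycles (H1). H0 comes from
union-find over edges sorted by length; H1 from GF(2) column reduction
of the triangle boundary matrix (compiled code). Design choices:

- **Coefficients** are GF(2), the standard choice for Rips persistence.
- **Tie-breaking** in the filtration order is `(value, dimension,
  lexicographic vertex tuple)`, making output fully deterministic.
- **Truncation radius.** The default stops 10% past the radius at which
  the cloud becomes one component (capped at 2 for cosine): the cycles
  of interest close before global connectivity, and truncation bounds
  the steep growth of the filtration. Cycles still open at truncation
  are reported with `death = max_radius` and a `truncated` flag — never
  silently dropped — so a cycle born exactly at the truncation boundary
  may show death = birth. Each component alive at truncation
  contributes one infinite H0 interval.
- **Scale control.** The filtration cost grows steeply with point
  count, so full-length clouds (thousands of points) are subsampled
  with greedy maxmin landmarks (`maxmin_landmarks()`, seeded), and
  `rips_persistence()` refuses more than `max_points` (default 512)
  unless raised deliberately. The correctness of the reduction is
  checked in the tests against an independent full boundary-matrix
  reduction on 110 random clouds of up to 18 points, exactly, including
  truncated and cosine cases.

Summaries are the Betti curve (cycle count per radius on a shared
grid, averageable across segments) and three scalars: maximum H1
persistence, total H1 cycle count, and the Betti-curve peak. H0 is
excluded from the scalar summaries, which follow the "cycles" reading
of the analysis; whether infinite bars enter summaries is a documented
choice (truncated bars do, with censored deaths).

## Ordinal partition networks

Each channel is treated separately — a joint multichannel ordinal
embedding over a hundred-plus channels is combinatorially infeasible —
and the results are aggregated afterwards.

- **Symbolization.** Windows `(x_i, x_{i+τ}, …, x_{i+(d−1)τ})` (stride
  1) map to their argsort permutation: the window positions listed in
  ascending value order. Ties break toward the earlier position
  (stable sort), required for determinism on flat or quantized
  stretches. Note that rank-vector and argsort conventions differ;
  this package uses argsort throughout.
- **Lag τ** (samples): first zero crossing of the biased
  (divide-by-n) sample autocorrelation, per channel. At discrete lags
  the crossing usually falls between two lags; the nearest lag to the
  interpolated sign change is returned, so a sinusoid yields exactly
  its quarter period. If no crossing occurs before the cap (default
  `min(n − 2, 1000)`), the cap is returned with a warning.
- **Dimension d** (shared across channels so that networks are
  comparable): for each candidate (default 3–7) build the OPN and
  compute the variance of its total-degree distribution; take the
  argmax (ties to the smallest d). Across channels the mode of the
  per-channel selections is used; the package default is d = 5, the
  value this criterion typically selects for cortical surface
  recordings. Degree means distinct-edge in+out degree; the choice of
  degree flavour is configurable because no convention is canonical.
- **Self-loops** are kept by default: overlapping consecutive windows
  often repeat a symbol, and removing self-transitions changes both
  determinism and entropy. The flag is recorded on the object.
- **Conservation.** Node weights sum to the window count and edge
  counts to windows − 1; these identities are asserted
  property-style in the tests.

### Information-theoretic measures

With `W_i_out` the normalized out-transition distribution of node i
and N the node count:

- `Det(X) = (log2 N − ⟨H(W_i_out)⟩)/log2 N`: 1 when every state has a
  unique successor, 0 when every future is uniform over all states.
- `Deg(X) = (log2 N − H(⟨W_i_out⟩))/log2 N`: 0 when the node-averaged
  future is uniform, approaching 1 as states funnel together.

The angle brackets are *unweighted* means over nodes with out-edges —
the maximum-entropy intervention convention of the effective-information
framework from which these measures come; visit-weighted averaging is
available as an option and recorded. The final observed symbol may
have no out-edges; such terminal nodes are excluded from both averages
and counted in an attribute. Single-node networks make both measures
undefined (log2 1 = 0); they return `NA` with a warning rather than a
silent 0. Both quantities are dimensionless ratios; permutation
entropy is reported unnormalized, in bits.

### Communities and modularity

"Modularity via the map-equation algorithm" is interpreted as a
two-step procedure, since a scalar Q is the reported quantity: (i)
minimize the two-level map equation for a random walker on the
weighted directed network (teleportation probability 0.15, uniform;
dangling nodes teleport uniformly), then (ii) evaluate directed
weighted Newman modularity `Q = Σ_ij (A_ij/m − k_i^out k_j^in / m²)
δ(c_i, c_j)` on that partition. Both the codelength and Q are
available. The search is repeated best-improvement node moves with
incremental codelength updates, then greedy module merges, restarted
from seeded shuffled orders (default 8 restarts; deterministic given
the seed). On every fixture with ≤ 8 nodes the tests verify that the
search attains the global codelength minimum found by exhaustive
enumeration of all set partitions, and that a planted two-community
graph is recovered exactly.

### Largest Lyapunov exponent

Rosenstein-style: delay-embed the channel (default m = 5, lag = the
channel's τ), pair each point with its nearest neighbour outside a
Theiler window of `lag · (m − 1)` samples, average log distances of
the pairs k steps ahead, and fit a least-squares slope over steps 1–5.
The short fit window is deliberate: for short noisy segments the
divergence curve saturates at the attractor scale within a handful of
steps, and including the saturated tail biases the slope toward zero —
on the fully chaotic logistic map (true exponent ln 2 per step) the
1–5-step fit recovers the exponent to within a few percent while a
1–10-step fit at m = 5 underestimates it by over 10%. Units are nats
per sample. The neighbour search is quadratic, so series are truncated
to `max_points` embedded points (default 2500; 1000 in the pipeline).
Constant or too-short series are rejected.

## Statistics and aggregation

Group differences use the Kruskal–Wallis rank test (χ² approximation,
tie-corrected) with two-sided Mann–Whitney U post hoc pairs (exact
null for tie-free samples of ≤ 20, otherwise the normal approximation
with tie correction), both delegated to the standard R implementations
behind thin wrappers that add the package's error contracts.
Nonparametric tests are used because no distributional assumptions are
warranted for these measures. No multiple-comparison correction is
applied by default; a Holm adjustment can be applied downstream (the
choice is recorded either way in provenance). Aggregation reports
means and *sample* SDs; single-observation groups report SD 0 flagged
by n = 1. TDA summaries aggregate at segment level, OPN measures at
channel level.

The morphospace embedding places each channel at its five OPN
coordinates (nodes, edges, det, deg, Q), standardizes features, and
projects to 2-D. The projection here is classical multidimensional
scaling: deterministic, duplicate-preserving, and sufficient for a
visualization whose axes carry no intrinsic meaning. A stochastic
neighbour embedding would also satisfy the contract; MDS was chosen
for reproducibility with zero tuning. It is a visualization utility
only and carries no acceptance weight.

## The synthetic regimes: what they do and do not show

`gen_regime()` produces C-channel, `duration_s`-second segments at
`fs` Hz (defaults 16 × 10 s × 250 Hz; 250 Hz keeps desk-scale Rips
filtrations tractable while 1000 Hz remains available) in three
regimes defined *operationally* by the fraction of broadband-chaotic
channels — 1, ½, 0 for rich / intermediate / poor:

- **rich** (awake-like): every channel is a weakly mean-field-coupled
  logistic map (coupling 0.05) summed with an equal-variance
  independent AR(1) (φ = 0.3) broadband source. The broadband term is
  essential: a bare deterministic 1-D map, symbolized at its
  autocorrelation-selected lag of 1, produces a *small, highly
  deterministic* transition network — the opposite of awake-like
  surface activity, which behaves like chaos embedded in broadband
  fluctuations.
- **poor** (sedated-like): one shared 2 Hz sinusoid with seeded random
  phase, projected to all channels with gains in [0.5, 1.5]. With zero
  noise the segment is exactly rank one.
- **intermediate**: half the channels rich-type, half poor-type —
  partial penetration of the sedated mode across the array. A
  per-sample 50/50 amplitude mixture was rejected: because τ adapts to
  the autocorrelation, such a mixture symbolizes almost like the rich
  regime (its windows sample the chaotic component at decorrelated
  spacing), whereas the channel split places every channel-aggregated
  measure genuinely between the extremes.
- All channels in all regimes receive independent AR(1) (φ = 0.95,
  unit-SD-scaled) low-frequency-weighted noise at relative scale
  `noise_scale` (default 0.1).

Every generator takes an explicit seed and leaves global random state
untouched; identical seeds give bit-identical output.

These surrogates reproduce the *directions* that distinguish
wakefulness from deep sedation — more micro-states, more unique
transitions, higher permutation entropy, more point-cloud cycles and a
larger Lyapunov exponent in the rich regime; higher determinism and
modularity in the poor regime — and the tests assert exactly those
orderings. They are not biophysical: no pharmacokinetics, no realistic
spectra beyond the slow-oscillation-versus-broadband contrast, no
volume conduction, no artifacts. Passing tests on them demonstrates
that the *pipeline* measures what it claims to measure on signals with
known structure, not that any particular neural dataset will show these
effects.

## Problem sizes and determinism

The test suite and the acceptance script run the regime study at 8
channels × 4 s × 250 Hz over 10–20 seeds with 80 Rips landmarks and
1000-point Lyapunov embeddings — sizes chosen so the full validation
runs in minutes on one CPU while every ordering remains stable across
seeds. Oracle comparisons (persistence against full boundary-matrix
reduction; map equation against exhaustive partition enumeration) use
clouds of ≤ 18 points and networks of ≤ 8 nodes, where brute force is
exact and fast. All stochastic steps — generators, landmark seeding,
partition restarts — are seeded explicitly, and `run_pipeline()`
records config, selected parameters and an MD5 provenance hash so a
rerun reproduces every number bit for bit.

## Known limitations

- H1 is the highest homology dimension computed; voids and higher
  structures are out of scope, as are persistence images/landscapes
  and bottleneck/Wasserstein comparisons.
- OPNs are strictly univariate per channel; joint ordinal embeddings
  across channels are not attempted.
- The Lyapunov estimate is a slope statistic on noisy data, not a
  certified exponent; on stochastic signals it measures divergence
  rate at the embedding scale rather than deterministic chaos.
- The landmark approximation underestimates small-persistence cycle
  counts relative to the full cloud; comparisons remain valid when all
  conditions use the same landmark budget.
- EDF input is not implemented; segments are exchanged as delimited
  text with a metadata header.
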