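---
title: "Methods: dual diet analysis with dietmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual diet analysis with dietmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dietmix` implements two complementary views of a marine predator's diet:
the *ingested* diet, reconstructed from hard parts recovered in stomachs,
and the *assimilated* diet, inferred from stable isotopes through a
Bayesian mass-balance mixing model. This vignette documents the models,
their assumptions, the tunable parameters, and the numerical decisions —
including the ones the underlying methodology leaves genuinely open.

## 1. Stomach-content reconstruction

### Counting individuals

Fish individuals are evidenced by otoliths and by diagnostic bones
(premaxilla, maxilla, cleitrum, dentary, opercula). Each otolith counts as
half a fish; paired bones likewise count half an individual each, unpaired
ones a whole individual. Per stomach and taxon the estimate is the
*maximum* over structure types, rounded up, so one detected hard part
always evidences at least one individual. Two decisions here are ours:

- **Ceiling, not rounding:** published diet tables report integer counts;
  the ceiling guarantees a detected taxon is never counted as zero.
- **Pairing table:** the five bone elements above are treated as paired by
  default because they occur bilaterally; the `paired` argument lets users
  override per element, since counting conventions differ between
  laboratories.

Cephalopod individuals are the larger of the upper- and lower-beak counts
(each animal carries one of each).

### Lengths and weights

Hard-part measurement `x` (mm) maps to body length through either a linear
(`L = a + b·x`) or power (`L = a·x^b`) model, and length to wet weight
through `W = c·L^d` (g). Regression entries resolve deterministically:
a species-scope entry beats a group-scope (family) entry beats a
"no-weight" outcome; taxa without any entry keep their counts but
contribute no weight (their rows show `NA` weight, and they are excluded
from the %W denominator).

When structures outnumber individuals — the normal case, with two otoliths
per fish — the per-occurrence weight is the *mean* reconstructed individual
weight times the individual count. Summing per-structure weights would
double-count paired structures; the mean-times-count rule is exact when
both otoliths of a fish are measured and is the natural estimator when only
some are.

### Dietary indices

For category *i* with count `N_i`, occurrence `O_i` (stomachs) and weight
`W_i`:

- `%N = 100·N_i/ΣN`, `%O = 100·O_i/n_stomachs`, `%W = 100·W_i/ΣW`
  with ΣW over weight-bearing categories only;
- `IRI = (%N + %W)·%O`, ranging 0–20 000.

Two computation modes exist because published tables are typeset from
rounded numbers: **analysis mode** keeps full precision, while **reporting
mode** rounds each percentage to two decimals *before* forming the IRI and
rounds the IRI to two decimals. Rounding is half-away-from-zero (the
convention of printed tables), not R's round-half-to-even, with a one part
in 10¹² nudge so values stored marginally below a half boundary still round
up. Published IRI values are consistent with the rounded-percentage
arithmetic, not the full-precision one, which is why reporting mode exists
as a first-class option rather than a formatting afterthought.

### Prey-specific abundance

The Costello–Amundsen diagram plots `%O` against
`%P_i = 100·ΣW_i/ΣW_ti`, where the denominator is the total stomach-content
weight of *only those stomachs containing prey i*. A prey near the top is
dominant wherever it occurs (specialisation); near the bottom it is
incidental. `%P` is defined only for weight-bearing taxa.

### Bootstrap confidence limits

Uncertainty in composition comes from the small number of stomachs, so the
bootstrap resamples *stomachs* (the sampling unit) with replacement —
n_stomachs per replicate — and recomputes all indices per replicate, with
taxa absent from a replicate contributing zero. We report percentile
2.5/50/97.5 limits with linear interpolation between order statistics
(`quantile` type 7): the simplest method consistent with "median and 95%
confidence limits", and the one an enumeration oracle can check exactly.
The default of 1000 replicates matches standard practice; the test suite
validates the machinery against exhaustive enumeration of all resample
multisets for 2–3 stomachs at 10⁵ replicates, where sample quantiles
converge to the population quantiles of the exact discrete resample
distribution. Stomachs examined but empty can be included via
`n_stomachs` exceeding the number of stomachs with prey; they enter the
resampling frame as empty units.

## 2. Source grouping

Mixing models need few, isotopically distinct sources. Prey species are
clustered on their (δ¹³C, δ¹⁵N) mean vectors by agglomerative hierarchical
clustering with Ward's minimum-variance linkage and Euclidean distance.
Open choices and our defaults:

- **Ward dialect:** `ward.D2` (distances squared inside the Lance–Williams
  update) is the default as the modern convention; the legacy `ward.D` is
  selectable because older software used it and the two can cut
  differently. On the bundled Gulf of Cadiz species means both dialects
  recover the same four groups, so the published grouping is not an
  artefact of dialect choice there.
- **No standardisation by default:** both axes are in ‰ with comparable
  spreads in typical marine data; a `standardize` flag exists for systems
  where they are not.
- **k is user-chosen:** the number of groups is an ecological judgement
  ("clearly separated clusters"), not an optimisation target; the function
  returns the full tree (and a Newick export via `ape`) so users can
  inspect separation before cutting.
- **Determinism:** rows are sorted by taxon before clustering, so the
  partition is invariant to input order.

Group summaries pool member species exactly:
`m = Σnᵢmᵢ/Σnᵢ` and `s² = [Σ(nᵢ−1)sᵢ² + Σnᵢ(mᵢ−m)²]/(Σnᵢ−1)`, which equals
recomputing mean and sd from the concatenated raw values. Single-species
groups pass through unchanged; a pooled n below 2 yields no sd.

## 3. The mixing model

Per isotope `j ∈ {δ¹³C, δ¹⁵N}` and consumer `i`:

    x_ij ~ Normal( Σ_k p_k (μ_kj + λ_kj),
                   sqrt( Σ_k p_k² (σ_kj² + τ_kj²) + ξ_j² ) )

with source summaries `μ, σ`, discrimination factors `λ ± τ` (per source or
broadcast), diet proportions `p` on the simplex with a Dirichlet(α) prior
(α = 1 by default, the uninformative standard), and residual sds `ξ_j` with
Uniform(0, upper) priors. Assumptions worth stating: isotopes are
conditionally independent given `p` (no δ¹³C–δ¹⁵N covariance), sources
combine linearly in delta space (no concentration dependence), and all
consumers share one `p` (no covariates or individual effects).

**Error structure.** "Process + residual" is the default because the
residual term absorbs consumer-level variation the source summaries cannot
explain; `residual = FALSE` gives the pure process-error model. The
residual prior upper bound defaults to twice the consumer sd per isotope —
generous enough to be vague, finite so the sampler cannot wander.
**Discrimination factors are deliberately not defaulted**: they are
species- and tissue-specific, typically taken from controlled-feeding
studies, and silently assuming one would be the single most dangerous
default this package could ship.

### Sampler

The proportions are sampled on the additive-log-ratio transform
`z_k = log(p_k/p_K)`, so every retained draw lies exactly on the simplex by
construction; the log-Jacobian `Σ_k log p_k` is included. `ξ` is updated by
Metropolis on the log scale (with its Jacobian). Proposals are spherical
Gaussian random walks whose scales adapt during the first half of burn-in
in 50-draw batches (scale ×1.1 if batch acceptance > 40%, ÷1.1 if < 20%)
and are frozen afterwards, keeping the post-adaptation chain a valid
Markov chain. Chains get distinct sub-seeds (`seed + 1000·(chain−1)`);
initialisation is the simplex centre, falling back to prior draws (at most
100) if the posterior is non-finite there.

The desk-scale default — 3 chains × 5 000 burn-in + 5 000 draws — is the
profile all shipped examples and tests use; it reaches split-chain R̂
below 1.1 on the bundled four-group problem in a couple of seconds. For
publication-scale runs the arguments accept arbitrarily large values
(e.g. 200 000/300 000); nothing in the implementation is specific to the
small profile.

Convergence is summarised by a split-chain Gelman–Rubin factor (each chain
halved, between/within variance ratio over the 2C half-chains). Posterior
summaries report means, medians, and central 50/75/95% credible intervals,
which are nested by construction.

The test suite checks the sampler against independent oracles rather than
against itself: a dense grid integration of the exact posterior for
two-source problems (posterior mean and sd within Monte-Carlo error),
prior recovery with zero consumers, exchangeability with identical
sources, invariance to an uninformative isotope, and truth-recovery on
synthetic four-group data at n = 51 consumers.

## 4. The mixing-polygon simulation

A mixing model can only explain consumers lying inside the convex hull of
its (discrimination-corrected) sources. Per iteration, each source is drawn
from `N(μ+λ, sqrt(σ²+τ²))` per isotope, the hull of the K draws is built,
and every consumer is tested; a consumer's inside probability is the
fraction of iterations covering it. The design passes when every consumer's
probability is at least 0.05 — i.e. no consumer is excluded from 95% of the
simulated polygons.

Numerical decisions:

- **Scatter convention:** hull vertices are drawn from combined source +
  TDF uncertainty (sd), matching the corrected-source distribution of the
  mixing model; a `use_sem` flag substitutes standard errors for users who
  read the source summaries as estimates of means rather than population
  spreads.
- **Boundary rule:** points on the hull boundary count as inside
  (conservative toward acceptance), implemented with orientation tests at a
  1e-12 relative tolerance; degenerate hulls (two sources collinear, or a
  single point) are handled by distance-to-segment tests.
- **Hull construction** uses `grDevices::chull` wrapped to return
  counter-clockwise vertices and to handle collinear and duplicate-point
  degeneracies; the test suite verifies it against an independent
  gift-wrapping implementation on random 100-point instances.
- **Defaults:** 1 500 iterations (inside probabilities are binomial
  proportions, so their Monte-Carlo sd is ≈ √(q(1−q)/1500) ≤ 0.013); the
  optional contour surface is evaluated on a 200×200 grid spanning the
  data extent ±1 ‰, with contours at every 10% level.

## 5. Synthetic-data generators

The generators exist so every downstream stage can be tested against known
truth without any external data.

**Stomach stream.** Per stomach, a composition is drawn from a Dirichlet
with per-taxon concentration (default 0.3 — small, giving the heavy-tailed,
few-taxa-dominate stomachs typical of opportunistic predators; no
published per-stomach data exist to calibrate this, so it is a fixed
pragmatic choice), prey counts from a multinomial, and each individual
materialises as two otoliths (fish) or one lower beak (cephalopod) whose
measurement is the drawn body length back-transformed through the
regression table. Reconstruction with the same table therefore recovers
counts and weights *exactly*, which the round-trip tests exploit. The
generator does not simulate digestion, otolith erosion, structure loss, or
secondary ingestion — so passing round-trip tests validates the counting
and regression arithmetic, not robustness to taphonomic bias in real
stomachs.

**Isotope stream.** Consumers are drawn from exactly the mixing model's
likelihood at a known `p` — the generator and the model share their moment
equations deliberately, so parameter-recovery tests probe the sampler, not
model mismatch. Real data violate the likelihood in ways the generator
does not emulate (isotope covariance, consumer heterogeneity, non-Gaussian
sources); recovery on synthetic data therefore shows correctness of the
inference machinery, not of the model for any particular ecosystem.
`default_gulf_config()` carries the published Gulf of Cadiz source
summaries (four groups, 51 consumers) as a realistic default
configuration; its default generating proportions take the study's rounded
headline posterior means for the two major groups (0.52, 0.22) and split
the remainder evenly, since no published values exist for the minor
groups.

Seeds are explicit arguments everywhere, with a package-wide default of
20170912, so identical configurations reproduce byte-identical datasets.

## 6. Bundled tables

The package ships the published Gulf of Cadiz summary tables as plain CSV:
the raw diet-composition columns (N, O, W per prey category — percentages
and IRIs are deliberately excluded and always recomputed) and the isotope
summaries (consumer and prey species/group means, sds, ranges). A few
published family rows are arithmetically inconsistent with their own
species rows (e.g. a family %N that cannot equal its printed N over the
table total — typesetting artefacts); the tables store only raw values,
and reproduction checks use only the internally consistent rows. The
published bootstrap confidence limits are not reproducible in principle —
they require per-stomach raw data that were never published — so bootstrap
correctness is established by enumeration oracles instead. Likewise the
published posterior means for the assimilated diet depend on unpublished
discrimination factors and raw consumer values; the package validates its
mixing model by oracle equivalence and synthetic recovery instead of
chasing those numbers.

## 7. Known limitations

- No digestion-grade correction factors or hard-part identification
  logic: records arrive identified, as in any guide-based workflow.
- The mixing model fits one population-level `p`; covariates, random
  effects and source-concentration dependence are out of scope.
- Ward clustering on species *means* ignores within-species variance; the
  pooled group sds reintroduce it downstream, but the partition itself is
  means-only, as in the standard workflow.
- The ALR random-walk sampler is adequate for small numbers of sources
  (K ≲ 8); for much larger source sets a gradient-based sampler would mix
  better.
- The polygon simulation is the frequentist hull-coverage check; it is a
  design diagnostic, not an inference about `p`.
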