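---
title: "Methods: community assembly and cross-domain co-occurrence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly and cross-domain co-occurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estuarch)
```

`estuarch` implements the downstream community-ecology analyses used to
compare planktonic archaeal communities across multiple estuaries: feature
table preparation, Sloan neutral community model (NCM) inference,
distance-based multivariate statistics, and constraint-based cross-domain
co-occurrence networks. A synthetic-data generator reproduces the
statistical structure of such a survey so every method can be validated
end-to-end without sequencing data. This vignette records the models, the
parameters that matter, and the numerical decisions behind the
implementation.

## The neutral community model

The Sloan NCM predicts how often a taxon should be detected across local
communities if assembly were driven purely by random drift and immigration
from a shared source pool. Let `p` be a taxon's relative abundance in the
source metacommunity, `N` the size of a local community in reads, and `m`
the migration rate (the probability that a local death is replaced by an
immigrant rather than by local reproduction). At stationarity the local
relative abundance `x` follows

    x ~ Beta(N m p, N m (1 - p))

and the probability of detecting the taxon at the detection limit `d`
reads is

    E[freq] = 1 - I(d / N; N m p, N m (1 - p))

with `I` the regularized incomplete beta function (`expected_frequency()`).
`fit_ncm()` estimates the single free parameter `Nm` by least squares of
observed occurrence frequencies on this curve, using `minpack.lm::nlsLM`
(with a deterministic golden-section fallback on `log(Nm)` if the
Levenberg-Marquardt step fails), and reports `m = Nm / N` plus an R² about
the mean observed frequency. R² may legitimately be negative for
communities far from neutrality; it is reported as computed, not
truncated.

Choices worth knowing:

* **Which taxa enter the fit.** Only taxa with `p > 0` and observed
  frequency `> 0` contribute points, matching the convention of the widely
  used NCM fitting scripts: a taxon never detected locally has no point on
  the occurrence curve. All taxa still receive predictions and category
  labels.
* **`N` and `d`.** `N` defaults to the rounded mean local sample depth and
  `d` to one read. Both are explicit parameters: simulation-based recovery
  work should pass the generating `N` so the exercise is self-consistent.
* **The envelope.** The 95% band around the fitted curve is the Wilson
  score interval for a proportion with `n` = number of local samples,
  evaluated along the curve. Two refinements are applied. First, ties:
  a frequency exactly on a boundary is *neutral* ("within the interval"
  is read inclusively). Second, a discreteness correction at the saturated
  ends: with `n` samples, an observed frequency of exactly 1 is not
  evidence of selection when the fitted curve itself gives
  `P(observed = n/n) = pred^n > α/2`, yet any interval bound below 1 would
  flag it. The bound is therefore widened to 1 (symmetrically, to 0)
  in that regime. Without this correction the apparent "selected-for"
  rate among genuinely neutral taxa runs near 15-20% purely from taxa
  sitting on the flat top of the curve; with it, the rate is at the
  nominal few percent, while mid-curve classifications are unchanged.
* **Partition of abundance.** `partition_abundance()` attributes the focal
  group's reads to the neutral / above / below classes; the neutral share
  is the usual summary of how much of the community's abundance is
  consistent with stochastic assembly.

## Distance-based statistics

`bray_curtis()`, `pcoa()`, `permanova()`, `mantel()`, `partial_mantel()`
and `env_correlations()` are implemented directly from their matrix
definitions (the test suite cross-checks them against independent
implementations and brute-force enumeration):

* PCoA eigendecomposes the Gower-centered matrix `-1/2 J D² J`. Negative
  eigenvalues — expected for Bray-Curtis — are reported untouched;
  proportions explained are over positive eigenvalues only.
* PERMANOVA uses sequential (Type I) sums of squares via hat matrices on
  the Gower-centered matrix, with terms in the order given. Order matters
  in unbalanced designs (e.g. after dropping shallow samples), which is
  why the order is the caller's explicit choice. Pseudo-F uses the
  full-model residual; significance comes from free (unrestricted)
  permutation of sample labels; restricted/nested permutation schemes are
  out of scope and this is a known limitation for nested readings of the
  design. All permutation p-values use the add-one rule, so
  `p ≥ 1/(n_perm + 1)`. A saturated or aliased design is an error; a
  perfectly separated design yields an infinite pseudo-F by convention.
* Mantel statistics default to Spearman (ranks of the off-diagonal
  vectors); the partial variant correlates residuals after linear
  regression on the (ranked) control vector, permuting the second matrix.
  Note one subtlety established during validation: when two distance
  matrices are *linear* mixtures of a shared driver plus independent
  noise, rank transformation introduces a small shared curvature that
  leaves a residual correlation of ~0.1 after controlling the driver.
  This is a property of rank-based partialling, not an implementation
  artifact; sharp conditional-independence checks should use
  `method = "pearson"` on such fixtures.

## Normalization

* `rarefy()` subsamples each sample without replacement to a fixed depth
  (multivariate hypergeometric; rows sum to the depth exactly).
* `css_normalize()` implements cumulative sum scaling: per sample, counts
  are divided by the sum of counts up to the `l`-th quantile of the
  sample's *nonzero* counts (linear interpolation, `stats::quantile`
  type 7 — pinned for bit-reproducibility), then multiplied by a scale
  constant (default 1000, a per-thousand scale). `l` defaults to 0.5; the
  adaptive instability search of the original CSS method is deliberately
  out of scope. CSS output is not log-transformed by default before
  ordination (a flag is available) — the package takes no position on
  which variant a given study used when it is not stated.
* `clr_transform()` (in the network module) maps counts to the centered
  log-ratio scale with a pseudocount; rows sum to zero.

## Direct co-occurrence networks

`infer_direct_network()` realizes a local-to-global, constraint-based
inference in the spirit of sensitive-mode direct-association tools:
taxa are clr-transformed, environmental covariates standardized, and all
variables share one correlation matrix. Candidate edges come from pairwise
Fisher-z tests at `alpha` (default 0.001). An edge `(i, j)` is then
removed if *any* conditioning subset `S` (up to `max_k = 3`) drawn from
the current neighbor sets of `i` or of `j` renders the partial correlation
insignificant — this removes associations explained by another measured
taxon or by an environmental covariate. Removals within each
conditioning-set size are applied simultaneously (an order-stable sweep),
making the output invariant to sample and feature order.

Interpretation decisions:

* `n_obs_min` (default 10) is read as the minimum number of samples in
  which *both* taxa of a pair are nonzero; pairs below it are never
  tested and never linked.
* Edges are symmetrized by the AND rule (both endpoints must retain the
  edge) — conservative by design.
* Edge weight and sign come from the *pairwise* clr correlation rather
  than the last partial correlation; pairwise signs are more stable and
  the two rarely disagree on surviving edges.
* Missing environmental values are a hard error at this module's
  boundary (metadata upstream may contain them).

`detect_modules()` delegates to greedy modularity maximization
(`igraph::cluster_fast_greedy`) on absolute edge weights, with vertices
supplied in sorted-id order so results are deterministic; isolated nodes
become singleton modules. `zi_pi()` computes within-module connectivity
`Zi` (the within-module degree standardized over the module's members;
0 where the module's spread is zero) and among-module connectivity
`Pi = 1 - Σ_s (k_is / k_i)²` on *unweighted* degrees (a weighted variant
of connectivity is not used for role classification, matching common
practice). `classify_roles()` applies the standard thresholds — `Zi = 2.5`
and `Pi = 0.62` — with both boundaries inclusive on the peripheral side:
peripherals (`Zi ≤ 2.5`, `Pi ≤ 0.62`), connectors (`Zi ≤ 2.5`,
`Pi > 0.62`), module hubs (`Zi > 2.5`, `Pi ≤ 0.62`), network hubs
(`Zi > 2.5`, `Pi > 0.62`).

The pre-filter `filter_for_network()` keeps a feature only with at least
100 total reads *and* detection in at least `ceiling(0.15 n)` samples
(both inclusive). The abundance threshold is interpreted as total reads in
the table being filtered; because networks are built per estuary/season
sub-table, the filter is applied per sub-table (both the threshold and
this scoping are configurable).

## The synthetic study generator

`simulate_study()` emulates the statistical structure of a multi-estuary
survey: 4 estuaries × 2 seasons × 2 stations × 5 replicates (80 samples,
ids like `WYE_L_1`), one lognormal source pool (`σ_log = 2`, 400 taxa by
default, 30% archaeal) shared by all estuaries, neutral local assembly
with estuary-specific migration rates (defaults 0.4 / 0.15 / 0.1 / 0.05,
spanning weak to strong dispersal limitation), a handful of planted
selected-for and selected-against archaeal taxa (effect 3 on occurrence
frequency), and environmental covariates tied to season (temperature),
station (salinity) and estuary (pH, nutrients).

Numerical decisions in the generator:

* **Stationary sampling, not birth-death dynamics.** Local communities are
  drawn directly from the model's stationary beta distribution — the
  object the fit estimates — at cost `O(S · n)`.
* **Counts.** A taxon's count is `floor(N x)`, the integer abundance of a
  community of `N` reads at relative abundance `x`, so detection at `d`
  reads is *exactly* the event `x ≥ d/N` whose probability the closed
  form computes. An alternative `count_model = "binomial"` resamples
  counts as `Binomial(N, x)`; this extra read-sampling layer smooths the
  detection threshold and (as measured during development) biases fitted
  `m` upward by 20-40%, so it is not the default. Taxa are drawn
  independently, matching the independent-taxon approximation of the fit;
  row sums therefore vary around `N` rather than equalling it.
* **Selection planting edits occurrence, not mean abundance**, because the
  NCM partition is defined on occurrence frequency: mode `"for"`
  multiplies a taxon's detection frequency by `min(effect, 1/freq)` by
  converting random zero cells to detections (counts resampled from the
  taxon's own nonzero counts); mode `"against"` divides it (target
  detections `floor(d₀/effect)`, so a strong effect silences a sparse
  taxon entirely).
* **Planted association graphs.** `simulate_graph_counts()` builds a
  Gaussian graphical model whose unit-diagonal precision matrix carries
  `-sign·strength` exactly at the planted edges (so each edge's latent
  partial correlation equals its signed strength); environmental
  covariates enter as additional latent parents. Latents map to counts by
  softmax-to-proportions and a multinomial draw at fixed sequencing
  depth, producing closed compositional counts as sequencing does.
  `random_planted_graph()` caps per-node degree so the precision matrix
  stays diagonally dominant, hence positive definite by construction.
  Benchmarks embed planted motifs among ≥ 30 taxa: with few taxa the clr
  closure term (order `1/S`) itself induces visible correlations.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: estuary-specific source pools or strong
deterministic habitat filtering (the synthetic estuaries share one pool
and differ only in `m`, so ordination separates estuaries only weakly and
whole-study networks are sparse, unlike real estuarine communities where
selection and biotic interactions dominate); sequencing error, chimeras
and read-level noise; phylogenetic structure; temporal autocorrelation
within a season. The generator validates the *machinery* — parameter
recovery, envelope calibration, filter and test correctness, planted-edge
recovery — not ecological conclusions.

## Problem sizes and runtime envelope

The validation suite uses sizes at which every check is sharp yet the
whole suite runs in well under a minute of CPU: NCM recovery at
`S = 500` taxa, `N = 10⁴`, 100-200 samples over 20 seeded replicates;
Monte-Carlo beta oracles at 10⁶ draws per grid point; PERMANOVA
enumeration at `n = 6` (720 relabelings) plus 200 null datasets at 999
permutations; network benchmarks at 50 taxa / 40 planted edges / 200
samples, and 40 seeded chain runs at 500 samples. These sizes are stated
here so that anyone scaling them up knows they were chosen for sharpness
per CPU-second, not as limits of the methods.

## Known limitations

* One free parameter (`Nm`) is fitted; no taxon-specific migration or
  phylogenetically informed null models (βNTI / Raup-Crick) are provided.
* PERMANOVA offers sequential SS only (no marginal/Type III), and free
  permutation only.
* The network module assumes roughly continuous clr values; extremely
  sparse taxa pass through the `n_obs_min` guard rather than a dedicated
  zero-inflation model, and heterogeneous (multi-habitat) inference modes
  are out of scope.
* CSS uses a fixed quantile; the adaptive instability criterion of the
  original method is intentionally not implemented.
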