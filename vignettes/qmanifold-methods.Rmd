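---
title: "Methods: embedding respondent groups on the statistical manifold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding respondent groups on the statistical manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmanifold)
```

## The model

A questionnaire with `N_Q` categorical questions, question `q` offering the
answer alphabet `A_q`, defines a finite outcome space of
`N = prod(|A_q|)` response strings. A group of respondents is modelled as
i.i.d. draws from an unknown distribution `p` over these strings. The set
of all such distributions is the statistical manifold; in square-root
coordinates `ξ_I = sqrt(p_I)` it is the positive quadrant of the unit
`(N−1)`-sphere, on which the Fisher–Rao metric is the ordinary round-sphere
metric. The geodesic distance between two groups is therefore the
great-circle arc, `D = arccos(Σ_I ξ_I^1 ξ_I^2)` — the arccos of the
Bhattacharyya coefficient. The full pipeline is: estimate a distribution
per group, form the `K×K` distance matrix, and embed with classical MDS.

Two assumptions carry the method:

1. **Grouping is given.** The researcher supplies the groups (a column or a
   cross-product of columns in the data). Discovering groups from raw
   response strings is a different, unsolved problem: single responses are
   symbol sequences without a natural distance.
2. **Factorization.** Within a group, questions are treated as independent,
   so `p_I = Π_q f_q(a_q)` with per-question marginals `f_q`. This makes
   estimation feasible (`Σ_q |A_q|` parameters instead of `N`) and lets the
   Bhattacharyya coefficient factorize into per-question sums, so no
   operation ever enumerates the exponential string space. The cost is that
   within-group answer correlations are invisible to the estimate; the
   simulation results below show the geometry between groups survives this
   even when the generating joints are strongly non-factorized.

## Tunable parameters

* `alpha` (pseudocount, default 0) — additive smoothing of the per-question
  frequencies, `f_q(a) = (count + α)/(n + α|A_q|)`. The default is the
  plug-in estimator. The reason `alpha` exists: two groups whose observed
  supports are disjoint on even one question sit at the maximal distance
  `π/2` exactly, and with small `n` such disjointness can be a sampling
  artefact. A small `alpha` (e.g. 0.5) softens this; increasing it pulls
  every frequency monotonically toward uniform.
* `d` (embedding dimension, default 2) — two dimensions are what one
  inspects visually, and the simulation study's one-parameter family is
  recovered well in the plane. `scree()` reports the positive spectrum,
  cumulative shares and an elbow suggestion (largest second difference of
  the positive eigenvalues) when the choice is not obvious; `d = "auto"` in
  `run_pipeline()` uses that suggestion.
* `min_group_size` (advisory, default 20) — `validate_table()` flags groups
  below this size. Small groups are the method's stated failure mode: their
  estimated distribution can land anywhere on the manifold by chance. The
  default sits at the knee of the accuracy-vs-`n` curve reproduced by the
  sample-size test (accuracy rises steeply up to roughly 20–25 respondents
  per group, then levels off). The check never blocks an analysis.
* Curve parameters `kappa`, `m`, `n_q`, `n_a` (simulation only) — `kappa`
  selects which spherical angle oscillates as `(π/2)·sin²(mπt)` while the
  others grow linearly in `t`; `m` counts the oscillations and hence sets
  the non-linearity of the family. `m` is restricted to positive integers
  so that the endpoint identities (`t = 1` closes the oscillating angle,
  `t = 1/(2m)` maximises it) hold exactly. Note that for `kappa = 1` the
  curve returns to its starting point at `t = 1`.

## The simulation framework: what it does and does not emulate

`simulate_study()` places `K` groups on the curve — uniformly spaced on
`[0, 1]` including both endpoints (default), or at sorted uniform random
positions — computes each group's exact joint by squaring the spherical
coordinates, and samples `n` respondents per group. The exact joints, the
curve parameters `t_k` and the theoretical distance matrix are retained as
ground truth, so the pipeline's output can be scored by the Pearson
correlation between the upper triangles of the theoretical and the
embedded distance matrices. The generating joints are generically
*non*-factorized (their multipartite information varies along the curve),
so the validation genuinely exercises the factorization assumption rather
than assuming it true.

What the generator does **not** emulate: missing answers, ordinal response
scales, respondent-level covariates, unequal group sizes, and question
blocks with designed correlation structure. A passing validation therefore
shows that the geometry-recovery machinery works under controlled
departures from factorization — not that any particular real questionnaire
satisfies the method's assumptions.

Default study sizes follow the two published regimes: `K = 50` groups with
50 respondents each (headline), and `K = 20` with 25 (small-sample). With
`κ = 1, m = 3, N_Q = 8, N_A = 3, d = 2`, the median correlation over ten
replicate seeds is about 0.93 in the first regime and above 0.9 in most
replicates in the second; both are recomputed by the test suite and by
`scripts/acceptance.R`, and no number quoted here is produced anywhere
else.

## Numerical choices

* **String order.** Joint vectors are indexed lexicographically over answer
  codes with question 1 most significant (the last question varies
  fastest). Any fixed bijection between spherical-coordinate indices and
  strings would do; this one is documented, versioned in the run log, and
  round-trips through `string_index()`/`index_to_answers()`.
* **Arccos clipping.** Products of per-question sums can exceed 1 by a few
  ulps; `fisher_distance()` silently clips values in `(1, 1 + 1e-9]` and
  clips tiny undershoots below 0, but raises an error beyond those
  tolerances — a coefficient genuinely outside `[0, 1]` means a broken
  distribution upstream, and masking it would hide the bug. The asymmetry
  is deliberate: ulp-level excess above 1 is routine, appreciably negative
  inner products of non-negative vectors are impossible.
* **Self-distances.** `arccos` has infinite derivative at 1, so a
  coefficient correct to machine epsilon still yields a self-distance of
  order `1e-8` rather than 0; diagonals are set to zero explicitly and the
  matrix symmetrized.
* **Negative eigenvalues.** Great-circle distance matrices are generally
  non-Euclidean, so the doubly-centered Gram matrix has negative
  eigenvalues. Standard Torgerson handling: they are reported in the
  spectrum (and by `scree()`) but never used for coordinates; requesting
  more dimensions than there are positive eigenvalues truncates with a
  warning.
* **Sign convention.** Each eigenvector's first coordinate of appreciable
  magnitude is made positive, so output files are reproducible across runs
  and platforms; all downstream quantities are invariant to this choice.
* **Ablation line fit.** The outlier-attribution procedure fits the
  non-focal group points with a total-least-squares line (first principal
  direction) and measures the focal centroid's perpendicular distance to
  it. Both are invariant under rotation and reflection of the embedding,
  which matters because each leave-one-question-out MDS solution has its
  own arbitrary orientation; an ordinary-regression vertical residual
  would not be comparable across ablations. The focal "group" may be a set
  of labels, whose embedded points are pooled into one centre of mass.
* **Degenerate inputs.** An all-zero distance matrix embeds to zero
  coordinates (with a truncation warning); Pearson correlation on constant
  matrices or on fewer than three groups raises an error rather than
  returning `NaN`; Procrustes alignment onto a zero-variance target is
  refused; multipartite information clamps floating-point negatives above
  `−1e-12` to zero and is defined as 0 for a single question.

## Design decisions on genuinely open points

* **Uniform placement includes both endpoints.** Group parameters
  `t_k = (k−1)/(K−1)`; "uniform or random" admits several conventions and
  the endpoint-inclusive one keeps the curve's extremes in every study.
* **Upper-triangle-only Pearson.** Including the zero diagonal (or the
  mirrored lower triangle) would inflate the correlation with `K` constant
  zero pairs; only the `K(K−1)/2` distinct distances enter.
* **MI colouring uses ground-truth joints.** In validation reports the
  multipartite information of each group is computed from the exact joint,
  as a property of the curve point, not of the estimate (an estimated
  factorized joint would give exactly 0 everywhere).
* **Validation correlates the 2-D embedding by default.** The embedding
  dimension that enters the correlation is a parameter (`d`); 2 is the
  default because that is the view one draws conclusions from.
* **One RNG stream per study.** Groups are sampled in order of increasing
  `t` from a single seeded stream, so a study is reproducible from its
  argument tuple; the flip side, documented, is that adding groups changes
  all subsequent draws.
* **Smoothing default 0.** The estimator is the plain plug-in frequency;
  whether any smoothing should be considered part of the method is left to
  the analyst, which is why `alpha` is an explicit argument everywhere
  rather than a hidden constant.

## Known limitations

* The factorization assumption discards within-group question
  correlations; relaxing it for strongly correlated question blocks would
  require joint estimation over those blocks and correspondingly more data
  per group.
* Groups with very few respondents get unreliable positions; the package
  only warns (via `validate_table()`), it cannot repair them.
* Continuous or ordinal questions are out of scope; answers are opaque
  categories.
* The simulation family is a one-parameter curve; higher-dimensional
  ground-truth manifolds are not generated.
* Classical MDS is the only embedding offered (plus PCA post-reduction);
  non-classical variants are deliberately not wrapped.

## Problem sizes used by the test suite

The suite regenerates everything in code. The heavier checks use the two
published regimes above (ten seeds each), a 100-fixture factorized-versus-
enumeration equivalence sweep at `N_Q ≤ 4, N_A ≤ 3`, a 1000-draw
normalization sweep of the spherical coordinate map, and a sample-size
trend over `n ∈ {10, 25, 50, 100}` at `K = 20` with ten seeds per point.
These sizes were chosen as the smallest that exercise the published
regimes directly; the full suite runs in well under a minute.
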