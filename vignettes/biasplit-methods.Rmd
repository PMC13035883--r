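---
title: "biasplit: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{biasplit: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasplit)
```

This vignette is the package's own account of its methods: the cost model
the sampler minimizes, the feasibility constraints on target
distributions, what the synthetic cohort generator does and does not
emulate, the numerical choices buried in the implementation, and the
scales at which the test suite exercises everything.

## The partitioning problem

Given a pooled cohort of $N$ samples with $d$ continuous labels (here
typically patient weight in kg and height in cm) and $M$ per-group target
distributions (Gaussian, specified by per-dimension mean and sd), find an
assignment of every sample to exactly one group such that each group's
empirical label distribution approximates its target, while group sizes
stay comparable. No sample is ever dropped: with desk-scale clinical
cohorts every sample is precious, and a partition (rather than a
subsample) keeps the mixture identities below exact.

## The cost model

Distributional fit is measured per group by a chi-squared histogram
distance on a grid shared by all groups,

$$\chi^2_i = \sum_{\text{cells}} \frac{(O - E)^2}{E}, \qquad
  E = n_i \, p_{\text{cell}},$$

where $O$ are the group's observed cell counts, $p_{\text{cell}}$ the
target's cell probability (Gaussian CDF differences per dimension,
multiplied across dimensions), and $n_i$ the *current* group size. The
same expression covers any dimensionality because cells are enumerated
linearly. Size balance is measured by the Gini coefficient of the group
sizes, and the combined objective is

$$C = \frac{\sum_{i=1}^M \chi^2_i}{(1 - \text{Gini})^2},$$

with the squared denominator deliberately emphasizing comparable group
sizes. The sampler (`split_greedy()`) shuffles the cohort, assigns each
sample in turn to the group whose tentative placement minimizes $C$, and
repeats this pass from `iterations` independent random permutations,
keeping the lowest-cost result.

Notes on this objective, where the design was genuinely open:

* **$E$ scaling.** Expected frequencies are scaled by the *current* group
  size and recomputed as groups grow. This makes $\chi^2$ meaningful from
  the very first placements; scaling by a fixed final size would make
  early placements nearly free.
* **Full-cost evaluation.** Each candidate placement is scored by the full
  $C$ (the candidate group's updated $\chi^2$, all other groups' cached
  values, and the updated Gini), not by a per-group $\chi^2$ delta alone —
  the balance term must see every tentative move.
* **Ties** break toward the lowest group index, so a pass is a pure
  function of its permutation.
* **Incremental bookkeeping.** A tentative placement touches one histogram
  cell of one group, so each pass costs $N \times M$ vectorized cost
  evaluations over the grid's cells; runtime grows linearly in restarts
  and groups, and with the number of grid cells (hence geometrically in
  the number of dimensions for a fixed per-dimension bin count).

## Guard rails in the numerics

* **Out-of-support cells.** Cells whose target probability falls below
  $\varepsilon = 10^{-12}$ are excluded from the $\chi^2$ sum; a sample
  observed in such a cell adds a flat penalty of $10^6$ instead. This
  avoids divisions by (near-)zero while making out-of-support placements
  effectively forbidden whenever an alternative exists.
* **Empty groups** have $\chi^2 = 0$ by convention; imbalance is the Gini
  term's job, keeping the two penalty mechanisms orthogonal. When one
  group holds *all* samples, Gini $= 1$ and $C$ is the `Inf` sentinel —
  never an exception — so the argmin simply avoids that state (the very
  first sample of a pass, for which every placement gives Gini 1, goes to
  group 1).
* **Grid construction.** Equal-width bins spanning the *global* cohort
  range, widened by 0.1% per side so extreme samples fall strictly
  inside; a constant label dimension degrades to a single bin with a
  warning. One grid is shared by all groups and restarts — per-group
  grids would make $\chi^2$ values incomparable.
* **Bin count.** Default 20 bins per dimension: fine enough to resolve a
  ±10 kg shift on an ~80 kg range, coarse enough that a ~1000-sample
  group still populates its cells. It is a configurable trade-off, not a
  law.

## Feasibility: which targets a cohort can support

Any true partition satisfies, per label dimension,

$$\mu = \frac{1}{N}\sum_i n_i \mu_i, \qquad
  \sigma^2 = \frac{1}{N}\sum_i n_i\left(\sigma_i^2 + (\mu_i - \mu)^2\right).$$

These identities are exact **only under the population (1/n) variance
convention**, which the package uses throughout its evaluation code —
worth stressing because nearly every R default (`var`, `sd`) is the
sample (1/(n−1)) convention. `mixture_consistency()` returns the
residuals of both identities (zero to rounding for every real partition —
the test suite asserts this across all three splitters as a universal
regression check) and `feasible_sigma()` solves the variance identity for
the common per-group sd given shifted target means:
$\sigma_i = \sqrt{\sigma^2 - \sum_i w_i (\mu_i - \mu)^2}$. For the
reference moments (σ = 18.7 kg, 9.7 cm) and symmetric ±10 kg / ±5 cm
shifts this yields σᵢ ≈ 15.80 kg and ≈ 8.31 cm — the spreads used by all
shifted-target studies in the package.

## Evaluation metrics

Match between an achieved group and its target is summarized by the
binned Bhattacharyya distance
$BD = -\ln \sum_{\text{cells}} \sqrt{\hat p \, q}$, with $\hat p$ the
group's empirical cell frequencies and $q$ the target cell
probabilities: 0 for perfect overlap, `Inf` (a sentinel, not an error)
for disjoint supports. By default BD is computed on the sampler's own
grid so the report speaks the same language as the objective; for two
unit-variance Gaussians one σ apart the closed form gives
$BD = (\Delta\mu)^2 / 8\sigma^2 = 0.125$, and the test suite checks the
binned estimate converges to within 5% of it at 100 bins and $n = 10^5$.
Whether a correlated or independent-marginal 2-D target is used, cell
probabilities are renormalized over the grid before comparison.

## The synthetic cohort generator

`generate_anthro_cohort()` emulates the *printed global statistics* of
the motivating clinical cohort: N = 2078, weight 79.9 kg (σ 18.7),
height 171.6 cm (σ 9.7). Choices that go beyond those statistics:

* **Correlation.** The empirical weight–height correlation of the
  reference data is unpublished. The generator defaults to ρ = 0.5 — a
  mid-range value typical of adult anthropometric surveys — as an
  explicit, documented knob, not a reproduction.
* **Truncation.** Labels are restricted to 45–120 kg and 140–200 cm, the
  inclusion ranges of the prior work the reference application builds on.
  Truncation is enforced by rejection sampling (resample out-of-bounds
  draws, up to 100 passes), never by clipping: clipping would pile atoms
  onto the boundary bins and the sampler's histograms would chase that
  artifact as if it were real structure.
* **What is not emulated.** Real anthropometric data are not exactly
  Gaussian (skewed weight, sex bimodality, site effects, measurement
  error). Passing tests on these cohorts show the machinery is correct
  and that Gaussian-target splitting behaves as designed; they do not
  show that any particular clinical dataset supports any particular
  target configuration — that is precisely what `feasible_sigma()` and
  `mixture_consistency()` are for on real data.

Regional demographic presets (`preset_targets()`) carry published mean
weight/height per country and sex; heights are published in metres and
converted to the package's cm convention by the loader. The literature
table prints no standard deviations, so presets leave `sd` to the caller
— typically the feasibility solver.

## The federated demonstrator

`run_federation()` is a deliberately small stand-in for the reference
application's depth-image network: a linear model on synthetic features
built as a seeded random linear transform of the (standardized) labels
plus Gaussian noise, trained by deterministic full-batch gradient
descent and aggregated by size-weighted Federated Averaging. The
reference schedule is 50 rounds × 20 epochs; every client keeps an 80/20
local train/validation split whose validation loss is logged but never
acted on (no early stopping), so a run is a pure function of its seed.

The feature noise (default sd 2 on standardized labels) is the one
parameter that matters: it bounds how much information the features carry
about the labels, mirroring the real situation where a depth image only
partially determines weight. With informative-but-noisy features, a
client whose label distribution is restricted (strict median split) fits
a more attenuated regression than an IID client, and the averaged model
inherits that attenuation — the mode-collapse mechanism the demonstrator
exists to show. With near-noiseless features all scenarios converge to
the same model and nothing can be learned from the comparison.

`federation_bias_study()` runs four scenarios per seed (central, IID,
realistic greedy-sampled bias, strict median split) at desk scale —
cohort 600, 30 rounds × 10 epochs, 5 seeds by default, a couple of
seconds per seed — and reports final global test MAE per label plus the
prediction-variance ratio var(pred)/var(label), whose collapse under
strict splitting is the quantitative mode-collapse signature. The
acceptance suite asserts only the qualitative pattern (IID ≈ central;
variance ratio strict < IID; MAE ordering IID ≤ realistic ≤ strict in a
majority of seeds); absolute MAE values of the toy task are meaningless
and never compared to the reference application's.

## Scales used by the test suite

Chosen so the full suite runs in about a minute while leaving each
statistical check comfortable headroom:

* formula suites: exact, closed-form, instantaneous;
* Bhattacharyya convergence: $n = 10^5$, 100 bins;
* mixture-identity property sweep: 100 random cohorts across the three
  splitters;
* sampler recovery: equal-share two-component mixture pools of
  $n = 2000$, default sampler settings, medianed over 3 seeds (a single
  component mean carries ~0.5 kg of sampling noise at this size, so
  single-run assertions against a 1 kg tolerance would be noise-bound);
* split-quality studies: N = 2078, 30 restarts, 20 bins, 5 seeds —
  matching `scripts/acceptance.R`;
* federated studies: as above.

## Known limitations

* Gaussian targets only; non-Gaussian target families would need their
  own expected-probability computation (the only place the Gaussian
  assumption enters).
* Greedy multi-restart is a heuristic: on exhaustively solvable toy
  instances the suite asserts it is bounded by the true optimum on one
  side and beats the median random assignment on the other, but it
  carries no optimality guarantee, and the combined cost can prefer a few
  percent of size imbalance when that buys distributional fit.
* Cost evaluation scales with the number of grid cells, i.e.
  geometrically in the label dimensionality at fixed per-dimension bins;
  beyond 2–3 dimensions, coarser grids are advisable.
* Correlated (non-independent-marginal) expected probabilities are
  implemented for 2-D targets (bivariate-normal rectangle probabilities
  by numerical quadrature); higher-dimensional correlated targets fall
  back to independent marginals with a warning.
* The demonstrator is a linear model on synthetic features; it reproduces
  the *mechanism* of bias-induced degradation, not any architecture's
  absolute performance.
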