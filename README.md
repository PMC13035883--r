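# biasplit

Simulating realistic non-IID client data distributions for federated
learning pre-studies.

## The problem

Federated learning (FL) trains one model across several sites — say,
hospitals — without pooling their data. FL works best when every client's
data look like draws from the same population (IID). In practice, label
distributions differ systematically between sites: average patient weight
and height vary by region, so a "German clinic" client and a "Japanese
clinic" client see different label ranges, and that bias can badly degrade
the jointly trained model. Before rolling out an FL setup it is therefore
worth *simulating* the expected client bias: take the one pooled cohort
you do have, and carve it into client-specific subsets whose label
distributions match prescribed targets (e.g. literature demographics),
then rehearse the federated training on those subsets.

`biasplit` does exactly that, for cohorts with one or more continuous
labels:

* a **greedy multi-restart sampler** that partitions a cohort into M
  groups approximating per-group Gaussian targets,
* **feasibility machinery** telling you which targets a given cohort can
  support at all,
* **baseline splitters** (strict median cut, random IID),
* **evaluation metrics** (χ² histogram distance, binned Bhattacharyya
  distance, moment residuals),
* a **synthetic cohort generator** with regional demographic presets, and
* a desk-scale **federated-averaging demonstrator** on toy regression
  tasks.

## The method

Samples are shuffled and assigned sequentially; each sample goes to the
group that minimizes the combined cost

```
C = Σᵢ χ²ᵢ / (1 − Gini)²,
    χ²ᵢ   = Σ_cells (O − E)² / E          (per-group histogram distance
                                           to its target; E = nᵢ · p_cell)
    Gini  = Σᵢⱼ |sᵢ − sⱼ| / (2 (M−1) Σᵢ sᵢ)  (group-size imbalance)
```

on a histogram grid shared by all groups (1-D or multi-dimensional). The
squared Gini denominator keeps group sizes comparable; the χ² terms pull
each group toward its target shape. The whole pass is repeated from many
random permutations and the lowest-cost assignment wins.

Targets cannot be arbitrary: any partition of a cohort with global mean μ
and variance σ² obeys the mixture identities

```
μ  = (1/N) Σᵢ nᵢ μᵢ
σ² = (1/N) Σᵢ nᵢ (σᵢ² + (μᵢ − μ)²)
```

so prescribing shifted group means fixes how much spread remains for the
groups. `feasible_sigma()` solves the variance identity for the common
per-group σᵢ (and errors out when the shift is infeasible).

## Worked example

Split a weight/height cohort (N = 2078, weight 79.9 ± 18.7 kg, height
171.6 ± 9.7 cm — the printed statistics of a real clinical depth-camera
cohort) into a "lighter/shorter" and a "heavier/taller" client, shifted
±10 kg and ±5 cm from the global means:

```r
library(biasplit)

cohort <- generate_anthro_cohort(n = 2078, seed = 42)

global <- target_spec(c(weight = 79.9, height = 171.6), sd = c(18.7, 9.7))
sig <- feasible_sigma(global, rbind(global$mean - c(10, 5),
                                    global$mean + c(10, 5)))
sig
#>    weight    height
#> 15.801582  8.312039

targets <- list(target_spec(global$mean - c(10, 5), sd = sig),
                target_spec(global$mean + c(10, 5), sd = sig))
split <- split_greedy(cohort, targets, iterations = 30, seed = 42)
split
#> <cohort_split> greedy split of 2078 samples into 2 groups
#>   sizes: 1038, 1040
#>   cost C = 466.5 (chi2: 224.1, 241.5; Gini = 0.0010)

ev <- evaluate_split(cohort, split)
tidy(ev)[, c("group", "n", "mean_weight", "mean_height",
             "sd_weight", "sd_height", "bhattacharyya")]
#> # A tibble: 2 × 7
#>   group     n mean_weight mean_height sd_weight sd_height bhattacharyya
#>   <int> <int>       <dbl>       <dbl>     <dbl>     <dbl>         <dbl>
#> 1     1  1038        71.4        167.      13.2      7.74        0.0448
#> 2     2  1040        89.2        177.      13.9      8.19        0.0445
```

Reading the numbers: the feasibility solver says that after shifting the
group means by ±10 kg / ±5 cm, each group can have at most σ ≈ 15.8 kg /
8.3 cm. The sampler then produces two near-equal groups (Gini 0.001)
whose means sit within ~1.5 kg / 0.5 cm of the requested targets and
whose binned Bhattacharyya distances to the targets are ≈ 0.045 each
(0 = perfect overlap). `autoplot(split, cohort)` draws the two groups in
the weight–height plane; `autoplot(ev)` bars the per-group distances.

The same cohort can instead be cut with the baselines
(`split_median(cohort, "weight")`, `split_random(cohort, 2)`), and any
split can be rehearsed in a toy federation:

```r
task <- make_regression_task(cohort, seed = 1)
fit  <- run_federation(client_datasets(task, split),
                       rounds = 30, epochs = 10, seed = 1)
autoplot(fit)   # per-round global test MAE
```

`federation_bias_study()` packages the full comparison (central vs IID vs
realistic-bias vs strict-median federation) across seeds, reproducing the
qualitative pattern that IID federation matches centralized training
while strict splits collapse the model toward the pooled label mean.

A command-line wrapper over these functions ships in
`inst/cli/biasplit.R` (`generate`, `sample`, `split-median`,
`split-random`, `evaluate`, `fedsim` subcommands), reading cohort CSVs
and writing JSON split manifests with full seed provenance.

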