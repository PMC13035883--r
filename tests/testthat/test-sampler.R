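two_targets_1d <- function(mu = c(-2, 2), sd = 1) {
  list(target_spec(c(weight = mu[1]), sd = sd),
       target_spec(c(weight = mu[2]), sd = sd))
}

test_that("two samples at the two target means go to their matching groups", {
  co <- tiny_cohort(c(-2, 2))
  targets <- two_targets_1d()
  grid <- build_grid(co, 4)
  pass <- greedy_pass(co, targets, grid)
  expect_equal(pass$assignment, c(1L, 2L))
  swapped <- assignment_cost(co, c(2L, 1L), targets, grid)
  expect_lt(pass$cost$total_cost, swapped)
})

test_that("identical targets on a symmetric pool force near-equal sizes", {
  co <- tiny_cohort(c(-3, -2, -1, -0.5, 0.5, 1, 2, 3))
  tg <- target_spec(c(weight = 0), sd = 2)
  grid <- build_grid(co, 4)
  pass <- greedy_pass(co, list(tg, tg), grid)
  expect_lte(pass$cost$gini, 2 / nrow(co))
})

test_that("empty cohort yields an empty zero-cost assignment", {
  co <- tiny_cohort(numeric(0))
  grid <- build_grid(tiny_cohort(c(0, 1)), 2)
  pass <- greedy_pass(co, two_targets_1d(), grid)
  expect_length(pass$assignment, 0)
  expect_equal(pass$cost$total_cost, 0)
})

test_that("stored incremental cost equals the from-scratch recomputation", {
  set.seed(31)
  co <- tiny_cohort(rnorm(120, 0, 2))
  targets <- two_targets_1d(c(-1, 1), sd = 1.5)
  split <- split_greedy(co, targets, iterations = 3, bins_per_dim = 8, seed = 5)
  rc <- recompute_cost(co, split)
  expect_equal(split$cost$total_cost, rc$total_cost, tolerance = 1e-9)
  expect_equal(split$cost$chi2_per_group, rc$chi2_per_group, tolerance = 1e-9)
  expect_equal(split$cost$group_sizes, rc$group_sizes)
})

test_that("greedy cost is bounded by the exhaustive optimum and random medians", {
  set.seed(17)
  for (rep in 1:3) {
    co <- tiny_cohort(rnorm(9, 0, 2))
    targets <- two_targets_1d(c(-1.5, 1.5), sd = 1)
    grid <- build_grid(co, 3)
    pass <- greedy_pass(co, targets, grid)
    best <- exhaustive_best_cost(co, targets, grid)
    expect_gte(pass$cost$total_cost, best - 1e-9)
    rand_costs <- vapply(1:40, function(i) {
      g <- sample(1:2, nrow(co), replace = TRUE)
      assignment_cost(co, g, targets, grid)
    }, numeric(1))
    expect_lte(pass$cost$total_cost, median(rand_costs))
  }
})

test_that("multi-restart keeps the best pass and is deterministic", {
  set.seed(23)
  co <- tiny_cohort(rnorm(200, 0, 2))
  targets <- two_targets_1d(c(-1, 1), sd = 1.5)
  s1 <- split_greedy(co, targets, iterations = 1, seed = 42)
  s30 <- split_greedy(co, targets, iterations = 30, seed = 42)
  # Restart 1 uses the same child seed stream: best-of-30 can't be worse.
  expect_lte(s30$cost$total_cost, s1$cost$total_cost)
  expect_true(all(diff(cummin(s30$provenance$restart_costs)) <= 0))
  expect_equal(s30$provenance$restart_costs[s30$provenance$restart],
               s30$cost$total_cost)

  again <- split_greedy(co, targets, iterations = 30, seed = 42)
  expect_identical(s30$assignment, again$assignment)
  expect_identical(s30$provenance$child_seeds, again$provenance$child_seeds)
})

test_that("sampler recovers the components of an exact two-target mixture", {
  # At n = 2000 the generator's own sampling noise in a component mean is
  # about 0.5 kg / 0.26 cm (1 SE), so recovery is asserted on the median
  # worst-group deviation over three independent pools.
  w <- split_quality_study("weight", n = 2000, n_seeds = 3, seed = 301)
  expect_lt(median(w$mean_dev_weight), 1)
  h <- split_quality_study("height", n = 2000, n_seeds = 3, seed = 302)
  expect_lt(median(h$mean_dev_height), 0.5)
  expect_lte(median(w$gini), 0.05)
  expect_lte(median(h$gini), 0.05)
})

test_that("every splitter produces a true partition of the cohort", {
  set.seed(51)
  co <- tiny_cohort2(rnorm(150, 80, 15), rnorm(150, 170, 9))
  splits <- list(
    split_greedy(co, list(target_spec(c(weight = 75, height = 168), sd = c(14, 8)),
                          target_spec(c(weight = 85, height = 172), sd = c(14, 8))),
                 iterations = 2, bins_per_dim = 6, seed = 1),
    split_median(co, "weight"),
    split_random(co, 3, seed = 2)
  )
  for (sp in splits) {
    expect_setequal(sp$assignment$sample_id, co$sample_id)
    expect_false(anyDuplicated(sp$assignment$sample_id) > 0)
    expect_true(all(sp$assignment$group %in% seq_len(sp$n_groups)))
  }
})

test_that("median split thresholds strictly below the median", {
  co <- tiny_cohort(c(1, 2, 3, 4))
  sp <- split_median(co, 1)
  g1 <- co$weight[sp$assignment$group == 1]
  g2 <- co$weight[sp$assignment$group == 2]
  expect_setequal(g1, c(1, 2))
  expect_setequal(g2, c(3, 4))
  expect_lt(max(g1), min(g2))

  expect_warning(split_median(tiny_cohort(rep(5, 6))), "empty")
  expect_error(split_median(co, "height"), "label dimensions")
})

test_that("random split is uniform, IID in moments, and seed-stable", {
  co <- tiny_cohort(rnorm(1662, 80, 15))
  sp <- split_random(co, 2, seed = 9)
  sizes <- tabulate(sp$assignment$group, 2)
  expect_lt(abs(sizes[1] - sizes[2]), 4 * sqrt(1662))
  for (k in 1:2) {
    gm <- mean(co$weight[sp$assignment$group == k])
    expect_lt(abs(gm - mean(co$weight)), 3 * sd(co$weight) / sqrt(sizes[k]))
  }
  expect_identical(sp$assignment, split_random(co, 2, seed = 9)$assignment)
})
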