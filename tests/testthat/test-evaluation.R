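test_that("Bhattacharyya distance: identity, symmetry, disjoint supports", {
  p <- c(0.25, 0.25, 0.5)
  expect_equal(bhattacharyya_binned(c(1, 1, 2), p), 0)
  expect_identical(bhattacharyya_binned(c(4, 0), c(0, 1)), Inf)
  o1 <- c(3, 1, 0)
  o2 <- c(1, 2, 1)
  bd12 <- bhattacharyya_binned(o1, o2 / sum(o2))
  bd21 <- bhattacharyya_binned(o2, o1 / sum(o1))
  expect_equal(bd12, bd21)
  expect_gt(bd12, 0)
  expect_error(bhattacharyya_binned(c(0, 0), c(0.5, 0.5)), "empty")
})

test_that("binned Bhattacharyya converges to the closed-form Gaussian value", {
  # Unit-variance Gaussians one sigma apart: BD = (dmu)^2 / (8 sigma^2) = 0.125.
  n <- 1e5
  co <- generate_cohort(n, target_spec(c(x = 0), sd = 1), seed = 77)
  grid <- build_grid(co, 100)
  q <- expected_probabilities(grid, target_spec(c(x = 1), sd = 1))
  bd <- bhattacharyya_binned(observed_counts(co, grid), q)
  expect_lt(abs(bd - 0.125) / 0.125, 0.05)
})

test_that("mixture identities hold exactly for every splitter's partitions", {
  set.seed(67)
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    co <- tiny_cohort2(rnorm(n, 80, 15), rnorm(n, 170, 9))
    sp <- switch(1 + rep %% 3,
      split_random(co, sample(2:4, 1), seed = rep),
      split_median(co, sample(1:2, 1)),
      split_greedy(co, list(target_spec(c(weight = 75, height = 168), sd = c(14, 8)),
                            target_spec(c(weight = 85, height = 172), sd = c(14, 8))),
                   iterations = 1, bins_per_dim = 4, seed = rep)
    )
    ev <- suppressWarnings(evaluate_split(co, sp))
    expect_lt(max(abs(ev$residuals$mean_residual)), 1e-9)
    expect_lt(max(abs(ev$residuals$var_residual)), 1e-9)
    expect_equal(sum(ev$groups$n), n)
  }
})

test_that("whole-cohort trivial partition has exactly zero residuals", {
  co <- tiny_cohort(c(1, 4, 9, 16))
  res <- mixture_consistency(
    sizes = nrow(co),
    group_means = matrix(mean(co$weight), 1),
    group_vars = matrix(mean((co$weight - mean(co$weight))^2), 1),
    global_mean = mean(co$weight),
    global_var = mean((co$weight - mean(co$weight))^2)
  )
  expect_identical(res$mean_residual, 0)
  expect_identical(res$var_residual, 0)
})

test_that("infeasible hypothetical targets are flagged by the variance identity", {
  # Means +/- 10 with per-group sd equal to the global sd: the mixture
  # would need variance sigma^2 + 100, so the residual is -100.
  sigma2 <- 18.7^2
  res <- mixture_consistency(
    sizes = c(500, 500),
    group_means = matrix(c(69.9, 89.9), 2),
    group_vars = matrix(c(sigma2, sigma2), 2),
    global_mean = 79.9,
    global_var = sigma2
  )
  expect_equal(res$var_residual, -100)
  expect_equal(res$mean_residual, 0)
})

test_that("feasibility solver returns the exact variance-preserving sigma", {
  sw <- feasible_sigma(target_spec(c(weight = 79.9), sd = 18.7), c(69.9, 89.9))
  expect_equal(unname(sw), sqrt(18.7^2 - 100), tolerance = 1e-12)
  expect_equal(unname(sw), 15.80, tolerance = 1e-3)
  sh <- feasible_sigma(target_spec(c(height = 171.6), sd = 9.7), c(166.6, 176.6))
  expect_equal(unname(sh), sqrt(9.7^2 - 25), tolerance = 1e-12)
  expect_equal(unname(sh), 8.31, tolerance = 1e-3)
  # No shift: no shrinkage.
  s0 <- feasible_sigma(target_spec(c(w = 10), sd = 2), c(10, 10))
  expect_equal(unname(s0), 2)
  expect_error(
    feasible_sigma(target_spec(c(w = 0), sd = 1), c(-5, 5)),
    "Infeasible"
  )
})

test_that("solved sigmas close the loop: mixture of targets matches the global spec", {
  global <- target_spec(c(weight = 79.9), sd = 18.7)
  sig <- feasible_sigma(global, c(69.9, 89.9))
  co <- dplyr::bind_rows(
    generate_cohort(4000, target_spec(c(weight = 69.9), sd = sig), 1, "a"),
    generate_cohort(4000, target_spec(c(weight = 89.9), sd = sig), 2, "b")
  )
  expect_lt(abs(mean(co$weight) - 79.9), 1)
  expect_lt(abs(sd(co$weight) - 18.7), 0.5)
  # And the component-level moments satisfy the identity by construction.
  g <- rep(1:2, each = 4000)
  res <- mixture_consistency(
    sizes = c(4000, 4000),
    group_means = matrix(tapply(co$weight, g, mean), 2),
    group_vars = matrix(tapply(co$weight, g, function(x) mean((x - mean(x))^2)), 2),
    global_mean = mean(co$weight),
    global_var = mean((co$weight - mean(co$weight))^2)
  )
  expect_lt(abs(res$var_residual), 1e-9)
})

test_that("IID halves overlap the global distribution better than median halves", {
  co <- generate_cohort(2000, target_spec(c(weight = 79.9), sd = 18.7), seed = 15)
  grid <- build_grid(co, 20)
  global_target <- target_spec(c(weight = 79.9), sd = 18.7)
  glist <- list(global_target, global_target)

  iid <- evaluate_split(co, split_random(co, 2, seed = 3),
                        targets = glist, grid = grid)
  med <- evaluate_split(co, split_median(co, 1),
                        targets = glist, grid = grid)
  expect_true(all(med$groups$bhattacharyya > max(iid$groups$bhattacharyya)))
  # IID groups sit within 3 SE of the global moments.
  se <- sd(co$weight) / sqrt(min(iid$groups$n))
  expect_true(all(abs(iid$groups$mean_weight - mean(co$weight)) < 3 * se))
})
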