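# Small in-code fixtures shared across test files.

# A tiny deterministic 1-D cohort with known values.
tiny_cohort <- function(values, dim = "weight") {
  out <- tibble::tibble(sample_id = sprintf("s%d", seq_along(values)))
  out[[dim]] <- as.numeric(values)
  out
}

# A 2-D cohort with explicit weight/height columns.
tiny_cohort2 <- function(weight, height) {
  tibble::tibble(sample_id = sprintf("s%d", seq_along(weight)),
                 weight = as.numeric(weight), height = as.numeric(height))
}

# Direct, loop-based evaluation of the cost formulas: the brute-force
# oracle against which the vectorized implementations are compared.
chi2_direct <- function(observed, probs, eps = 1e-12, penalty = 1e6) {
  n <- sum(observed)
  if (n == 0) return(0)
  acc <- 0
  for (i in seq_along(observed)) {
    if (probs[i] >= eps) {
      e <- n * probs[i]
      acc <- acc + (observed[i] - e)^2 / e
    } else {
      acc <- acc + penalty * observed[i]
    }
  }
  acc
}

gini_direct <- function(sizes) {
  m <- length(sizes)
  acc <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) acc <- acc + abs(sizes[i] - sizes[j])
  acc / (2 * (m - 1) * sum(sizes))
}

cost_direct <- function(chi2s, sizes) {
  g <- gini_direct(sizes)
  if (g >= 1) Inf else sum(chi2s) / (1 - g)^2
}

# Exhaustive minimum of the combined cost over all 2^N two-group
# assignments of a tiny cohort (used to bound the greedy heuristic).
exhaustive_best_cost <- function(cohort, targets, grid) {
  n <- nrow(cohort)
  probs <- lapply(targets, function(t) expected_probabilities(grid, t))
  best <- Inf
  for (mask in 0:(2^n - 1)) {
    g <- as.integer(intToBits(mask))[seq_len(n)] + 1L
    sizes <- tabulate(g, 2L)
    chi2s <- vapply(1:2, function(k) {
      chi_squared(observed_counts(cohort[g == k, , drop = FALSE], grid),
                  probs[[k]])
    }, numeric(1))
    cc <- cost_direct(chi2s, sizes)
    if (cc < best) best <- cc
  }
  best
}

# Cost of an arbitrary assignment vector under the same machinery.
assignment_cost <- function(cohort, g, targets, grid) {
  probs <- lapply(targets, function(t) expected_probabilities(grid, t))
  sizes <- tabulate(g, length(targets))
  chi2s <- vapply(seq_along(targets), function(k) {
    chi_squared(observed_counts(cohort[g == k, , drop = FALSE], grid),
                probs[[k]])
  }, numeric(1))
  cost_direct(chi2s, sizes)
}
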