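new_cohort_split <- function(assignment, method, n_groups, cost = NULL,
                             provenance = list(), config = list(),
                             grid = NULL, targets = NULL) {
  structure(
    list(assignment = assignment, method = method, n_groups = n_groups,
         cost = cost, provenance = provenance, config = config,
         grid = grid, targets = targets),
    class = "cohort_split"
  )
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("<cohort_split>", x$method, "split of", nrow(x$assignment),
      "samples into", x$n_groups, "groups\n")
  cat("  sizes:", paste(tabulate(x$assignment$group, x$n_groups),
                        collapse = ", "), "\n")
  if (!is.null(x$cost)) {
    cat(sprintf("  cost C = %.4g (chi2: %s; Gini = %.4f)\n",
                x$cost$total_cost,
                paste(signif(x$cost$chi2_per_group, 4), collapse = ", "),
                x$cost$gini))
  }
  invisible(x)
}

# Per-group views of a cohort under a split, in group order.
split_groups <- function(cohort, split) {
  ord <- match(cohort$sample_id, split$assignment$sample_id)
  if (anyNA(ord)) abort("Split does not cover every cohort sample.")
  g <- split$assignment$group[ord]
  lapply(seq_len(split$n_groups), function(k) cohort[g == k, , drop = FALSE])
}

#' One greedy assignment pass over a fixed sample ordering
#'
#' Visits the cohort's samples in the given order and assigns each to the
#' group that minimizes the combined cost [total_cost()] after a tentative
#' placement, evaluating every group as a candidate. Ties break toward the
#' lowest group index. Group histograms, sizes, and chi-squared distances
#' are maintained incrementally -- a tentative placement touches only the
#' candidate group's histogram -- so one pass costs N x M cost evaluations.
#'
#' This is the inner loop of [split_greedy()]; it is exported so the greedy
#' mechanics can be studied (and tested) in isolation on a fixed
#' permutation.
#'
#' @param cohort A cohort tibble.
#' @param targets List of M >= 2 [target_spec()]s, one per group.
#' @param grid A shared [build_grid()] grid.
#' @param ordering Permutation of `1:nrow(cohort)` giving the visit order.
#' @return A list: `assignment` (integer group per cohort row), `cost`
#'   (final cost breakdown).
#' @export
greedy_pass <- function(cohort, targets, grid,
                        ordering = seq_len(nrow(cohort))) {
  check_cohort(cohort)
  m <- length(targets)
  if (m < 2) abort("Need at least two target groups.")
  n <- nrow(cohort)
  if (n == 0) {
    return(list(assignment = integer(0),
                cost = list(chi2_per_group = numeric(m), gini = NA_real_,
                            total_cost = 0, group_sizes = integer(m))))
  }
  cells <- cell_index(cohort, grid)
  nc <- n_cells(grid)
  eps <- 1e-12
  pen <- 1e6
  # Per-group in-support cell mask and probabilities, fixed for the run.
  probs <- lapply(targets, function(t) expected_probabilities(grid, t))
  keep <- lapply(probs, function(p) p >= eps)
  pk <- lapply(seq_len(m), function(g) probs[[g]][keep[[g]]])
  # Map full-grid cell index -> position in the kept-cell vector (0 = penalty cell).
  kpos <- lapply(seq_len(m), function(g) {
    pos <- integer(nc)
    pos[keep[[g]]] <- seq_len(sum(keep[[g]]))
    pos
  })
  counts <- lapply(seq_len(m), function(g) numeric(sum(keep[[g]])))
  pencount <- numeric(m)
  sizes <- numeric(m)
  chi2 <- numeric(m)
  assignment <- integer(n)
  cand <- numeric(m)
  for (s in ordering) {
    cell <- cells[s]
    for (g in seq_len(m)) {
      pos <- kpos[[g]][cell]
      ng <- sizes[g] + 1
      if (pos > 0L) {
        cnt <- counts[[g]]
        cnt[pos] <- cnt[pos] + 1
        e <- ng * pk[[g]]
        chi_g <- sum((cnt - e)^2 / e) + pen * pencount[g]
      } else {
        e <- ng * pk[[g]]
        chi_g <- sum((counts[[g]] - e)^2 / e) + pen * (pencount[g] + 1)
      }
      sz <- sizes
      sz[g] <- ng
      ch <- chi2
      ch[g] <- chi_g
      cand[g] <- total_cost(ch, sz)
    }
    g_best <- which.min(cand)
    if (!is.finite(cand[g_best])) g_best <- 1L
    # Commit.
    pos <- kpos[[g_best]][cell]
    if (pos > 0L) {
      counts[[g_best]][pos] <- counts[[g_best]][pos] + 1
    } else {
      pencount[g_best] <- pencount[g_best] + 1
    }
    sizes[g_best] <- sizes[g_best] + 1
    e <- sizes[g_best] * pk[[g_best]]
    chi2[g_best] <- sum((counts[[g_best]] - e)^2 / e) + pen * pencount[g_best]
    assignment[s] <- g_best
  }
  list(assignment = assignment, cost = cost_breakdown(chi2, sizes))
}

#' Greedy multi-restart cohort splitter
#'
#' The package's core sampler: runs `iterations` independent greedy passes
#' ([greedy_pass()]), each initialized with a freshly seeded random
#' permutation of the cohort, and keeps the pass with the lowest final
#' combined cost. Every sample is assigned to exactly one group -- no
#' sample is dropped. Deterministic given `seed`: a master seed spawns one
#' child seed per restart, all recorded in the result's provenance.
#'
#' @param cohort A cohort tibble.
#' @param targets List of M >= 2 [target_spec()]s (with `sd`), one per
#'   group.
#' @param iterations Number of random-permutation restarts (default 30).
#' @param bins_per_dim Histogram bins per label dimension for the shared
#'   grid (default 20).
#' @param seed Master integer seed.
#' @return A `cohort_split` with the winning assignment, its cost
#'   breakdown, and full provenance (master seed, winning restart, child
#'   seeds, per-restart costs).
#' @seealso [split_median()], [split_random()], [evaluate_split()]
#' @export
split_greedy <- function(cohort, targets, iterations = 30, bins_per_dim = 20,
                         seed = 1) {
  check_cohort(cohort)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1) {
    abort("`iterations` must be a positive integer.")
  }
  grid <- build_grid(cohort, bins_per_dim)
  child <- spawn_seeds(seed, iterations)
  best <- NULL
  best_restart <- NA_integer_
  restart_costs <- numeric(iterations)
  for (r in seq_len(iterations)) {
    ordering <- with_seed(child[r], sample.int(nrow(cohort)))
    pass <- greedy_pass(cohort, targets, grid, ordering)
    restart_costs[r] <- pass$cost$total_cost
    if (is.null(best) || pass$cost$total_cost < best$cost$total_cost) {
      best <- pass
      best_restart <- r
    }
  }
  new_cohort_split(
    assignment = tibble::tibble(sample_id = cohort$sample_id,
                                group = best$assignment),
    method = "greedy", n_groups = length(targets),
    cost = best$cost,
    provenance = list(seed = as.integer(seed), restart = best_restart,
                      child_seeds = as.integer(child),
                      restart_costs = restart_costs),
    config = list(iterations = iterations, bins_per_dim = bins_per_dim),
    grid = grid, targets = targets
  )
}

#' Strict median split along one label dimension
#'
#' The hard-cut baseline: thresholds a single label at its median, putting
#' samples strictly below the median in group 1 and the rest in group 2.
#' Produces two groups with non-overlapping label supports -- the extreme
#' non-IID scenario.
#'
#' @param cohort A cohort tibble.
#' @param dim Label dimension: a column name or index.
#' @return A `cohort_split` with two groups.
#' @export
split_median <- function(cohort, dim = 1) {
  check_cohort(cohort)
  dims <- label_dims(cohort)
  if (is.numeric(dim)) dim <- dims[dim]
  if (is.na(dim) || !dim %in% dims) {
    abort("`dim` must name one of the cohort's label dimensions.")
  }
  x <- cohort[[dim]]
  med <- median(x)
  g <- ifelse(x < med, 1L, 2L)
  if (min(tabulate(g, 2L)) == 0) {
    warn(paste0("Strict median split on '", dim,
                "' left one group empty (tied values at the median)."))
  }
  new_cohort_split(
    assignment = tibble::tibble(sample_id = cohort$sample_id, group = g),
    method = "median", n_groups = 2L,
    config = list(dim = dim, median = med)
  )
}

#' Random IID split
#'
#' Assigns every sample independently and uniformly to one of `n_groups`
#' groups: the IID federated baseline, whose groups share the global label
#' distribution in expectation.
#'
#' @param cohort A cohort tibble.
#' @param n_groups Number of groups (M >= 2).
#' @param seed Integer seed.
#' @return A `cohort_split`.
#' @export
split_random <- function(cohort, n_groups = 2, seed = 1) {
  check_cohort(cohort)
  n_groups <- as.integer(n_groups)
  if (is.na(n_groups) || n_groups < 2) abort("`n_groups` must be >= 2.")
  g <- with_seed(seed, sample.int(n_groups, nrow(cohort), replace = TRUE))
  new_cohort_split(
    assignment = tibble::tibble(sample_id = cohort$sample_id, group = g),
    method = "random", n_groups = n_groups,
    provenance = list(seed = as.integer(seed))
  )
}

#' Recompute a split's cost breakdown from scratch
#'
#' Rebuilds each group's histogram on the given grid and evaluates the
#' chi-squared distances, Gini, and combined cost directly -- an
#' independent check on the incrementally maintained cost stored by
#' [split_greedy()].
#'
#' @param cohort The cohort the split was computed on.
#' @param split A `cohort_split`.
#' @param targets Per-group [target_spec()]s; defaults to the split's own.
#' @param grid Grid; defaults to the split's own.
#' @return A cost breakdown list (`chi2_per_group`, `gini`, `total_cost`,
#'   `group_sizes`).
#' @export
recompute_cost <- function(cohort, split, targets = split$targets,
                           grid = split$grid) {
  if (is.null(targets) || is.null(grid)) {
    abort("`targets` and `grid` are required (the split carries none).")
  }
  groups <- split_groups(cohort, split)
  chi2 <- purrr::map2_dbl(groups, targets, function(gc, tg) {
    chi_squared(observed_counts(gc, grid), expected_probabilities(grid, tg))
  })
  cost_breakdown(chi2, vapply(groups, nrow, integer(1)))
}
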