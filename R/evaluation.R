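#' Binned Bhattacharyya distance between a group and its target
#'
#' `BD = -ln sum_cells sqrt(p_hat * q)`, where `p_hat` is the group's
#' empirical cell frequency and `q` the target's cell probability on the
#' same grid. 0 indicates perfect overlap; disjoint supports yield the
#' `Inf` sentinel (no overlap goes to infinity). Symmetric in its two
#' binned distributions.
#'
#' @param observed Integer cell counts of a non-empty group
#'   ([observed_counts()]).
#' @param expected Target cell probabilities ([expected_probabilities()]),
#'   same grid.
#' @return A non-negative number, `Inf` for disjoint supports.
#' @export
bhattacharyya_binned <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    abort("`observed` and `expected` must live on the same grid.")
  }
  n <- sum(observed)
  if (n == 0) abort("Bhattacharyya distance is undefined for an empty group.")
  bc <- sum(sqrt((observed / n) * expected))
  if (bc <= 0) return(Inf)
  -log(bc)
}

#' Mixture-moment residuals of a partition against global moments
#'
#' Any partition of a cohort of size N with global mean `mu` and variance
#' `sigma^2` into M subsets of sizes `n_i` with means `mu_i` and variances
#' `sigma_i^2` satisfies the exact mixture identities
#' `mu = (1/N) sum n_i mu_i` and
#' `sigma^2 = (1/N) sum n_i (sigma_i^2 + (mu_i - mu)^2)`.
#' This function returns the per-dimension residuals of both identities:
#' zero (to rounding) for any true partition, and non-zero for moment
#' combinations no partition can achieve -- which makes it a feasibility
#' check for hypothetical target distributions. The identities are exact
#' only under the population (1/n) variance convention, which this package
#' uses throughout.
#'
#' @param sizes Integer subset sizes `n_i` (length M).
#' @param group_means M x d matrix (or length-M vector for d = 1) of subset
#'   means.
#' @param group_vars M x d matrix of subset *population* variances.
#' @param global_mean Length-d global mean `mu`.
#' @param global_var Length-d global population variance `sigma^2`.
#' @return A list with numeric vectors `mean_residual` and `var_residual`
#'   (length d).
#' @export
mixture_consistency <- function(sizes, group_means, group_vars,
                                global_mean, global_var) {
  group_means <- rbind2(group_means)
  group_vars <- rbind2(group_vars)
  m <- length(sizes)
  if (nrow(group_means) != m || nrow(group_vars) != m) {
    abort("`group_means`/`group_vars` must have one row per group.")
  }
  n <- sum(sizes)
  w <- sizes / n
  mean_res <- global_mean - colSums(w * group_means)
  centered <- sweep(group_means, 2, global_mean, `-`)^2
  var_res <- global_var - colSums(w * (group_vars + centered))
  list(mean_residual = as.numeric(mean_res), var_residual = as.numeric(var_res))
}

rbind2 <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1)
}

# Population (1/n) column variances.
pop_var <- function(x) {
  x <- rbind2(x)
  colMeans(sweep(x, 2, colMeans(x), `-`)^2)
}

#' Feasible per-group standard deviations for shifted target means
#'
#' Because subset moments are tied to the global moments by the mixture
#' identities (see [mixture_consistency()]), target distributions cannot be
#' chosen arbitrarily: prescribing the group means fixes how much variance
#' remains for the groups themselves. Assuming a common per-group sigma
#' across all groups (the symmetric case), this solver returns, per
#' dimension, `sigma_i = sqrt(sigma^2 - sum_i share_i (mu_i - mu)^2)` --
#' the unique common spread that makes the variance identity hold exactly.
#'
#' @param global A [target_spec()] carrying the global mean and sd.
#' @param target_means M x d matrix (or length-M vector for d = 1) of
#'   per-group target means.
#' @param shares Desired size shares, summing to 1 (default equal).
#' @return Length-d numeric vector of feasible common sds, named by
#'   dimension.
#' @examples
#' # Global weight sd 18.7 kg, group means shifted +/- 10 kg:
#' feasible_sigma(target_spec(c(weight = 79.9), sd = 18.7),
#'                c(69.9, 89.9)) # ~15.80 kg
#' @export
feasible_sigma <- function(global, target_means,
                           shares = NULL) {
  stopifnot(inherits(global, "target_spec"))
  if (is.null(global$sd)) abort("`global` must carry standard deviations.")
  mu <- rbind2(target_means)
  m <- nrow(mu)
  if (m < 2) abort("Need at least two group means.")
  if (ncol(mu) != length(global$mean)) {
    abort("`target_means` dimensionality must match `global`.")
  }
  if (is.null(shares)) shares <- rep(1 / m, m)
  if (abs(sum(shares) - 1) > 1e-9) abort("`shares` must sum to 1.")
  wmean <- colSums(shares * mu)
  if (max(abs(wmean - global$mean)) > 1e-6 * max(1, abs(global$mean))) {
    warn("Share-weighted target means do not reproduce the global mean; the mean identity will not hold.")
  }
  spread <- colSums(shares * sweep(mu, 2, global$mean, `-`)^2)
  radicand <- global$sd^2 - spread
  bad <- which(radicand < 0)
  if (length(bad)) {
    abort(paste0(
      "Infeasible target means: dimension '",
      paste(names(global$mean)[bad], collapse = "', '"),
      "' would require negative group variance (shift exceeds the global spread)."
    ))
  }
  setNames(sqrt(radicand), names(global$mean))
}

#' Evaluate how well a split's groups match their targets
#'
#' Assembles, per group: size, achieved mean and population sd per label
#' dimension, and -- when targets are available -- the chi-squared distance
#' and binned Bhattacharyya distance to the group's target on a shared
#' grid. Also reports the global moments and the mixture-identity residuals
#' of the partition (zero for any true partition; a universal regression
#' check for every splitter).
#'
#' @param cohort The cohort the split partitions.
#' @param split A `cohort_split` from [split_greedy()], [split_median()],
#'   or [split_random()].
#' @param targets Optional per-group [target_spec()]s; defaults to the
#'   split's own (if any).
#' @param grid Optional grid; defaults to the split's own, else a fresh
#'   20-bins-per-dimension grid on the cohort.
#' @return A `split_evaluation`: list with a per-group tibble (`groups`),
#'   global moments (`global`), and mixture residuals (`residuals`).
#'   `tidy()` returns the per-group tibble, `glance()` a one-row summary.
#' @export
evaluate_split <- function(cohort, split, targets = NULL, grid = NULL) {
  check_cohort(cohort)
  targets <- targets %||% split$targets
  grid <- grid %||% split$grid %||% build_grid(cohort)
  dims <- label_dims(cohort)
  groups <- split_groups(cohort, split)
  sizes <- vapply(groups, nrow, integer(1))
  lab <- label_matrix(cohort, dims)
  gmean <- colMeans(lab)
  gvar <- pop_var(lab)

  per_group <- purrr::map_dfr(seq_along(groups), function(k) {
    gc <- groups[[k]]
    row <- tibble::tibble(group = k, n = nrow(gc))
    if (nrow(gc) > 0) {
      glab <- label_matrix(gc, dims)
      mu <- colMeans(glab)
      sg <- sqrt(pop_var(glab))
    } else {
      mu <- sg <- setNames(rep(NA_real_, length(dims)), dims)
    }
    for (d in dims) {
      row[[paste0("mean_", d)]] <- mu[[d]]
      row[[paste0("sd_", d)]] <- sg[[d]]
    }
    if (!is.null(targets)) {
      tg <- targets[[k]]
      for (d in dims) {
        row[[paste0("target_mean_", d)]] <- unname(tg$mean[d])
        row[[paste0("target_sd_", d)]] <-
          if (is.null(tg$sd)) NA_real_ else unname(tg$sd[d])
      }
      q <- expected_probabilities(grid, tg)
      o <- observed_counts(gc, grid)
      row$chi_squared <- chi_squared(o, q)
      row$bhattacharyya <- if (nrow(gc) > 0) bhattacharyya_binned(o, q) else NA_real_
    }
    row
  })

  stack_rows <- function(f) {
    mom <- vapply(groups, f, numeric(length(dims)))
    if (is.matrix(mom)) t(mom) else matrix(mom, ncol = 1)
  }
  mu_g <- stack_rows(function(gc) {
    if (nrow(gc) > 0) colMeans(label_matrix(gc, dims)) else rep(0, length(dims))
  })
  var_g <- stack_rows(function(gc) {
    if (nrow(gc) > 0) pop_var(label_matrix(gc, dims)) else rep(0, length(dims))
  })
  res <- mixture_consistency(sizes, mu_g, var_g, gmean, gvar)

  structure(
    list(groups = per_group,
         global = list(n = nrow(cohort), mean = gmean, var = gvar,
                       sd = sqrt(gvar)),
         residuals = res,
         method = split$method, grid = grid),
    class = "split_evaluation"
  )
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat("<split_evaluation> of a", x$method, "split, N =", x$global$n, "\n")
  print(x$groups)
  cat("  mixture residuals (mean):",
      paste(signif(x$residuals$mean_residual, 3), collapse = ", "), "\n")
  cat("  mixture residuals (var): ",
      paste(signif(x$residuals$var_residual, 3), collapse = ", "), "\n")
  invisible(x)
}
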