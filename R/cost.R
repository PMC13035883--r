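#' Chi-squared distance between a group histogram and its target
#'
#' The distance sum((O_i - E_i)^2 / E_i) over grid cells, where `O` are a
#' group's observed cell counts and `E_i = n * p_i` scales the target cell
#' probability `p_i` by the current group size `n = sum(observed)`. This
#' scaling makes the distance meaningful while a group is still being grown
#' sample by sample. The same formula covers 1-D and multi-dimensional
#' grids, since cells are enumerated linearly.
#'
#' Cells whose target probability falls below `eps` are excluded from the
#' sum; an observed sample landing in such an out-of-support cell instead
#' adds a flat `penalty` per sample, strongly discouraging the placement
#' without producing infinite or NaN costs. An empty group has distance 0
#' by convention -- size imbalance is penalized exclusively by the Gini
#' term, keeping the two mechanisms orthogonal.
#'
#' @param observed Integer cell counts, e.g. from [observed_counts()].
#' @param expected Cell probabilities from [expected_probabilities()]
#'   (same grid, same cell order).
#' @param eps Probability floor below which a cell is treated as
#'   out-of-support.
#' @param penalty Cost added per observed sample in an out-of-support cell.
#' @return A non-negative number.
#' @examples
#' chi_squared(c(10, 0), c(0.5, 0.5)) # E = (5, 5): 25/5 + 25/5 = 10
#' @export
chi_squared <- function(observed, expected, eps = 1e-12, penalty = 1e6) {
  if (length(observed) != length(expected)) {
    abort("`observed` and `expected` must live on the same grid.")
  }
  if (any(observed < 0)) abort("`observed` counts must be non-negative.")
  n <- sum(observed)
  if (n == 0) return(0)
  keep <- expected >= eps
  e <- n * expected[keep]
  sum((observed[keep] - e)^2 / e) + penalty * sum(observed[!keep])
}

#' Gini coefficient of group sizes
#'
#' Normalized mean absolute difference between group sizes,
#' `sum_ij |s_i - s_j| / (2 (M - 1) sum_i s_i)`: 0 when all groups are
#' equally sized, 1 when a single group holds every sample. Scale-invariant
#' in the sizes.
#'
#' @param sizes Vector of M >= 2 non-negative group sizes, not all zero.
#' @return A number in `[0, 1]`.
#' @examples
#' gini_coefficient(c(500, 500)) # 0
#' gini_coefficient(c(1, 3))     # 0.5
#' @export
gini_coefficient <- function(sizes) {
  m <- length(sizes)
  if (m < 2) abort("Gini needs at least two groups.")
  if (any(sizes < 0)) abort("Group sizes must be non-negative.")
  total <- sum(sizes)
  if (total == 0) abort("At least one group size must be positive.")
  sum(abs(outer(sizes, sizes, `-`))) / (2 * (m - 1) * total)
}

#' Combined sampling cost: chi-squared sum over a squared balance penalty
#'
#' The objective the greedy sampler minimizes:
#' `C = sum_i chi2_i / (1 - Gini)^2`, coupling distributional fit (the
#' per-group chi-squared distances to their targets) with group-size
#' balance. The denominator is squared to emphasize comparable group
#' sizes. When one group holds all samples (Gini = 1) the cost is the
#' `Inf` sentinel, never a division-by-zero error, so an argmin over
#' placements simply avoids that state whenever an alternative exists.
#'
#' @param chi2_per_group Non-negative chi-squared distance per group.
#' @param sizes Group sizes (same length, M >= 2).
#' @return A non-negative number, or `Inf` when Gini = 1.
#' @examples
#' total_cost(c(4, 6), c(1, 3)) # 10 / (1 - 0.5)^2 = 40
#' @export
total_cost <- function(chi2_per_group, sizes) {
  if (length(chi2_per_group) != length(sizes)) {
    abort("`chi2_per_group` and `sizes` must have equal length.")
  }
  if (any(chi2_per_group < 0)) abort("Chi-squared distances must be non-negative.")
  g <- gini_coefficient(sizes)
  if (g >= 1) return(Inf)
  sum(chi2_per_group) / (1 - g)^2
}

cost_breakdown <- function(chi2_per_group, sizes) {
  list(
    chi2_per_group = as.numeric(chi2_per_group),
    gini = gini_coefficient(sizes),
    total_cost = total_cost(chi2_per_group, sizes),
    group_sizes = as.integer(sizes)
  )
}
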