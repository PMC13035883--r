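#' Build a shared histogram grid over a cohort's label range
#'
#' Equal-width bins per dimension spanning the cohort's `[min, max]`,
#' widened by 0.1% of the range on each side so extreme samples always fall
#' strictly inside the support. One grid is built from the *global* cohort
#' and shared by every group so that per-group chi-squared values are
#' directly comparable.
#'
#' @param cohort A cohort tibble.
#' @param bins_per_dim Bins per dimension: a single integer (recycled) or
#'   one integer per label dimension. Default 20.
#' @return A `histogram_grid`: list of strictly increasing edge vectors,
#'   one per label dimension.
#' @export
build_grid <- function(cohort, bins_per_dim = 20) {
  check_cohort(cohort)
  dims <- label_dims(cohort)
  bins_per_dim <- as.integer(bins_per_dim)
  if (any(is.na(bins_per_dim)) || any(bins_per_dim < 1)) {
    abort("`bins_per_dim` must be positive integers.")
  }
  bins <- rep_len(bins_per_dim, length(dims))
  edges <- purrr::map2(dims, bins, function(d, k) {
    x <- cohort[[d]]
    lo <- min(x)
    hi <- max(x)
    if (lo == hi) {
      warn(paste0("Label '", d, "' is constant; using a single bin."))
      return(c(lo - 0.5, hi + 0.5))
    }
    pad <- 0.001 * (hi - lo)
    seq(lo - pad, hi + pad, length.out = k + 1L)
  })
  names(edges) <- dims
  structure(list(edges = edges, dims = dims,
                 bins = vapply(edges, function(e) length(e) - 1L, integer(1))),
            class = "histogram_grid")
}

#' @export
print.histogram_grid <- function(x, ...) {
  cat("<histogram_grid>", paste(x$bins, collapse = " x "), "bins over:\n")
  for (d in x$dims) {
    e <- x$edges[[d]]
    cat(sprintf("  %s: [%g, %g]\n", d, e[1], e[length(e)]))
  }
  invisible(x)
}

n_cells <- function(grid) prod(grid$bins)

# Linear (column-major over dimensions) cell index of every sample.
# Samples outside the grid are clamped into the boundary bins.
cell_index <- function(cohort, grid) {
  dims <- grid$dims
  if (!all(dims %in% names(cohort))) {
    abort("Cohort is missing label columns required by the grid.")
  }
  idx <- rep(1L, nrow(cohort))
  stride <- 1L
  for (d in dims) {
    e <- grid$edges[[d]]
    k <- length(e) - 1L
    j <- findInterval(cohort[[d]], e, all.inside = TRUE)
    idx <- idx + (j - 1L) * stride
    stride <- stride * k
  }
  idx
}

#' Observed histogram counts of a (sub)cohort on a grid
#'
#' @param cohort A cohort tibble (e.g. one group of a split).
#' @param grid A [build_grid()] grid.
#' @return Integer vector of counts, one per grid cell, summing to
#'   `nrow(cohort)`.
#' @export
observed_counts <- function(cohort, grid) {
  tabulate(cell_index(cohort, grid), nbins = n_cells(grid))
}

#' Expected cell probabilities of a Gaussian target on a grid
#'
#' Computes the probability a draw from `target` lands in each grid cell,
#' then renormalizes over the grid so the cell probabilities sum to one.
#' With independent marginals (the default) each cell probability is the
#' product of per-dimension Gaussian CDF differences; if `target` carries a
#' 2-D correlation matrix, bivariate-normal rectangle probabilities are
#' computed by numerical quadrature instead.
#'
#' @param grid A [build_grid()] grid.
#' @param target A [target_spec()] with `sd` set, matching the grid's
#'   dimensionality.
#' @return Numeric vector of cell probabilities (same cell order as
#'   [observed_counts()]), summing to 1.
#' @export
expected_probabilities <- function(grid, target) {
  stopifnot(inherits(grid, "histogram_grid"), inherits(target, "target_spec"))
  d <- length(grid$dims)
  if (length(target$mean) != d) {
    abort("Grid and target dimensionalities disagree.")
  }
  if (is.null(target$sd)) abort("`target` must carry standard deviations.")
  correlated <- !is.null(target$correlation) &&
    max(abs(target$correlation - diag(d))) > 1e-12
  if (correlated && d == 2) {
    p <- bivariate_cell_probs(grid, target)
  } else {
    if (correlated) {
      warn("Correlated expected probabilities are only supported in 2-D; using independent marginals.")
    }
    marg <- purrr::map(seq_len(d), function(j) {
      diff(pnorm(grid$edges[[j]], mean = target$mean[j], sd = target$sd[j]))
    })
    p <- Reduce(function(a, b) as.vector(outer(a, b)), marg)
  }
  total <- sum(p)
  if (!is.finite(total) || total < 1e-12) {
    abort("Target distribution has (numerically) no mass on the grid support.")
  }
  p / total
}

# P(a1 < X < b1, a2 < Y < b2) for a standardized bivariate normal with
# correlation rho, by quadrature over the first dimension. Probabilities
# for a full k1 x k2 grid are assembled from per-row integrals.
bivariate_cell_probs <- function(grid, target) {
  rho <- target$correlation[1, 2]
  s <- sqrt(1 - rho^2)
  z1 <- (grid$edges[[1]] - target$mean[1]) / target$sd[1]
  z2 <- (grid$edges[[2]] - target$mean[2]) / target$sd[2]
  k1 <- length(z1) - 1L
  k2 <- length(z2) - 1L
  p <- matrix(0, k1, k2)
  for (i in seq_len(k1)) {
    for (j in seq_len(k2)) {
      f <- function(x) {
        dnorm(x) * (pnorm((z2[j + 1] - rho * x) / s) - pnorm((z2[j] - rho * x) / s))
      }
      p[i, j] <- integrate(f, lower = z1[i], upper = z1[i + 1],
                           rel.tol = 1e-8, abs.tol = 1e-12)$value
    }
  }
  as.vector(p)
}

# Serializable snapshot of a grid (edges as plain lists) for manifests.
grid_to_list <- function(grid) {
  list(dims = as.list(grid$dims),
       bins = as.list(unname(grid$bins)),
       edges = purrr::map(grid$edges, as.numeric))
}

grid_from_list <- function(x) {
  edges <- purrr::map(x$edges, as.numeric)
  names(edges) <- as.character(unlist(x$dims))
  structure(list(edges = edges, dims = names(edges),
                 bins = vapply(edges, function(e) length(e) - 1L, integer(1))),
            class = "histogram_grid")
}
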