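#' Toy regression task standing in for an image-based estimator
#'
#' Builds a deterministic synthetic feature matrix from a cohort's labels:
#' a seeded random linear transform of the (standardized) labels plus
#' Gaussian noise, followed by feature standardization. The model's job is
#' then to regress the labels back out of the noisy features -- a
#' desk-scale stand-in for learning weight/height from depth images that
#' preserves the property under study: what the *label distribution* of
#' each client does to federated training. The transform is generated once
#' from the full cohort and shared by all clients.
#'
#' @param cohort A cohort tibble.
#' @param n_features Feature dimensionality p.
#' @param noise_sd Feature noise sd (on standardized scale). Nonzero noise
#'   is what makes restricted-range clients fit attenuated models.
#' @param seed Integer seed for the transform and noise.
#' @return A `toy_task`: list with `features` (n x p), `labels` (n x d),
#'   `sample_id`, and the generating `transform`.
#' @export
make_regression_task <- function(cohort, n_features = 8, noise_sd = 2,
                                 seed = 1) {
  check_cohort(cohort)
  dims <- label_dims(cohort)
  lab <- label_matrix(cohort, dims)
  d <- ncol(lab)
  mu <- colMeans(lab)
  sg <- sqrt(pop_var(lab))
  z <- sweep(sweep(lab, 2, mu, `-`), 2, sg, `/`)
  feats <- with_seed(seed, {
    a <- matrix(rnorm(d * n_features), d, n_features)
    z %*% a + noise_sd * matrix(rnorm(nrow(lab) * n_features),
                                nrow(lab), n_features)
  })
  fm <- colMeans(feats)
  fs <- sqrt(pop_var(feats))
  fs[fs == 0] <- 1
  feats <- sweep(sweep(feats, 2, fm, `-`), 2, fs, `/`)
  structure(
    list(features = feats, labels = lab, sample_id = cohort$sample_id,
         dims = dims,
         transform = list(seed = as.integer(seed), n_features = n_features,
                          noise_sd = noise_sd)),
    class = "toy_task"
  )
}

# Subset a task to the samples of one split group.
task_subset <- function(task, ids) {
  idx <- match(ids, task$sample_id)
  if (anyNA(idx)) abort("Task does not cover the requested samples.")
  list(features = task$features[idx, , drop = FALSE],
       labels = task$labels[idx, , drop = FALSE])
}

#' Split a toy task into per-client datasets
#'
#' @param task A [make_regression_task()] task.
#' @param split A `cohort_split` over the same samples.
#' @return List of M client datasets (`features`, `labels`).
#' @export
client_datasets <- function(task, split) {
  ids <- base::split(split$assignment$sample_id,
                     factor(split$assignment$group, levels = seq_len(split$n_groups)))
  lapply(ids, function(i) task_subset(task, i))
}

new_linear_model <- function(weights, bias) {
  if (any(!is.finite(weights)) || any(!is.finite(bias))) {
    abort("Model parameters must be finite.")
  }
  structure(list(weights = weights, bias = bias), class = "linear_model")
}

init_model <- function(p, d, seed = 1, scale = 0.01) {
  with_seed(seed, new_linear_model(
    weights = matrix(rnorm(p * d, sd = scale), p, d),
    bias = rep(0, d)
  ))
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$features)) newdata$features else newdata
  sweep(x %*% object$weights, 2, object$bias, `+`)
}

#' Full-batch gradient-descent training on one client
#'
#' Deterministic full-batch gradient descent on mean squared error: no
#' minibatch randomness, so a federated run is exactly reproducible from
#' its seed. Zero epochs returns the model unchanged.
#'
#' @param model A linear model (weights p x d, bias d).
#' @param data Client data: list with `features` (n x p) and `labels`
#'   (n x d).
#' @param epochs Number of gradient steps.
#' @param learning_rate Step size (features are standardized, so order 0.1
#'   is stable for moderate p).
#' @return The trained linear model.
#' @export
local_train <- function(model, data, epochs, learning_rate = 0.1) {
  x <- data$features
  y <- data$labels
  if (nrow(x) == 0) abort("Client data must be non-empty.")
  n <- nrow(x)
  w <- model$weights
  b <- model$bias
  for (e in seq_len(epochs)) {
    resid <- sweep(x %*% w, 2, b, `+`) - y
    if (any(!is.finite(resid))) {
      abort(paste0("Training diverged at epoch ", e,
                   " (non-finite loss); reduce the learning rate."))
    }
    w <- w - learning_rate * (2 / n) * crossprod(x, resid)
    b <- b - learning_rate * (2 / n) * colSums(resid)
  }
  new_linear_model(w, b)
}

mse_loss <- function(model, data) {
  mean((predict(model, data) - data$labels)^2)
}

#' Federated Averaging of client models
#'
#' Parameter-wise weighted mean of structurally identical client models,
#' with weights proportional to client dataset sizes -- the FedAvg
#' aggregation rule. The averaged parameters lie elementwise in the convex
#' hull of the client parameters.
#'
#' @param models List of M linear models with identical shapes.
#' @param sizes Positive client dataset sizes (length M).
#' @return The aggregated linear model.
#' @export
fedavg_round <- function(models, sizes) {
  if (length(models) != length(sizes)) {
    abort("One size per model is required.")
  }
  if (any(sizes <= 0)) abort("Client sizes must be positive.")
  shapes <- lapply(models, function(m) dim(m$weights))
  if (length(unique(vapply(shapes, paste, character(1), collapse = "x"))) != 1) {
    abort("Client models are not structurally identical.")
  }
  w <- sizes / sum(sizes)
  weights <- Reduce(`+`, purrr::map2(models, w, function(m, wi) wi * m$weights))
  bias <- Reduce(`+`, purrr::map2(models, w, function(m, wi) wi * m$bias))
  new_linear_model(weights, bias)
}

#' Run a desk-scale federated-averaging simulation
#'
#' Alternates full-batch local training on every client with FedAvg
#' aggregation for `rounds` rounds, starting from a common seeded
#' initialization. Each client keeps an 80/20 local train/validation
#' split (validation loss is logged per round, but never used for early
#' stopping, keeping runs deterministic). Global test MAE per label is
#' recorded each round if test data are supplied.
#'
#' @param clients List of client datasets (`features`, `labels`).
#' @param rounds Federation rounds (reference schedule: 50).
#' @param epochs Local epochs per round (reference schedule: 20).
#' @param learning_rate Local gradient-descent step size.
#' @param seed Seed for the common initialization and local splits.
#' @param test Optional global test data (`features`, `labels`).
#' @param dims Label dimension names for the history columns.
#' @param val_fraction Client-local validation fraction (default 0.2). Set
#'   to 0 to train on every client sample, e.g. when checking exact
#'   degenerate equivalences.
#' @return A `federation_fit`: final `model`, per-round `history` tibble,
#'   and the run configuration.
#' @export
run_federation <- function(clients, rounds = 50, epochs = 20,
                           learning_rate = 0.1, seed = 1, test = NULL,
                           dims = NULL, val_fraction = 0.2) {
  if (length(clients) < 1) abort("Need at least one client.")
  sizes <- vapply(clients, function(cl) nrow(cl$features), integer(1))
  if (any(sizes == 0)) abort("Every client needs at least one sample.")
  d <- ncol(clients[[1]]$labels)
  p <- ncol(clients[[1]]$features)
  dims <- dims %||% colnames(clients[[1]]$labels) %||% paste0("y", seq_len(d))
  child <- spawn_seeds(seed, length(clients) + 1)
  model <- init_model(p, d, seed = child[1])
  # Frozen per-client 80/20 train/validation index split.
  local <- purrr::map2(clients, seq_along(clients), function(cl, k) {
    n <- nrow(cl$features)
    n_val <- floor(val_fraction * n)
    val <- with_seed(child[k + 1], sample.int(n, n_val))
    tr <- if (length(val)) setdiff(seq_len(n), val) else seq_len(n)
    list(
      train = list(features = cl$features[tr, , drop = FALSE],
                   labels = cl$labels[tr, , drop = FALSE]),
      val = if (length(val)) list(features = cl$features[val, , drop = FALSE],
                                  labels = cl$labels[val, , drop = FALSE])
    )
  })
  train_sizes <- vapply(local, function(l) nrow(l$train$features), integer(1))
  history <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    fitted <- lapply(local, function(l) {
      local_train(model, l$train, epochs, learning_rate)
    })
    model <- fedavg_round(fitted, train_sizes)
    row <- tibble::tibble(round = r)
    val_losses <- vapply(seq_along(local), function(k) {
      if (is.null(local[[k]]$val)) NA_real_ else mse_loss(model, local[[k]]$val)
    }, numeric(1))
    row$mean_val_mse <- mean(val_losses, na.rm = TRUE)
    if (!is.null(test)) {
      err <- abs(predict(model, test) - test$labels)
      for (j in seq_len(d)) row[[paste0("mae_", dims[j])]] <- mean(err[, j])
    }
    history[[r]] <- row
  }
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         config = list(rounds = rounds, epochs = epochs,
                       learning_rate = learning_rate, seed = as.integer(seed),
                       n_clients = length(clients), client_sizes = sizes),
         dims = dims),
    class = "federation_fit"
  )
}

#' @export
print.federation_fit <- function(x, ...) {
  cat("<federation_fit>", x$config$n_clients, "clients,",
      x$config$rounds, "rounds x", x$config$epochs, "epochs\n")
  print(utils::tail(x$history, 1))
  invisible(x)
}

#' Per-bin mean absolute error of a model across the label range
#'
#' Bins the true labels and reports the model's MAE within each bin, per
#' label dimension, plus the overall MAE. Errors concentrating in the edge
#' bins are the signature of mode collapse: a model predicting near the
#' pooled label mean. Bins with no samples are reported with `NA` MAE,
#' not zero.
#'
#' @param model A linear model.
#' @param test Test data (`features`, `labels`).
#' @param bins Number of equal-width bins per label dimension.
#' @return A tibble: `label`, `bin`, `bin_center`, `n`, `mae`.
#' @export
binned_mae <- function(model, test, bins = 5) {
  pred <- predict(model, test)
  y <- test$labels
  d <- ncol(y)
  dims <- colnames(y) %||% paste0("y", seq_len(d))
  purrr::map_dfr(seq_len(d), function(j) {
    err <- abs(pred[, j] - y[, j])
    edges <- seq(min(y[, j]), max(y[, j]), length.out = bins + 1)
    idx <- findInterval(y[, j], edges, all.inside = TRUE)
    purrr::map_dfr(seq_len(bins), function(b) {
      sel <- idx == b
      tibble::tibble(
        label = dims[j], bin = b,
        bin_center = (edges[b] + edges[b + 1]) / 2,
        n = sum(sel),
        mae = if (any(sel)) mean(err[sel]) else NA_real_
      )
    })
  })
}

#' Overall per-label MAE of a model on test data
#'
#' @param model A linear model.
#' @param test Test data (`features`, `labels`).
#' @return Named numeric vector of MAE per label dimension.
#' @export
overall_mae <- function(model, test) {
  err <- abs(predict(model, test) - test$labels)
  dims <- colnames(test$labels) %||% paste0("y", seq_len(ncol(err)))
  setNames(colMeans(err), dims)
}
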