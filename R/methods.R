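#' Tidy a cohort split into a per-sample tibble
#'
#' @param x A `cohort_split`.
#' @param cohort Optional cohort tibble; if given, label columns are joined
#'   onto the per-sample assignment.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `group`, and (optionally) labels.
#' @method tidy cohort_split
#' @export
tidy.cohort_split <- function(x, cohort = NULL, ...) {
  out <- x$assignment
  if (!is.null(cohort)) {
    out <- dplyr::left_join(out, cohort, by = "sample_id")
  }
  out
}

#' One-row summary of a cohort split
#'
#' @param x A `cohort_split`.
#' @param ... Unused.
#' @return A tibble with method, group counts/sizes, Gini, and (for greedy
#'   splits) the final combined cost and winning restart.
#' @method glance cohort_split
#' @export
glance.cohort_split <- function(x, ...) {
  sizes <- tabulate(x$assignment$group, x$n_groups)
  tibble::tibble(
    method = x$method,
    n = nrow(x$assignment),
    n_groups = x$n_groups,
    min_size = min(sizes),
    max_size = max(sizes),
    gini = if (!is.null(x$cost)) x$cost$gini else gini_coefficient(sizes),
    total_cost = if (!is.null(x$cost)) x$cost$total_cost else NA_real_,
    restart = x$provenance$restart %||% NA_integer_
  )
}

#' @method tidy split_evaluation
#' @export
tidy.split_evaluation <- function(x, ...) x$groups

#' @method glance split_evaluation
#' @export
glance.split_evaluation <- function(x, ...) {
  g <- x$groups
  tibble::tibble(
    method = x$method,
    n = x$global$n,
    n_groups = nrow(g),
    max_bhattacharyya = if ("bhattacharyya" %in% names(g)) {
      max(g$bhattacharyya, na.rm = TRUE)
    } else NA_real_,
    max_abs_mean_residual = max(abs(x$residuals$mean_residual)),
    max_abs_var_residual = max(abs(x$residuals$var_residual))
  )
}

#' @method tidy federation_fit
#' @export
tidy.federation_fit <- function(x, ...) x$history

#' @method glance federation_fit
#' @export
glance.federation_fit <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  out <- tibble::tibble(
    rounds = x$config$rounds,
    epochs = x$config$epochs,
    n_clients = x$config$n_clients
  )
  dplyr::bind_cols(out, last[setdiff(names(last), "round")])
}

#' Plot a cohort split as label histograms or a scatter plot
#'
#' 1-D cohorts get overlaid per-group histograms; 2-D (or higher) cohorts
#' get a scatter plot of the first two label dimensions colored by group.
#'
#' @param object A `cohort_split`.
#' @param cohort The cohort tibble that was split.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_split
#' @export
autoplot.cohort_split <- function(object, cohort, ...) {
  df <- tidy(object, cohort)
  df$group <- factor(df$group)
  dims <- setdiff(names(df), c("sample_id", "group"))
  if (length(dims) == 1) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[dims[1]]], fill = .data$group)) +
      ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
      ggplot2::labs(title = paste0(object$method, " split"), fill = "group")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                                     colour = .data$group)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::labs(title = paste0(object$method, " split"), colour = "group")
  }
}

#' Plot per-group target match from an evaluation
#'
#' Bar chart of each group's binned Bhattacharyya distance to its target
#' (when targets were available to the evaluation).
#'
#' @param object A `split_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot split_evaluation
#' @export
autoplot.split_evaluation <- function(object, ...) {
  g <- object$groups
  if (!"bhattacharyya" %in% names(g)) {
    abort("Evaluation has no target distances to plot (no targets supplied).")
  }
  g$group <- factor(g$group)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$bhattacharyya)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(y = "Bhattacharyya distance to target", x = "group")
}

#' Plot federated training history
#'
#' Per-round global test MAE curves (one line per label dimension).
#'
#' @param object A `federation_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot federation_fit
#' @export
autoplot.federation_fit <- function(object, ...) {
  h <- object$history
  mae_cols <- grep("^mae_", names(h), value = TRUE)
  if (length(mae_cols) == 0) {
    abort("Federation was run without test data; no MAE history to plot.")
  }
  long <- tidyr::pivot_longer(h[c("round", mae_cols)], -"round",
                              names_to = "label", values_to = "mae",
                              names_prefix = "mae_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$round, y = .data$mae,
                                     colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "global test MAE", x = "federation round")
}
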