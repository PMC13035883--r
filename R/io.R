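MANIFEST_SCHEMA <- "biasplit-manifest-v1"

#' Read a cohort from CSV
#'
#' Expects the cohort CSV dialect: a `sample_id` header column followed by
#' one numeric column per label dimension, one row per sample, UTF-8, no
#' index column. Duplicate ids and non-numeric or non-finite labels are
#' rejected with the offending rows named.
#'
#' @param path Path to a cohort CSV file.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!"sample_id" %in% names(raw)) {
    abort("Cohort CSV must have a `sample_id` header column.")
  }
  if (ncol(raw) < 2) abort("Cohort CSV needs at least one label column.")
  out <- raw["sample_id"]
  for (d in setdiff(names(raw), "sample_id")) {
    v <- suppressWarnings(as.numeric(raw[[d]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      abort(paste0("Non-numeric or non-finite '", d, "' values at data rows: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    out[[d]] <- v
  }
  if (anyDuplicated(out$sample_id)) {
    dup <- unique(out$sample_id[duplicated(out$sample_id)])
    abort(paste0("Duplicate sample_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  check_cohort(out)
  out
}

#' Write a cohort to CSV
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

target_to_list <- function(t) {
  out <- list(mean = as.list(t$mean))
  if (!is.null(t$sd)) out$sd <- as.list(t$sd)
  if (!is.null(t$correlation)) out$correlation <- apply(t$correlation, 1, as.list)
  if (!is.null(t$truncation)) out$truncation <- apply(t$truncation, 2, as.list)
  if (!is.null(t$share)) out$share <- t$share
  out
}

target_from_list <- function(x) {
  num <- function(v) if (is.null(v)) NULL else unlist(v)
  corr <- if (!is.null(x$correlation)) {
    m <- do.call(rbind, lapply(x$correlation, unlist))
    unname(m)
  }
  trunc <- if (!is.null(x$truncation)) {
    do.call(cbind, lapply(x$truncation, unlist))
  }
  target_spec(mean = num(x$mean), sd = num(x$sd), correlation = corr,
              truncation = trunc, share = x$share)
}

#' Read per-group target specs from JSON
#'
#' The targets file is a JSON array of objects with fields `mean` (named
#' by label dimension), and optionally `sd`, `correlation`, `truncation`,
#' `share`.
#'
#' @param path Path to a targets JSON file.
#' @return List of [target_spec()]s.
#' @export
read_targets <- function(path) {
  x <- jsonlite::read_json(path)
  lapply(x, target_from_list)
}

#' Write a split manifest to JSON
#'
#' The manifest records everything needed to audit and reproduce a split:
#' schema version, splitter method and configuration, full provenance
#' (master seed, winning restart, child seeds, per-restart best costs),
#' the cost breakdown, the shared grid, the targets, and the per-sample
#' group assignment keyed by `sample_id`. Round-trips losslessly through
#' [read_manifest()].
#'
#' @param split A `cohort_split`.
#' @param path Output path.
#' @param cohort_file Optional provenance note: the cohort file the split
#'   was computed from.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(split, path, cohort_file = NULL) {
  stopifnot(inherits(split, "cohort_split"))
  obj <- list(
    schema = MANIFEST_SCHEMA,
    method = split$method,
    n_groups = split$n_groups,
    cohort_file = cohort_file,
    config = split$config,
    provenance = split$provenance,
    cost = split$cost,
    grid = if (!is.null(split$grid)) grid_to_list(split$grid),
    targets = if (!is.null(split$targets)) lapply(split$targets, target_to_list),
    assignment = as.list(setNames(split$assignment$group,
                                  split$assignment$sample_id))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a split manifest from JSON
#'
#' @param path Path to a manifest written by [write_manifest()].
#' @return A `cohort_split`.
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path)
  if (is.null(x$schema) || x$schema != MANIFEST_SCHEMA) {
    abort(paste0("Unsupported manifest schema: ",
                 x$schema %||% "<missing>", " (expected ", MANIFEST_SCHEMA, ")"))
  }
  if (is.null(x$assignment) || length(x$assignment) == 0) {
    abort("Manifest has no sample assignments.")
  }
  assignment <- tibble::tibble(
    sample_id = names(x$assignment),
    group = as.integer(unlist(x$assignment))
  )
  cost <- if (!is.null(x$cost)) {
    list(chi2_per_group = as.numeric(unlist(x$cost$chi2_per_group)),
         gini = x$cost$gini,
         total_cost = if (is.null(x$cost$total_cost)) Inf else as.numeric(x$cost$total_cost),
         group_sizes = as.integer(unlist(x$cost$group_sizes)))
  }
  new_cohort_split(
    assignment = assignment,
    method = x$method, n_groups = as.integer(x$n_groups),
    cost = cost,
    provenance = x$provenance %||% list(),
    config = x$config %||% list(),
    grid = if (!is.null(x$grid)) grid_from_list(x$grid),
    targets = if (!is.null(x$targets)) lapply(x$targets, target_from_list)
  )
}
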