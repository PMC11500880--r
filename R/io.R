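#' Read a prediction matrix from CSV
#'
#' Expects a header row of class names and one probability row per
#' sample. A leading `sample_id` column (by that name, or any
#' non-numeric first column) is accepted and preserved as row names.
#' Rows are validated against the prediction-matrix invariants; a row
#' whose sum deviates from 1 by more than `tol` is an error naming the
#' row, unless `renormalize = TRUE`, in which case offending rows are
#' rescaled with a warning.
#'
#' @param path CSV file path.
#' @param source_id Classifier identifier; defaults to the file name
#'   without extension.
#' @param renormalize Rescale out-of-tolerance rows instead of erroring.
#' @param tol Row-sum tolerance.
#' @return A `prediction_matrix`.
#' @export
load_predictions <- function(path, source_id = NULL, renormalize = FALSE,
                             tol = 1e-6) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L || nrow(df) < 1L) stop(sprintf("%s: empty prediction file", path))
  ids <- NULL
  first <- df[[1L]]
  if (identical(names(df)[1L], "sample_id") || is.character(first)) {
    ids <- as.character(first)
    df <- df[, -1L, drop = FALSE]
  }
  if (ncol(df) < 1L) stop(sprintf("%s: no probability columns", path))
  bad_num <- !vapply(df, is.numeric, logical(1L))
  if (any(bad_num)) {
    stop(sprintf("%s: non-numeric cell(s) in column(s) %s", path,
                 paste(names(df)[bad_num], collapse = ", ")))
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    stop(sprintf("%s: missing value at line %d", path,
                 which(rowSums(is.na(m)) > 0)[1L] + 1L))
  }
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0L) {
    if (renormalize) {
      warning(sprintf("%s: renormalized %d row(s) whose sums deviated from 1 (first at line %d)",
                      path, length(off), off[1L] + 1L), call. = FALSE)
      m <- m / rs
    } else {
      stop(sprintf("%s: line %d sums to %.8f (tolerance %g)",
                   path, off[1L] + 1L, rs[off[1L]], tol))
    }
  }
  pm <- prediction_matrix(m, class_names = colnames(m), source_id = source_id)
  if (!is.null(ids)) rownames(pm) <- ids
  pm
}

#' Write a prediction matrix to CSV
#'
#' Serializes probabilities with `digits` significant digits, class order
#' fixed by the header. Row names, when present, are written as a leading
#' `sample_id` column.
#'
#' @param pm A `prediction_matrix`.
#' @param path Output CSV path.
#' @param digits Significant digits (default 9).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pm, path, digits = 9L) {
  pm <- as_prediction_matrix(pm)
  df <- as.data.frame(signif(unclass(pm), digits))
  names(df) <- colnames(pm)
  if (!is.null(rownames(pm))) df <- cbind(sample_id = rownames(pm), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label vector from CSV
#'
#' Expects a `label` column of 0-based integer class indices (an optional
#' `sample_id` column is ignored for alignment, which is by row order).
#' A single unnamed column is also accepted.
#'
#' @param path CSV file path.
#' @param n_classes Optional class count for range validation.
#' @return Integer vector of 0-based labels.
#' @export
load_labels <- function(path, n_classes = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  col <- if ("label" %in% names(df)) df$label else {
    numcols <- which(vapply(df, is.numeric, logical(1L)))
    if (length(numcols) == 0L) stop(sprintf("%s: no numeric label column", path))
    df[[numcols[1L]]]
  }
  if (is.null(n_classes)) n_classes <- max(col) + 1L
  validate_labels(col, n_classes)
}

#' Write a label vector to CSV
#' @param labels Integer 0-based labels.
#' @param path Output CSV path.
#' @param sample_ids Optional ids for a leading column.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, sample_ids = NULL) {
  df <- data.frame(label = as.integer(labels))
  if (!is.null(sample_ids)) df <- cbind(sample_id = sample_ids, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a sample manifest
#'
#' CSV with columns `image_id`, `lesion_id`, `class_label`.
#'
#' @param path CSV file path.
#' @return `load_manifest`: a `sample_manifest` data frame.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "lesion_id", "class_label")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0L) {
    stop(sprintf("%s: manifest is missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(m$image_id)) stop(sprintf("%s: duplicate image_id", path))
  cl_per_lesion <- tapply(m$class_label, m$lesion_id, function(v) length(unique(v)))
  if (any(cl_per_lesion > 1L)) {
    stop(sprintf("%s: lesion(s) mapped to multiple classes: %s", path,
                 paste(names(cl_per_lesion)[cl_per_lesion > 1L], collapse = ", ")))
  }
  class(m) <- c("sample_manifest", class(m))
  m
}

#' @rdname load_manifest
#' @param manifest A `sample_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ensemble-tree configuration
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) describing either a built-in
#' topology — `{"topology": "mligpa_all"}` or `{"topology":
#' "mligpa_best3"}`, resolved through [ml_igpa_topology()] — or an
#' explicit nested node structure with fields `id`, `children`,
#' `selection`, `k`, `alpha`, validated by [build_tree()].
#'
#' @param path Configuration file path.
#' @param sources Optional known prediction-source names for leaf
#'   validation.
#' @return The root `ensemble_node`.
#' @export
load_tree_config <- function(path, sources = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(sub(".*\\.", "", path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (!is.null(cfg$topology)) {
    variant <- switch(as.character(cfg$topology),
                      mligpa_all = "all",
                      mligpa_best3 = "best3",
                      stop(sprintf("unknown built-in topology '%s' (use mligpa_all or mligpa_best3)",
                                   cfg$topology)))
    return(ml_igpa_topology(variant))
  }
  build_tree(cfg, sources = sources)
}

# JSON-serializable view of an ensemble report (plus run provenance)
report_to_list <- function(report, extra = list()) {
  entries <- lapply(unclass(report), function(e) {
    list(node_id = e$node_id, level = e$level, alpha = e$alpha,
         mode = e$mode, selection = e$selection,
         children = as.list(e$children), kept = as.list(e$kept),
         accuracies = as.list(e$accuracies),
         ig_values = as.list(e$ig_values),
         weights = as.list(e$weights))
  })
  c(list(package_version = as.character(utils::packageVersion("igpa")),
         nodes = entries), extra)
}

metrics_to_list <- function(rep) {
  pct <- function(v) round(100 * v, 2)
  out <- list(accuracy = pct(rep$accuracy), precision = pct(rep$precision),
              recall = pct(rep$recall), f1 = pct(rep$f1),
              specificity = pct(rep$specificity),
              averaging = as.list(rep$averaging))
  if (!is.null(rep$roc_auc_macro)) {
    out$roc_auc_macro <- rep$roc_auc_macro
    out$roc_auc_per_class <- as.list(rep$roc_auc)
  }
  out$per_class <- rep$per_class
  out
}
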