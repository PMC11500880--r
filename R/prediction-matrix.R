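#' Construct a prediction matrix
#'
#' A prediction matrix holds one classifier's class-probability outputs:
#' one row per sample, one column per class. Rows must be probability
#' vectors (entries in \eqn{[0, 1]}, each row summing to 1 within
#' tolerance).
#'
#' @param probs Numeric matrix, `n_samples x n_classes`.
#' @param class_names Character vector of class identifiers, one per
#'   column. Defaults to the column names of `probs`, or `C0, C1, ...`.
#' @param source_id Single string identifying the classifier that
#'   produced these probabilities.
#' @param tol Row-sum tolerance for validation.
#'
#' @return A numeric matrix of class `prediction_matrix` with column
#'   names set to `class_names` and a `source_id` attribute.
#' @examples
#' pm <- prediction_matrix(rbind(c(0.9, 0.1), c(0.2, 0.8)),
#'                         class_names = c("benign", "malignant"),
#'                         source_id = "cnn1")
#' @export
prediction_matrix <- function(probs, class_names = NULL, source_id = "classifier",
                              tol = 1e-6) {
  probs <- as.matrix(probs)
  storage.mode(probs) <- "double"
  if (is.null(class_names)) {
    class_names <- colnames(probs)
    if (is.null(class_names)) class_names <- paste0("C", seq_len(ncol(probs)) - 1L)
  }
  colnames(probs) <- as.character(class_names)
  attr(probs, "source_id") <- as.character(source_id)[1L]
  class(probs) <- c("prediction_matrix", class(probs))
  validate_prediction_matrix(probs, tol = tol)
  probs
}

#' Validate prediction-matrix invariants
#'
#' Checks that entries lie in \eqn{[0, 1]}, each row sums to 1 within
#' `tol`, and the number of class names matches the number of columns.
#'
#' @param x A matrix-like object of probabilities.
#' @param tol Row-sum tolerance.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_prediction_matrix <- function(x, tol = 1e-6) {
  if (!is.matrix(x) || !is.numeric(x)) stop("prediction matrix must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("prediction matrix must be non-empty")
  if (length(colnames(x)) != ncol(x)) stop("class_names length must equal number of columns")
  if (anyNA(x) || any(!is.finite(x))) stop("prediction matrix contains non-finite entries")
  if (any(x < 0) || any(x > 1)) {
    bad <- which(x < 0 | x > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("probability outside [0, 1] at row %d, column %d", bad[1L], bad[2L]))
  }
  rs <- rowSums(x)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0L) {
    stop(sprintf("row %d sums to %.8f (tolerance %g)", off[1L], rs[off[1L]], tol))
  }
  invisible(x)
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> source_id = %s, %d samples x %d classes\n",
              source_id(x), nrow(x), ncol(x)))
  y <- x
  attr(y, "source_id") <- NULL
  class(y) <- "matrix"
  print(utils::head(y, 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Classifier identifier of a prediction matrix
#' @param x A `prediction_matrix`.
#' @return The `source_id` string ("classifier" if unset).
#' @export
source_id <- function(x) {
  sid <- attr(x, "source_id")
  if (is.null(sid)) "classifier" else sid
}

# Coerce plain numeric matrices on entry to combiner/metric functions.
as_prediction_matrix <- function(x, tol = 1e-6) {
  if (inherits(x, "prediction_matrix")) {
    validate_prediction_matrix(x, tol = tol)
    x
  } else {
    prediction_matrix(x, tol = tol)
  }
}

#' Validate a label vector against a prediction matrix
#'
#' Labels are 0-based class indices, aligned by row order with the
#' prediction matrices they annotate.
#'
#' @param labels Integer vector of 0-based class indices.
#' @param n_classes Number of classes the labels must index into.
#' @param n_samples Optional expected length.
#' @return The labels as an integer vector.
#' @export
validate_labels <- function(labels, n_classes, n_samples = NULL) {
  if (length(labels) == 0L) stop("label vector is empty")
  if (anyNA(labels)) stop("label vector contains NA")
  li <- as.integer(round(labels))
  if (any(abs(labels - li) > 1e-9)) stop("labels must be integers")
  if (any(li < 0L) || any(li >= n_classes)) {
    stop(sprintf("labels must lie in [0, %d)", n_classes))
  }
  if (!is.null(n_samples) && length(li) != n_samples) {
    stop(sprintf("label vector length %d does not match sample count %d",
                 length(li), n_samples))
  }
  li
}

# Shared shape/class-name check for lists of prediction matrices.
check_aligned_preds <- function(preds, tol = 1e-6) {
  if (!is.list(preds) || length(preds) == 0L) {
    stop("need a non-empty list of prediction matrices")
  }
  preds <- lapply(preds, as_prediction_matrix, tol = tol)
  ref <- preds[[1L]]
  for (i in seq_along(preds)[-1L]) {
    p <- preds[[i]]
    if (!identical(dim(p), dim(ref))) {
      stop(sprintf("prediction matrix %d has shape %dx%d, expected %dx%d",
                   i, nrow(p), ncol(p), nrow(ref), ncol(ref)))
    }
    if (!identical(colnames(p), colnames(ref))) {
      stop(sprintf("prediction matrix %d has different class names", i))
    }
  }
  preds
}
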