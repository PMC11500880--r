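#' Binary entropy in bits
#'
#' Entropy of a two-outcome random variable with success probability `p`:
#' \eqn{H(p) = -p \log_2 p - (1-p) \log_2 (1-p)}, with
#' \eqn{0 \log_2 0 := 0}. The result lies in \eqn{[0, 1]} bits and is
#' symmetric about 0.5.
#'
#' @param p Numeric vector of probabilities in \eqn{[0, 1]}.
#' @return Entropy in bits, same length as `p`.
#' @examples
#' binary_entropy(0.5)  # 1 bit
#' binary_entropy(c(0, 1))  # both 0
#' @export
binary_entropy <- function(p) {
  if (length(p) == 0L || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Per-sample correctness indicator of a classifier
#'
#' Marks each sample 1 if the classifier's maximum-probability class
#' equals the true label, else 0. Ties in the maximum probability are
#' broken toward the lowest class index, deterministically.
#'
#' @param pred A `prediction_matrix`.
#' @param truth Integer vector of 0-based true class indices, one per row
#'   of `pred`.
#' @return Integer vector of 0/1 bits with attribute `accuracy` (the mean).
#' @export
correctness <- function(pred, truth) {
  pred <- as_prediction_matrix(pred)
  truth <- validate_labels(truth, n_classes = ncol(pred), n_samples = nrow(pred))
  hard <- predicted_labels(pred)
  bits <- as.integer(hard == truth)
  attr(bits, "accuracy") <- mean(bits)
  bits
}

#' Hard class assignments of a prediction matrix
#'
#' @param pred A `prediction_matrix`.
#' @return Integer vector of 0-based argmax labels (ties to the lowest
#'   class index).
#' @export
predicted_labels <- function(pred) {
  pred <- as_prediction_matrix(pred)
  max.col(unclass(pred), ties.method = "first") - 1L
}

#' Information gain of a correctness vector
#'
#' The gain is the reduction in binary entropy of the correct/incorrect
#' indicator relative to a reference entropy `h_prior` (default 1 bit, the
#' no-information state), scaled by the ensemble level `alpha`:
#' \deqn{IG = \alpha \, \max(0,\; h_{prior} - H(acc))}{IG = alpha * max(0, h_prior - H(acc))}
#' where `acc` is the fraction of correct samples. In the default
#' multiplicative mode `alpha` cancels when gains are later normalized
#' into weights; the opt-in `"exponent"` mode instead computes
#' \eqn{(h_{prior} - H(acc))^\alpha}, which amplifies the dominance of
#' stronger classifiers as the level grows.
#'
#' Accuracies below 0.5 make the entropy gap symmetric (a 10%-accurate
#' classifier would score like a 90% one); a warning is raised there
#' rather than silently re-weighting.
#'
#' @param bits Integer 0/1 correctness vector (from [correctness()]).
#' @param alpha Positive ensemble level.
#' @param h_prior Reference entropy in bits, in \eqn{[0, 1]}.
#' @param mode `"multiplicative"` (default) or `"exponent"`.
#' @return An object of class `ig_score`: a list with `value`,
#'   `accuracy`, `h_correctness`, `h_prior`, `alpha`, `mode`, and
#'   `low_accuracy` (whether the sub-coin-flip warning fired).
#' @examples
#' b <- c(1L, 1L, 1L, 0L)  # 75% accurate
#' information_gain(b, alpha = 1)
#' @export
information_gain <- function(bits, alpha = 1, h_prior = 1,
                             mode = c("multiplicative", "exponent")) {
  mode <- match.arg(mode)
  if (length(bits) == 0L) stop("correctness vector is empty")
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) stop("correctness bits must be 0 or 1")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) stop("alpha must be a positive number")
  if (h_prior < 0 || h_prior > 1) stop("h_prior must lie in [0, 1]")
  acc <- mean(bits)
  low <- acc < 0.5
  if (low) {
    warning(sprintf(
      "accuracy %.4f is below 0.5; the entropy-gap information gain no longer reflects skill",
      acc), call. = FALSE)
  }
  h <- binary_entropy(acc)
  gap <- max(0, h_prior - h)
  value <- if (mode == "multiplicative") alpha * gap else gap^alpha
  structure(
    list(value = value, accuracy = acc, h_correctness = h, h_prior = h_prior,
         alpha = alpha, mode = mode, low_accuracy = low),
    class = "ig_score")
}

#' @export
print.ig_score <- function(x, ...) {
  cat(sprintf("<ig_score> IG = %.6f (accuracy %.4f, H = %.6f bits, alpha = %g, mode = %s)\n",
              x$value, x$accuracy, x$h_correctness, x$alpha, x$mode))
  invisible(x)
}

#' Information-gain proportioned weights
#'
#' Normalizes a set of information-gain values into ensemble weights:
#' \eqn{w_i = IG_i / \sum_j IG_j}. When every gain is exactly zero (all
#' classifiers at coin-flip correctness) the ratio is undefined; the
#' uniform vector is returned with a warning.
#'
#' @param scores A list of `ig_score` objects, or a numeric vector of
#'   non-negative gain values.
#' @param source_ids Optional classifier identifiers used to name the
#'   result.
#' @return Numeric weight vector summing to 1, named by `source_ids` when
#'   given.
#' @examples
#' igpa_weights(c(0.6, 0.3, 0.1))
#' @export
igpa_weights <- function(scores, source_ids = NULL) {
  if (length(scores) == 0L) stop("need at least one information-gain score")
  values <- if (is.list(scores)) {
    vapply(scores, function(s) {
      if (inherits(s, "ig_score")) s$value else as.numeric(s)
    }, numeric(1L))
  } else {
    as.numeric(scores)
  }
  if (anyNA(values) || any(!is.finite(values))) stop("information-gain values must be finite")
  if (any(values < 0)) stop("information-gain values must be non-negative")
  total <- sum(values)
  w <- if (total == 0) {
    warning("total information gain is zero; falling back to uniform weights",
            call. = FALSE)
    rep(1 / length(values), length(values))
  } else {
    values / total
  }
  if (!is.null(source_ids)) names(w) <- as.character(source_ids)
  w
}
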