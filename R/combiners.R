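#' Weighted average of prediction matrices
#'
#' Fuses aligned probability matrices into one:
#' \eqn{E_{jk} = \sum_i w_i \, p_{ijk}} for sample `j` and class `k`.
#' When the inputs are row-stochastic and the weights sum to 1 the output
#' is row-stochastic too (a convex combination).
#'
#' @param preds List of `prediction_matrix` objects sharing shape and
#'   class names.
#' @param w Numeric weight vector aligned with `preds`; must be
#'   non-negative and sum to 1 within `1e-9`.
#' @param source_id Identifier for the fused output.
#' @return The fused `prediction_matrix`.
#' @export
weighted_average <- function(preds, w, source_id = "ensemble") {
  preds <- check_aligned_preds(preds)
  w <- as.numeric(w)
  if (length(w) != length(preds)) stop("weight vector length must match number of classifiers")
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1")
  out <- matrix(0, nrow(preds[[1L]]), ncol(preds[[1L]]))
  for (i in seq_along(preds)) out <- out + w[i] * unclass(preds[[i]])
  prediction_matrix(out, class_names = colnames(preds[[1L]]), source_id = source_id)
}

#' Softmax averaging baseline
#'
#' Unweighted arithmetic mean of the probability matrices; identical to
#' [weighted_average()] with the uniform weight vector.
#'
#' @inheritParams weighted_average
#' @return The fused `prediction_matrix`.
#' @export
softmax_average <- function(preds, source_id = "softmax_average") {
  preds <- check_aligned_preds(preds)
  weighted_average(preds, rep(1 / length(preds), length(preds)), source_id = source_id)
}

#' Information-gain proportioned averaging (IGPA)
#'
#' The full fusion rule: score each classifier's correctness on a
#' weighting label set, convert the scores to information gains, normalize
#' the gains into weights, and average the probability matrices under
#' those weights.
#'
#' By default the correctness used for weighting is computed on `preds`
#' themselves against `weighting_truth`. To keep the weighting partition
#' separate from the evaluation partition, pass `weighting_preds`: the
#' same classifiers' outputs on a held-out (e.g. validation) set, aligned
#' with `weighting_truth`; the resulting weights are then applied to
#' `preds`.
#'
#' @inheritParams weighted_average
#' @param weighting_truth Integer 0-based labels aligned with the rows of
#'   the weighting matrices.
#' @param alpha Positive ensemble level fed to [information_gain()].
#' @param h_prior Reference entropy in bits.
#' @param mode `"multiplicative"` (default) or `"exponent"`; see
#'   [information_gain()].
#' @param weighting_preds Optional list of prediction matrices (aligned
#'   with `preds` by position) used to compute correctness.
#' @return A list with `fused` (the combined `prediction_matrix`),
#'   `weights`, `scores` (per-classifier `ig_score`s), `accuracies`,
#'   `alpha`, and `mode`.
#' @examples
#' p1 <- prediction_matrix(rbind(c(0.9, 0.1), c(0.2, 0.8)), source_id = "a")
#' p2 <- prediction_matrix(rbind(c(0.6, 0.4), c(0.6, 0.4)), source_id = "b")
#' igpa_ensemble(list(p1, p2), weighting_truth = c(0L, 1L))$weights
#' @export
igpa_ensemble <- function(preds, weighting_truth, alpha = 1, h_prior = 1,
                          mode = c("multiplicative", "exponent"),
                          weighting_preds = NULL, source_id = "igpa") {
  mode <- match.arg(mode)
  preds <- check_aligned_preds(preds)
  wpreds <- if (is.null(weighting_preds)) preds else check_aligned_preds(weighting_preds)
  if (length(wpreds) != length(preds)) {
    stop("weighting_preds must have one matrix per classifier in preds")
  }
  scores <- lapply(wpreds, function(p) {
    information_gain(correctness(p, weighting_truth),
                     alpha = alpha, h_prior = h_prior, mode = mode)
  })
  ids <- vapply(preds, function(p) source_id(p), character(1L))
  w <- igpa_weights(scores, source_ids = ids)
  list(fused = weighted_average(preds, w, source_id = source_id),
       weights = w,
       scores = scores,
       accuracies = stats::setNames(vapply(scores, `[[`, numeric(1L), "accuracy"), ids),
       alpha = alpha, mode = mode)
}

#' Majority voting baseline
#'
#' Each classifier votes its maximum-probability class per sample; the
#' modal class wins. Vote ties are broken by the largest summed
#' probability over the tied classes across classifiers, then by the
#' lowest class index — both deterministic.
#'
#' @inheritParams weighted_average
#' @return A list with `labels` (integer 0-based winners) and `fused`
#'   (the one-hot `prediction_matrix` of those winners).
#' @export
majority_vote <- function(preds, source_id = "majority_vote") {
  preds <- check_aligned_preds(preds)
  n <- nrow(preds[[1L]]); k <- ncol(preds[[1L]])
  votes <- vapply(preds, predicted_labels, integer(n))
  votes <- matrix(votes, nrow = n)  # n x n_classifiers
  prob_sum <- Reduce(`+`, lapply(preds, unclass))
  winners <- integer(n)
  for (j in seq_len(n)) {
    counts <- tabulate(votes[j, ] + 1L, nbins = k)
    top <- which(counts == max(counts))
    if (length(top) > 1L) {
      best <- top[prob_sum[j, top] == max(prob_sum[j, top])]
      top <- min(best)
    }
    winners[j] <- top[1L] - 1L
  }
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), winners + 1L)] <- 1
  list(labels = winners,
       fused = prediction_matrix(onehot, class_names = colnames(preds[[1L]]),
                                 source_id = source_id))
}

# Printed fixed-weight presets, best-ranked first.
fixed_weight_profiles <- list(
  wa4 = c(0.30, 0.26, 0.24, 0.20),
  wa3 = c(0.35, 0.35, 0.30)
)

#' Fixed-weight averaging baseline
#'
#' Ranks the classifiers by accuracy on a label set and assigns a fixed
#' weight profile best-to-worst, then averages. The named presets encode
#' the conventional comparison weights: `"wa4"` assigns 30/26/24/20% over
#' exactly four classifiers and `"wa3"` assigns 35/35/30% over exactly
#' three. An arbitrary numeric weight vector (summing to 1, one entry per
#' rank) is also accepted.
#'
#' Accuracy ties are broken by input order (stable ranking).
#'
#' @inheritParams weighted_average
#' @param ranking_truth Integer 0-based labels used to rank the
#'   classifiers by accuracy.
#' @param profile `"wa4"`, `"wa3"`, or a numeric weight vector ordered
#'   best-to-worst.
#' @return A list with `fused` (the combined `prediction_matrix`),
#'   `weights` (in input order), and `ranking` (input positions
#'   best-to-worst).
#' @export
fixed_weight_average <- function(preds, ranking_truth, profile = "wa4",
                                 source_id = "fixed_weight_average") {
  preds <- check_aligned_preds(preds)
  if (is.character(profile)) {
    profile <- match.arg(profile, names(fixed_weight_profiles))
    prof <- fixed_weight_profiles[[profile]]
    if (length(preds) != length(prof)) {
      stop(sprintf("profile '%s' requires exactly %d classifiers, got %d",
                   profile, length(prof), length(preds)))
    }
  } else {
    prof <- as.numeric(profile)
    if (length(prof) != length(preds)) stop("weight profile length must match number of classifiers")
    if (any(prof < 0) || abs(sum(prof) - 1) > 1e-9) stop("weight profile must be non-negative and sum to 1")
  }
  acc <- vapply(preds, function(p) mean(correctness(p, ranking_truth)), numeric(1L))
  ranking <- order(-acc)  # stable: ties keep input order
  w <- numeric(length(preds))
  w[ranking] <- prof
  names(w) <- vapply(preds, function(p) source_id(p), character(1L))
  list(fused = weighted_average(preds, w, source_id = source_id),
       weights = w, ranking = ranking)
}

#' Select the top-k classifiers by accuracy
#'
#' Returns the `k` classifiers with the highest accuracy on `truth`.
#' Accuracy ties are broken by lexicographically smaller `source_id`; the
#' returned subset preserves the original relative order of the inputs.
#'
#' @inheritParams weighted_average
#' @param truth Integer 0-based labels used to score accuracy.
#' @param k Number of classifiers to keep, `1 <= k <= length(preds)`.
#' @return The selected sub-list of `preds`, with attribute `selected`
#'   (the chosen input positions, in original order).
#' @export
select_top_k <- function(preds, truth, k) {
  preds <- check_aligned_preds(preds)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(preds)) {
    stop(sprintf("k must lie in [1, %d]", length(preds)))
  }
  k <- as.integer(k)
  acc <- vapply(preds, function(p) mean(correctness(p, truth)), numeric(1L))
  ids <- vapply(preds, source_id, character(1L))
  ranked <- order(-acc, ids)
  keep <- sort(ranked[seq_len(k)])
  out <- preds[keep]
  attr(out, "selected") <- keep
  out
}
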