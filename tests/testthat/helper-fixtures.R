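# Fixture builders and independent oracles used across the suite.

# random row-stochastic prediction matrix
random_pred <- function(n, k, source_id = "clf", concentrate = NULL) {
  m <- matrix(stats::rexp(n * k), n, k)
  if (!is.null(concentrate)) {
    m[cbind(seq_len(n), concentrate + 1L)] <-
      m[cbind(seq_len(n), concentrate + 1L)] + 5
  }
  prediction_matrix(m / rowSums(m), source_id = source_id)
}

# prediction matrix whose argmax labels are exactly `hard`
onehotish_pred <- function(hard, k, source_id = "clf", top = 0.9) {
  n <- length(hard)
  m <- matrix((1 - top) / (k - 1), n, k)
  m[cbind(seq_len(n), hard + 1L)] <- top
  prediction_matrix(m, source_id = source_id)
}

# classifier with a prescribed set of correct rows against `truth`
pred_with_correct <- function(truth, correct_rows, k, source_id = "clf") {
  hard <- truth
  wrong <- setdiff(seq_along(truth), correct_rows)
  hard[wrong] <- (truth[wrong] + 1L) %% k
  onehotish_pred(hard, k, source_id = source_id)
}

# --- independent oracles -------------------------------------------------

# naive per-sample loop version of the weighted average (Eq.-10 style)
oracle_weighted_average <- function(preds, w) {
  n <- nrow(preds[[1]]); k <- ncol(preds[[1]])
  out <- matrix(0, n, k)
  for (j in seq_len(n)) {
    for (cc in seq_len(k)) {
      acc <- 0
      for (i in seq_along(preds)) acc <- acc + w[i] * preds[[i]][j, cc]
      out[j, cc] <- acc
    }
  }
  out
}

# naive per-sample majority vote with summed-prob then lowest-index ties
oracle_majority_vote <- function(preds) {
  n <- nrow(preds[[1]]); k <- ncol(preds[[1]])
  out <- integer(n)
  for (j in seq_len(n)) {
    votes <- integer(0)
    for (p in preds) {
      row <- p[j, ]
      votes <- c(votes, which(row == max(row))[1])
    }
    counts <- tabulate(votes, nbins = k)
    tied <- which(counts == max(counts))
    if (length(tied) > 1) {
      sums <- sapply(tied, function(cc) sum(sapply(preds, function(p) p[j, cc])))
      tied <- tied[sums == max(sums)]
    }
    out[j] <- min(tied) - 1L
  }
  out
}

# pairwise-comparison AUC estimator: P(score_pos > score_neg) + 0.5 ties
oracle_auc_pairwise <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# random confusion matrix with positive total count
random_confusion <- function(k, max_count = 40) {
  matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k,
         dimnames = list(paste0("C", 1:k - 1L), paste0("C", 1:k - 1L)))
}
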