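test_that("weighted average is the convex combination of its inputs", {
  pm <- random_pred(5, 3, "a")
  expect_equal(unclass(weighted_average(list(pm, pm), c(0.3, 0.7))),
               unclass(pm), ignore_attr = TRUE)
  expect_equal(unclass(weighted_average(list(pm), 1.0)), unclass(pm),
               ignore_attr = TRUE)
  e1 <- prediction_matrix(matrix(c(1, 0), 1))
  e2 <- prediction_matrix(matrix(c(0, 1), 1))
  fused <- weighted_average(list(e1, e2), c(0.75, 0.25))
  expect_equal(as.numeric(fused), c(0.75, 0.25))
  expect_error(weighted_average(list(e1, random_pred(2, 2)), c(0.5, 0.5)), "shape")
  expect_error(weighted_average(list(e1, e2), c(0.5, 0.4)), "sum to 1")
  expect_error(weighted_average(list(e1, e2), c(1.5, -0.5)), "non-negative")
})

test_that("weighted average and majority vote agree with naive per-sample loops", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    k <- sample(2:7, 1)
    m <- sample(2:10, 1)
    preds <- lapply(seq_len(m), function(ii) random_pred(n, k, paste0("c", ii)))
    w <- igpa_weights(stats::rexp(m))
    expect_equal(unclass(weighted_average(preds, w)),
                 oracle_weighted_average(preds, w),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(majority_vote(preds)$labels, oracle_majority_vote(preds))
  }
})

test_that("softmax averaging equals uniform weighted averaging", {
  set.seed(3)
  preds <- lapply(1:5, function(i) random_pred(30, 4, paste0("c", i)))
  expect_equal(unclass(softmax_average(preds)),
               unclass(weighted_average(preds, rep(0.2, 5))),
               ignore_attr = TRUE, tolerance = 1e-12)
  pm <- random_pred(4, 3)
  expect_equal(unclass(softmax_average(list(pm, pm))), unclass(pm),
               ignore_attr = TRUE)
})

test_that("weighted-average output stays row-stochastic on randomized inputs", {
  set.seed(19)
  for (i in 1:50) {
    m <- sample(2:8, 1)
    preds <- lapply(seq_len(m), function(ii) random_pred(20, 5))
    w <- igpa_weights(stats::rexp(m))
    out <- weighted_average(preds, w)
    expect_true(all(out >= 0 & out <= 1))
    expect_equal(rowSums(out), rep(1, 20), tolerance = 1e-9)
  }
})

test_that("majority vote resolves ties by summed probability then lowest index", {
  # strict majority: classifiers voting (0, 0, 1) on every sample -> 0
  preds <- lapply(c(0L, 0L, 1L), function(v) onehotish_pred(rep(v, 4), 2, top = 0.8))
  expect_equal(majority_vote(preds)$labels, rep(0L, 4))
  # 1-1 vote split, class 0 carries more total probability (1.3 vs 0.7)
  a <- prediction_matrix(matrix(c(0.9, 0.1), 1))
  b <- prediction_matrix(matrix(c(0.4, 0.6), 1))
  expect_equal(majority_vote(list(a, b))$labels, 0L)
  # identical classifiers vote their own argmax
  pm <- random_pred(25, 4)
  expect_equal(majority_vote(list(pm, pm, pm))$labels, predicted_labels(pm))
  # one-hot fused output is row-stochastic with a single 1
  oh <- majority_vote(list(a, b))$fused
  expect_equal(rowSums(oh), 1)
  expect_true(all(oh %in% c(0, 1)))
})

test_that("igpa ensemble composes correctness, gain, weights and averaging", {
  set.seed(5)
  truth <- sample(0:2, 40, replace = TRUE)
  # single classifier: identity with weight 1
  solo <- onehotish_pred(truth, 3, "solo")
  fit <- igpa_ensemble(list(solo), truth)
  expect_equal(unclass(fit$fused), unclass(solo), ignore_attr = TRUE)
  expect_equal(unname(fit$weights), 1)
  # equal empirical accuracy -> unweighted mean
  p1 <- pred_with_correct(truth, 1:30, 3, "p1")
  p2 <- pred_with_correct(truth, 11:40, 3, "p2")
  fit2 <- igpa_ensemble(list(p1, p2), truth)
  expect_equal(unclass(fit2$fused), unclass(softmax_average(list(p1, p2))),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unname(fit2$weights), c(0.5, 0.5))
})

test_that("the strongest simulated classifier gets the dominant igpa weight", {
  sim <- simulate_predictions(simulator_config(
    n_samples = 2000, classifier_accuracies = c(0.95, 0.70, 0.70),
    correlation = 0, seed = 123))
  fit <- igpa_ensemble(sim$preds, sim$truth)
  expect_gt(fit$weights[1], fit$weights[2])
  expect_gt(fit$weights[1], fit$weights[3])
})

test_that("fixed-weight profiles assign the printed percentages by accuracy rank", {
  set.seed(9)
  truth <- sample(0:3, 50, replace = TRUE)
  # identical classifiers: any convex profile returns the common input
  pm <- onehotish_pred(truth, 4)
  same <- fixed_weight_average(list(pm, pm, pm, pm), truth, "wa4")
  expect_equal(unclass(same$fused), unclass(pm), ignore_attr = TRUE,
               tolerance = 1e-12)
  # accuracies (0.7, 0.9, 0.8, 0.6) -> weights (0.24, 0.30, 0.26, 0.20) in input order
  mk <- function(acc, id) pred_with_correct(truth, seq_len(round(50 * acc)), 4, id)
  fit <- fixed_weight_average(list(mk(0.7, "a"), mk(0.9, "b"), mk(0.8, "c"), mk(0.6, "d")),
                              truth, "wa4")
  expect_equal(unname(fit$weights), c(0.24, 0.30, 0.26, 0.20))
  # the third-ranked classifier of the wa3 profile carries 30%
  fit3 <- fixed_weight_average(list(mk(0.9, "a"), mk(0.8, "b"), mk(0.7, "c")),
                               truth, "wa3")
  expect_equal(unname(fit3$weights), c(0.35, 0.35, 0.30))
  expect_equal(unname(fit3$weights[fit3$ranking[3]]), 0.30)
  expect_error(fixed_weight_average(list(pm, pm), truth, "wa4"), "exactly 4")
  expect_error(fixed_weight_average(list(pm, pm), truth, "wa3"), "exactly 3")
})

test_that("top-k selection ranks by accuracy with lexicographic id tie-breaks", {
  set.seed(21)
  truth <- sample(0:3, 100, replace = TRUE)
  mk <- function(acc, id) pred_with_correct(truth, seq_len(round(100 * acc)), 4, id)
  preds <- list(mk(0.92, "w"), mk(0.90, "x"), mk(0.93, "y"), mk(0.91, "z"))
  sel <- select_top_k(preds, truth, 3)
  expect_equal(attr(sel, "selected"), c(1L, 3L, 4L))
  # identity at k = m
  expect_equal(attr(select_top_k(preds, truth, 4), "selected"), 1:4)
  # tie at equal accuracy: lexicographically smaller source_id wins
  tie <- list(mk(0.9, "beta"), mk(0.9, "alpha"))
  expect_equal(attr(select_top_k(tie, truth, 1), "selected"), 2L)
  expect_error(select_top_k(preds, truth, 5), "\\[1, 4\\]")
  expect_error(select_top_k(preds, truth, 0), "\\[1, 4\\]")
})
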