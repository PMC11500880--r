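test_that("tree construction computes levels bottom-up and validates the config", {
  leaf1 <- ensemble_node("n1", "src_a")
  expect_equal(leaf1$level, 1L)
  expect_equal(leaf1$alpha, 1)
  two <- ensemble_node("root", list(leaf1, "src_b"))
  expect_equal(two$level, 2L)
  expect_equal(two$alpha, 2)  # alpha defaults to the node's level

  cfg <- list(id = "root", children = list(
    list(id = "left", children = c("a", "b")),
    list(id = "right", children = c("c", "d"), selection = "top_k", k = 1)))
  root <- build_tree(cfg, sources = letters[1:4])
  expect_equal(sort(tree_nodes(root)), c("left", "right", "root"))
  expect_equal(root$level, 2L)

  expect_error(build_tree(cfg, sources = c("a", "b", "c")), "unknown leaf")
  dup <- list(id = "x", children = list(list(id = "x", children = "a")))
  expect_error(build_tree(dup, sources = "a"), "duplicate")
  expect_error(ensemble_node("n", c("a", "b", "c", "d"), selection = "top_k", k = 5),
               "\\[1, 4\\]")
})

test_that("the reference topology has 36 leaves, 13 nodes and the documented grouping", {
  for (variant in c("all", "best3")) {
    root <- ml_igpa_topology(variant)
    expect_equal(length(tree_leaves(root)), 36L)
    expect_equal(length(tree_nodes(root)), 13L)
    expect_equal(root$node_id, "DMIX")
    expect_equal(root$level, 3L)
    expect_equal(root$alpha, 3)
    groups <- vapply(root$children, `[[`, character(1), "node_id")
    expect_equal(groups, c("DN", "MN", "IX"))
    mn <- root$children[[2]]
    expect_equal(vapply(mn$children, `[[`, character(1), "node_id"),
                 c("MNv1", "MNv2", "MNv3L"))
    expect_equal(mn$alpha, 2)
    for (l1 in unlist(lapply(root$children, `[[`, "children"), recursive = FALSE)) {
      expect_equal(l1$alpha, 1)
      expect_length(l1$children, 4L)
    }
  }
  expect_equal(ml_igpa_topology("best3")$selection, "top_k")
  expect_equal(ml_igpa_topology("best3")$k, 3L)
  expect_equal(ml_igpa_topology("all")$selection, "all")
})

test_that("running a tree reduces to its algebraic special cases", {
  set.seed(31)
  truth <- sample(0:3, 60, replace = TRUE)
  solo <- onehotish_pred(truth, 4, "only")
  res <- run_tree(ensemble_node("root", "only"), list(only = solo), truth)
  expect_equal(unclass(res$fused), unclass(solo), ignore_attr = TRUE)

  # identical correctness at every leaf -> flat unweighted mean of all leaves
  leaves <- lapply(1:4, function(i) {
    pm <- pred_with_correct(truth, 1:45, 4, paste0("s", i))
  })
  names(leaves) <- paste0("s", 1:4)
  cfg <- list(id = "root", children = list(
    list(id = "l", children = c("s1", "s2")),
    list(id = "r", children = c("s3", "s4"))))
  res2 <- run_tree(build_tree(cfg, names(leaves)), leaves, truth)
  expect_equal(unclass(res2$fused), unclass(softmax_average(leaves)),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("tree output is row-stochastic and invariant to child permutation", {
  set.seed(57)
  sim <- simulate_predictions(simulator_config(
    n_samples = 300, classifier_accuracies = c(0.95, 0.9, 0.85, 0.8),
    seed = 57))
  store <- setNames(sim$preds, paste0("s", 1:4))
  cfg <- list(id = "root", children = c("s1", "s2", "s3", "s4"))
  out1 <- run_tree(build_tree(cfg, names(store)), store, sim$truth)
  expect_equal(rowSums(out1$fused), rep(1, 300), tolerance = 1e-9)
  cfg_perm <- list(id = "root", children = c("s3", "s1", "s4", "s2"))
  out2 <- run_tree(build_tree(cfg_perm, names(store)), store, sim$truth)
  expect_equal(unclass(out1$fused), unclass(out2$fused), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("multiplicative alpha cancellation propagates through the whole tree", {
  sim <- simulate_predictions(simulator_config(
    n_samples = 250, classifier_accuracies = seq(0.75, 0.95, length.out = 6),
    seed = 99))
  store <- setNames(sim$preds, paste0("s", 1:6))
  cfg <- function(a1, a2) list(id = "root", alpha = a2, children = list(
    list(id = "l", children = c("s1", "s2", "s3"), alpha = a1),
    list(id = "r", children = c("s4", "s5", "s6"), alpha = a1)))
  res_lvl <- run_tree(build_tree(cfg(1, 2), names(store)), store, sim$truth)
  res_one <- run_tree(build_tree(cfg(1, 1), names(store)), store, sim$truth)
  expect_equal(unclass(res_lvl$fused), unclass(res_one$fused),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the 36-leaf best-3 tree runs end-to-end and reports 13 weight vectors", {
  accs <- rep(c(0.95, 0.92, 0.89, 0.86), 9)  # four heads per backbone
  sim <- simulate_predictions(simulator_config(
    n_samples = 1000, classifier_accuracies = accs, seed = 2024))
  store <- setNames(sim$preds, ml_igpa_sources())
  res <- run_tree(ml_igpa_topology("best3"), store, sim$truth)
  expect_length(res$report, 13L)
  for (e in res$report) {
    expect_equal(sum(e$weights), 1, tolerance = 1e-9)
    expect_true(all(e$weights >= 0))
  }
  # best-3 selection keeps 3 of 4 heads at level 1
  lvl1 <- Filter(function(e) e$level == 1L, unclass(res$report))
  expect_length(lvl1, 9L)
  for (e in lvl1) {
    expect_length(e$children, 4L)
    expect_length(e$kept, 3L)
  }
  expect_equal(rowSums(res$fused), rep(1, 1000), tolerance = 1e-9)
})

test_that("a strongly superior group earns more than a third of the root weight", {
  accs <- c(rep(0.97, 12), rep(0.80, 24))  # DN backbones far stronger
  sim <- simulate_predictions(simulator_config(
    n_samples = 2000, classifier_accuracies = accs, correlation = 0,
    seed = 77))
  store <- setNames(sim$preds, ml_igpa_sources())
  res <- run_tree(ml_igpa_topology("all"), store, sim$truth)
  root <- res$report$DMIX
  expect_gt(root$weights[["DN"]], 1 / 3)
})

test_that("single-level igpa equals flat igpa and softmax under equal accuracy", {
  set.seed(101)
  truth <- sample(0:6, 80, replace = TRUE)
  preds <- lapply(1:5, function(i) pred_with_correct(truth, 1:70, 7, paste0("c", i)))
  sl <- single_level_igpa(preds, truth)
  expect_length(sl$report, 1L)
  flat <- igpa_ensemble(preds, truth, alpha = 1)
  expect_equal(unclass(sl$fused), unclass(flat$fused), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unclass(sl$fused), unclass(softmax_average(preds)),
               ignore_attr = TRUE, tolerance = 1e-9)
  solo <- single_level_igpa(preds[1], truth)
  expect_equal(unclass(solo$fused), unclass(preds[[1]]), ignore_attr = TRUE)
})
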