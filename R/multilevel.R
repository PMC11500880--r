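#' Construct an ensemble-tree node
#'
#' A node fuses its children with IGPA. Children are either leaf
#' references (character names of prediction sources) or further
#' `ensemble_node`s. Leaves sit at level 0; a node's level is one more
#' than the maximum level of its children, and `alpha` defaults to that
#' level, so the first round of fusion above the raw classifiers runs at
#' `alpha = 1`.
#'
#' @param node_id Unique node identifier string.
#' @param children List mixing character leaf references and
#'   `ensemble_node` objects (a single character vector is also accepted).
#' @param selection `"all"` (fuse every child) or `"top_k"` (fuse only the
#'   `k` most accurate children on the weighting set).
#' @param k Number of children kept when `selection = "top_k"`.
#' @param alpha Positive level parameter for [information_gain()];
#'   `NULL` means "use the node's level".
#' @return An `ensemble_node`.
#' @examples
#' n <- ensemble_node("pair", c("clfA", "clfB"))
#' n$level
#' @export
ensemble_node <- function(node_id, children, selection = c("all", "top_k"),
                          k = NULL, alpha = NULL) {
  selection <- match.arg(selection)
  if (!is.character(node_id) || length(node_id) != 1L || !nzchar(node_id)) {
    stop("node_id must be a non-empty string")
  }
  if (is.character(children)) children <- as.list(children)
  if (!is.list(children) || length(children) == 0L) stop("children must be a non-empty list")
  ok <- vapply(children, function(ch) {
    (is.character(ch) && length(ch) == 1L) || inherits(ch, "ensemble_node")
  }, logical(1L))
  if (!all(ok)) stop("each child must be a leaf reference string or an ensemble_node")
  child_levels <- vapply(children, function(ch) {
    if (inherits(ch, "ensemble_node")) ch$level else 0L
  }, integer(1L))
  level <- 1L + max(child_levels)
  if (selection == "top_k") {
    if (is.null(k)) stop("selection = 'top_k' requires k")
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(children)) {
      stop(sprintf("node '%s': k = %s must lie in [1, %d]",
                   node_id, format(k), length(children)))
    }
    k <- as.integer(k)
  } else {
    k <- NULL
  }
  if (is.null(alpha)) alpha <- as.numeric(level)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a positive number")
  }
  structure(
    list(node_id = node_id, children = children, level = level,
         selection = selection, k = k, alpha = as.numeric(alpha)),
    class = "ensemble_node")
}

#' @export
print.ensemble_node <- function(x, ...) {
  cat(sprintf("<ensemble_node> %s: level %d, alpha %g, %s%s, %d leaves / %d internal nodes\n",
              x$node_id, x$level, x$alpha,
              x$selection, if (identical(x$selection, "top_k")) sprintf("(k=%d)", x$k) else "",
              length(tree_leaves(x)), length(tree_nodes(x))))
  invisible(x)
}

#' Leaf references of an ensemble tree
#' @param node An `ensemble_node`.
#' @return Character vector of leaf reference names (with repeats, in
#'   traversal order).
#' @export
tree_leaves <- function(node) {
  unlist(lapply(node$children, function(ch) {
    if (is.character(ch)) ch else tree_leaves(ch)
  }), use.names = FALSE)
}

#' Internal node ids of an ensemble tree
#' @param node An `ensemble_node`.
#' @return Character vector of node ids, post-order (root last).
#' @export
tree_nodes <- function(node) {
  below <- unlist(lapply(node$children, function(ch) {
    if (is.character(ch)) character(0L) else tree_nodes(ch)
  }), use.names = FALSE)
  c(below, node$node_id)
}

#' Build and validate an ensemble tree from a configuration list
#'
#' The configuration mirrors the JSON/YAML tree format: a nested list
#' with fields `id`, `children` (strings for leaves, nested lists for
#' internal nodes), optional `selection` (`"all"`/`"top_k"`), `k`, and
#' `alpha`. Validation checks that every leaf reference is a known
#' prediction source, node ids are unique, and `k` never exceeds the
#' child count; levels are computed bottom-up and `alpha` defaults to the
#' node's level.
#'
#' @param config Nested list describing the tree.
#' @param sources Character vector of known prediction-source names; when
#'   supplied, unknown leaf references are an error.
#' @return The validated root `ensemble_node`.
#' @export
build_tree <- function(config, sources = NULL) {
  root <- build_node(config)
  ids <- tree_nodes(root)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate node_id(s): %s", paste(dup, collapse = ", ")))
  }
  if (!is.null(sources)) {
    unknown <- setdiff(unique(tree_leaves(root)), sources)
    if (length(unknown) > 0L) {
      stop(sprintf("unknown leaf reference(s): %s", paste(unknown, collapse = ", ")))
    }
  }
  root
}

build_node <- function(cfg) {
  if (inherits(cfg, "ensemble_node")) return(cfg)
  if (!is.list(cfg)) stop("tree node configuration must be a list")
  if (is.null(cfg$id)) stop("tree node configuration is missing 'id'")
  if (is.null(cfg$children)) stop(sprintf("node '%s' has no 'children'", cfg$id))
  kids <- cfg$children
  if (is.character(kids)) kids <- as.list(kids)
  children <- lapply(kids, function(ch) {
    if (is.character(ch) && length(ch) == 1L) ch else build_node(ch)
  })
  ensemble_node(node_id = as.character(cfg$id),
                children = children,
                selection = if (is.null(cfg$selection)) "all" else cfg$selection,
                k = cfg$k,
                alpha = cfg$alpha)
}

#' The nine-backbone, four-head ML-IGPA reference topology
#'
#' Builds the three-level tree used for HAM10000-style dermoscopy
#' ensembles. Level 1 holds one node per backbone — the DenseNet family
#' (DN121, DN169, DN201), the MobileNet family (MNv1, MNv2, MNv3L), and
#' the Inception/Xception family (Iv3, IRv2, X) — each fusing that backbone's
#' four attention heads (CCNN, CACNN, SEACNN, SACNN) at `alpha = 1`.
#' Level 2 groups the backbones into DN, MN and IX at `alpha = 2`; level 3
#' fuses those three at the DMIX root with `alpha = 3`. Leaf sources are
#' named `<backbone>_<head>`, 36 in total over 13 internal nodes.
#'
#' @param variant `"all"` fuses every child at every node; `"best3"` sets
#'   `top_k = 3` selection uniformly (the selection only bites at level 1,
#'   where each node has four children; levels 2-3 already have exactly
#'   three).
#' @return The root `ensemble_node`.
#' @examples
#' length(tree_leaves(ml_igpa_topology("all")))   # 36
#' length(tree_nodes(ml_igpa_topology("best3")))  # 13
#' @export
ml_igpa_topology <- function(variant = c("all", "best3")) {
  variant <- match.arg(variant)
  backbones <- list(
    DN = c("DN121", "DN169", "DN201"),
    MN = c("MNv1", "MNv2", "MNv3L"),
    IX = c("Iv3", "IRv2", "X"))
  heads <- c("CCNN", "CACNN", "SEACNN", "SACNN")
  sel <- if (variant == "best3") "top_k" else "all"
  kk <- if (variant == "best3") 3L else NULL
  level2 <- lapply(names(backbones), function(grp) {
    level1 <- lapply(backbones[[grp]], function(bb) {
      ensemble_node(bb, paste(bb, heads, sep = "_"),
                    selection = sel, k = kk, alpha = 1)
    })
    ensemble_node(grp, level1, selection = sel, k = kk, alpha = 2)
  })
  ensemble_node("DMIX", level2, selection = sel, k = kk, alpha = 3)
}

#' Names of the 36 leaf prediction sources of the reference topology
#' @return Character vector `<backbone>_<head>`, backbone-major order.
#' @export
ml_igpa_sources <- function() {
  unique(tree_leaves(ml_igpa_topology("all")))
}

#' Run an ensemble tree level by level
#'
#' Post-order traversal: each internal node first resolves its children
#' (leaves from `store`, internal nodes recursively), optionally keeps
#' only its `k` most accurate children on the weighting set, then fuses
#' them with [igpa_ensemble()] at the node's `alpha`. The report records
#' every node's child accuracies, information gains and weights, so the
#' full weighting arithmetic is auditable.
#'
#' Leak-free weighting: pass `weighting_store` (the same sources' outputs
#' on a held-out partition, aligned with `weighting_truth`) to compute all
#' correctness/selection on that partition while fusing the matrices in
#' `store`. By default the weighting store is `store` itself.
#'
#' @param root An `ensemble_node` (from [build_tree()] or
#'   [ml_igpa_topology()]).
#' @param store Named list mapping leaf reference names to
#'   `prediction_matrix` objects.
#' @param weighting_truth Integer 0-based labels aligned with the
#'   weighting matrices.
#' @param weighting_store Optional named list of weighting-partition
#'   matrices for the same sources.
#' @param h_prior,mode Passed to [information_gain()].
#' @return A list with `fused` (the root's `prediction_matrix`) and
#'   `report` (an `ensemble_report`: one entry per internal node).
#' @export
run_tree <- function(root, store, weighting_truth, weighting_store = NULL,
                     h_prior = 1, mode = c("multiplicative", "exponent")) {
  mode <- match.arg(mode)
  if (!inherits(root, "ensemble_node")) stop("root must be an ensemble_node")
  if (is.null(names(store)) || any(!nzchar(names(store)))) {
    stop("store must be a named list of prediction matrices")
  }
  if (is.null(weighting_store)) weighting_store <- store
  missing_src <- setdiff(unique(tree_leaves(root)), names(store))
  if (length(missing_src) > 0L) {
    stop(sprintf("store is missing source(s): %s", paste(missing_src, collapse = ", ")))
  }
  missing_w <- setdiff(unique(tree_leaves(root)), names(weighting_store))
  if (length(missing_w) > 0L) {
    stop(sprintf("weighting_store is missing source(s): %s",
                 paste(missing_w, collapse = ", ")))
  }
  report <- list()
  eval_node <- function(node) {
    resolved <- lapply(node$children, function(ch) {
      if (is.character(ch)) {
        list(pred = as_prediction_matrix(store[[ch]]),
             wpred = as_prediction_matrix(weighting_store[[ch]]),
             id = ch)
      } else {
        eval_node(ch)
      }
    })
    preds <- lapply(resolved, `[[`, "pred")
    wpreds <- lapply(resolved, `[[`, "wpred")
    ids <- vapply(resolved, `[[`, character(1L), "id")
    kept <- seq_along(preds)
    if (identical(node$selection, "top_k") && node$k < length(preds)) {
      sel <- select_top_k(wpreds, weighting_truth, node$k)
      kept <- attr(sel, "selected")
    }
    fit <- igpa_ensemble(preds[kept], weighting_truth, alpha = node$alpha,
                         h_prior = h_prior, mode = mode,
                         weighting_preds = wpreds[kept],
                         source_id = node$node_id)
    # the node's own weighting-set output, for correctness at the parent
    wfused <- weighted_average(wpreds[kept], fit$weights, source_id = node$node_id)
    report[[node$node_id]] <<- list(
      node_id = node$node_id, level = node$level, alpha = node$alpha,
      mode = mode, selection = node$selection,
      children = ids, kept = ids[kept],
      accuracies = fit$accuracies,
      ig_values = stats::setNames(
        vapply(fit$scores, `[[`, numeric(1L), "value"), ids[kept]),
      weights = fit$weights)
    list(pred = fit$fused, wpred = wfused, id = node$node_id)
  }
  out <- eval_node(root)
  structure(list(fused = out$pred, report = structure(report, class = "ensemble_report")),
            class = "tree_result")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble_report> %d internal nodes\n", length(x)))
  for (e in x) {
    cat(sprintf("  %-8s level %d alpha %g [%s]  weights: %s\n",
                e$node_id, e$level, e$alpha, e$mode,
                paste(sprintf("%s=%.4f", names(e$weights), e$weights), collapse = " ")))
  }
  invisible(x)
}

#' Single-level IGPA over a flat classifier list
#'
#' The flat baseline: one IGPA fusion over every supplied prediction
#' matrix at `alpha = 1`, with the same report structure as [run_tree()].
#'
#' @inheritParams igpa_ensemble
#' @return A list with `fused` and a one-entry `report`.
#' @export
single_level_igpa <- function(preds, weighting_truth, h_prior = 1,
                              mode = c("multiplicative", "exponent"),
                              weighting_preds = NULL) {
  mode <- match.arg(mode)
  preds <- check_aligned_preds(preds)
  fit <- igpa_ensemble(preds, weighting_truth, alpha = 1, h_prior = h_prior,
                       mode = mode, weighting_preds = weighting_preds,
                       source_id = "SL_IGPA")
  report <- list(SL_IGPA = list(
    node_id = "SL_IGPA", level = 1L, alpha = 1, mode = mode, selection = "all",
    children = names(fit$weights), kept = names(fit$weights),
    accuracies = fit$accuracies,
    ig_values = stats::setNames(vapply(fit$scores, `[[`, numeric(1L), "value"),
                                names(fit$weights)),
    weights = fit$weights))
  structure(list(fused = fit$fused,
                 report = structure(report, class = "ensemble_report")),
            class = "tree_result")
}
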