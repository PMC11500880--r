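#' Default 7-class imbalanced prior
#'
#' Qualitatively mimics the class imbalance of the HAM10000 dermoscopy
#' collection: a nevus-dominated distribution (NV ~ 67%) over the seven
#' lesion classes AK, BCC, BKL, DF, MEL, NV, VASC.
#'
#' @return Named numeric probability vector summing to 1.
#' @export
ham_like_class_probs <- function() {
  c(AK = 0.033, BCC = 0.051, BKL = 0.110, DF = 0.011,
    MEL = 0.111, NV = 0.670, VASC = 0.014)
}

#' Simulator configuration
#'
#' Parameters of the classifier-prediction simulator. The defaults
#' emulate a bank of fine-tuned dermoscopy CNNs: heterogeneous accuracies
#' spread over 0.85-0.95, a nevus-dominated 7-class prior, fairly
#' confident probability rows, and moderately correlated mistakes (hard
#' lesions tend to be hard for every classifier).
#'
#' @param n_samples Number of samples per prediction matrix.
#' @param classifier_accuracies Target accuracy per simulated classifier.
#' @param class_probs Distribution over classes (named vector gives the
#'   class names).
#' @param concentration Positive sharpness of the probability rows: the
#'   predicted class's Dirichlet shape is `1 + concentration`, the rest 1.
#' @param correlation Fraction in \eqn{[0, 1]} of correctness draws taken
#'   from a shared per-sample difficulty variable rather than
#'   independently per classifier.
#' @param confusion_bias Optional `K x K` row-stochastic matrix; when a
#'   classifier errs on a sample of true class `t`, the wrong class is
#'   drawn from row `t` (diagonal ignored) instead of uniformly.
#' @param seed Integer RNG seed.
#' @return A validated `simulator_config` list.
#' @export
simulator_config <- function(n_samples = 1000L,
                             classifier_accuracies = seq(0.85, 0.95, length.out = 9L),
                             class_probs = ham_like_class_probs(),
                             concentration = 10,
                             correlation = 0.3,
                             confusion_bias = NULL,
                             seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 1) stop("n_samples must be >= 1")
  if (length(classifier_accuracies) < 1L ||
      any(classifier_accuracies < 0) || any(classifier_accuracies > 1)) {
    stop("classifier_accuracies must lie in [0, 1]")
  }
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs < 0)) {
    stop("class_probs must be a probability distribution")
  }
  if (length(class_probs) < 2L) stop("need at least 2 classes")
  if (!is.numeric(concentration) || concentration <= 0) stop("concentration must be > 0")
  if (correlation < 0 || correlation > 1) stop("correlation must lie in [0, 1]")
  k <- length(class_probs)
  if (!is.null(confusion_bias)) {
    confusion_bias <- as.matrix(confusion_bias)
    if (!identical(dim(confusion_bias), c(k, k)) || any(confusion_bias < 0)) {
      stop("confusion_bias must be a non-negative K x K matrix")
    }
  }
  nm <- names(class_probs)
  if (is.null(nm)) nm <- paste0("C", seq_len(k) - 1L)
  structure(
    list(n_samples = as.integer(n_samples),
         classifier_accuracies = as.numeric(classifier_accuracies),
         class_probs = as.numeric(class_probs),
         class_names = nm,
         concentration = as.numeric(concentration),
         correlation = as.numeric(correlation),
         confusion_bias = confusion_bias,
         seed = as.integer(seed)),
    class = "simulator_config")
}

# draw one wrong class per erring sample, uniform or confusion-biased
draw_wrong_class <- function(truth_wrong, k, confusion_bias) {
  n_wrong <- length(truth_wrong)
  if (n_wrong == 0L) return(integer(0L))
  if (is.null(confusion_bias)) {
    offset <- sample.int(k - 1L, n_wrong, replace = TRUE)
    return((truth_wrong + offset) %% k)
  }
  vapply(truth_wrong, function(t0) {
    p <- confusion_bias[t0 + 1L, ]
    p[t0 + 1L] <- 0
    if (sum(p) == 0) p <- rep(1, k) * (seq_len(k) != t0 + 1L)
    sample.int(k, 1L, prob = p) - 1L
  }, integer(1L))
}

#' Simulate a bank of classifier prediction matrices
#'
#' Draws true labels from the configured class prior, then, per
#' classifier and sample, a correct/incorrect outcome: with probability
#' `correlation` the outcome comes from a shared per-sample difficulty
#' draw (so all classifiers sharing it agree), otherwise from an
#' independent Bernoulli at the classifier's target accuracy. The
#' predicted class is the truth when correct, otherwise a uniformly (or
#' confusion-biased) chosen other class. Each probability row is a
#' Dirichlet-style draw whose shape is boosted by `concentration` on the
#' predicted class; after normalization the predicted class is guaranteed
#' to be the row's argmax, so each classifier's empirical accuracy is a
#' binomial draw at its target rate. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [simulator_config()].
#' @return List with `preds` (list of `prediction_matrix`, source ids
#'   `sim01, sim02, ...`), `truth` (integer 0-based labels) and
#'   `class_names`.
#' @export
simulate_predictions <- function(cfg) {
  if (!inherits(cfg, "simulator_config")) cfg <- do.call(simulator_config, cfg)
  set.seed(cfg$seed)
  n <- cfg$n_samples
  k <- length(cfg$class_probs)
  truth <- sample.int(k, n, replace = TRUE, prob = cfg$class_probs) - 1L
  shared_u <- stats::runif(n)
  preds <- lapply(seq_along(cfg$classifier_accuracies), function(i) {
    acc <- cfg$classifier_accuracies[i]
    use_shared <- stats::runif(n) < cfg$correlation
    correct <- ifelse(use_shared, shared_u < acc, stats::runif(n) < acc)
    pred <- truth
    wrong <- which(!correct)
    pred[wrong] <- draw_wrong_class(truth[wrong], k, cfg$confusion_bias)
    g <- matrix(stats::rgamma(n * k, shape = 1), n, k)
    g[cbind(seq_len(n), pred + 1L)] <- stats::rgamma(n, shape = 1 + cfg$concentration)
    probs <- g / rowSums(g)
    # guarantee the intended class is the argmax (swap if a flat draw won)
    top <- max.col(probs, ties.method = "first")
    flip <- which(top != pred + 1L)
    if (length(flip) > 0L) {
      for (j in flip) {
        tmp <- probs[j, top[j]]
        probs[j, top[j]] <- probs[j, pred[j] + 1L]
        probs[j, pred[j] + 1L] <- tmp
      }
    }
    prediction_matrix(probs, class_names = cfg$class_names,
                      source_id = sprintf("sim%02d", i))
  })
  list(preds = preds, truth = truth, class_names = cfg$class_names)
}

#' Generate a lesion-grouped sample manifest
#'
#' Assigns each lesion a class drawn from `class_probs` and distributes
#' images over lesions so that some lesions carry several (redundant)
#' images, as dermoscopy collections do. Every image of a lesion shares
#' that lesion's class.
#'
#' @param n_images Total number of image records.
#' @param n_lesions Number of distinct lesions (`<= n_images`; each
#'   lesion receives at least one image).
#' @param class_probs Distribution over classes.
#' @param seed Integer RNG seed.
#' @return Data frame of class `sample_manifest` with columns
#'   `image_id`, `lesion_id`, `class_label` (integer 0-based).
#' @export
make_manifest <- function(n_images, n_lesions,
                          class_probs = ham_like_class_probs(), seed = 1L) {
  if (n_images < 1 || n_lesions < 1) stop("counts must be >= 1")
  if (n_lesions > n_images) stop("n_lesions must not exceed n_images")
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs < 0)) {
    stop("class_probs must be a probability distribution")
  }
  set.seed(seed)
  k <- length(class_probs)
  lesion_class <- sample.int(k, n_lesions, replace = TRUE, prob = class_probs) - 1L
  lesion_of_image <- c(seq_len(n_lesions),
                       if (n_images > n_lesions)
                         sample.int(n_lesions, n_images - n_lesions, replace = TRUE))
  m <- data.frame(
    image_id = sprintf("IMG_%06d", seq_len(n_images)),
    lesion_id = sprintf("LES_%06d", lesion_of_image),
    class_label = lesion_class[lesion_of_image],
    stringsAsFactors = FALSE)
  class(m) <- c("sample_manifest", class(m))
  m
}

#' Lesion-grouped train/validation/test split
#'
#' Shuffles the lesion ids with the seed and assigns whole lesions
#' greedily: first filling the test partition to its image-count quota,
#' then validation, with the remainder going to train. No lesion ever
#' spans two partitions, so no image of a lesion seen in training can
#' leak into evaluation. When every lesion holds a single image and the
#' fractions divide the image count exactly, the partition sizes are
#' exact.
#'
#' @param manifest A [make_manifest()] data frame (columns `image_id`,
#'   `lesion_id`).
#' @param fractions Numeric `(train, validation, test)` fractions, all
#'   positive, summing to 1. Default `c(0.70, 0.15, 0.15)`.
#' @param seed Integer RNG seed for the lesion shuffle.
#' @return A `partition`: list of `train`, `validation`, `test` image-id
#'   character vectors.
#' @export
grouped_split <- function(manifest, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (!all(c("image_id", "lesion_id") %in% names(manifest))) {
    stop("manifest must have image_id and lesion_id columns")
  }
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be three positive numbers summing to 1")
  }
  set.seed(seed)
  n <- nrow(manifest)
  lesions <- unique(manifest$lesion_id)
  sizes <- table(manifest$lesion_id)[lesions]
  shuffled <- sample(lesions)
  quota_test <- round(n * fractions[3L])
  quota_val <- round(n * fractions[2L])
  assign <- stats::setNames(rep("train", length(lesions)), shuffled)
  filled_test <- 0L; filled_val <- 0L
  for (les in shuffled) {
    sz <- as.integer(sizes[[les]])
    if (filled_test < quota_test) {
      assign[[les]] <- "test"; filled_test <- filled_test + sz
    } else if (filled_val < quota_val) {
      assign[[les]] <- "validation"; filled_val <- filled_val + sz
    }
  }
  part_of <- assign[manifest$lesion_id]
  out <- list(train = manifest$image_id[part_of == "train"],
              validation = manifest$image_id[part_of == "validation"],
              test = manifest$image_id[part_of == "test"])
  class(out) <- "partition"
  out
}

#' @export
print.partition <- function(x, ...) {
  n <- sum(lengths(x))
  cat(sprintf("<partition> %d images: train %d (%.1f%%), validation %d (%.1f%%), test %d (%.1f%%)\n",
              n, length(x$train), 100 * length(x$train) / n,
              length(x$validation), 100 * length(x$validation) / n,
              length(x$test), 100 * length(x$test) / n))
  invisible(x)
}
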