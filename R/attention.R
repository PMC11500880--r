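#' Construct a feature map
#'
#' A feature map is a real array of shape channels x height x width, the
#' unit the attention operators act on.
#'
#' @param values Numeric array `C x H x W` (a matrix is promoted to
#'   `C x H x 1`, a vector to `C x 1 x 1`).
#' @return A `feature_map` array.
#' @export
feature_map <- function(values) {
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("feature map must be a C x H x W array")
  if (any(dim(values) < 1L)) stop("all feature-map dimensions must be >= 1")
  if (anyNA(values) || any(!is.finite(values))) stop("feature map entries must be finite")
  storage.mode(values) <- "double"
  class(values) <- c("feature_map", class(values))
  values
}

#' Attention operator parameters
#'
#' Two weight matrices for the bottleneck `W2 . act(W1 . d)` shared by the
#' channel and squeeze-excitation operators. The channel descriptor `d`
#' is either the per-channel spatial means (`descriptor_mode = "mean"`,
#' length `C`) or means concatenated with per-channel spatial standard
#' deviations (`"mean_std"`, length `2C`; population standard deviation,
#' so a 1x1 spatial plane gives 0 rather than NA).
#'
#' @param W1 Matrix `hidden x descriptor_length`.
#' @param W2 Matrix `channels x hidden`.
#' @param descriptor_mode `"mean_std"` (default) or `"mean"`.
#' @return An `attention_params` object.
#' @export
attention_params <- function(W1, W2, descriptor_mode = c("mean_std", "mean")) {
  descriptor_mode <- match.arg(descriptor_mode)
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  if (ncol(W2) != nrow(W1)) {
    stop(sprintf("inner dimensions disagree: W2 is %dx%d but W1 has %d rows",
                 nrow(W2), ncol(W2), nrow(W1)))
  }
  structure(list(W1 = W1, W2 = W2, descriptor_mode = descriptor_mode),
            class = "attention_params")
}

#' Random attention parameters for a channel count
#'
#' Convenience generator of Gaussian-initialized weights with the usual
#' bottleneck width `max(1, floor(C / reduction))`.
#'
#' @param channels Channel count `C`.
#' @param descriptor_mode Passed to [attention_params()].
#' @param reduction Bottleneck reduction ratio (default 8).
#' @param sd Standard deviation of the Gaussian entries.
#' @return An `attention_params` object.
#' @export
random_attention_params <- function(channels, descriptor_mode = c("mean_std", "mean"),
                                    reduction = 8, sd = 0.5) {
  descriptor_mode <- match.arg(descriptor_mode)
  d_len <- if (descriptor_mode == "mean_std") 2L * channels else channels
  hidden <- max(1L, floor(channels / reduction))
  attention_params(
    W1 = matrix(stats::rnorm(hidden * d_len, sd = sd), hidden, d_len),
    W2 = matrix(stats::rnorm(channels * hidden, sd = sd), channels, hidden),
    descriptor_mode = descriptor_mode)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) stats::plogis(x)

channel_descriptor <- function(x, mode) {
  mu <- apply(x, 1L, mean)
  if (mode == "mean") return(mu)
  sdev <- apply(x, 1L, function(v) sqrt(mean((v - mean(v))^2)))
  c(mu, sdev)
}

check_attention_shapes <- function(x, p, d_len) {
  C <- dim(x)[1L]
  if (ncol(p$W1) != d_len) {
    stop(sprintf("W1 has %d columns but the %s descriptor of a %d-channel map has length %d",
                 ncol(p$W1), p$descriptor_mode, C, d_len))
  }
  if (nrow(p$W2) != C) {
    stop(sprintf("W2 has %d rows but the feature map has %d channels", nrow(p$W2), C))
  }
}

#' Channel attention forward pass
#'
#' Computes per-channel gates from a channel descriptor (spatial mean,
#' optionally concatenated with spatial standard deviation) through a
#' sigmoid bottleneck, \eqn{w_c = \sigma(W_2\, \delta(W_1 d))} with
#' \eqn{\delta} = ReLU, and rescales each channel's spatial plane:
#' \eqn{y = w_c \odot x}. Gates lie in `(0, 1)`, so the output never
#' exceeds the input in magnitude; the shape is preserved.
#'
#' @param x A `feature_map` (`C x H x W`).
#' @param p An `attention_params` whose shapes match `x`'s channel count.
#' @return A `feature_map` the same shape as `x`, with attribute
#'   `gates` (the per-channel weights `w_c`).
#' @export
channel_attention <- function(x, p) {
  x <- feature_map(unclass(x))
  if (!inherits(p, "attention_params")) stop("p must be attention_params")
  d <- channel_descriptor(x, p$descriptor_mode)
  check_attention_shapes(x, p, length(d))
  w <- sigmoid(as.numeric(p$W2 %*% relu(p$W1 %*% d)))
  y <- unclass(x) * array(w, dim = dim(x))  # w recycles over the channel margin
  out <- feature_map(y)
  attr(out, "gates") <- w
  out
}

#' Squeeze-and-excitation attention forward pass
#'
#' Squeezes each channel to its global average \eqn{z_c}, excites through
#' the bottleneck \eqn{s = \mathrm{ReLU}(W_2\, \mathrm{sigmoid}(W_1 z))},
#' and rescales: \eqn{y = s \odot x}. Note the activation order (outer
#' ReLU, inner sigmoid) inverts the usual squeeze-excitation design; it
#' is implemented exactly as specified, so the gates are non-negative but
#' not bounded above by 1.
#'
#' @inheritParams channel_attention
#' @return A `feature_map` the same shape as `x`, with attribute `gates`
#'   (the per-channel excitations `s`).
#' @export
squeeze_excitation <- function(x, p) {
  x <- feature_map(unclass(x))
  if (!inherits(p, "attention_params")) stop("p must be attention_params")
  z <- apply(x, 1L, mean)
  C <- dim(x)[1L]
  if (ncol(p$W1) != C) {
    stop(sprintf("W1 has %d columns but the squeezed descriptor has length %d",
                 ncol(p$W1), C))
  }
  if (nrow(p$W2) != C) {
    stop(sprintf("W2 has %d rows but the feature map has %d channels", nrow(p$W2), C))
  }
  s <- relu(as.numeric(p$W2 %*% sigmoid(p$W1 %*% z)))
  y <- unclass(x) * array(s, dim = dim(x))
  out <- feature_map(y)
  attr(out, "gates") <- s
  out
}

#' Soft-attention weights of a score vector
#'
#' Softmax over scalar scores, \eqn{a_i = e^{e_i} / \sum_j e^{e_j}},
#' computed with a max shift for overflow safety. The result is positive
#' and sums to 1, and is invariant to adding a constant to every score.
#'
#' @param e Numeric vector of finite scores (length `T >= 1`).
#' @return Numeric weight vector the same length as `e`.
#' @examples
#' soft_attention_weights(c(0, log(2)))  # 1/3, 2/3
#' @export
soft_attention_weights <- function(e) {
  if (length(e) == 0L) stop("score vector is empty")
  if (anyNA(e) || any(!is.finite(e))) stop("scores must be finite")
  z <- exp(e - max(e))
  z / sum(z)
}
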