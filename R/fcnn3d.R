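#' Same-padded 3D convolution
#'
#' Sliding inner product of an odd-sized kernel over a 3D volume with zero
#' padding (CNN convention, no kernel flip).  Compiled implementation.
#'
#' @param x 3D numeric array.
#' @param kernel 3D numeric array with odd dims.
#' @return 3D array of the same shape as `x`.
#' @export
conv3d_same <- function(x, kernel) {
  stopifnot(is.array(x), length(dim(x)) == 3L,
            is.array(kernel), length(dim(kernel)) == 3L)
  .conv3d_same_cpp(x + 0.0, kernel + 0.0)
}

#' Parametric ReLU activation
#'
#' `max(a*x + b, c*x + d)` with `a = b = d = 0`, i.e. `c * max(0, x)`:
#' a single positive slope per layer is the only activation parameter.
#'
#' @param x Numeric array or vector.
#' @param c Positive slope, `0 < c <= 2`.
#' @return Same shape as `x`.
#' @export
parametric_relu <- function(x, c) {
  stopifnot(is.numeric(c), length(c) == 1L)
  if (!is.finite(c) || c <= 0) stop("parametric_relu: slope c must be > 0")
  c * pmax(x, 0)
}

# Replicate-pad each odd spatial dim of a 3D array to even size.
.pad_even <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L == 1L) x <- x[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  d <- dim(x)
  if (d[2] %% 2L == 1L) x <- x[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  d <- dim(x)
  if (d[3] %% 2L == 1L) x <- x[, , c(seq_len(d[3]), d[3]), drop = FALSE]
  x
}

# 2x2x2 max pool with stride 2 (after replicate-padding odd dims to even).
.maxpool3d <- function(x) {
  x <- .pad_even(x)
  d <- dim(x)
  i1 <- seq(1L, d[1], by = 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], by = 2L); j2 <- j1 + 1L
  k1 <- seq(1L, d[3], by = 2L); k2 <- k1 + 1L
  pmax(x[i1, j1, k1, drop = FALSE], x[i2, j1, k1, drop = FALSE],
       x[i1, j2, k1, drop = FALSE], x[i2, j2, k1, drop = FALSE],
       x[i1, j1, k2, drop = FALSE], x[i2, j1, k2, drop = FALSE],
       x[i1, j2, k2, drop = FALSE], x[i2, j2, k2, drop = FALSE])
}

#' Forward pass of the 3D fully-convolutional feature extractor
#'
#' Five same-padded 3D convolution layers (channels 8, 16, 32, 64, 128)
#' with parametric-ReLU activations; 2x2x2 max pooling of stride 2 after
#' layers 1-4 (odd dims replicate-padded to even first) and a global
#' average pool after layer 5, giving one feature per final channel.
#' There are no biases; all weights come from the kernel bank.
#'
#' Because every filter's kernel is replicated across its input channels,
#' the sum over input channels commutes with the convolution: each layer
#' convolves the channel-sum once per output kernel.
#'
#' @param volume 4D numeric array, spatial dims then channel
#'   (`nx x ny x nz x 4`); every spatial dim must be at least 16.
#' @param bank A [build_kernel_bank()] result.
#' @param relu Numeric vector of per-layer ReLU slopes (length = layers).
#' @return Numeric feature vector of length `spec$feature_length` (128).
#' @export
forward_features <- function(volume, bank, relu) {
  stopifnot(inherits(bank, "kernel_bank"))
  spec <- bank$spec
  d <- dim(volume)
  if (is.null(d) || length(d) != 4L || d[4] != spec$in_channels) {
    stop(sprintf("forward_features: expected a %d-channel 4D volume, got dims [%s]",
                 spec$in_channels, paste(d, collapse = ", ")))
  }
  if (any(d[1:3] < 16L)) {
    stop(sprintf("forward_features: spatial dims [%s] too small; need >= 16 per axis",
                 paste(d[1:3], collapse = ", ")))
  }
  if (length(relu) != spec$n_layers || any(!is.finite(relu)) || any(relu <= 0)) {
    stop("forward_features: relu must hold one positive slope per layer")
  }

  # current activation: list of 3D arrays, one per channel
  act <- lapply(seq_len(d[4]), function(cc) volume[, , , cc])
  for (l in seq_len(spec$n_layers)) {
    layer <- bank$layers[[l]]
    s <- Reduce(`+`, act)                       # channel-sum
    if (isTRUE(layer$tied)) {
      base <- conv3d_same(s, attr(layer, "kernel"))
      base <- parametric_relu(base, relu[l])
      if (l < spec$n_layers) base <- .maxpool3d(base)
      act <- rep(list(base), layer$n_out)
    } else {
      act <- lapply(seq_len(layer$n_out), function(j) {
        a <- parametric_relu(conv3d_same(s, layer$kernels[, , , j]), relu[l])
        if (l < spec$n_layers) a <- .maxpool3d(a) else a
        a
      })
    }
  }
  feats <- vapply(act, mean, numeric(1))        # global average pool
  stopifnot(length(feats) == spec$feature_length)
  feats
}

#' Numerically stable softmax
#'
#' `exp(z_i) / sum(exp(z_i))` computed with max-logit subtraction.
#'
#' @param z Numeric vector of logits.
#' @return Probabilities summing to 1.
#' @export
softmax <- function(z) {
  if (any(!is.finite(z))) stop("softmax: logits must be finite")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Fully-connected softmax head parameters
#'
#' @param fc_weights `feature_length x 2` matrix.
#' @param fc_bias Length-2 numeric.
#' @return Object of class `head_params`.
#' @export
head_params <- function(fc_weights, fc_bias) {
  fc_weights <- as.matrix(fc_weights)
  stopifnot(ncol(fc_weights) == 2L, length(fc_bias) == 2L,
            all(is.finite(fc_weights)), all(is.finite(fc_bias)))
  structure(list(fc_weights = fc_weights, fc_bias = as.numeric(fc_bias)),
            class = "head_params")
}

#' Class probabilities from features through the softmax head
#'
#' Logits are `t(W) %*% f + b`; probabilities are the stable softmax of
#' the logits.  Column/element 1 is LGG, 2 is HGG.
#'
#' @param features Feature vector (length = rows of `fc_weights`).
#' @param head A [head_params()] object.
#' @return Length-2 probability vector named `c("LGG", "HGG")`.
#' @export
softmax_probs <- function(features, head) {
  stopifnot(inherits(head, "head_params"))
  if (length(features) != nrow(head$fc_weights)) {
    stop(sprintf("softmax_probs: feature length %d but head expects %d",
                 length(features), nrow(head$fc_weights)))
  }
  if (any(!is.finite(features))) stop("softmax_probs: non-finite features")
  z <- drop(crossprod(head$fc_weights, features)) + head$fc_bias
  p <- softmax(z)
  names(p) <- c("LGG", "HGG")
  p
}
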