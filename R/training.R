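# Map labels to 0/1 with HGG as the positive class.
.as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    if (!all(labels %in% c("HGG", "LGG"))) {
      stop("labels must be 'HGG'/'LGG' (or 0/1 with 1 = HGG)")
    }
    return(as.integer(labels == "HGG"))
  }
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1 (1 = HGG)")
  as.integer(labels)
}

#' Training configuration for the two-stage protocol
#'
#' Stage 1 tunes the filter genes and per-layer ReLU slopes for feature
#' separability on a small stratified subset; stage 2 freezes them and
#' trains the classification head on the full training split.
#'
#' @param stage1_subset_size Images used by the stage-1 objective
#'   (default 100; must not exceed the training-split size).
#' @param stage1_iterations Hybrid-optimizer iterations in stage 1 (50).
#' @param stage2_iterations Hybrid-optimizer iterations for the softmax
#'   head in stage 2 (120).
#' @param head `"softmax"` or `"svm"`.
#' @param tie_genes_per_layer One gene per layer (default `TRUE`) instead
#'   of one per filter.
#' @param population Optimizer population for both stages (16).
#' @param svm List: `lambda` L2 penalty (1e-3), `epochs` (200),
#'   `learning_rate` (0.5).
#' @param seed Integer seed governing subset draw and both optimizers.
#' @return Object of class `train_config`.
#' @export
train_config <- function(stage1_subset_size = 100L,
                         stage1_iterations = 50L,
                         stage2_iterations = 120L,
                         head = c("softmax", "svm"),
                         tie_genes_per_layer = TRUE,
                         population = 16L,
                         svm = list(),
                         seed = 1L) {
  head <- match.arg(head)
  stopifnot(stage1_subset_size >= 2L, stage1_iterations >= 1L,
            stage2_iterations >= 1L, population >= 2L)
  svm <- utils::modifyList(
    list(lambda = 1e-3, epochs = 200L, learning_rate = 0.5), svm)
  structure(
    list(stage1_subset_size = as.integer(stage1_subset_size),
         stage1_iterations = as.integer(stage1_iterations),
         stage2_iterations = as.integer(stage2_iterations),
         head = head,
         tie_genes_per_layer = isTRUE(tie_genes_per_layer),
         population = as.integer(population),
         svm = svm,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Fisher trace-ratio class separability
#'
#' `trace(S_b) / (trace(S_w) + eps)` with the between-class scatter
#' `S_b = sum_k n_k (m_k - m)(m_k - m)'` and within-class scatter
#' `S_w = sum_k sum_{i in k} (x_i - m_k)(x_i - m_k)'`; larger means more
#' separable.  The stage-1 objective is the negative of this value.
#'
#' @param features Numeric matrix, samples in rows.
#' @param labels Binary labels (`"HGG"`/`"LGG"` or 0/1).
#' @param eps Denominator guard (1e-9).
#' @return Non-negative scalar.
#' @export
fisher_fitness <- function(features, labels, eps = 1e-9) {
  features <- as.matrix(features)
  y <- .as_binary_labels(labels)
  stopifnot(nrow(features) == length(y))
  if (length(unique(y)) < 2L) {
    stop("fisher_fitness: both classes must be present")
  }
  m <- colMeans(features)
  between <- 0; within <- 0
  for (k in unique(y)) {
    xk <- features[y == k, , drop = FALSE]
    mk <- colMeans(xk)
    between <- between + nrow(xk) * sum((mk - m)^2)
    within <- within + sum(sweep(xk, 2, mk)^2)
  }
  between / (within + eps)
}

# Search-space layout for stage 1.  Tied mode: (w, code) per layer then one
# ReLU slope per layer.  Untied: (w, code) per filter, then the slopes.
.stage1_bounds <- function(spec, tied) {
  n_units <- if (tied) spec$n_layers else sum(spec$channels)
  list(lower = c(rep(0, 2L * n_units), rep(0.05, spec$n_layers)),
       upper = c(rep(1, 2L * n_units), rep(2, spec$n_layers)),
       n_units = n_units)
}

# Decode a stage-1 parameter vector into genes + ReLU slopes.
.decode_stage1 <- function(x, spec, tied) {
  n_units <- if (tied) spec$n_layers else sum(spec$channels)
  gene_part <- x[seq_len(2L * n_units)]
  relu <- x[2L * n_units + seq_len(spec$n_layers)]
  if (tied) {
    genes <- lapply(seq_len(spec$n_layers), function(l) {
      filter_gene(gene_part[2L * l - 1L], gene_part[2L * l])
    })
  } else {
    genes <- vector("list", spec$n_layers)
    off <- 0L
    for (l in seq_len(spec$n_layers)) {
      genes[[l]] <- lapply(seq_len(spec$channels[l]), function(j) {
        filter_gene(gene_part[off + 2L * j - 1L], gene_part[off + 2L * j])
      })
      off <- off + 2L * spec$channels[l]
    }
  }
  list(genes = genes, relu = relu)
}

# Feature matrix (n x feature_length) for a list of 4-channel volumes.
.extract_features <- function(volumes, bank, relu) {
  t(vapply(volumes, forward_features, numeric(bank$spec$feature_length),
           bank = bank, relu = relu))
}

#' Stage 1: optimize filter genes and ReLU slopes for separability
#'
#' Draws a stratified, seeded subset of the training split and runs the
#' hybrid transit-search/PSO optimizer over the concatenated gene
#' coordinates (each in `[0, 1]`) and per-layer ReLU slopes (in
#' `[0.05, 2]`), minimizing the negative Fisher trace ratio of the
#' extracted features.
#'
#' @param samples List of samples, each a list with `volume` (4D array)
#'   and `label` (`"HGG"`/`"LGG"`).
#' @param spec A [network_spec()].
#' @param cfg A [train_config()].
#' @return List: `genes`, `relu`, `fitness` (Fisher value attained),
#'   `history`, `evaluations`, `subset_idx`.
#' @export
stage1_optimize <- function(samples, spec = network_spec(),
                            cfg = train_config()) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "train_config"))
  y <- .as_binary_labels(vapply(samples, function(s) s$label, character(1)))
  if (length(unique(y)) < 2L) stop("stage1_optimize: need both classes")
  if (cfg$stage1_subset_size > length(samples)) {
    stop(sprintf("stage1_subset_size (%d) exceeds training-set size (%d)",
                 cfg$stage1_subset_size, length(samples)))
  }
  subset_idx <- withr::with_seed(cfg$seed, {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    n1 <- max(1L, round(cfg$stage1_subset_size * length(idx1) / length(y)))
    n1 <- min(n1, cfg$stage1_subset_size - 1L, length(idx1))
    n0 <- min(cfg$stage1_subset_size - n1, length(idx0))
    sort(c(sample(idx1, n1), sample(idx0, n0)))
  })
  vols <- lapply(samples[subset_idx], `[[`, "volume")
  ysub <- y[subset_idx]

  b <- .stage1_bounds(spec, cfg$tie_genes_per_layer)
  objective <- function(x) {
    dec <- .decode_stage1(x, spec, cfg$tie_genes_per_layer)
    bank <- build_kernel_bank(dec$genes, spec)
    f <- .extract_features(vols, bank, dec$relu)
    -fisher_fitness(f, ysub)
  }
  ocfg <- optimizer_config(b$lower, b$upper,
                           population = cfg$population,
                           iterations = cfg$stage1_iterations,
                           seed = cfg$seed)
  res <- run_hybrid(objective, ocfg)
  dec <- .decode_stage1(res$best$position, spec, cfg$tie_genes_per_layer)
  list(genes = dec$genes, relu = dec$relu,
       fitness = -res$best$fitness, history = res$history,
       evaluations = res$evaluations, subset_idx = subset_idx)
}

# Mean cross-entropy of the softmax head on a feature matrix.
.head_cross_entropy <- function(theta, features, y) {
  d <- ncol(features)
  W <- matrix(theta[seq_len(2L * d)], d, 2L)
  b <- theta[2L * d + 1:2]
  Z <- sweep(features %*% W, 2, b, `+`)
  Z <- Z - apply(Z, 1, max)
  logp <- Z - log(rowSums(exp(Z)))
  # column 1 = LGG (y = 0), column 2 = HGG (y = 1)
  -mean(logp[cbind(seq_along(y), y + 1L)])
}

#' Linear SVM parameters
#'
#' @param weights Numeric weight vector.
#' @param bias Scalar bias.
#' @return Object of class `svm_params`.
#' @export
svm_params <- function(weights, bias) {
  stopifnot(all(is.finite(weights)), is.finite(bias))
  structure(list(weights = as.numeric(weights), bias = as.numeric(bias)),
            class = "svm_params")
}

#' Linear SVM decision
#'
#' Score is `weights . features + bias`; label is HGG when the score is
#' strictly positive, LGG otherwise (ties at exactly zero go to LGG).
#'
#' @param features Feature vector.
#' @param svm An [svm_params()] object.
#' @return List with `score` and `label`.
#' @export
svm_decision <- function(features, svm) {
  stopifnot(inherits(svm, "svm_params"))
  if (length(features) != length(svm$weights)) {
    stop(sprintf("svm_decision: feature length %d but weight length %d",
                 length(features), length(svm$weights)))
  }
  score <- sum(svm$weights * features) + svm$bias
  list(score = score, label = if (score > 0) "HGG" else "LGG")
}

# Deterministic full-batch subgradient descent on L2-regularized hinge loss.
.svm_subgradient <- function(features, y, w0, b0, lambda, epochs, lr0) {
  t_i <- ifelse(y == 1, 1, -1)
  w <- w0; b <- b0
  n <- nrow(features)
  for (ep in seq_len(epochs)) {
    s <- drop(features %*% w) + b
    active <- t_i * s < 1
    gw <- 2 * lambda * w -
      colSums(features[active, , drop = FALSE] * t_i[active]) / n
    gb <- -sum(t_i[active]) / n
    lr <- lr0 / (1 + 0.05 * ep)
    w <- w - lr * gw
    b <- b - lr * gb
  }
  svm_params(w, b)
}

#' Stage 2: train the classification head on frozen features
#'
#' Softmax path: the hybrid optimizer minimizes the mean cross-entropy of
#' the fully-connected softmax head over its `d x 2` weights and 2 biases
#' (258 scalars for 128-d features).  SVM path: the same fully-connected
#' optimization is run first, the linear SVM is initialized from the FC
#' weight-difference vector, then refined by deterministic full-batch
#' subgradient descent on the L2-regularized hinge loss.
#'
#' @param features Numeric matrix (samples x feature length), produced by
#'   the frozen stage-1 extractor (and standardized by the caller).
#' @param labels Binary labels.
#' @param cfg A [train_config()]; `cfg$head` selects the path.
#' @return A [head_params()] (softmax) or [svm_params()] (svm) object.
#' @export
stage2_train <- function(features, labels, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  features <- as.matrix(features)
  y <- .as_binary_labels(labels)
  stopifnot(nrow(features) == length(y))
  if (length(unique(y)) < 2L) stop("stage2_train: both classes required")
  d <- ncol(features)

  objective <- function(theta) .head_cross_entropy(theta, features, y)
  ocfg <- optimizer_config(rep(-5, 2L * d + 2L), rep(5, 2L * d + 2L),
                           population = max(cfg$population, 24L),
                           iterations = cfg$stage2_iterations,
                           seed = cfg$seed + 1L)
  res <- run_hybrid(objective, ocfg)
  theta <- res$best$position
  W <- matrix(theta[seq_len(2L * d)], d, 2L)
  b <- theta[2L * d + 1:2]
  fc <- head_params(W, b)
  if (cfg$head == "softmax") return(fc)

  # SVM warm start: decision direction of the optimized FC layer
  w0 <- W[, 2L] - W[, 1L]
  b0 <- b[2L] - b[1L]
  .svm_subgradient(features, y, w0, b0,
                   lambda = cfg$svm$lambda,
                   epochs = cfg$svm$epochs,
                   lr0 = cfg$svm$learning_rate)
}

#' Train the full two-stage model on a cohort
#'
#' Runs [stage1_optimize()] on the training split, freezes the resulting
#' genes and ReLU slopes, extracts features for the whole training split,
#' standardizes them (z-score per feature, the scaler is stored in the
#' model), and runs [stage2_train()] for the configured head.
#'
#' @param cohort A [generate_cohort()] result (or any list with `samples`
#'   carrying `volume`, `label`, `split`).
#' @param spec A [network_spec()].
#' @param cfg A [train_config()].
#' @return Object of class `gliofuzz_model`: `genes`, `relu`, `bank`,
#'   `head`, `head_type`, `spec`, `scaler`, `audit` (parameter-count
#'   ledger) and `stage1` diagnostics.
#' @export
train_model <- function(cohort, spec = network_spec(), cfg = train_config()) {
  samples <- cohort$samples
  train <- samples[vapply(samples, function(s) s$split, character(1)) == "train"]
  if (length(train) < 4L) stop("train_model: training split too small")
  s1 <- stage1_optimize(train, spec, cfg)
  bank <- build_kernel_bank(s1$genes, spec)
  feats <- .extract_features(lapply(train, `[[`, "volume"), bank, s1$relu)
  mu <- colMeans(feats)
  sd_ <- apply(feats, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  feats_std <- sweep(sweep(feats, 2, mu), 2, sd_, `/`)
  labels <- vapply(train, function(s) s$label, character(1))
  head <- stage2_train(feats_std, labels, cfg)

  ledger <- parameter_ledger(spec, cfg$tie_genes_per_layer)
  head_n <- if (inherits(head, "head_params")) {
    length(head$fc_weights) + length(head$fc_bias)
  } else {
    length(head$weights) + 1L
  }
  ledger$head_scalars <- head_n
  ledger$total_trainable <- ledger$gene_scalars + ledger$relu_scalars + head_n

  structure(
    list(genes = s1$genes, relu = s1$relu, bank = bank, head = head,
         head_type = cfg$head, spec = spec,
         scaler = list(mean = mu, sd = sd_),
         audit = ledger,
         stage1 = list(fitness = s1$fitness, history = s1$history,
                       evaluations = s1$evaluations)),
    class = "gliofuzz_model"
  )
}

#' Predict glioma grade for new volumes
#'
#' @param object A trained `gliofuzz_model`.
#' @param volumes A list of 4-channel volumes (or samples with `$volume`).
#' @param type `"label"`, `"prob"` (softmax head only) or `"score"`.
#' @param ... Unused.
#' @return Character labels, probability matrix, or numeric scores.
#' @export
predict.gliofuzz_model <- function(object, volumes,
                                   type = c("label", "prob", "score"), ...) {
  type <- match.arg(type)
  if (!is.null(volumes$samples)) volumes <- volumes$samples
  vols <- lapply(volumes, function(v) if (is.list(v)) v$volume else v)
  feats <- .extract_features(vols, object$bank, object$relu)
  feats <- sweep(sweep(feats, 2, object$scaler$mean), 2, object$scaler$sd, `/`)
  if (object$head_type == "softmax") {
    probs <- t(apply(feats, 1, softmax_probs, head = object$head))
    switch(type,
           prob = probs,
           score = probs[, "HGG"],
           label = ifelse(probs[, "HGG"] > probs[, "LGG"], "HGG", "LGG"))
  } else {
    dec <- apply(feats, 1, function(f) {
      d <- svm_decision(f, object$head)
      c(score = d$score, label = d$label)
    })
    switch(type,
           prob = stop("prob predictions require the softmax head"),
           score = as.numeric(dec["score", ]),
           label = as.character(dec["label", ]))
  }
}
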