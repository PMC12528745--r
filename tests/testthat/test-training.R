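test_that("fisher fitness matches hand-expanded scatter traces", {
  f <- matrix(c(0, 0, 1, 0, 4, 0, 5, 0), ncol = 2, byrow = TRUE)
  y <- c(0, 0, 1, 1)
  # class means (0.5, 0), (4.5, 0); grand mean (2.5, 0)
  # between = 2*4 + 2*4 = 16 ; within = 4 * 0.25 = 1
  expect_equal(fisher_fitness(f, y), 16 / (1 + 1e-9), tolerance = 1e-12)
  # identical class means, nonzero spread -> 0
  g <- matrix(c(-1, 0, 1, 0, -1, 0, 1, 0), ncol = 2, byrow = TRUE)
  expect_equal(fisher_fitness(g, c(0, 0, 1, 1)), 0)
  # point masses at distinct means -> dominated by 1/eps, finite and large
  h <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), ncol = 2, byrow = TRUE)
  v <- fisher_fitness(h, c(0, 0, 1, 1))
  expect_true(is.finite(v))
  expect_gt(v, 1e8)
  expect_error(fisher_fitness(f, c(1, 1, 1, 1)), "both classes")
})

test_that("stage-1 search space has the documented dimension and improves fitness", {
  spec <- network_spec()
  b <- gliofuzz:::.stage1_bounds(spec, tied = TRUE)
  expect_length(b$lower, 2 * 5 + 5)
  b_un <- gliofuzz:::.stage1_bounds(spec, tied = FALSE)
  expect_length(b_un$lower, 2 * 248 + 5)

  coh <- desk_cohort(n_hgg = 14, n_lgg = 6, seed = 7)
  train <- coh$samples[vapply(coh$samples, `[[`, character(1), "split") == "train"]
  cfg <- train_config(stage1_subset_size = 10L, stage1_iterations = 8L,
                      population = 8L, seed = 3)
  s1 <- stage1_optimize(train, spec, cfg)
  expect_length(s1$genes, 5)
  expect_length(s1$relu, 5)
  expect_true(all(s1$relu > 0 & s1$relu <= 2))
  expect_true(all(diff(-s1$history) >= 0) || all(diff(s1$history) <= 0))

  # optimized genes separate better than a random gene set (paired check)
  rand <- withr::with_seed(0, {
    list(genes = lapply(1:5, function(l) filter_gene(runif(1), runif(1))),
         relu = runif(5, 0.05, 2))
  })
  vols <- lapply(train, `[[`, "volume")
  labs <- vapply(train, `[[`, character(1), "label")
  fit_of <- function(p) {
    f <- gliofuzz:::.extract_features(vols, build_kernel_bank(p$genes, spec),
                                      p$relu)
    fisher_fitness(f, labs)
  }
  expect_gt(fit_of(s1), fit_of(rand))

  expect_error(
    stage1_optimize(train, spec, train_config(stage1_subset_size = 500L)),
    "exceeds training-set size")
})

test_that("stage 2 heads fit separable features and behave under symmetry", {
  withr::with_seed(9, {
    f <- rbind(matrix(rnorm(40 * 4, mean = -2), 40, 4),
               matrix(rnorm(40 * 4, mean = 2), 40, 4))
    y <- rep(c(0, 1), each = 40)
    shuffle <- sample(80)
    f <- f[shuffle, ]; y <- y[shuffle]
  })
  cfg_soft <- train_config(stage2_iterations = 80L, head = "softmax", seed = 2)
  head_soft <- stage2_train(f, y, cfg_soft)
  probs <- t(apply(f, 1, softmax_probs, head = head_soft))
  expect_equal(mean((probs[, "HGG"] > 0.5) == (y == 1)), 1.0)

  cfg_svm <- train_config(stage2_iterations = 80L, head = "svm", seed = 2)
  head_svm <- stage2_train(f, y, cfg_svm)
  pred <- apply(f, 1, function(x) svm_decision(x, head_svm)$label)
  expect_equal(mean((pred == "HGG") == (y == 1)), 1.0)

  # label flip flips every decision score's sign region
  head_flip <- stage2_train(f, 1 - y, cfg_svm)
  s_orig <- apply(f, 1, function(x) svm_decision(x, head_svm)$score)
  s_flip <- apply(f, 1, function(x) svm_decision(x, head_flip)$score)
  expect_lt(cor(s_orig, s_flip), -0.9)
})

test_that("softmax head on shuffled labels stays near chance", {
  withr::with_seed(10, {
    f <- matrix(rnorm(60 * 3), 60, 3)
    accs <- vapply(1:10, function(i) {
      y <- sample(rep(c(0, 1), each = 30))
      head <- stage2_train(f, y, train_config(stage2_iterations = 40L,
                                              population = 8L, seed = i))
      probs <- t(apply(f, 1, softmax_probs, head = head))
      mean((probs[, "HGG"] > 0.5) == (y == 1))
    }, numeric(1))
    # training accuracy on noise hovers above chance but far from separation
    expect_gt(mean(accs), 0.45)
    expect_lt(mean(accs), 0.8)
  })
})

test_that("svm decision rule is linear with LGG on ties", {
  svm <- svm_params(c(1, rep(0, 127)), -0.5)
  d <- svm_decision(c(1, rep(0, 127)), svm)
  expect_equal(d$score, 0.5)
  expect_equal(d$label, "HGG")
  # zero weights, positive bias labels everything HGG
  all_pos <- svm_params(rep(0, 4), 0.5)
  expect_equal(svm_decision(rnorm(4), all_pos)$label, "HGG")
  # tie at exactly zero goes to the negative class
  expect_equal(svm_decision(c(0, 0), svm_params(c(1, 1), 0))$label, "LGG")
  # linearity in the features for zero bias
  svm0 <- svm_params(c(2, -1, 0.5), 0)
  x <- c(1, 2, 3)
  expect_equal(svm_decision(3 * x, svm0)$score, 3 * svm_decision(x, svm0)$score)
  expect_error(svm_decision(rnorm(3), svm), "length")
})

test_that("full two-stage training freezes stage 1 and audits its ledger", {
  coh <- desk_cohort(n_hgg = 14, n_lgg = 6, seed = 19)
  cfg <- train_config(stage1_subset_size = 12L, stage1_iterations = 8L,
                      stage2_iterations = 50L, population = 8L, seed = 4)
  model <- train_model(coh, network_spec(), cfg)
  expect_s3_class(model, "gliofuzz_model")

  # frozen-extractor contract: the head training never touches genes/ReLU
  genes_copy <- model$genes; relu_copy <- model$relu
  feats <- gliofuzz:::.extract_features(
    lapply(coh$samples[1:4], `[[`, "volume"), model$bank, model$relu)
  stage2_train(rbind(feats, feats), c(0, 1, 0, 1, 1, 0, 1, 0),
               train_config(stage2_iterations = 5L, seed = 1))
  expect_identical(model$genes, genes_copy)
  expect_identical(model$relu, relu_copy)

  # audit: 2 per layer (tied) + 5 slopes + softmax head 128*2+2
  expect_equal(model$audit$gene_scalars, 10)
  expect_equal(model$audit$relu_scalars, 5)
  expect_equal(model$audit$head_scalars, 258)
  expect_equal(model$audit$total_trainable, 10 + 5 + 258)

  # deterministic retraining
  model2 <- train_model(coh, network_spec(), cfg)
  expect_identical(predict(model, coh$samples[1:4], type = "score"),
                   predict(model2, coh$samples[1:4], type = "score"))
})
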