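test_that("confusion counts match hand counts and symmetry under inversion", {
  cm <- confusion(truth = c(1, 1, 0, 0, 1), pred = c(1, 0, 0, 1, 1))
  expect_equal(unclass(cm)[c("TP", "FN", "TN", "FP")],
               list(TP = 2L, FN = 1L, TN = 1L, FP = 1L))
  # all correct on positives only
  cm2 <- confusion(rep("HGG", 10), rep("HGG", 10))
  expect_equal(unclass(cm2)[c("TP", "TN", "FP", "FN")],
               list(TP = 10L, TN = 0L, FP = 0L, FN = 0L))
  # inverting predictions swaps TP<->FN and TN<->FP
  y <- c(1, 1, 0, 0, 1); p <- c(1, 0, 0, 1, 1)
  a <- confusion(y, p); b <- confusion(y, 1 - p)
  expect_equal(c(a$TP, a$FN, a$TN, a$FP), c(b$FN, b$TP, b$FP, b$TN))
  expect_error(confusion(c(1, 0), c(1)), "1 predictions")
})

test_that("classification metrics follow the defining ratios", {
  m <- classification_metrics(confusion(
    truth = c(rep(1, 10), rep(0, 10)),
    pred = c(rep(1, 9), 0, rep(0, 8), 1, 1)))
  expect_equal(m$Rec, 0.9)
  expect_equal(m$Spe, 0.8)
  expect_equal(m$Pre, 9 / 11)
  expect_equal(m$ACC, 0.85)
  expect_equal(m$F1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))
  perfect <- classification_metrics(confusion(rep(c(1, 0), 50), rep(c(1, 0), 50)))
  expect_true(all(unlist(perfect[c("ACC", "Rec", "Spe", "Pre", "F1")]) == 1))
})

test_that("metrics agree with an independent recomputation on 1000 random draws", {
  withr::with_seed(3, {
    for (i in seq_len(1000)) {
      n <- sample(2:40, 1)
      y <- rbinom(n, 1, 0.5); p <- rbinom(n, 1, 0.5)
      m <- classification_metrics(confusion(y, p))
      o <- oracle_metrics(y, p)
      for (k in c("ACC", "Rec", "Spe", "Pre", "F1")) {
        expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
      }
    }
  })
})

test_that("zero-denominator metrics surface as NA, never as silent zeros", {
  m <- classification_metrics(confusion(rep(0, 5), rep(0, 5)))
  expect_true(is.na(m$Rec))   # no positives in truth
  expect_true(is.na(m$Pre))   # no predicted positives
  expect_equal(m$Spe, 1)
})

test_that("error metrics implement standard MAE/RMSE with their inequality", {
  e <- error_metrics(c(0.5, 0.5), c(0, 1))
  expect_equal(e$MAE, 0.5)
  expect_equal(e$RMSE, 0.5)
  expect_equal(error_metrics(c(0, 1, 1), c(0, 1, 1)), list(MAE = 0, RMSE = 0))
  withr::with_seed(4, {
    for (i in 1:100) {
      s <- runif(20); y <- rbinom(20, 1, 0.5)
      e <- error_metrics(s, y)
      expect_gte(e$RMSE, e$MAE - 1e-15)
      expect_equal(e$MAE, mean(abs(y - s)), tolerance = 1e-12)
      expect_equal(e$RMSE, sqrt(mean((y - s)^2)), tolerance = 1e-12)
    }
  })
  expect_error(error_metrics(c(1.5, 0), c(1, 0)), "\\[0, 1\\]")
})

test_that("AUC matches pair counting, the external oracle, and handles ties", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(6:30, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), 1)   # coarse scores force ties
      a <- roc_auc(s, y)
      expect_equal(a, oracle_auc(s, y), tolerance = 1e-12)
      if (requireNamespace("pROC", quietly = TRUE)) {
        expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                       direction = "<"))),
                     tolerance = 1e-12)
      }
    }
  })
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(6, {
    s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
    a <- roc_auc(s, y)
    expect_equal(roc_auc(exp(s), y), a, tolerance = 1e-12)
    expect_equal(roc_auc(2 * s + 7, y), a, tolerance = 1e-12)
    expect_equal(roc_auc(atan(s), y), a, tolerance = 1e-12)
  })
})

test_that("label-independent scores give AUC near one half (null)", {
  withr::with_seed(7, {
    s <- runif(2000); y <- rbinom(2000, 1, 0.5)
    expect_lt(abs(roc_auc(s, y) - 0.5), 0.03)
  })
})

test_that("stratified folds are balanced, seeded, and bounded", {
  coh <- desk_cohort(n_hgg = 14, n_lgg = 6, seed = 3)
  labels <- vapply(coh$samples, `[[`, character(1), "label")
  # each K=2 training split holds 10 cases; keep the budget desk-sized
  cfg <- train_config(stage1_subset_size = 8L, stage1_iterations = 6L,
                      stage2_iterations = 40L, population = 8L, seed = 5)
  res <- kfold_crossval(coh, K = 2, cfg = cfg, seed = 21)
  # fold sizes differ by at most one per class
  for (cl in c("HGG", "LGG")) {
    sizes <- table(res$fold_assignment[labels == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_true(all(res$per_fold$accuracy >= 0 & res$per_fold$accuracy <= 1))
  expect_equal(res$mean_accuracy, mean(res$per_fold$accuracy))
  # seeded fold assignment is reproducible
  res2 <- kfold_crossval(coh, K = 2, cfg = cfg, seed = 21)
  expect_identical(res$fold_assignment, res2$fold_assignment)
  # separable desk cohort is graded accurately even at this small scale
  expect_gte(res$mean_accuracy, 0.9)
  expect_error(kfold_crossval(coh, K = 10, cfg = cfg), "minority-class")
})
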