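test_that("IT2 triangular membership matches the closed form and keeps FOU order", {
  mf <- it2_triangular(0.5, 0.4, 0.6)
  expect_equal(membership_interval(0.5, mf), list(lower = 1, upper = 1))
  expect_equal(membership_interval(0.8, mf), list(lower = 0.25, upper = 0.5))
  # beyond the upper support both grades vanish
  expect_equal(membership_interval(1.2, mf), list(lower = 0, upper = 0))
  expect_equal(membership_interval(-0.2, mf), list(lower = 0, upper = 0))

  # lower <= upper everywhere, for every default term
  rb <- default_rulebase()
  xs <- seq(0, 1, by = 0.01)
  for (term in rb$terms) {
    g <- membership_interval(xs, term)
    expect_true(all(g$lower <= g$upper + 1e-15))
    expect_true(all(g$lower >= 0 & g$upper <= 1))
  }

  expect_error(membership_interval(NaN, mf), "finite")
  expect_error(it2_triangular(0.5, 0.6, 0.4), "strictly smaller")
})

test_that("rule base is the full 3x3 antecedent product with increasing consequents", {
  rb <- default_rulebase()
  expect_equal(nrow(rb$rules), 9L)
  pairs <- paste(rb$rules$numin, rb$rules$code)
  expect_setequal(pairs, paste(rep(c("Low", "Mid", "High"), 3),
                               rep(c("Low", "Mid", "High"), each = 3)))
  expect_true(all(diff(rb$consequents) > 0))
  expect_true(all(rb$consequents > 0 & rb$consequents < 1))
})

test_that("type-reduced inference matches the independent Nie-Tan oracle", {
  rb <- default_rulebase()
  grid <- expand.grid(numin = seq(0, 1, by = 0.125),
                      code = seq(0, 1, by = 0.125))
  for (i in seq_len(nrow(grid))) {
    expect_equal(infer_pattern(grid$numin[i], grid$code[i], rb),
                 oracle_infer(grid$numin[i], grid$code[i]),
                 tolerance = 1e-12)
  }
  # convexity: always within the consequent range
  s <- infer_pattern(runif(500), runif(1), rb)
  expect_true(all(s >= 0.25 & s <= 0.75))
  # corner case dominated by the (Low, Low) -> L rule
  expect_gt(infer_pattern(0, 0, rb), 0.25)
  expect_lte(infer_pattern(0, 0, rb), 0.5)
  expect_equal(infer_pattern(0, 0, rb), 0.3166667, tolerance = 1e-6)
  # Table-of-rules asymmetry: the midpoint output is the frozen 0.5125,
  # the average of the center rule (M) and the eight off-center rules
  expect_equal(infer_pattern(0.5, 0.5, rb), 0.5125, tolerance = 1e-12)
  expect_error(infer_pattern(1.5, 0.5, rb), "\\[0, 1\\]")
})

test_that("weighting_func composes inference and cosine dispersion deterministically", {
  gene <- filter_gene(0.5, 0.5)
  kw <- weighting_func(gene, 9)
  golden <- read.csv(system.file("extdata", "golden_kernel_w05_code05_n9.csv",
                                 package = "gliofuzz"))
  expect_equal(kw$values, golden$W, tolerance = 1e-12)

  # determinism: repeated calls are bitwise identical
  expect_identical(kw$values, weighting_func(gene, 9)$values)

  # supported sizes give exactly that many coefficients from the same gene
  for (n in c(9, 25, 27, 49, 125)) {
    expect_length(weighting_func(gene, n)$values, n)
  }
  expect_error(weighting_func(gene, 10), "must be one of")

  # w = 0 collapses the cosine to its maximum everywhere
  expect_equal(weighting_func(filter_gene(0, 0.7), 27)$values, rep(3, 27))

  # gene fields are clamped on construction
  g <- filter_gene(-0.5, 1.7)
  expect_equal(c(g$w, g$code), c(0, 1))
})

test_that("kernel coefficients are bounded by 3 over random genes", {
  withr::with_seed(99, {
    for (i in seq_len(200)) {
      v <- weighting_func(filter_gene(runif(1), runif(1)),
                          sample(c(9, 25, 27, 49, 125), 1))$values
      expect_true(all(abs(v) <= 3 + 1e-12))
    }
  })
})

test_that("increasing w never increases the coefficient at the largest pattern value", {
  for (code in c(0, 0.25, 0.5, 0.75, 1)) {
    p <- (seq_len(27) - 0.5) / 27
    win <- infer_pattern(p, code)
    imax <- which.max(win)
    w_grid <- seq(0, 1, by = 0.05)
    vals <- vapply(w_grid, function(w) {
      weighting_func(filter_gene(w, code), 27)$values[imax]
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("kernel bank has one generated kernel per filter and respects tying", {
  spec <- network_spec()
  # untied: one gene per output channel of each layer -> 248 kernels
  withr::with_seed(3, {
    genes <- lapply(spec$channels, function(n) {
      lapply(seq_len(n), function(i) filter_gene(runif(1), runif(1)))
    })
  })
  bank <- build_kernel_bank(genes, spec)
  n_kernels <- sum(vapply(bank$layers, function(l) dim(l$kernels)[4], numeric(1)))
  expect_equal(n_kernels, 248)
  expect_true(all(vapply(bank$layers, function(l) all(abs(l$kernels) <= 3),
                         logical(1))))

  # layer-tied: five genes drive the whole bank
  tied <- lapply(1:5, function(l) filter_gene(0.2 * l, 0.5))
  bank_t <- build_kernel_bank(tied, spec)
  expect_true(all(vapply(bank_t$layers, `[[`, logical(1), "tied")))
  expect_equal(dim(bank_t$layers[[5]]$kernels), c(3, 3, 3, 128))

  # mismatched gene counts are rejected with the counts in the message
  bad <- genes; bad[[2]] <- bad[[2]][1:3]
  expect_error(build_kernel_bank(bad, spec), "3 genes but 16")
})

test_that("parameter ledger reports two trainables per filter and the 92.6% reduction", {
  led <- parameter_ledger(network_spec(), tied = FALSE)
  expect_equal(led$n_filters, 248)
  expect_equal(led$trainable_per_filter, 2L)
  expect_equal(led$gene_scalars, 496)
  expect_equal(led$relu_scalars, 5L)
  expect_equal(led$reduction_pct, 100 * 25 / 27)
  expect_equal(round(led$reduction_pct, 1), 92.6)
  expect_equal(parameter_ledger(network_spec(), tied = TRUE)$gene_scalars, 10L)
})
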