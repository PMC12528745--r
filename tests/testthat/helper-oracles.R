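# Independent reference implementations used as oracles.  These deliberately
# re-derive each quantity from the defining formulas, sharing no code with
# the package internals.

# pointwise symmetric triangle
oracle_tri <- function(x, peak, hw) max(0, 1 - abs(x - peak) / hw)

# interval type-2 Nie-Tan inference with the Table-of-rules layout
oracle_rules <- data.frame(
  numin = rep(c("Low", "Mid", "High"), 3),
  code = rep(c("Low", "Mid", "High"), each = 3),
  out = c("L", "M", "H", "H", "M", "L", "H", "L", "H"),
  stringsAsFactors = FALSE
)

oracle_infer <- function(numin, code, h = 0.5, delta = 0.1,
                         cons = c(L = 0.25, M = 0.5, H = 0.75)) {
  peaks <- c(Low = 0, Mid = 0.5, High = 1)
  num <- 0; den <- 0
  for (r in seq_len(9)) {
    fl <- min(oracle_tri(numin, peaks[[oracle_rules$numin[r]]], h - delta),
              oracle_tri(code, peaks[[oracle_rules$code[r]]], h - delta))
    fu <- min(oracle_tri(numin, peaks[[oracle_rules$numin[r]]], h + delta),
              oracle_tri(code, peaks[[oracle_rules$code[r]]], h + delta))
    w <- (fl + fu) / 2
    num <- num + w * cons[[oracle_rules$out[r]]]
    den <- den + w
  }
  num / den
}

# brute-force zero-padded sliding-window 3D convolution (sextuple loop)
oracle_conv3d <- function(x, k) {
  d <- dim(x); kd <- dim(k); h <- (kd - 1L) / 2L
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    acc <- 0
    for (a in seq_len(kd[1])) for (b in seq_len(kd[2])) for (cc in seq_len(kd[3])) {
      ii <- i + a - 1L - h[1]; jj <- j + b - 1L - h[2]; ll <- l + cc - 1L - h[3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && ll >= 1 && ll <= d[3]) {
        acc <- acc + x[ii, jj, ll] * k[a, b, cc]
      }
    }
    out[i, j, l] <- acc
  }
  out
}

# AUC by exhaustive positive/negative pair counting, half credit for ties
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# metrics recomputed directly from label vectors (not from counts)
oracle_metrics <- function(y, p) {
  tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  pre <- div(tp, tp + fp); rec <- div(tp, tp + fn)
  list(ACC = (tp + tn) / length(y), Rec = rec, Spe = div(tn, tn + fp),
       Pre = pre,
       F1 = if (is.na(pre) || is.na(rec) || pre + rec == 0) NA_real_ else
         2 * pre * rec / (pre + rec))
}

# small separable cohort used by the training / evaluation tests
desk_cohort <- function(n_hgg = 14L, n_lgg = 6L, split = c(0.7, 0, 0.3),
                        seed = 11L, shape = c(32L, 32L, 16L)) {
  sc <- function(n) {
    tr <- round(split[1] * n); te <- n - tr - round(split[2] * n)
    c(tr, n - tr - te, te)
  }
  generate_cohort(cohort_spec(
    n_hgg = n_hgg, n_lgg = n_lgg,
    split_counts = list(HGG = sc(n_hgg), LGG = sc(n_lgg)),
    shape = shape, seed = seed
  ))
}

# quick training configuration for desk-scale pipeline tests
quick_cfg <- function(n_train, head = "softmax", seed = 5L) {
  train_config(stage1_subset_size = min(24L, n_train),
               stage1_iterations = 12L,
               stage2_iterations = 60L,
               population = 10L,
               head = head, seed = seed)
}

# spherical-lesion phantom with known mask, for segmentation tests
lesion_phantom <- function(seed, radius = 4.5, contrast = 0.45,
                           shape = c(32L, 32L, 16L), lesion = TRUE) {
  withr::with_seed(seed, {
    d <- shape; ctr <- (d + 1) / 2; semi <- 0.45 * d
    ax <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
    ay <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
    az <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
    brain <- ((ax - ctr[1]) / semi[1])^2 + ((ay - ctr[2]) / semi[2])^2 +
      ((az - ctr[3]) / semi[3])^2 <= 1
    lc <- ctr + c(2, -2, 1) * runif(3, 0, 1)
    les <- ((ax - lc[1])^2 + (ay - lc[2])^2 + (az - lc[3])^2) <= radius^2
    les <- les & brain
    vol <- array(0, dim = c(d, 4L))
    for (cc in 1:4) {
      ch <- array(0.02, dim = d)
      ch[brain] <- 0.45 + rnorm(sum(brain), sd = 0.03)
      if (lesion) ch[les] <- ch[les] + contrast
      vol[, , , cc] <- pmin(pmax(ch, 0), 1)
    }
    list(volume = vol, mask = les, brain = brain)
  })
}
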