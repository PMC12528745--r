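# Separable 3D Gaussian smoothing kernel (outer product), odd width.
.gauss_kernel3 <- function(width = 5L, sigma = 1.2) {
  r <- (width - 1L) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  k <- outer(outer(g, g), g)
  array(k, dim = c(width, width, width))
}

#' Synthetic cohort specification
#'
#' Defines the pseudo-MRI study conditions: cohort composition (230 HGG /
#' 70 LGG with a 220/40/40 train/validation/test split by default), volume
#' shape, and the class-discriminative lesion model.  HGG-like lesions are
#' larger (radius 0.18-0.28 of the shortest axis vs 0.08-0.14), carry a
#' bright contrast rim in the T1ce-like channel, extra FLAIR
#' hyperintensity, and heterogeneous core speckle; LGG-like lesions are
#' small and homogeneous.  All channels receive Rician-like noise.
#'
#' @param n_hgg,n_lgg Class totals (defaults 230, 70).
#' @param split_counts List with `HGG` and `LGG` integer vectors
#'   `(train, val, test)` summing to the class totals.
#' @param shape Spatial dims, default `c(32, 32, 16)` (desk scale).
#' @param lesion_radius_frac List of per-class `(min, max)` lesion radii as
#'   fractions of the shortest axis.
#' @param contrast_effect T1ce rim intensity boost for HGG (0.5).
#' @param heterogeneity Multiplicative core speckle sd for HGG (0.3).
#' @param noise_sigma Rician noise scale (0.05).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hgg = 230L, n_lgg = 70L,
                        split_counts = list(HGG = c(172L, 32L, 26L),
                                            LGG = c(48L, 8L, 14L)),
                        shape = c(32L, 32L, 16L),
                        lesion_radius_frac = list(HGG = c(0.18, 0.28),
                                                  LGG = c(0.08, 0.14)),
                        contrast_effect = 0.5,
                        heterogeneity = 0.3,
                        noise_sigma = 0.05,
                        seed = 1L) {
  n_hgg <- as.integer(n_hgg); n_lgg <- as.integer(n_lgg)
  shape <- as.integer(shape)
  stopifnot(n_hgg >= 1L, n_lgg >= 1L, length(shape) == 3L, all(shape >= 16L))
  if (sum(split_counts$HGG) != n_hgg || sum(split_counts$LGG) != n_lgg) {
    stop(sprintf("split counts (HGG %d, LGG %d) must sum to class totals (%d, %d)",
                 sum(split_counts$HGG), sum(split_counts$LGG), n_hgg, n_lgg))
  }
  for (cl in c("HGG", "LGG")) {
    fr <- lesion_radius_frac[[cl]]
    if (any(fr <= 0) || any(fr >= 1) || fr[1] > fr[2]) {
      stop("lesion_radius_frac must be ordered fractions in (0, 1)")
    }
    if (fr[2] > 0.35) {
      stop("lesion_radius_frac above 0.35 of the short axis does not fit ",
           "inside the brain ellipsoid")
    }
  }
  structure(
    list(n_hgg = n_hgg, n_lgg = n_lgg,
         split_counts = lapply(split_counts, as.integer),
         shape = shape,
         lesion_radius_frac = lesion_radius_frac,
         contrast_effect = contrast_effect,
         heterogeneity = heterogeneity,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate one synthetic pseudo-MRI case
#'
#' Builds a centered ellipsoidal "brain" with smooth tissue texture in four
#' co-registered channels (T1-, T1ce-, T2-, FLAIR-like), places a
#' class-dependent ellipsoidal lesion fully inside the brain, applies the
#' HGG-specific rim/heterogeneity/FLAIR effects, and adds Rician-like
#' noise (magnitude of a complex Gaussian) to every channel.
#'
#' When `seed` is `NULL` the current RNG stream is used (as inside
#' [generate_cohort()]); a non-`NULL` seed makes the case bitwise
#' reproducible on its own.
#'
#' @param label `"HGG"` or `"LGG"`.
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @param case_id Optional identifier string.
#' @return A sample: list with `volume` (4D array, channels T1, T1ce, T2,
#'   FLAIR), `label`, `mask` (logical 3D ground-truth lesion), `split`
#'   (`NA` until assigned), `case_id`.
#' @export
generate_case <- function(label, spec = cohort_spec(), seed = NULL,
                          case_id = NA_character_) {
  stopifnot(label %in% c("HGG", "LGG"), inherits(spec, "cohort_spec"))
  gen <- function() .generate_case_impl(label, spec, case_id)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.generate_case_impl <- function(label, spec, case_id) {
  d <- spec$shape
  ctr <- (d + 1) / 2
  semi <- 0.45 * d
  ax <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  ay <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  az <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  brain <- ((ax - ctr[1]) / semi[1])^2 + ((ay - ctr[2]) / semi[2])^2 +
    ((az - ctr[3]) / semi[3])^2 <= 1

  # lesion geometry: radius from the class range, fully inside the brain
  fr <- spec$lesion_radius_frac[[label]]
  r0 <- stats::runif(1, fr[1], fr[2]) * min(d)
  r_axes <- r0 * stats::runif(3, 0.85, 1.15)
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2)) * stats::runif(1)^(1 / 3)
  # offset scale 0.55 * semi keeps the whole lesion inside the unit ellipsoid
  les_ctr <- ctr + v * pmax(0.55 * semi - r_axes, 0)
  lesion <- ((ax - les_ctr[1]) / r_axes[1])^2 +
    ((ay - les_ctr[2]) / r_axes[2])^2 +
    ((az - les_ctr[3]) / r_axes[3])^2 <= 1
  lesion <- lesion & brain
  rim <- lesion & (((ax - les_ctr[1]) / pmax(r_axes[1] - 1, 0.5))^2 +
                     ((ay - les_ctr[2]) / pmax(r_axes[2] - 1, 0.5))^2 +
                     ((az - les_ctr[3]) / pmax(r_axes[3] - 1, 0.5))^2 > 1)

  # smooth shared tissue texture
  texture <- conv3d_same(array(stats::rnorm(prod(d)), dim = d),
                         .gauss_kernel3())
  texture <- texture / max(stats::sd(texture), 1e-12) * 0.03

  base <- c(t1 = 0.55, t1ce = 0.50, t2 = 0.40, flair = 0.45)
  lesion_shift <- c(t1 = -0.12, t1ce = 0.05, t2 = 0.25, flair = 0.20)
  vol <- array(0, dim = c(d, 4L))
  speckle <- if (label == "HGG") {
    1 + spec$heterogeneity * array(stats::rnorm(prod(d)), dim = d)
  } else NULL
  for (cc in 1:4) {
    ch <- array(0.02, dim = d)
    ch[brain] <- base[cc] + texture[brain]
    ch[lesion] <- ch[lesion] + lesion_shift[cc]
    if (label == "HGG") {
      if (cc >= 2) ch[lesion] <- ch[lesion] * speckle[lesion]
      if (cc == 2) ch[rim] <- ch[rim] + spec$contrast_effect
      if (cc == 4) ch[lesion] <- ch[lesion] + 0.15
    }
    # Rician-like noise: magnitude of complex Gaussian around the signal
    n1 <- array(stats::rnorm(prod(d), sd = spec$noise_sigma), dim = d)
    n2 <- array(stats::rnorm(prod(d), sd = spec$noise_sigma), dim = d)
    vol[, , , cc] <- sqrt((ch + n1)^2 + n2^2)
  }
  list(volume = vol, label = label, mask = lesion, split = NA_character_,
       case_id = case_id)
}

#' Generate a labeled synthetic cohort with train/val/test splits
#'
#' Generates `n_hgg + n_lgg` cases and assigns splits per class by the
#' spec's split counts using a stratified seeded shuffle.  The manifest
#' records `case_id`, `label` and `split` for every case.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `gliofuzz_cohort`: list with `samples`,
#'   `manifest` (data.frame) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    counts <- list(HGG = spec$n_hgg, LGG = spec$n_lgg)
    samples <- list()
    for (cl in c("HGG", "LGG")) {
      n <- counts[[cl]]
      sc <- spec$split_counts[[cl]]
      split_tags <- rep(c("train", "val", "test"), times = sc)
      split_tags <- split_tags[sample.int(n)]
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", cl, i)
        s <- .generate_case_impl(cl, spec, id)
        s$split <- split_tags[i]
        samples[[id]] <- s
      }
    }
    manifest <- data.frame(
      case_id = vapply(samples, `[[`, character(1), "case_id"),
      label = vapply(samples, `[[`, character(1), "label"),
      split = vapply(samples, `[[`, character(1), "split"),
      row.names = NULL, stringsAsFactors = FALSE
    )
    structure(list(samples = samples, manifest = manifest, spec = spec),
              class = "gliofuzz_cohort")
  })
}
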