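# --- binary 3D morphology on top of the compiled convolution ---------------

# Ball structuring element of integer radius r.
.ball_se <- function(r) {
  w <- 2L * r + 1L
  g <- seq(-r, r)
  d2 <- outer(outer(g^2, g^2, `+`), g^2, `+`)
  array(as.numeric(d2 <= r^2), dim = c(w, w, w))
}

.dilate3d <- function(mask, se) {
  conv3d_same(array(as.numeric(mask), dim = dim(mask)), se) > 1e-9
}

.erode3d <- function(mask, se) {
  conv3d_same(array(as.numeric(mask), dim = dim(mask)), se) >= sum(se) - 1e-9
}

.open3d <- function(mask, r) { se <- .ball_se(r); .dilate3d(.erode3d(mask, se), se) }
.close3d <- function(mask, r) { se <- .ball_se(r); .erode3d(.dilate3d(mask, se), se) }

# Connected components of a logical 3D array (26- or 6-connectivity).
.label3d <- function(mask, connectivity = 26L) {
  m <- array(as.integer(mask), dim = dim(mask))
  .label3d_cpp(m, as.integer(connectivity))
}

.largest_component <- function(mask, connectivity = 26L) {
  lab <- .label3d(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# Fill interior holes: background components (6-connectivity) that do not
# touch the array border are part of the object.
.fill_holes3d <- function(mask) {
  bg <- .label3d(!mask, 6L)
  d <- dim(mask)
  border_labels <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                            bg[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (bg > 0L & !(bg %in% border_labels))
}

# Otsu threshold over a 256-bin histogram (maximizes between-class variance).
.otsu_threshold <- function(v, bins = 256L) {
  rng <- range(v)
  if (diff(rng) <= 0) stop("otsu: constant input")
  h <- tabulate(pmin(bins, floor((v - rng[1]) / diff(rng) * bins) + 1L), bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  mu_t <- mu[bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / bins * diff(rng)
}

#' Preprocessing configuration
#'
#' @param target_inplane Output in-plane size (default 128; must be at
#'   least 16 and divisible by 16 so four pooling stages stay integral).
#' @param equalize Apply histogram equalization over brain voxels (TRUE).
#' @param strip Compute and apply the skull-strip mask (TRUE).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_inplane = 128L, equalize = TRUE,
                              strip = TRUE) {
  target_inplane <- as.integer(target_inplane)
  if (target_inplane < 16L || target_inplane %% 16L != 0L) {
    stop("target_inplane must be >= 16 and divisible by 16")
  }
  structure(list(target_inplane = target_inplane,
                 equalize = isTRUE(equalize), strip = isTRUE(strip)),
            class = "preprocess_config")
}

#' Skull-strip mask from a single-channel volume
#'
#' Otsu threshold on the intensity histogram, largest 26-connected
#' foreground component, binary closing with a ball of radius 2, then hole
#' filling; the result is a single connected brain mask.
#'
#' @param volume 3D numeric array (non-constant).
#' @return Logical 3D array.
#' @export
skull_strip_mask <- function(volume) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  if (diff(range(volume)) <= 0) {
    stop("skull_strip_mask: constant volume has no foreground")
  }
  thr <- .otsu_threshold(as.numeric(volume))
  fg <- volume > thr
  if (!any(fg)) stop("skull_strip_mask: empty foreground after thresholding")
  m <- .largest_component(fg)
  m <- .close3d(m, 2L)
  m <- .fill_holes3d(m)
  .largest_component(m)
}

# Bilinear in-plane resample of one 3D channel to t x t (depth untouched).
.resample_inplane <- function(x, t) {
  d <- dim(x)
  if (d[1] == t && d[2] == t) return(x)
  map <- function(n_src) {
    s <- (seq_len(t) - 0.5) * n_src / t + 0.5
    s <- pmin(pmax(s, 1), n_src)
    i0 <- pmin(floor(s), n_src - 1L)
    list(i0 = as.integer(i0), w = s - i0)
  }
  mx <- map(d[1]); my <- map(d[2])
  out <- array(0, dim = c(t, t, d[3]))
  for (z in seq_len(d[3])) {
    sl <- x[, , z]
    rows <- sl[mx$i0, , drop = FALSE] * (1 - mx$w) +
      sl[mx$i0 + 1L, , drop = FALSE] * mx$w
    out[, , z] <- rows[, my$i0, drop = FALSE] %*% diag(1 - my$w, t) +
      rows[, my$i0 + 1L, drop = FALSE] %*% diag(my$w, t)
  }
  out
}

# Histogram equalization (256 bins) restricted to the given voxels.
.equalize_masked <- function(v, bins = 256L) {
  if (diff(range(v)) <= 0) return(v)
  b <- pmin(bins, floor(v * (bins - 1L)) + 1L)
  h <- tabulate(b, bins)
  cdf <- cumsum(h) / length(v)
  cdf_min <- cdf[which(h > 0)[1]]
  (cdf[b] - cdf_min) / max(1 - cdf_min, 1e-12)
}

#' Preprocess a 4-channel volume
#'
#' Applies the shared skull-strip mask computed from the first (T1-like)
#' channel, min-max scales brain voxels of each channel to `[0, 1]`
#' (background stays 0), bilinearly resamples the in-plane dims to
#' `target_inplane` squared (depth is never resampled), and optionally
#' applies 256-bin histogram equalization over brain voxels.  Channel
#' order is preserved.  A channel that is constant over the brain is
#' mapped to all zeros with a warning.
#'
#' @param volume 4D numeric array (`nx x ny x nz x 4`) or a sample list
#'   with a `$volume` element.
#' @param cfg A [preprocess_config()].
#' @return 4D numeric array `target x target x nz x 4` in `[0, 1]`.
#' @export
preprocess_volume <- function(volume, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (is.list(volume)) volume <- volume$volume
  d <- dim(volume)
  if (is.null(d) || length(d) != 4L) stop("preprocess_volume: need a 4D array")
  mask <- if (cfg$strip) skull_strip_mask(volume[, , , 1]) else
    array(TRUE, dim = d[1:3])

  t <- cfg$target_inplane
  out <- array(0, dim = c(t, t, d[3], d[4]))
  mask_r <- .resample_inplane(array(as.numeric(mask), dim = d[1:3]), t) > 0.5
  for (cc in seq_len(d[4])) {
    ch <- volume[, , , cc]
    ch[!mask] <- 0
    bv <- ch[mask]
    if (diff(range(bv)) <= 0) {
      warning(sprintf("channel %d is constant over the brain; mapped to zeros", cc))
      next
    }
    ch[mask] <- (bv - min(bv)) / (max(bv) - min(bv))
    ch <- .resample_inplane(ch, t)
    ch[!mask_r] <- 0
    ch <- pmin(pmax(ch, 0), 1)
    if (cfg$equalize) ch[mask_r] <- .equalize_masked(ch[mask_r])
    out[, , , cc] <- ch
  }
  attr(out, "brain_mask") <- mask_r
  out
}
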