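#' @useDynLib gliofuzz, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Interval type-2 triangular membership function
#'
#' A symmetric triangular fuzzy term whose membership grade is an interval:
#' the upper bound uses a wider support than the lower bound, and the region
#' between the two is the footprint of uncertainty (FOU).  Both bounds peak
#' at 1 at `peak`.
#'
#' @param peak Apex position on the `[0, 1]` universe.
#' @param lower_halfwidth Half-support of the lower membership bound
#'   (must be strictly smaller than `upper_halfwidth`).
#' @param upper_halfwidth Half-support of the upper membership bound.
#' @return An object of class `it2_triangular`.
#' @examples
#' mf <- it2_triangular(0.5, 0.4, 0.6)
#' membership_interval(0.8, mf)
#' @export
it2_triangular <- function(peak, lower_halfwidth, upper_halfwidth) {
  stopifnot(is.numeric(peak), length(peak) == 1L, is.finite(peak))
  if (!is.finite(lower_halfwidth) || !is.finite(upper_halfwidth) ||
      lower_halfwidth <= 0 || upper_halfwidth <= 0) {
    stop("halfwidths must be finite and positive")
  }
  if (lower_halfwidth >= upper_halfwidth) {
    stop("lower_halfwidth must be strictly smaller than upper_halfwidth ",
         "(the footprint of uncertainty must have positive width)")
  }
  structure(
    list(peak = peak,
         lower_halfwidth = lower_halfwidth,
         upper_halfwidth = upper_halfwidth),
    class = "it2_triangular"
  )
}

#' Membership interval of an interval type-2 triangular term
#'
#' Evaluates the lower and upper membership bounds at `x`:
#' `max(0, 1 - |x - peak| / halfwidth)` with the term's lower and upper
#' half-supports respectively, so the lower grade never exceeds the upper.
#'
#' @param x Numeric vector of universe values (finite).
#' @param mf An [it2_triangular()] term.
#' @return A list with numeric vectors `lower` and `upper`, both in `[0, 1]`.
#' @export
membership_interval <- function(x, mf) {
  stopifnot(inherits(mf, "it2_triangular"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("membership_interval: x must be finite numeric")
  }
  d <- abs(x - mf$peak)
  list(lower = pmax(0, 1 - d / mf$lower_halfwidth),
       upper = pmax(0, 1 - d / mf$upper_halfwidth))
}

#' Default fuzzy rule base for kernel weight generation
#'
#' Nine Takagi-Sugeno rules over the Cartesian product of the linguistic
#' terms \{Low, Mid, High\} for the two antecedents `numin` (normalized
#' spatial index) and `code` (shape control), each mapping to a singleton
#' consequent category L, M or H.  Antecedent terms are interval type-2
#' triangles on `[0, 1]` with peaks at 0, 0.5 and 1, base halfwidth `h`
#' and footprint-of-uncertainty halfwidth perturbation `delta` (upper
#' support `h + delta`, lower support `h - delta`).
#'
#' The antecedent-to-consequent map is, by `code` column
#' (numin = Low, Mid, High):
#' code Low -> L, M, H; code Mid -> H, M, L; code High -> H, L, H.
#'
#' @param h Base halfwidth of each triangular term (default 0.5).
#' @param delta FOU halfwidth perturbation (default 0.1, `0 < delta < h`).
#' @param consequents Named numeric vector with entries `L`, `M`, `H`,
#'   strictly increasing and inside (0, 1).
#' @return An object of class `fuzzy_rulebase`.
#' @export
default_rulebase <- function(h = 0.5, delta = 0.1,
                             consequents = c(L = 0.25, M = 0.50, H = 0.75)) {
  stopifnot(delta > 0, delta < h)
  cq <- consequents[c("L", "M", "H")]
  if (any(is.na(cq)) || any(diff(cq) <= 0) || any(cq <= 0) || any(cq >= 1)) {
    stop("consequents must be named L/M/H, strictly increasing, inside (0,1)")
  }
  terms <- list(
    Low  = it2_triangular(0.0, h - delta, h + delta),
    Mid  = it2_triangular(0.5, h - delta, h + delta),
    High = it2_triangular(1.0, h - delta, h + delta)
  )
  rules <- data.frame(
    numin = rep(c("Low", "Mid", "High"), times = 3),
    code  = rep(c("Low", "Mid", "High"), each = 3),
    numout = c("L", "M", "H",   # code = Low
               "H", "M", "L",   # code = Mid
               "H", "L", "H"),  # code = High
    stringsAsFactors = FALSE
  )
  structure(
    list(terms = terms, rules = rules, consequents = cq,
         h = h, delta = delta),
    class = "fuzzy_rulebase"
  )
}

#' Interval type-2 Takagi-Sugeno inference
#'
#' For each of the nine rules the firing interval is the min t-norm of the
#' two antecedents' lower/upper membership grades; the crisp output is the
#' Nie-Tan type reduction, the average-firing-strength weighted mean of the
#' singleton consequents:
#' `s = sum_r ((fl_r + fu_r)/2) y_r / sum_r ((fl_r + fu_r)/2)`.
#'
#' `numin` may be a vector (inference is applied elementwise); `code` is a
#' scalar.  The output always lies between the smallest and largest
#' consequent values.
#'
#' @param numin Numeric vector in `[0, 1]` (normalized spatial index).
#' @param code Scalar in `[0, 1]` (shape control).
#' @param rulebase A [default_rulebase()] object.
#' @return Numeric vector of type-reduced outputs, same length as `numin`.
#' @export
infer_pattern <- function(numin, code, rulebase = default_rulebase()) {
  stopifnot(inherits(rulebase, "fuzzy_rulebase"),
            is.numeric(code), length(code) == 1L)
  if (any(!is.finite(numin)) || any(numin < 0) || any(numin > 1)) {
    stop("infer_pattern: numin must lie in [0, 1]")
  }
  if (!is.finite(code) || code < 0 || code > 1) {
    stop("infer_pattern: code must lie in [0, 1]")
  }
  term_names <- names(rulebase$terms)
  g_numin <- lapply(rulebase$terms, function(mf) membership_interval(numin, mf))
  g_code  <- lapply(rulebase$terms, function(mf) membership_interval(code, mf))

  num <- rep(0, length(numin))
  den <- rep(0, length(numin))
  for (r in seq_len(nrow(rulebase$rules))) {
    a <- g_numin[[rulebase$rules$numin[r]]]
    b <- g_code[[rulebase$rules$code[r]]]
    f_lower <- pmin(a$lower, b$lower)
    f_upper <- pmin(a$upper, b$upper)
    w <- (f_lower + f_upper) / 2
    y <- rulebase$consequents[[rulebase$rules$numout[r]]]
    num <- num + w * y
    den <- den + w
  }
  if (any(den <= 0)) {
    stop("infer_pattern: no rule fired (degenerate term layout)")
  }
  unname(num / den)
}

#' Two-parameter filter gene
#'
#' The pair of meta-parameters that replaces a convolution kernel's native
#' coefficients: `w` controls the cosine dispersion phase and `code` the
#' fuzzy-inferred spatial pattern.  Both are clamped to `[0, 1]`.
#'
#' @param w,code Scalars; clamped into `[0, 1]`.
#' @return An object of class `filter_gene`.
#' @export
filter_gene <- function(w, code) {
  stopifnot(is.numeric(w), is.numeric(code),
            length(w) == 1L, length(code) == 1L,
            is.finite(w), is.finite(code))
  structure(list(w = min(max(w, 0), 1), code = min(max(code, 0), 1)),
            class = "filter_gene")
}

.supported_kernel_sizes <- c(9L, 25L, 27L, 49L, 125L)

#' Generate kernel coefficients from a filter gene
#'
#' The weight-generating function: positions `p_i = (i + 0.5)/n` for
#' `i = 0..n-1` are fed as `numin` to the interval type-2 Takagi-Sugeno
#' engine together with the gene's `code`, giving an intermediate pattern
#' `Win_i`; the coefficients are the cosine dispersion
#' `W_i = 3 * cos(pi * w * Win_i)`.  The same two-scalar gene therefore
#' produces 9, 25, 27, 49 or 125 coefficients on demand, and the output is
#' fully deterministic in `(gene, n)`.
#'
#' Because `Win_i` lies within the consequent range and `w` in `[0, 1]`,
#' every coefficient is bounded by 3 in absolute value.
#'
#' @param gene A [filter_gene()].
#' @param n Number of coefficients; one of 9, 25, 27, 49, 125
#'   (3x3, 5x5, 3x3x3, 7x7, 5x5x5 footprints).
#' @param rulebase Rule base used for inference.
#' @return An object of class `kernel_weights`: list with `values`
#'   (numeric length `n`) and `n`.
#' @examples
#' weighting_func(filter_gene(0.5, 0.5), 9)
#' @export
weighting_func <- function(gene, n, rulebase = default_rulebase()) {
  stopifnot(inherits(gene, "filter_gene"))
  n <- as.integer(n)
  if (length(n) != 1L || !(n %in% .supported_kernel_sizes)) {
    stop("weighting_func: n must be one of ",
         paste(.supported_kernel_sizes, collapse = ", "))
  }
  p <- (seq_len(n) - 0.5) / n
  win <- infer_pattern(p, gene$code, rulebase)
  w_i <- 3 * cos(pi * gene$w * win)
  structure(list(values = w_i, n = n), class = "kernel_weights")
}

#' Network architecture specification
#'
#' Five 3D convolutional layers with channel depths 8, 16, 32, 64, 128,
#' 3x3x3 kernels and same padding; max pooling of stride 2 follows layers
#' 1-4 and a global average pool follows layer 5, so the per-volume feature
#' vector has length equal to the last channel count (128).
#'
#' @param channels Integer vector of per-layer output channel counts.
#' @param kernel_shape Kernel dims, default `c(3, 3, 3)`.
#' @param in_channels Input modality count (default 4: T1, T1ce, T2, FLAIR).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(channels = c(8L, 16L, 32L, 64L, 128L),
                         kernel_shape = c(3L, 3L, 3L),
                         in_channels = 4L) {
  channels <- as.integer(channels)
  kernel_shape <- as.integer(kernel_shape)
  stopifnot(length(channels) >= 1L, all(channels >= 1L),
            length(kernel_shape) == 3L, all(kernel_shape %% 2L == 1L),
            in_channels >= 1L)
  structure(
    list(channels = channels, kernel_shape = kernel_shape,
         in_channels = as.integer(in_channels),
         n_layers = length(channels),
         feature_length = channels[length(channels)]),
    class = "network_spec"
  )
}

#' Build the per-layer kernel bank from filter genes
#'
#' Turns genes into the network's effective convolution weights.  In untied
#' mode `genes` holds one gene per filter (per output channel of each
#' layer); in layer-tied mode a single gene per layer generates one kernel
#' shared by all of that layer's filters.  Each generated kernel is
#' replicated across a filter's input channels, which keeps the trainable
#' count at two scalars per filter (or per layer when tied).
#'
#' @param genes A list with one element per layer; each element either a
#'   single `filter_gene` (tied) or a list of `filter_gene`s of length equal
#'   to the layer's output channel count (untied).
#' @param spec A [network_spec()].
#' @param rulebase Rule base forwarded to [weighting_func()].
#' @return An object of class `kernel_bank`: per layer a 4D array
#'   `kernel_shape x n_out` of coefficients plus a `tied` flag.
#' @export
build_kernel_bank <- function(genes, spec, rulebase = default_rulebase()) {
  stopifnot(inherits(spec, "network_spec"), is.list(genes))
  if (length(genes) != spec$n_layers) {
    stop(sprintf("build_kernel_bank: %d gene groups supplied for %d layers",
                 length(genes), spec$n_layers))
  }
  n_coef <- prod(spec$kernel_shape)
  layers <- vector("list", spec$n_layers)
  for (l in seq_len(spec$n_layers)) {
    g <- genes[[l]]
    n_out <- spec$channels[l]
    if (inherits(g, "filter_gene")) {
      kw <- weighting_func(g, n_coef, rulebase)
      kern <- array(kw$values, dim = spec$kernel_shape)
      layers[[l]] <- structure(
        list(kernels = array(kern, dim = c(spec$kernel_shape, n_out)),
             tied = TRUE, n_out = n_out),
        kernel = kern)
    } else if (is.list(g)) {
      if (length(g) != n_out) {
        stop(sprintf(paste0("build_kernel_bank: layer %d has %d genes but ",
                            "%d output channels"), l, length(g), n_out))
      }
      arr <- array(0, dim = c(spec$kernel_shape, n_out))
      for (j in seq_len(n_out)) {
        stopifnot(inherits(g[[j]], "filter_gene"))
        arr[, , , j] <- array(weighting_func(g[[j]], n_coef, rulebase)$values,
                              dim = spec$kernel_shape)
      }
      layers[[l]] <- list(kernels = arr, tied = FALSE, n_out = n_out)
    } else {
      stop("build_kernel_bank: each layer needs a filter_gene or a list of them")
    }
  }
  structure(list(layers = layers, spec = spec), class = "kernel_bank")
}

#' Trainable-parameter ledger of the generator
#'
#' Audits how many scalars the optimizer actually controls: two per filter
#' (or per layer in tied mode) instead of the kernel's native coefficient
#' count, plus one ReLU slope per layer.  For a 3x3x3 kernel the per-filter
#' reduction is (27 - 2)/27 = 92.59...%.
#'
#' @param spec A [network_spec()].
#' @param tied Logical; layer-tied genes (default `FALSE`).
#' @return List with `n_filters`, `gene_scalars`, `relu_scalars`,
#'   `native_per_filter`, `reduction_pct` (per-filter percentage).
#' @export
parameter_ledger <- function(spec = network_spec(), tied = FALSE) {
  stopifnot(inherits(spec, "network_spec"))
  n_filters <- sum(spec$channels)
  n_units <- if (tied) spec$n_layers else n_filters
  native <- prod(spec$kernel_shape)
  list(
    n_filters = n_filters,
    gene_scalars = 2L * n_units,
    relu_scalars = spec$n_layers,
    native_per_filter = native,
    trainable_per_filter = 2L,
    reduction_pct = 100 * (native - 2) / native
  )
}
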