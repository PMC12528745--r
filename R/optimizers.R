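#' Optimizer configuration
#'
#' Settings shared by the particle-swarm, transit-search and hybrid
#' optimizers.  All optimizers minimize over a bounded box; every source
#' of randomness flows from `seed`.
#'
#' @param lower,upper Numeric vectors of per-dimension box bounds.
#' @param population Swarm/host count (>= 2).
#' @param iterations Iteration count (>= 1).
#' @param seed Integer seed.
#' @param pso List: `inertia` (0.729), `cognitive` (1.49445),
#'   `social` (1.49445), `vclamp_frac` (velocity clamp as a fraction of the
#'   box range, 0.5).
#' @param tso List: `explore_frac` (probability of a transit move, 0.5),
#'   `neighbor_frac` (probability of a neighbor recombination move, 0.25;
#'   the remainder exploits around the global best), `perturb_scale`
#'   (heavy-tailed noise scale as a fraction of the range, 0.05),
#'   `radius0` (initial exploitation radius fraction, 0.3),
#'   `shrink_rate` (per-iteration radius multiplier, 0.95).
#' @param hybrid List: `split` — fraction of iterations given to the
#'   transit-search phase before the swarm refinement phase (0.5).
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(lower, upper,
                             population = 16L,
                             iterations = 50L,
                             seed = 1L,
                             pso = list(),
                             tso = list(),
                             hybrid = list()) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  population <- as.integer(population); iterations <- as.integer(iterations)
  stopifnot(population >= 2L, iterations >= 1L)
  pso <- utils::modifyList(
    list(inertia = 0.729, cognitive = 1.49445, social = 1.49445,
         vclamp_frac = 0.5), pso)
  tso <- utils::modifyList(
    list(explore_frac = 0.5, neighbor_frac = 0.25, perturb_scale = 0.05,
         radius0 = 0.3, shrink_rate = 0.95), tso)
  hybrid <- utils::modifyList(list(split = 0.5), hybrid)
  structure(
    list(lower = lower, upper = upper, dim = length(lower),
         population = population, iterations = iterations,
         seed = as.integer(seed), pso = pso, tso = tso, hybrid = hybrid),
    class = "optimizer_config"
  )
}

# Evaluation wrapper: counts calls, maps non-finite objective values to +Inf.
.make_counter <- function(objective) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$nonfinite <- 0L
  env$f <- function(x) {
    env$n <- env$n + 1L
    v <- objective(x)
    if (!is.finite(v)) {
      env$nonfinite <- env$nonfinite + 1L
      v <- Inf
    }
    v
  }
  env
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.init_population <- function(cfg, counter) {
  D <- cfg$dim
  X <- matrix(stats::runif(cfg$population * D), cfg$population, D)
  X <- sweep(sweep(X, 2, cfg$upper - cfg$lower, `*`), 2, cfg$lower, `+`)
  fit <- apply(X, 1, counter$f)
  list(X = X, fit = fit)
}

# Core PSO loop; assumes RNG already seeded. init: list(X, fit) or NULL.
.pso_core <- function(counter, cfg, iterations, init = NULL) {
  D <- cfg$dim
  rng_range <- cfg$upper - cfg$lower
  vmax <- cfg$pso$vclamp_frac * rng_range
  if (is.null(init)) init <- .init_population(cfg, counter)
  X <- init$X; fit <- init$fit
  P <- X; pfit <- fit
  gi <- which.min(pfit); G <- P[gi, ]; gfit <- pfit[gi]
  V <- matrix(stats::runif(cfg$population * D, -0.1, 0.1), cfg$population, D) *
    matrix(rng_range, cfg$population, D, byrow = TRUE)
  history <- numeric(iterations)
  for (it in seq_len(iterations)) {
    r1 <- matrix(stats::runif(cfg$population * D), cfg$population, D)
    r2 <- matrix(stats::runif(cfg$population * D), cfg$population, D)
    V <- cfg$pso$inertia * V +
      cfg$pso$cognitive * r1 * (P - X) +
      cfg$pso$social * r2 * sweep(-X, 2, G, `+`)
    V <- sweep(V, 2, vmax, function(v, m) pmin(pmax(v, -m), m))
    X <- X + V
    X <- sweep(sweep(X, 2, cfg$lower, pmax), 2, cfg$upper, pmin)
    fit <- apply(X, 1, counter$f)
    imp <- fit < pfit
    P[imp, ] <- X[imp, , drop = FALSE]
    pfit[imp] <- fit[imp]
    bi <- which.min(pfit)
    if (pfit[bi] < gfit) { gfit <- pfit[bi]; G <- P[bi, ] }
    history[it] <- gfit
  }
  list(best = list(position = G, fitness = gfit), history = history,
       population = list(X = P, fit = pfit))
}

# Core transit-search loop; assumes RNG already seeded.
.tso_core <- function(counter, cfg, iterations, init = NULL) {
  D <- cfg$dim
  rng_range <- cfg$upper - cfg$lower
  if (is.null(init)) init <- .init_population(cfg, counter)
  X <- init$X; fit <- init$fit
  gi <- which.min(fit); G <- X[gi, ]; gfit <- fit[gi]
  radius <- cfg$tso$radius0
  history <- numeric(iterations)
  p_transit <- cfg$tso$explore_frac
  p_neigh <- cfg$tso$explore_frac + cfg$tso$neighbor_frac
  for (it in seq_len(iterations)) {
    for (i in seq_len(cfg$population)) {
      u <- stats::runif(1)
      if (u < p_transit) {
        # transit: probe between self and global best, heavy-tailed noise
        y <- X[i, ] + stats::runif(D) * (G - X[i, ]) +
          cfg$tso$perturb_scale * rng_range * stats::rcauchy(D)
      } else if (u < p_neigh) {
        # neighbor: blend recombination with a random other host
        j <- sample.int(cfg$population, 1L)
        if (j == i) j <- (i %% cfg$population) + 1L
        a <- stats::runif(D)
        y <- a * X[i, ] + (1 - a) * X[j, ]
      } else {
        # exploitation: shrinking Gaussian around the global best
        y <- G + radius * rng_range * stats::rnorm(D)
      }
      y <- .clamp(y, cfg$lower, cfg$upper)
      fy <- counter$f(y)
      if (fy < fit[i]) { X[i, ] <- y; fit[i] <- fy }
      if (fy < gfit) { gfit <- fy; G <- y }
    }
    radius <- radius * cfg$tso$shrink_rate
    history[it] <- gfit
  }
  list(best = list(position = G, fitness = gfit), history = history,
       population = list(X = X, fit = fit))
}

.finish_run <- function(res, counter) {
  res$evaluations <- counter$n
  res$nonfinite <- counter$nonfinite
  res
}

#' Particle swarm optimization
#'
#' Standard global-best PSO with inertia, cognitive and social terms,
#' velocities clamped to a fraction of the box range and positions clamped
#' to the bounds.  Minimizes.  Deterministic given `config$seed`.
#'
#' @param objective Function from a numeric vector (length `config$dim`)
#'   to a scalar; non-finite values are treated as `+Inf` and counted.
#' @param config An [optimizer_config()].
#' @param init Optional warm start: list with matrix `X`
#'   (population x dim) and vector `fit` of already-known fitnesses.
#' @return List: `best` (`position`, `fitness`), `history` (best-so-far per
#'   iteration, non-increasing), `population`, `evaluations`, `nonfinite`.
#' @export
run_pso <- function(objective, config, init = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  counter <- .make_counter(objective)
  res <- withr::with_seed(config$seed,
    .pso_core(counter, config, config$iterations, init))
  .finish_run(res, counter)
}

#' Transit-search-style global optimizer
#'
#' Population metaheuristic with three move types per host and iteration:
#' a transit move probing a random point between the host and the global
#' best plus heavy-tailed (Cauchy) noise; a neighbor move recombining with
#' a random other host; and an exploitation move sampling a Gaussian around
#' the global best with a radius that shrinks geometrically per iteration.
#' Improvements are accepted greedily and the global best is elitist, so
#' the best-so-far trace never increases.
#'
#' @inheritParams run_pso
#' @return As [run_pso()].
#' @export
run_tso <- function(objective, config, init = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  counter <- .make_counter(objective)
  res <- withr::with_seed(config$seed,
    .tso_core(counter, config, config$iterations, init))
  .finish_run(res, counter)
}

#' Hybrid transit-search + particle-swarm optimizer
#'
#' Runs the transit-search explorer for the first `hybrid$split` fraction
#' of the iteration budget, then hands its final population (global best
#' included) to PSO for refinement.  Elitism across the hand-off guarantees
#' the final best is no worse than the transit-phase best.  With
#' `split = 1` the run is identical to [run_tso()] under the same seed.
#'
#' @inheritParams run_pso
#' @return As [run_pso()], plus `split_iteration` (iterations given to the
#'   transit phase).
#' @export
run_hybrid <- function(objective, config, init = NULL) {
  stopifnot(inherits(config, "optimizer_config"))
  n1 <- round(config$hybrid$split * config$iterations)
  n1 <- max(0L, min(config$iterations, as.integer(n1)))
  n2 <- config$iterations - n1
  counter <- .make_counter(objective)
  res <- withr::with_seed(config$seed, {
    if (n1 > 0L) {
      r1 <- .tso_core(counter, config, n1, init)
    } else {
      ip <- if (is.null(init)) .init_population(config, counter) else init
      gi <- which.min(ip$fit)
      r1 <- list(best = list(position = ip$X[gi, ], fitness = ip$fit[gi]),
                 history = numeric(0), population = ip)
    }
    if (n2 > 0L) {
      r2 <- .pso_core(counter, config, n2, init = r1$population)
      best <- if (r2$best$fitness <= r1$best$fitness) r2$best else r1$best
      list(best = best, history = c(r1$history, r2$history),
           population = r2$population)
    } else r1
  })
  res$split_iteration <- n1
  .finish_run(res, counter)
}
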