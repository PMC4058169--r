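#' Lévy-flight proposal
#'
#' Proposes a new position `current + alpha * step * (current - best)` where
#' `step` is a heavy-tailed Lévy-stable variate drawn per dimension by
#' Mantegna's algorithm with stability index `lambda` (the Yang–Deb cuckoo
#' search convention; `lambda = 1.5` gives tail exponent ~1.5, so occasional
#' long jumps escape local basins). The drift factor `(current - best)`
#' shrinks the walk as a nest approaches the best solution. When
#' `current == best` the drift vanishes; as a documented fallback the step is
#' then taken directly (`current + alpha * step`) so the best nest can still
#' move. `alpha = 0` always returns `current`.
#'
#' @param current,best position vectors.
#' @param alpha step scale per dimension (scalar or vector); the cuckoo
#'   driver uses 1% of each dimension's range.
#' @param lambda Lévy stability index in (1, 3].
#' @param bounds optional 2 x d matrix; the proposal is clamped to it.
#' @return the proposed position vector.
#' @export
levy_flight <- function(current, best, alpha, lambda = 1.5, bounds = NULL) {
  stopifnot(lambda > 1, lambda <= 3, all(alpha >= 0))
  d <- length(current)
  step <- levy_step(d, lambda)
  drift <- current - best
  prop <- if (all(drift == 0)) current + alpha * step
          else current + alpha * step * drift
  if (!is.null(bounds)) {
    bounds <- validate_bounds(bounds)
    prop <- pmin(pmax(prop, bounds[1, ]), bounds[2, ])
  }
  prop
}

# Mantegna's algorithm: step = u / |v|^(1/beta), u ~ N(0, sigma_u^2),
# v ~ N(0, 1), which approximates a symmetric Lévy-stable law of index beta.
levy_step <- function(n, beta) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  rnorm(n, 0, sigma_u) / abs(rnorm(n))^(1 / beta)
}

#' One cuckoo search generation
#'
#' Applies the three idealized brood-parasitism rules to a nest set:
#' (i) every nest emits one Lévy-flight cuckoo egg which is dumped into a
#' host nest and replaces it if strictly fitter; (ii) a fraction `pa` of the
#' worst nests (the current best nest excluded) is abandoned and re-seeded
#' with uniform random solutions; (iii) the best solution ever seen is
#' carried over unchanged, so the best-fitness trace is non-decreasing.
#'
#' Which nest hosts the egg is set by `nests$acceptance`: `"per-nest"`
#' (default) compares each egg against its own parent nest, the rule of the
#' reference cuckoo search implementation and the variant with reliably fast
#' late-stage refinement; `"random"` compares against a uniformly chosen
#' nest, as the textbook pseudocode states.
#'
#' @param nests nest-set list with `positions` (pop x d), `fitness`,
#'   `best_pos`, `best_fit`, `pa`, `alpha`, `lambda`, `acceptance`.
#' @param objective function of a position vector, maximized.
#' @param bounds 2 x d bounds matrix.
#' @return the updated nest set.
#' @export
cuckoo_step <- function(nests, objective, bounds) {
  bounds <- validate_bounds(bounds)
  pop <- nrow(nests$positions)
  random_host <- identical(nests$acceptance, "random")
  for (i in seq_len(pop)) {
    cand <- levy_flight(nests$positions[i, ], nests$best_pos,
                        nests$alpha, nests$lambda, bounds)
    fc <- objective(cand)
    j <- if (random_host) sample.int(pop, 1) else i
    if (fc > nests$fitness[j]) {
      nests$positions[j, ] <- cand
      nests$fitness[j] <- fc
    }
  }
  n_abandon <- floor(nests$pa * pop)
  if (n_abandon > 0) {
    keep_best <- which.max(nests$fitness)
    worst <- setdiff(order(nests$fitness), keep_best)[seq_len(n_abandon)]
    fresh <- random_positions(n_abandon, bounds)
    nests$positions[worst, ] <- fresh
    nests$fitness[worst] <- apply(fresh, 1, objective)
  }
  bi <- which.max(nests$fitness)
  if (nests$fitness[bi] > nests$best_fit) {
    nests$best_fit <- nests$fitness[bi]
    nests$best_pos <- nests$positions[bi, ]
  }
  nests
}

#' Cuckoo search with Lévy flights
#'
#' Population search driven by [cuckoo_step()]. Per generation the objective
#' is evaluated `pop + floor(pa * pop)` times (one Lévy proposal per nest
#' plus the abandonment refills), so a full run costs
#' `pop + iters * (pop + floor(pa * pop))` evaluations including
#' initialization — the count returned in `$evals`. The abandonment
#' probability default `pa = 0.25` is the reference setting of the tuning
#' experiments.
#'
#' @inheritParams optimize_pso
#' @param pa abandonment probability in (0, 1).
#' @param lambda Lévy stability index.
#' @param alpha_frac Lévy step scale as a fraction of each dimension's range
#'   (default 0.01).
#' @param acceptance egg-hosting rule, `"per-nest"` (default) or `"random"`;
#'   see [cuckoo_step()].
#' @return An `optim_run` with `best`, `trace`, `evals`, and `nests` (the
#'   final nest set, used to warm-start the hybrid's PSO stage).
#' @export
optimize_cuckoo <- function(objective, bounds, pop = 20L, iters = 100L,
                            pa = 0.25, lambda = 1.5, alpha_frac = 0.01,
                            acceptance = c("per-nest", "random"),
                            seed = 1L, trace_offset = 0L) {
  acceptance <- match.arg(acceptance)
  bounds <- validate_bounds(bounds)
  stopifnot(pa > 0, pa < 1)
  objective <- counted_objective(objective)
  with_seed(seed, {
    positions <- random_positions(pop, bounds)
    fitness <- apply(positions, 1, objective)
    bi <- which.max(fitness)
    nests <- list(positions = positions, fitness = fitness,
                  best_pos = positions[bi, ], best_fit = fitness[bi],
                  pa = pa, alpha = alpha_frac * (bounds[2, ] - bounds[1, ]),
                  lambda = lambda, acceptance = acceptance)
    trace <- vector("list", iters)
    for (g in seq_len(iters)) {
      nests <- cuckoo_step(nests, objective, bounds)
      trace[[g]] <- new_trace_row(g + trace_offset, nests$best_fit,
                                  mean(nests$fitness),
                                  stats::setNames(nests$best_pos, colnames(bounds)))
    }
    optim_result(stats::setNames(nests$best_pos, colnames(bounds)),
                 nests$best_fit, do.call(rbind, trace),
                 counted_total(objective), list(nests = nests))
  })
}
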