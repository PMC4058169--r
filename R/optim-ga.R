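#' One real-coded genetic algorithm generation
#'
#' Roulette-wheel selection on min-shifted fitness (all-equal fitness falls
#' back to uniform selection), blend (extended intermediate) crossover with
#' probability `pc` -- each gene of the two children is the complementary
#' pair `t x1 + (1 - t) x2` / `(1 - t) x1 + t x2` with an independent
#' `t ~ U(-blend_ext, 1 + blend_ext)` per gene, so children can fall
#' slightly outside the parents' span (pure convex recombination collapses
#' the population prematurely) -- per-gene Gaussian mutation with
#' probability `pm` and standard deviation `mut_sd` times the dimension
#' range, positions clamped to bounds, and 1-elitism: the previous best
#' individual replaces the worst child whenever it beats the best child.
#'
#' @param population list with `positions` (pop x d, pop even) and `fitness`.
#' @param objective function of a position vector, maximized.
#' @param bounds 2 x d bounds matrix.
#' @param pc crossover probability.
#' @param pm per-gene mutation probability.
#' @param mut_sd mutation standard deviation as a fraction of the range.
#' @param blend_ext crossover extension beyond the parents' interval
#'   (default 0.5, the customary blend-crossover setting).
#' @return the next-generation population list.
#' @export
ga_step <- function(population, objective, bounds, pc = 0.5, pm = 0.005,
                    mut_sd = 0.1, blend_ext = 0.5) {
  bounds <- validate_bounds(bounds)
  pop <- nrow(population$positions)
  stopifnot(pop %% 2 == 0)
  d <- ncol(population$positions)
  fit <- population$fitness

  w <- fit - min(fit)
  probs <- if (max(w) == 0) rep(1 / pop, pop) else w / sum(w)
  parents <- sample.int(pop, pop, replace = TRUE, prob = probs)
  children <- population$positions[parents, , drop = FALSE]
  for (p in seq(1, pop, by = 2)) {
    if (runif(1) < pc) {
      t <- runif(d, -blend_ext, 1 + blend_ext)
      p1 <- children[p, ]; p2 <- children[p + 1, ]
      children[p, ] <- t * p1 + (1 - t) * p2
      children[p + 1, ] <- (1 - t) * p1 + t * p2
    }
  }
  mutate <- matrix(runif(pop * d) < pm, pop, d)
  if (any(mutate)) {
    sds <- matrix(mut_sd * (bounds[2, ] - bounds[1, ]), pop, d, byrow = TRUE)
    children[mutate] <- children[mutate] + rnorm(sum(mutate), 0, sds[mutate])
  }
  children <- clamp_rows(children, bounds)
  child_fit <- apply(children, 1, objective)

  prev_best <- which.max(fit)
  if (fit[prev_best] > max(child_fit)) {
    worst <- which.min(child_fit)
    children[worst, ] <- population$positions[prev_best, ]
    child_fit[worst] <- fit[prev_best]
  }
  list(positions = children, fitness = child_fit)
}

#' Real-coded genetic algorithm
#'
#' Baseline tuner driven by [ga_step()]. Defaults follow the reference
#' settings of the tuning experiments: population 20, 100 generations,
#' crossover probability 0.5, mutation probability 0.005. The run costs
#' `pop + iters * pop` objective evaluations (`$evals`); elitism makes the
#' best-fitness trace non-decreasing.
#'
#' @inheritParams optimize_pso
#' @param pc crossover probability.
#' @param pm per-gene mutation probability.
#' @param mut_sd mutation standard deviation as a fraction of the range.
#' @param blend_ext crossover extension, see [ga_step()].
#' @return An `optim_run` with `best`, `trace`, `evals`.
#' @export
optimize_ga <- function(objective, bounds, pop = 20L, iters = 100L,
                        pc = 0.5, pm = 0.005, mut_sd = 0.1, blend_ext = 0.5,
                        seed = 1L) {
  bounds <- validate_bounds(bounds)
  objective <- counted_objective(objective)
  with_seed(seed, {
    positions <- random_positions(pop, bounds)
    population <- list(positions = positions,
                       fitness = apply(positions, 1, objective))
    best_fit <- max(population$fitness)
    best_pos <- population$positions[which.max(population$fitness), ]
    trace <- vector("list", iters)
    for (g in seq_len(iters)) {
      population <- ga_step(population, objective, bounds, pc, pm, mut_sd,
                            blend_ext)
      bi <- which.max(population$fitness)
      if (population$fitness[bi] > best_fit) {
        best_fit <- population$fitness[bi]
        best_pos <- population$positions[bi, ]
      }
      trace[[g]] <- new_trace_row(g, best_fit, mean(population$fitness),
                                  stats::setNames(best_pos, colnames(bounds)))
    }
    optim_result(stats::setNames(best_pos, colnames(bounds)), best_fit,
                 do.call(rbind, trace), counted_total(objective))
  })
}
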