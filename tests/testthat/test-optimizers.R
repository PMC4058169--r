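test_that("levy_flight degenerate cases follow the stated contract", {
  cur <- c(1, 2); best <- c(0, 0)
  # alpha = 0 always returns the current position
  set.seed(1)
  expect_identical(levy_flight(cur, best, alpha = 0), cur)
  expect_identical(levy_flight(best, best, alpha = 0), best)
  # proposals are clamped to the box
  set.seed(2)
  for (i in 1:20) {
    p <- levy_flight(c(4.9, 4.9), c(-4.9, -4.9), alpha = 1, bounds = bowl_bounds)
    expect_true(all(p >= -5 & p <= 5))
  }
  expect_error(levy_flight(cur, best, alpha = 1, lambda = 0.5))
})

test_that("Mantegna steps are heavy-tailed with index near 1.5", {
  set.seed(10)
  s <- cspsosvm:::levy_step(1e5, 1.5)
  # kurtosis far beyond the Gaussian value of 3
  k <- mean((s - mean(s))^4) / stats::var(s)^2
  expect_gt(k, 30)
  # Hill tail-index estimate on the top 1% of |s| is near 1.5
  a <- sort(abs(s), decreasing = TRUE)[1:1000]
  hill <- 1 / mean(log(a[-1000] / a[1000]))
  expect_gt(hill, 1.1)
  expect_lt(hill, 1.9)
})

test_that("a particle sitting at both bests with zero velocity stays put", {
  state <- cspsosvm:::pso_init(bowl, bowl_bounds, 4, 1.5, 1.7, 1)
  state$positions[1, ] <- state$pbest_pos[1, ] <- state$gbest_pos <- c(0, 0)
  state$velocities[1, ] <- 0
  state$fitness[1] <- state$pbest_fit[1] <- state$gbest_fit <- 0
  set.seed(3)
  out <- pso_step(state, bowl, bowl_bounds)
  expect_equal(out$positions[1, ], c(0, 0))
})

test_that("a constant objective leaves the cuckoo best unchanged", {
  flat <- function(x) 1
  r <- optimize_cuckoo(flat, bowl_bounds, pop = 6, iters = 10, seed = 4)
  expect_true(all(r$trace$best_fitness == 1))
})

test_that("GA with pc = pm = 0 propagates copies and preserves the best", {
  set.seed(5)
  pos <- cspsosvm:::random_positions(6, bowl_bounds)
  population <- list(positions = pos, fitness = apply(pos, 1, bowl))
  nxt <- ga_step(population, bowl, bowl_bounds, pc = 0, pm = 0)
  # every child is a copy of some parent
  parent_keys <- apply(pos, 1, paste, collapse = ",")
  child_keys <- apply(nxt$positions, 1, paste, collapse = ",")
  expect_true(all(child_keys %in% parent_keys))
  expect_equal(max(nxt$fitness), max(population$fitness))
})

test_that("GA with pm = 1 and large mutation decorrelates children from parents", {
  set.seed(6)
  pos <- matrix(0, 10, 2)
  population <- list(positions = pos, fitness = apply(pos, 1, bowl))
  nxt <- ga_step(population, bowl, bowl_bounds, pc = 0, pm = 1, mut_sd = 0.5)
  moved <- sqrt(rowSums(nxt$positions^2))
  expect_gt(mean(moved), 1)  # steps of ~0.5 * range = 5 per gene
})

test_that("every optimizer has a monotone elitist best-fitness trace", {
  noisy <- function(x) -sum(x^2) + rnorm(1, 0, 0.3)  # noisy objective
  runs <- list(
    optimize_pso(noisy, bowl_bounds, pop = 8, iters = 30, seed = 1),
    optimize_cuckoo(noisy, bowl_bounds, pop = 8, iters = 30, seed = 2),
    optimize_ga(noisy, bowl_bounds, pop = 8, iters = 30, seed = 3),
    optimize_hybrid(noisy, bowl_bounds, pop = 8, total_iters = 30, seed = 4)
  )
  for (r in runs) {
    expect_true(all(diff(r$trace$best_fitness) >= 0))
  }
})

test_that("every evaluated position respects the search bounds", {
  seen <- new.env(); seen$bad <- 0L
  watched <- function(x) {
    if (any(x < bowl_bounds[1, ] - 1e-12 | x > bowl_bounds[2, ] + 1e-12)) {
      seen$bad <- seen$bad + 1L
    }
    bowl(x)
  }
  invisible(optimize_pso(watched, bowl_bounds, pop = 6, iters = 15, seed = 5))
  invisible(optimize_cuckoo(watched, bowl_bounds, pop = 6, iters = 15, seed = 6))
  invisible(optimize_ga(watched, bowl_bounds, pop = 6, iters = 15, seed = 7))
  expect_equal(seen$bad, 0L)
})

test_that("objective evaluation counts match the documented budget formulas", {
  pop <- 6L; iters <- 12L; pa <- 0.25
  r <- optimize_pso(bowl, bowl_bounds, pop = pop, iters = iters, seed = 1)
  expect_equal(r$evals, pop + pop * iters)
  r <- optimize_ga(bowl, bowl_bounds, pop = pop, iters = iters, seed = 1)
  expect_equal(r$evals, pop + pop * iters)
  r <- optimize_cuckoo(bowl, bowl_bounds, pop = pop, iters = iters, pa = pa,
                       seed = 1)
  expect_equal(r$evals, pop + iters * (pop + floor(pa * pop)))
  # hybrid: cuckoo stage + pop * pso iters (population transfer, no re-eval)
  r <- optimize_hybrid(bowl, bowl_bounds, pop = pop, total_iters = iters,
                       cs_fraction = 0.5, seed = 1)
  cs_iters <- 6L
  expect_equal(r$evals,
               pop + cs_iters * (pop + floor(pa * pop)) + pop * (iters - cs_iters))
})

test_that("optimizer runs are reproducible under a fixed seed", {
  for (fn in list(optimize_pso, optimize_cuckoo, optimize_ga)) {
    a <- fn(bowl, bowl_bounds, pop = 6, iters = 10, seed = 42)
    b <- fn(bowl, bowl_bounds, pop = 6, iters = 10, seed = 42)
    expect_identical(a$trace, b$trace)
    c <- fn(bowl, bowl_bounds, pop = 6, iters = 10, seed = 43)
    expect_false(identical(a$trace, c$trace))
  }
})

test_that("optimizers close in on the bowl optimum at reduced budgets", {
  # smoke-level convergence; the full 100-run competence study lives in the
  # acceptance suite
  r <- optimize_pso(bowl, bowl_bounds, pop = 10, iters = 40, seed = 8)
  expect_lt(sqrt(sum(r$best$position^2)), 0.05)
  r <- optimize_cuckoo(bowl, bowl_bounds, pop = 10, iters = 40, seed = 8)
  expect_lt(sqrt(sum(r$best$position^2)), 0.2)
  r <- optimize_ga(bowl, bowl_bounds, pop = 10, iters = 40, seed = 8)
  expect_lt(sqrt(sum(r$best$position^2)), 0.5)
})

test_that("trace export round-trips through a delimited file", {
  r <- optimize_pso(bowl, bowl_bounds, pop = 4, iters = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(r$trace, path)
  back <- read.delim(path)
  expect_equal(back$generation, 1:5)
  expect_equal(back$best_fitness, r$trace$best_fitness)
})
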