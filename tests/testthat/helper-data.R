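# Fixtures built in code: tiny deterministic datasets and random problem
# generators used across the suite.

# the symmetric two-point problem whose dual optimum is alpha = (1/2, 1/2),
# b = 0 (maximize s - s^2/2 over s = alpha1 + alpha2 with alpha1 = alpha2)
toy_two_points <- function() {
  labeled_dataset(rbind(c(1, 0), c(-1, 0)), c(1, -1))
}

# random small two-class dataset with both classes guaranteed present
random_dataset <- function(n, d = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
  labeled_dataset(X, y)
}

# 2-D quadratic bowl objective and its box, the known-optimum benchmark
bowl <- function(x) -sum(x^2)
bowl_bounds <- rbind(lower = c(-5, -5), upper = c(5, 5))

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".data", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
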