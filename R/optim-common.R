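# Shared plumbing for the population optimizers. All of them MAXIMIZE the
# objective over a box given as a 2 x d matrix rbind(lower, upper) (the
# encoded coordinates of a search_space), count every objective evaluation,
# keep an elitist best-ever candidate, and record a per-generation trace.

validate_bounds <- function(bounds) {
  if (is.null(dim(bounds)) && length(bounds) == 2) {
    bounds <- matrix(bounds, 2, 1)
  }
  stopifnot(is.matrix(bounds), nrow(bounds) == 2, all(bounds[1, ] < bounds[2, ]))
  if (is.null(colnames(bounds))) {
    colnames(bounds) <- paste0("x", seq_len(ncol(bounds)))
  }
  bounds
}

clamp_rows <- function(X, bounds) {
  lo <- matrix(bounds[1, ], nrow(X), ncol(X), byrow = TRUE)
  hi <- matrix(bounds[2, ], nrow(X), ncol(X), byrow = TRUE)
  pmin(pmax(X, lo), hi)
}

random_positions <- function(n, bounds) {
  d <- ncol(bounds)
  X <- matrix(runif(n * d), n, d)
  sweep(sweep(X, 2, bounds[2, ] - bounds[1, ], "*"), 2, bounds[1, ], "+")
}

# Wrap an objective with an evaluation counter (read with counted_total).
counted_objective <- function(objective) {
  force(objective)  # callers rebind the same name; unforced promise would recurse
  count <- 0L
  f <- function(position) {
    count <<- count + 1L
    objective(position)
  }
  attr(f, "env") <- environment()
  f
}

counted_total <- function(f) get("count", envir = attr(f, "env"))

new_trace_row <- function(generation, best_fitness, mean_fitness, best_pos) {
  row <- data.frame(generation = generation, best_fitness = best_fitness,
                    mean_fitness = mean_fitness)
  pos <- as.data.frame(as.list(best_pos))
  names(pos) <- paste0("best_", names(best_pos))
  cbind(row, pos)
}

#' Export a convergence trace
#'
#' Writes the per-generation record behind the convergence-curve figures
#' (best fitness, population mean fitness, best position) as a delimited
#' table, one row per generation.
#'
#' @param trace data.frame as returned in an optimizer result's `$trace`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_trace <- function(trace, path, sep = "\t") {
  write.table(trace, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

optim_result <- function(best_pos, best_fit, trace, evals, extra = list()) {
  res <- c(list(best = list(position = best_pos, fitness = best_fit),
                trace = trace, evals = evals), extra)
  class(res) <- "optim_run"
  res
}

#' @export
print.optim_run <- function(x, ...) {
  cat("optimizer run:", nrow(x$trace), "generations,", x$evals,
      "objective evaluations\n")
  cat("  best fitness:", x$best$fitness, "at (",
      paste(signif(x$best$position, 5), collapse = ", "), ")\n")
  invisible(x)
}
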