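#' Train a soft-margin kernel SVM by sequential minimal optimization
#'
#' Solves the dual problem
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \alpha^T H \alpha, \quad
#'       H_{ij} = y_i y_j k(x_i, x_j),}
#' subject to the box constraint \eqn{0 \le \alpha_i \le C} and the equality
#' constraint \eqn{\sum_i \alpha_i y_i = 0}, with a Platt-style SMO solver
#' (analytic two-variable updates, KKT-violation sweeps). The penalty `C`
#' trades margin width against slack. The bias is recomputed after
#' convergence by [compute_bias()].
#'
#' @param data a [labeled_dataset()] with at least one example of each class.
#' @param kernel an `svm_kernel` (see [kernels]); default RBF with width 1.
#' @param C box-constraint penalty, `> 0`.
#' @param tol KKT tolerance used by the solver and stored for later checks.
#' @param max_sweeps cap on outer solver sweeps (guards pathological cases;
#'   a warning is emitted if reached).
#' @param seed integer seed for the solver's randomized fallback scans; fixed
#'   seed gives a fully reproducible model.
#' @return An object of class `svm_model` with fields `alphas`, `bias`,
#'   `support_indices` (indices with `alpha > 1e-8 * C`), `kernel`, `C`,
#'   `tol`, and the training features/labels it references.
#' @export
svm_train <- function(data, kernel = kernel_rbf(1), C = 1,
                      tol = 1e-3, max_sweeps = 1000L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(kernel, "svm_kernel"),
            C > 0, tol > 0)
  y <- data$labels
  if (length(unique(y)) < 2) {
    stop("training data contains a single class; need both +1 and -1")
  }
  if (kernel$kind == "sigmoid") {
    warning("sigmoid kernel is not positive semi-definite in general; ",
            "the dual is solved but may not be a convex QP")
  }
  K <- kernel_matrix(kernel, data$features)
  fit <- with_seed(seed, smo_solve_cpp(K, y, C, tol, 1e-12, as.integer(max_sweeps)))
  if (!fit$converged) {
    warning("SMO reached max_sweeps = ", max_sweeps, " before convergence")
  }
  model <- structure(
    list(alphas = fit$alpha, bias = fit$b,
         support_indices = which(fit$alpha > 1e-8 * C),
         train_features = data$features, train_labels = y,
         kernel = kernel, C = C, tol = tol,
         normalization = data$normalization),
    class = "svm_model"
  )
  model$bias <- compute_bias(model)
  model
}

#' @export
print.svm_model <- function(x, ...) {
  cat("Soft-margin SVM (", x$kernel$kind, " kernel), C = ", x$C, "\n", sep = "")
  cat("  ", length(x$support_indices), "support vectors of",
      length(x$alphas), "training points; b =", signif(x$bias, 6), "\n")
  invisible(x)
}

#' Bias term from the support-vector set
#'
#' Averages \eqn{y_v - \sum_i \alpha_i y_i k(x_i, x_v)} over the support set.
#' Unbounded support vectors (`0 < alpha < C`), which sit exactly on the
#' margin, are preferred; if none exist the average runs over all support
#' vectors (bounded ones only constrain the bias to one side, so the
#' unbounded-only average is less biased when available).
#'
#' @param model an `svm_model`.
#' @return the scalar bias `b`.
#' @export
compute_bias <- function(model) {
  a <- model$alphas
  sv <- model$support_indices
  if (length(sv) == 0) stop("empty support set: no alpha exceeds threshold")
  unbounded <- sv[a[sv] < model$C * (1 - 1e-8)]
  V <- if (length(unbounded) > 0) unbounded else sv
  Ksv <- kernel_matrix(model$kernel,
                       model$train_features[sv, , drop = FALSE],
                       model$train_features[V, , drop = FALSE])
  f_no_b <- drop(crossprod(Ksv, a[sv] * model$train_labels[sv]))
  mean(model$train_labels[V] - f_no_b)
}

#' Decision values for new points
#'
#' Computes \eqn{f(x) = \sum_{i \in V} \alpha_i y_i k(x_i, x) + b} from the
#' support vectors only.
#'
#' @param model an `svm_model`.
#' @param newdata numeric matrix (or vector for a single point).
#' @return numeric vector of raw decision values.
#' @export
decision_values <- function(model, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != ncol(model$train_features)) {
    stop("dimension mismatch: model expects ", ncol(model$train_features),
         " features, got ", ncol(newdata))
  }
  sv <- model$support_indices
  K <- kernel_matrix(model$kernel, model$train_features[sv, , drop = FALSE],
                     newdata)
  drop(crossprod(K, model$alphas[sv] * model$train_labels[sv])) + model$bias
}

#' Predict class labels
#'
#' Labels are `sign(f(x))` with the tie `f(x) == 0` mapped to `+1` (a fixed
#' convention so predictions are always in \{+1, -1\}).
#'
#' @param object an `svm_model`.
#' @param newdata numeric matrix or [labeled_dataset()].
#' @param ... unused.
#' @return numeric vector of labels in \{+1, -1\}; the raw decision values are
#'   attached as attribute `"decision"`.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$features
  f <- decision_values(object, newdata)
  structure(ifelse(f >= 0, 1, -1), decision = f)
}

#' Dual objective value of a model
#'
#' \eqn{\sum_i \alpha_i - \tfrac12 \alpha^T H \alpha} with
#' \eqn{H_{ij} = y_i y_j k(x_i, x_j)}; the quantity SMO maximizes.
#'
#' @param model an `svm_model`.
#' @return the scalar dual objective.
#' @export
dual_objective <- function(model) {
  a <- model$alphas
  if (all(a == 0)) return(0)
  nz <- which(a > 0)
  K <- kernel_matrix(model$kernel, model$train_features[nz, , drop = FALSE])
  ay <- a[nz] * model$train_labels[nz]
  sum(a) - 0.5 * drop(crossprod(ay, K %*% ay))
}

#' Brute-force dual oracle
#'
#' Independent solution of the same dual QP for testing the SMO solver on
#' tiny instances (`n <= 7`). The equality constraint eliminates one
#' multiplier (`alpha_n = -y_n sum_{i<n} alpha_i y_i`); the remaining
#' `n - 1` dimensional box is searched by a dense grid that is repeatedly
#' refined around the incumbent. The dual is concave, so coarse-to-fine
#' refinement converges to the global maximum.
#'
#' @param data a [labeled_dataset()] with `n <= 7` rows.
#' @param kernel an `svm_kernel`.
#' @param C box penalty.
#' @param resolution grid points per dimension at each refinement stage.
#' @param refinements number of refinement stages (each halves the window
#'   around the incumbent).
#' @return list with `alpha`, `objective`.
#' @export
dual_oracle <- function(data, kernel, C, resolution = 9L, refinements = 18L) {
  y <- data$labels
  n <- length(y)
  if (n > 7) stop("oracle is brute force; use n <= 7 points")
  K <- kernel_matrix(kernel, data$features)
  H <- (y %o% y) * K
  obj <- function(A) {           # rows of A are candidate alpha vectors
    rowSums(A) - 0.5 * rowSums((A %*% H) * A)
  }
  m <- n - 1
  lo <- rep(0, m); hi <- rep(C, m)
  best_a <- NULL; best_obj <- -Inf
  for (r in seq_len(refinements)) {
    grids <- lapply(seq_len(m), function(j) seq(lo[j], hi[j], length.out = resolution))
    A <- as.matrix(expand.grid(grids))
    last <- -drop(A %*% y[seq_len(m)]) * y[n]
    ok <- last >= 0 & last <= C
    if (any(ok)) {
      Afull <- cbind(A[ok, , drop = FALSE], last[ok])
      vals <- obj(Afull)
      k <- which.max(vals)
      if (vals[k] > best_obj) {
        best_obj <- vals[k]
        best_a <- Afull[k, ]
      }
    }
    centre <- if (is.null(best_a)) (lo + hi) / 2 else best_a[seq_len(m)]
    width <- (hi - lo) / 2
    lo <- pmax(0, centre - width / 2)
    hi <- pmin(C, centre + width / 2)
  }
  if (is.null(best_a)) stop("oracle found no feasible grid point")
  list(alpha = unname(best_a), objective = best_obj)
}

#' Save / load a trained model as plain-text JSON
#'
#' Serializes everything prediction needs (support-vector coefficients and
#' rows, bias, kernel spec, C, normalization parameters) so a model can be
#' reloaded and applied without the training session.
#'
#' @param model an `svm_model`.
#' @param path file path for the JSON record.
#' @return `svm_save` returns `path` invisibly; `svm_load` returns the
#'   restored `svm_model`.
#' @export
svm_save <- function(model, path) {
  sv <- model$support_indices
  rec <- list(
    kernel = list(kind = model$kernel$kind, params = model$kernel$params),
    C = model$C, bias = model$bias, tol = model$tol,
    support_indices = sv,
    alphas = model$alphas[sv],
    sv_features = model$train_features[sv, , drop = FALSE],
    sv_labels = model$train_labels[sv],
    normalization = model$normalization
  )
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname svm_save
#' @export
svm_load <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  nsv <- length(rec$sv_labels)
  alphas <- numeric(nsv); alphas[] <- rec$alphas
  feats <- matrix(as.numeric(rec$sv_features), nrow = nsv)
  kernel <- new_kernel(rec$kernel$kind, as.list(rec$kernel$params))
  norm <- if (is.null(rec$normalization)) NULL else
    list(min = as.numeric(rec$normalization$min),
         max = as.numeric(rec$normalization$max))
  structure(
    list(alphas = alphas, bias = rec$bias,
         support_indices = seq_len(nsv),
         train_features = feats, train_labels = as.numeric(rec$sv_labels),
         kernel = kernel, C = rec$C, tol = rec$tol, normalization = norm),
    class = "svm_model"
  )
}
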