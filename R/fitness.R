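# Deterministic stratified fold assignment: shuffles within each class under
# `seed`, then deals rows round-robin into k folds.
make_cv_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validation fitness of a hyperparameter candidate
#'
#' The objective every optimizer maximizes: the mean stratified k-fold
#' cross-validation accuracy (in percent) of an SVM trained with the decoded
#' hyperparameters. `position` is a named vector with `C` and, for the RBF
#' kernel, `sigma` (for polynomial: `offset`, `degree`; sigmoid: `scale`,
#' `offset`). Fold assignment and the SMO solver are both seeded, so the
#' fitness is a deterministic function of `(position, train, seed)`. A fold
#' whose training fails scores 0 and raises a warning. `mode = "train"`
#' instead scores plain training-set accuracy (no folds) -- a cheaper,
#' leakage-prone alternative offered because reported 100% train accuracies
#' suggest some published tunings used it.
#'
#' @param position named numeric vector of raw (decoded) hyperparameters.
#' @param train a [labeled_dataset()].
#' @param k number of folds, `>= 2` (default 5).
#' @param kernel_kind `"rbf"`, `"linear"`, `"polynomial"`, or `"sigmoid"`.
#' @param seed integer seed controlling folds and solver.
#' @param mode `"cv"` (default) or `"train"`.
#' @return fitness in `[0, 100]` (higher is better).
#' @export
evaluate_fitness <- function(position, train, k = 5L, kernel_kind = "rbf",
                             seed = 1L, mode = c("cv", "train")) {
  mode <- match.arg(mode)
  kernel <- kernel_from_position(kernel_kind, position)
  C <- unname(position[["C"]])
  # candidates at extreme C may hit the sweep cap; the capped solution is
  # still scored, so silence just that warning inside the search
  quiet_train <- function(...) {
    withCallingHandlers(
      try(svm_train(...), silent = TRUE),
      warning = function(w) {
        if (grepl("max_sweeps", conditionMessage(w))) invokeRestart("muffleWarning")
      })
  }
  if (mode == "train") {
    model <- quiet_train(train, kernel, C = C, seed = seed)
    if (inherits(model, "try-error")) {
      warning("SVM training failed; fitness 0")
      return(0)
    }
    return(accuracy(confusion(train$labels, predict(model, train))))
  }
  stopifnot(k >= 2)
  fold <- make_cv_folds(train$labels, k, seed)
  accs <- vapply(seq_len(k), function(f) {
    tr <- subset_rows(train, which(fold != f))
    te <- subset_rows(train, which(fold == f))
    model <- quiet_train(tr, kernel, C = C, seed = seed)
    if (inherits(model, "try-error")) {
      warning("SVM training failed on fold ", f, "; fold scores 0")
      return(0)
    }
    accuracy(confusion(te$labels, predict(model, te)))
  }, numeric(1))
  mean(accs)
}

# Build a kernel spec from named hyperparameters.
kernel_from_position <- function(kind, position) {
  g <- function(nm, default) {
    if (nm %in% names(position)) unname(position[[nm]]) else default
  }
  switch(kind,
    linear = kernel_linear(),
    rbf = kernel_rbf(g("sigma", 1)),
    polynomial = kernel_polynomial(g("offset", 1), round(g("degree", 3))),
    sigmoid = kernel_sigmoid(g("scale", 1), g("offset", 0)),
    stop("unknown kernel kind: ", kind)
  )
}

# Objective closure over the encoded search box for the optimizers.
make_svm_objective <- function(space, train, k = 5L, kernel_kind = "rbf",
                               seed = 1L, mode = "cv") {
  function(position) {
    evaluate_fitness(space_decode(space, position), train, k = k,
                     kernel_kind = kernel_kind, seed = seed, mode = mode)
  }
}
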