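#' Experiment configuration
#'
#' Bundles everything a single tuning run needs: the dataset source, the
#' split, the kernel, the optimizer and its parameters, the fitness mode,
#' and the seed. Optimizer parameter defaults are the reference settings:
#' GA (pop 20, 100 iterations, pc 0.5, pm 0.005), PSO (pop 20, 100
#' iterations, c1 1.5, c2 1.7), CS-PSO (pop 20, 100 iterations, Pa 0.25,
#' c1 1.5, c2 1.7).
#'
#' @param data a [labeled_dataset()], or `NULL` if `file` is given.
#' @param file path to a delimited dataset read with [read_delimited()]
#'   (passed `read_args`).
#' @param read_args list of extra arguments for [read_delimited()].
#' @param n_train training-set size for the split.
#' @param split_order `"random"` (stratified, default) or `"first-n"`.
#' @param kernel_kind kernel for the tuned SVM (default `"rbf"`).
#' @param optimizer `"ga"`, `"pso"`, or `"cs-pso"`.
#' @param optimizer_params named list overriding the defaults above
#'   (`pop`, `iters`, plus `pc`/`pm` for GA, `c1`/`c2`/`inertia` for PSO,
#'   `pa`/`cs_fraction`/`transfer` for CS-PSO).
#' @param space a [search_space()]; default `C` and `sigma`, log-scaled.
#' @param fitness_mode `"cv"` (stratified 5-fold CV accuracy, default) or
#'   `"train"` (training accuracy).
#' @param cv_folds folds for `"cv"` fitness.
#' @param positive_label class reported as positive in the metrics.
#' @param seed master seed; controls split, folds, solver, and optimizer.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(data = NULL, file = NULL, read_args = list(),
                              n_train, split_order = c("random", "first-n"),
                              kernel_kind = "rbf",
                              optimizer = c("cs-pso", "ga", "pso"),
                              optimizer_params = list(),
                              space = search_space(),
                              fitness_mode = c("cv", "train"),
                              cv_folds = 5L, positive_label = -1,
                              seed = 1L) {
  optimizer <- match.arg(optimizer)
  fitness_mode <- match.arg(fitness_mode)
  split_order <- match.arg(split_order)
  if (is.null(data) && is.null(file)) stop("supply either data or file")
  defaults <- switch(optimizer,
    "ga" = list(pop = 20L, iters = 100L, pc = 0.5, pm = 0.005),
    "pso" = list(pop = 20L, iters = 100L, c1 = 1.5, c2 = 1.7,
                 inertia = c(0.9, 0.4)),
    "cs-pso" = list(pop = 20L, iters = 100L, pa = 0.25, cs_fraction = 0.5,
                    c1 = 1.5, c2 = 1.7, inertia = c(0.9, 0.4),
                    transfer = "population"))
  params <- utils::modifyList(defaults, optimizer_params)
  structure(
    list(data = data, file = file, read_args = read_args,
         n_train = n_train, split_order = split_order,
         kernel_kind = kernel_kind, optimizer = optimizer,
         optimizer_params = params, space = space,
         fitness_mode = fitness_mode, cv_folds = cv_folds,
         positive_label = positive_label, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Load an experiment config from a plain-text key=value file
#'
#' Lines of the form `key = value` (comments with `#`). Recognized keys
#' mirror [experiment_config()] arguments (`file`, `n_train`, `optimizer`,
#' `kernel_kind`, `fitness_mode`, `seed`, `split_order`, plus dotted
#' optimizer keys like `opt.pop`, `opt.iters`, `opt.pa`).
#'
#' @param path config file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(x) if (is.na(suppressWarnings(as.numeric(x)))) x else as.numeric(x)
  opt_keys <- grep("^opt\\.", names(vals), value = TRUE)
  opt <- lapply(vals[opt_keys], num)
  names(opt) <- sub("^opt\\.", "", opt_keys)
  args <- list()
  for (key in c("file", "optimizer", "kernel_kind", "fitness_mode", "split_order")) {
    if (key %in% names(vals)) args[[key]] <- vals[[key]]
  }
  for (key in c("n_train", "seed", "cv_folds", "positive_label")) {
    if (key %in% names(vals)) args[[key]] <- as.numeric(vals[[key]])
  }
  args$optimizer_params <- opt
  do.call(experiment_config, args)
}

resolve_dataset <- function(config) {
  if (!is.null(config$data)) return(config$data)
  do.call(read_delimited, c(list(config$file), config$read_args))
}

run_optimizer <- function(config, objective, bounds) {
  p <- config$optimizer_params
  switch(config$optimizer,
    "ga" = optimize_ga(objective, bounds, pop = p$pop, iters = p$iters,
                       pc = p$pc, pm = p$pm, seed = config$seed + 2L),
    "pso" = optimize_pso(objective, bounds, pop = p$pop, iters = p$iters,
                         c1 = p$c1, c2 = p$c2, inertia = p$inertia,
                         seed = config$seed + 2L),
    "cs-pso" = optimize_hybrid(objective, bounds, pop = p$pop,
                               total_iters = p$iters,
                               cs_fraction = p$cs_fraction, pa = p$pa,
                               c1 = p$c1, c2 = p$c2, inertia = p$inertia,
                               transfer = p$transfer,
                               seed = config$seed + 2L))
}

#' Run one tuning experiment
#'
#' The full pipeline: split the data, fit min-max normalization on the
#' training rows and apply it to both splits, tune `(C, kernel parameter)`
#' with the configured optimizer against the cross-validation fitness,
#' retrain the final SVM on the whole training split at the best
#' hyperparameters, and evaluate on both splits. Fully reproducible: the
#' master seed drives the split, the folds, the solver, and the optimizer.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_result`: `report` (one-row data.frame
#'   with algorithm, train/test accuracy, precision, recall, F-measure, best
#'   `C`/kernel parameter, fitness), `trace`, `model`, `best`
#'   (decoded hyperparameters), `split` (index vectors), `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("experiment failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  data <- stage("load", resolve_dataset(config))
  sp <- stage("split",
              split_dataset(data, config$n_train, seed = config$seed,
                            order = config$split_order))
  norm <- stage("normalize", normalize_minmax(sp$train))
  train <- norm$data
  test <- stage("normalize", apply_normalization(sp$test, norm$params))

  bounds <- space_bounds(config$space)
  colnames(bounds) <- config$space$name
  objective <- make_svm_objective(config$space, train, k = config$cv_folds,
                                  kernel_kind = config$kernel_kind,
                                  seed = config$seed + 1L,
                                  mode = config$fitness_mode)
  opt <- stage("optimize", run_optimizer(config, objective, bounds))
  # trace positions are recorded in encoded (log2) coordinates; report them
  # on the raw hyperparameter scale
  for (j in seq_len(nrow(config$space))) {
    col <- paste0("best_", config$space$name[j])
    if (config$space$scale[j] == "log" && col %in% names(opt$trace)) {
      opt$trace[[col]] <- 2^opt$trace[[col]]
    }
  }

  best <- space_decode(config$space, opt$best$position)
  kernel <- kernel_from_position(config$kernel_kind, best)
  model <- stage("train",
                 svm_train(train, kernel, C = best[["C"]],
                           seed = config$seed + 1L))
  eval_split <- function(d) {
    cm <- confusion(d$labels, predict(model, d), config$positive_label)
    c(accuracy = accuracy(cm), precision_recall_f(cm))
  }
  tr <- eval_split(train); te <- eval_split(test)
  report <- data.frame(
    algorithm = toupper(paste0(config$optimizer, "-svm")),
    train_accuracy = tr[["accuracy"]], test_accuracy = te[["accuracy"]],
    precision = te[["precision"]], recall = te[["recall"]],
    f_measure = te[["f_measure"]],
    best_C = best[["C"]],
    best_param = if (length(best) > 1) best[[2]] else NA_real_,
    fitness = opt$best$fitness, seed = config$seed,
    stringsAsFactors = FALSE
  )
  structure(list(report = report, trace = opt$trace, model = model,
                 best = best, optim = opt,
                 split = sp[c("train_idx", "test_idx")], config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", x$report$algorithm, "\n")
  print(x$report[, c("train_accuracy", "test_accuracy", "precision",
                     "recall", "f_measure")], row.names = FALSE)
  invisible(x)
}

#' Compare tuning algorithms on a shared split
#'
#' Runs one experiment per optimizer with identical data, split, kernel, and
#' seed, and stacks the one-row reports into a comparison table. It is an
#' error for the configs to differ in anything but the optimizer; the shared
#' split is additionally asserted by comparing the train/test index sets of
#' every run.
#'
#' @param configs list of [experiment_config()]s differing only in
#'   `optimizer`/`optimizer_params`.
#' @return list of class `model_comparison`: `table` (one row per
#'   algorithm), `results` (the full [run_experiment()] results).
#' @export
compare_models <- function(configs) {
  stopifnot(length(configs) >= 1)
  ref <- configs[[1]]
  for (cfg in configs[-1]) {
    same <- identical(cfg$data, ref$data) && identical(cfg$file, ref$file) &&
      identical(cfg$n_train, ref$n_train) && identical(cfg$seed, ref$seed) &&
      identical(cfg$kernel_kind, ref$kernel_kind) &&
      identical(cfg$split_order, ref$split_order)
    if (!same) stop("configs must share data, split, kernel, and seed")
  }
  results <- lapply(configs, run_experiment)
  split0 <- results[[1]]$split
  for (r in results[-1]) {
    if (!identical(r$split, split0)) stop("runs used different splits")
  }
  table <- do.call(rbind, lapply(results, `[[`, "report"))
  structure(list(table = table, results = results), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table[, c("algorithm", "train_accuracy", "test_accuracy",
                    "precision", "recall", "f_measure")], row.names = FALSE)
  invisible(x)
}
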