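#' Labeled dataset container
#'
#' A light container for a two-class classification problem: a numeric feature
#' matrix, labels recoded to \{+1, -1\} (as the SVM dual requires), the original
#' raw label encoding (UCI clinical tables use 1 = benign, 2 = malignant), and
#' the min-max normalization parameters if the features have been rescaled.
#'
#' @param features numeric matrix, one row per sample.
#' @param labels numeric vector in \{+1, -1\}, one per row of `features`.
#' @param raw_labels original label encoding, defaults to `labels`.
#' @param feature_names character vector of column identifiers.
#' @param normalization `NULL`, or a list with numeric vectors `min` and `max`
#'   (one entry per feature) recording the training ranges used for scaling.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, raw_labels = labels,
                            feature_names = colnames(features),
                            normalization = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.numeric(labels)
  if (length(labels) != nrow(features)) {
    stop("labels length (", length(labels), ") != number of feature rows (",
         nrow(features), ")")
  }
  if (!all(labels %in% c(-1, 1))) {
    bad <- unique(labels[!labels %in% c(-1, 1)])
    stop("labels must be +1 or -1; found: ", paste(bad, collapse = ", "))
  }
  if (length(raw_labels) != length(labels)) {
    stop("raw_labels length must match labels")
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("V", seq_len(ncol(features)))
  }
  colnames(features) <- feature_names
  if (!is.null(normalization)) {
    stopifnot(is.list(normalization),
              length(normalization$min) == ncol(features),
              length(normalization$max) == ncol(features))
  }
  structure(
    list(features = features, labels = labels, raw_labels = raw_labels,
         feature_names = feature_names, normalization = normalization),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$features), "samples x",
      ncol(x$features), "features\n")
  tab <- table(x$labels)
  cat("  class counts: ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  cat("  normalized:", if (is.null(x$normalization)) "no" else "yes (min-max)", "\n")
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$features)

# Row subset preserving all metadata.
subset_rows <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  data$raw_labels[idx], data$feature_names, data$normalization)
}

#' Read a UCI-style delimited table
#'
#' Reads a numeric delimited file (comma- or whitespace-separated, no header by
#' default -- the dialect of UCI `.data` files such as Statlog heart, 270 x 13,
#' or Wisconsin breast cancer, 699 x 9), takes the class label from a chosen
#' column, and recodes it to \{+1, -1\}.
#'
#' @param path file to read.
#' @param label_column column index holding the class label; `NULL` (default)
#'   means the last column.
#' @param label_map named numeric vector mapping raw label values to +1/-1.
#'   Default `c("1" = 1, "2" = -1)`: raw 1 (benign) is the +1 class, raw 2
#'   (malignant) the -1 class.
#' @param sep field separator: `","` (default) or `""` for whitespace.
#' @param header logical, does the file start with a header line?
#' @param missing_policy what to do with missing-value tokens (`"?"`):
#'   `"error"` (default) or `"drop"` (discard those rows).
#' @return A [labeled_dataset()] with row order preserved.
#' @export
read_delimited <- function(path, label_column = NULL,
                           label_map = c("1" = 1, "2" = -1),
                           sep = ",", header = FALSE,
                           missing_policy = c("error", "drop")) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = sep, skip = as.integer(header))
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1] + as.integer(header)
    stop("malformed row at line ", bad, ": expected ", nf[1],
         " fields, found ", nf[bad - as.integer(header)])
  }
  df <- read.table(path, sep = sep, header = header, na.strings = "?",
                   colClasses = "character", strip.white = TRUE)
  if (is.null(label_column)) label_column <- ncol(df)
  if (label_column < 1 || label_column > ncol(df)) {
    stop("label_column ", label_column, " out of range 1..", ncol(df))
  }
  raw <- df[[label_column]]
  feat <- df[, -label_column, drop = FALSE]

  has_na <- is.na(raw) | Reduce(`|`, lapply(feat, is.na))
  if (any(has_na)) {
    if (missing_policy == "error") {
      stop("missing value ('?') at line ", which(has_na)[1] + as.integer(header),
           "; set missing_policy = 'drop' to discard such rows")
    }
    raw <- raw[!has_na]
    feat <- feat[!has_na, , drop = FALSE]
  }

  unknown <- setdiff(unique(raw), names(label_map))
  if (length(unknown) > 0) {
    stop("unknown label value(s): ", paste(unknown, collapse = ", "),
         " (label_map covers: ", paste(names(label_map), collapse = ", "), ")")
  }
  labels <- unname(label_map[raw])
  features <- vapply(feat, as.numeric, numeric(nrow(feat)))
  if (nrow(feat) == 1) features <- matrix(features, nrow = 1)
  labeled_dataset(features, labels, raw_labels = raw,
                  feature_names = if (header) names(feat) else NULL)
}

#' Write a dataset in the same delimited dialect
#'
#' Emits features followed by the raw label in the last column, with full
#' numeric precision so that a write/read round trip is exact.
#'
#' @param data a [labeled_dataset()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_delimited <- function(data, path, sep = ",") {
  df <- as.data.frame(data$features)
  # %.17g round-trips doubles exactly; write.table's own formatting does not
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  df$label <- data$raw_labels
  write.table(df, path, sep = sep, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Min-max normalization fitted on a training set
#'
#' Rescales every feature to `(x - min) / (max - min)` using the per-feature
#' ranges of `train`; constant features map to 0. The fitted parameters are
#' stored on the returned dataset and in `$params` so they can be reused on
#' test data via [apply_normalization()] -- scaling is fitted on training rows
#' only to avoid leaking test information.
#'
#' @param train a [labeled_dataset()].
#' @return list with `data` (the scaled dataset, normalization recorded) and
#'   `params` (list of `min` and `max` vectors).
#' @export
normalize_minmax <- function(train) {
  if (nrow(train$features) == 0) stop("cannot normalize an empty dataset")
  mins <- apply(train$features, 2, min)
  maxs <- apply(train$features, 2, max)
  params <- list(min = mins, max = maxs)
  list(data = apply_normalization(train, params), params = params)
}

#' Apply stored min-max parameters
#'
#' Applies `(x - min) / (max - min)` with previously fitted parameters. Test
#' values outside the training range map outside `[0, 1]`; no clipping is done.
#' The transform is not idempotent: reapplying it reuses the same stored
#' parameters on the already-scaled values.
#'
#' @param data a [labeled_dataset()].
#' @param params list with `min` and `max` vectors, one entry per feature.
#' @return The rescaled [labeled_dataset()] with `normalization` set.
#' @export
apply_normalization <- function(data, params) {
  p <- ncol(data$features)
  if (length(params$min) != p || length(params$max) != p) {
    stop("normalization params dimensioned for ", length(params$min),
         " features, data has ", p)
  }
  range <- params$max - params$min
  range[range == 0] <- 1  # constant feature: (x - min)/1 = 0
  scaled <- sweep(sweep(data$features, 2, params$min), 2, range, "/")
  labeled_dataset(scaled, data$labels, data$raw_labels, data$feature_names,
                  normalization = params)
}

#' Train/test split
#'
#' Splits a dataset into `n_train` training rows and the remainder as test
#' (the clinical benchmarks use 190 of 270 and 549 of 699 training instances).
#' By default the training rows are a stratified random sample -- class
#' proportions are preserved within rounding -- drawn reproducibly from `seed`;
#' `order = "first-n"` instead takes the first `n_train` rows in file order.
#'
#' @param data a [labeled_dataset()].
#' @param n_train number of training rows, `< nrow(data)`.
#' @param stratified preserve class proportions (default `TRUE`).
#' @param seed integer seed for the random draw.
#' @param order `"random"` (default) or `"first-n"`.
#' @return list with `train`, `test` ([labeled_dataset()]s), and the integer
#'   index vectors `train_idx`, `test_idx` (a disjoint partition of all rows).
#' @export
split_dataset <- function(data, n_train, stratified = TRUE, seed = 1L,
                          order = c("random", "first-n")) {
  order <- match.arg(order)
  n <- nrow(data$features)
  if (n_train >= n) stop("n_train (", n_train, ") must be < n_samples (", n, ")")
  if (n_train < 1) stop("n_train must be >= 1")

  if (order == "first-n") {
    train_idx <- seq_len(n_train)
  } else if (!stratified) {
    train_idx <- with_seed(seed, sample.int(n, n_train))
  } else {
    classes <- sort(unique(data$labels), decreasing = TRUE)
    idx_by_class <- lapply(classes, function(cl) which(data$labels == cl))
    sizes <- vapply(idx_by_class, length, integer(1))
    # largest-remainder apportionment of n_train across classes
    quota <- n_train * sizes / n
    take <- floor(quota)
    rem <- n_train - sum(take)
    if (rem > 0) {
      extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    take <- pmin(take, sizes)
    if (any(take == sizes) && n_train < n) {
      # keep both classes represented in the test set too
      full <- which(take == sizes & sizes > 0)
      take[full] <- take[full] - 1
      short <- sum(take) < n_train
      while (short) {
        room <- which(take < sizes - 1)
        if (length(room) == 0) break
        take[room[1]] <- take[room[1]] + 1
        short <- sum(take) < n_train
      }
    }
    train_idx <- with_seed(seed, {
      sort(unlist(mapply(function(idx, k) idx[sample.int(length(idx), k)],
                         idx_by_class, take, SIMPLIFY = FALSE)))
    })
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  if (stratified && length(unique(data$labels[test_idx])) < 2) {
    warning("test split does not contain both classes")
  }
  list(train = subset_rows(data, train_idx),
       test = subset_rows(data, test_idx),
       train_idx = as.integer(train_idx), test_idx = as.integer(test_idx))
}

#' Synthetic two-class Gaussian clusters
#'
#' Generates the stand-in for the UCI clinical tables: two spherical Gaussian
#' clusters with unit-variance noise whose means are `separation` apart along
#' the normalized all-ones direction (so every feature is equally informative).
#' The Bayes accuracy is `pnorm(separation / 2)` -- the defaults (270 samples,
#' 13 features, separation 2.5, class sizes 150/120) emulate the size, class
#' balance, and ~85-90% attainable-accuracy regime of the heart-disease table.
#' Raw labels use the clinical 1/2 encoding mapped to +1/-1.
#'
#' @param n_per_class integer vector of length 2: samples in the +1 (raw 1)
#'   and -1 (raw 2) class.
#' @param n_features dimensionality.
#' @param separation Euclidean distance between the class means, in units of
#'   the noise standard deviation; `>= 0`.
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @return A [labeled_dataset()].
#' @export
generate_synthetic <- function(n_per_class = c(150L, 120L), n_features = 13L,
                               separation = 2.5, seed = 1L) {
  stopifnot(length(n_per_class) == 2, all(n_per_class >= 1),
            n_features >= 1, separation >= 0)
  u <- rep(1, n_features) / sqrt(n_features)
  mu_pos <- (separation / 2) * u
  mu_neg <- -mu_pos
  n1 <- n_per_class[1]; n2 <- n_per_class[2]
  X <- with_seed(seed, {
    noise <- matrix(rnorm((n1 + n2) * n_features), n1 + n2, n_features)
    centers <- rbind(matrix(mu_pos, n1, n_features, byrow = TRUE),
                     matrix(mu_neg, n2, n_features, byrow = TRUE))
    noise + centers
  })
  labels <- c(rep(1, n1), rep(-1, n2))
  labeled_dataset(X, labels, raw_labels = c(rep("1", n1), rep("2", n2)))
}
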