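test_that("read_delimited maps labels, preserves order, and validates input", {
  path <- write_temp_csv(c("1.5,2.0,1", "0.5,1.0,1", "3.0,0.1,2", "2.2,0.4,2"))
  d <- read_delimited(path)
  expect_equal(dim(d), c(4L, 2L))
  expect_equal(d$labels, c(1, 1, -1, -1))
  expect_equal(d$raw_labels, c("1", "1", "2", "2"))
  expect_equal(d$features[, 1], c(1.5, 0.5, 3.0, 2.2))

  # malformed row names the offending line
  bad <- write_temp_csv(c("1,2,1", "1,2", "3,4,2"))
  expect_error(read_delimited(bad), "line 2")

  # unknown label value named in the error
  odd <- write_temp_csv(c("1,2,1", "3,4,9"))
  expect_error(read_delimited(odd), "9")

  # missing values: error by default, dropped on request
  mis <- write_temp_csv(c("1,2,1", "?,4,2", "5,6,2"))
  expect_error(read_delimited(mis), "\\?|missing")
  d2 <- read_delimited(mis, missing_policy = "drop")
  expect_equal(nrow(d2$features), 2L)
  expect_equal(d2$labels, c(1, -1))
})

test_that("a breast-cancer-shaped file reads back as 699 x 9", {
  set.seed(42)
  synth <- generate_synthetic(c(458L, 241L), n_features = 9L, seed = 42)
  path <- withr::local_tempfile(fileext = ".data")
  write_delimited(synth, path)
  d <- read_delimited(path)
  expect_equal(nrow(d$features), 699L)
  expect_equal(ncol(d$features), 9L)
})

test_that("write/read round trip reproduces features exactly", {
  for (seed in 1:3) {
    d <- random_dataset(11, d = 4, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_delimited(d, path)
    back <- read_delimited(path, label_map = c("1" = 1, "-1" = -1))
    expect_identical(back$features, d$features, label = paste("seed", seed))
    expect_identical(back$labels, d$labels)
  }
})

test_that("labeled_dataset enforces its invariants", {
  expect_error(labeled_dataset(matrix(1:4, 2), c(1, -1, 1)), "length")
  expect_error(labeled_dataset(matrix(1:4, 2), c(1, 2)), "\\+1 or -1")
})

test_that("min-max normalization scales train features to [0, 1]", {
  d <- labeled_dataset(cbind(c(2, 4, 6), c(5, 5, 5)), c(1, -1, 1))
  nm <- normalize_minmax(d)
  expect_equal(nm$data$features[, 1], c(0, 0.5, 1))
  expect_equal(nm$data$features[, 2], c(0, 0, 0))  # constant column rule

  # property: every non-constant feature spans exactly [0, 1] after fitting
  for (seed in 1:3) {
    r <- random_dataset(20, d = 5, seed = seed)
    s <- normalize_minmax(r)$data$features
    expect_equal(unname(apply(s, 2, min)), rep(0, 5))
    expect_equal(unname(apply(s, 2, max)), rep(1, 5))
  }
})

test_that("stored normalization params transfer to test data without clipping", {
  params <- list(min = 0, max = 10)
  d <- labeled_dataset(matrix(c(5, 12), 2), c(1, -1))
  out <- apply_normalization(d, params)
  expect_equal(unname(out$features[1, 1]), 0.5)
  expect_equal(unname(out$features[2, 1]), 1.2)  # above train max: > 1 allowed

  # identity params leave data unchanged
  id <- apply_normalization(d, list(min = 0, max = 1))
  expect_equal(id$features, d$features)

  # dimension mismatch
  expect_error(apply_normalization(d, list(min = c(0, 0), max = c(1, 1))),
               "dimension|features")
  expect_error(normalize_minmax(labeled_dataset(matrix(0, 0, 2), numeric(0))),
               "empty")
})

test_that("split produces the stated test sizes and is a disjoint partition", {
  heart <- generate_synthetic(c(150L, 120L), 13L, seed = 1)
  sp <- split_dataset(heart, 190, seed = 9)
  expect_equal(nrow(sp$train$features), 190L)
  expect_equal(nrow(sp$test$features), 80L)

  breast <- generate_synthetic(c(458L, 241L), 9L, seed = 2)
  sp2 <- split_dataset(breast, 549, seed = 9)
  expect_equal(nrow(sp2$test$features), 150L)

  # partition: every index exactly once
  all_idx <- sort(c(sp$train_idx, sp$test_idx))
  expect_identical(all_idx, seq_len(270L))

  # stratification preserves class ratio within rounding
  frac_train <- mean(sp$train$labels == 1)
  expect_lt(abs(frac_train - 150 / 270), 0.01)

  # determinism and seed sensitivity
  expect_identical(split_dataset(heart, 190, seed = 9)$train_idx, sp$train_idx)
  expect_false(identical(split_dataset(heart, 190, seed = 10)$train_idx,
                         sp$train_idx))

  # first-n order takes the leading rows; on class-sorted data that leaves a
  # single-class test set, which is warned about
  expect_warning(spf <- split_dataset(heart, 190, order = "first-n"),
                 "both classes")
  expect_identical(spf$train_idx, 1:190)

  expect_error(split_dataset(heart, 270), "n_train")
})

test_that("synthetic generator is seed-reproducible with the stated geometry", {
  a <- generate_synthetic(c(50, 50), 4, separation = 3, seed = 5)
  b <- generate_synthetic(c(50, 50), 4, separation = 3, seed = 5)
  expect_identical(a$features, b$features)
  expect_false(identical(
    generate_synthetic(c(50, 50), 4, separation = 3, seed = 6)$features,
    a$features))
  expect_equal(a$labels, c(rep(1, 50), rep(-1, 50)))

  # empirical class-mean distance ~ separation (n = 500 per class)
  big <- generate_synthetic(c(500, 500), 6, separation = 4, seed = 1)
  mu1 <- colMeans(big$features[big$labels == 1, ])
  mu2 <- colMeans(big$features[big$labels == -1, ])
  expect_lt(abs(sqrt(sum((mu1 - mu2)^2)) - 4), 0.3)
})

test_that("widely separated clusters are perfectly classified by a linear SVM", {
  d <- generate_synthetic(c(50, 50), 4, separation = 10, seed = 3)
  m <- svm_train(d, kernel_linear(), C = 1)
  expect_equal(as.vector(predict(m, d)), d$labels)
})
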