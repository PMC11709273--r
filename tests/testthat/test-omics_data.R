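# Data layer: loading, preprocessing, masks, simulated missingness, splits.

write_tmp_csv <- function(mat, ids, path) {
  df <- data.frame(sample_id = ids, mat, check.names = FALSE)
  readr::write_csv(df, path)
  path
}

test_that("loading round-trips values and honours orientation", {
  m <- matrix(c(1.5, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(NULL, c("f1", "f2")))
  p1 <- write_tmp_csv(m, c("a", "b", "c"), tempfile(fileext = ".csv"))
  blk <- load_omics_matrix(p1, "mRNA")
  expect_equal(unname(blk$values), unname(m))
  expect_equal(rownames(blk$values), c("a", "b", "c"))
  expect_equal(colnames(blk$values), c("f1", "f2"))

  # transposed file with features in rows yields the identical block
  p2 <- write_tmp_csv(t(m), c("f1", "f2"), tempfile(fileext = ".csv"))
  blk2 <- load_omics_matrix(p2, "mRNA", orientation = "features_in_rows")
  expect_equal(unname(blk2$values), unname(m))

  # duplicated sample id is a format error naming the id
  p3 <- write_tmp_csv(m, c("a", "a", "c"), tempfile(fileext = ".csv"))
  expect_error(load_omics_matrix(p3, "mRNA"), "duplicate sample.*a")

  # non-numeric cell is a parse error with row/column coordinates
  df <- data.frame(sample_id = c("a", "b"), f1 = c("1", "oops"),
                   f2 = c("2", "3"))
  p4 <- tempfile(fileext = ".csv")
  readr::write_csv(df, p4)
  expect_error(load_omics_matrix(p4, "mRNA"), "non-numeric cell.*row 3")
})

test_that("preprocessing matches the log2 and min-max contracts", {
  blk <- omics_block(matrix(c(2, 4, 6), 3, 1,
                            dimnames = list(letters[1:3], "f")), "mRNA")
  out <- preprocess_omics(blk, do_log2 = FALSE)
  expect_equal(unname(out$block$values[, 1]), c(0, 0.5, 1))

  # log2(1023 + 1) = 10 before scaling
  blk2 <- omics_block(matrix(c(0, 1023), 2, 1,
                             dimnames = list(c("a", "b"), "f")), "mRNA")
  expect_equal(log2(blk2$values[2, 1] + 1), 10)

  # methylation convention: no log2, values unchanged before scaling
  beta <- matrix(runif(10), 5, 2,
                 dimnames = list(paste0("s", 1:5), c("cg1", "cg2")))
  blk3 <- omics_block(beta, "methylation")
  out3 <- preprocess_omics(blk3, do_log2 = FALSE)
  rng <- apply(beta, 2, range)
  manual <- sweep(sweep(beta, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/")
  expect_equal(out3$block$values, manual)

  # negative values reject the log2 transform
  blk4 <- omics_block(matrix(c(-1, 2), 2, 1), "mRNA")
  expect_error(preprocess_omics(blk4, do_log2 = TRUE), "negative")
})

test_that("test-time normalization reuses training stats, clips, and is idempotent", {
  train <- omics_block(matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
                              dimnames = list(letters[1:3],
                                              c("f1", "f2"))), "mRNA")
  fit <- preprocess_omics(train, do_log2 = FALSE)
  test <- omics_block(matrix(c(0, 8, 2, 4), 2, 2,
                             dimnames = list(c("x", "y"),
                                             c("f1", "f2"))), "mRNA")
  out <- preprocess_omics(test, do_log2 = FALSE, fit_stats = fit$stats)
  expect_equal(unname(out$block$values[, "f1"]), c(0, 1))  # clipped
  expect_equal(unname(out$block$values[, "f2"]), c(0.25, 0.75))
  # idempotence: re-normalizing normalized output with its own stats
  again <- preprocess_omics(fit$block, do_log2 = FALSE,
                            fit_stats = preprocess_omics(fit$block)$stats)
  expect_equal(again$block$values, fit$block$values)
})

test_that("variance filter keeps exactly the features above threshold", {
  set.seed(4)
  v <- cbind(f_lo = rnorm(50, sd = sqrt(0.05)),
             f_mid = rnorm(50, sd = sqrt(0.25)),
             f_hi = rnorm(50, sd = sqrt(0.9)))
  # force the sample variances to the designed values exactly
  v <- scale(v) %*% diag(sqrt(c(0.05, 0.25, 0.9)))
  colnames(v) <- c("f_lo", "f_mid", "f_hi")
  blk <- omics_block(v, "methylation")
  kept <- variance_filter(blk, 0.2)
  expect_setequal(colnames(kept$values), c("f_mid", "f_hi"))

  # constant feature removed at any positive threshold
  blk2 <- omics_block(cbind(flat = rep(1, 10), live = rnorm(10)), "x")
  expect_equal(colnames(variance_filter(blk2, 1e-9)$values), "live")

  # omics-name default: miRNA threshold 0.1
  blk3 <- omics_block(v, "miRNA")
  expect_setequal(colnames(variance_filter(blk3)$values),
                  colnames(variance_filter(blk3, 0.1)$values))

  # monotone: raising the threshold never adds features
  th <- sort(runif(8, 0, 1))
  kept_n <- vapply(th, function(t) {
    tryCatch(ncol(variance_filter(blk, t)$values), error = function(e) 0L)
  }, integer(1))
  expect_true(all(diff(kept_n) <= 0))

  # all features removed is an error advising a lower threshold
  expect_error(variance_filter(blk, 100), "lower the threshold")
})

test_that("missingness mask detects all-NA rows and zero-fills them", {
  b1 <- omics_block(matrix(c(1, NA, 3, 4, NA, 6), 3, 2,
                           dimnames = list(c("a", "b", "c"), NULL)), "o1")
  b1$values["b", ] <- NA
  b2 <- omics_block(matrix(1:6 / 10, 3, 2,
                           dimnames = list(c("a", "b", "c"), NULL)), "o2")
  ds <- multiomics_dataset(list(o1 = b1, o2 = b2))
  expect_equal(unname(ds$mask["b", ]), c(0L, 1L))
  expect_true(all(ds$blocks$o1$values["b", ] == 0))
  expect_equal(sum(ds$mask), 5L)

  # fully observed dataset: all-ones mask
  ds2 <- small_dataset(seed = 2, n = 20)$dataset
  expect_true(all(ds2$mask == 1))

  # a sample empty in every omics is rejected by name
  b1$values["c", ] <- NA
  b2$values["c", ] <- NA
  expect_error(multiomics_dataset(list(o1 = b1, o2 = b2)),
               "no available omics.*c")
})

test_that("simulated missingness masks round(rate * N) samples and preserves the invariant", {
  ds <- small_dataset(seed = 7, n = 8)$dataset
  out <- simulate_missingness(ds, 0.25, rng_seed = 1)
  expect_equal(sum(out$mask == 0), 2L)  # round(0.25 * 8)
  expect_identical(simulate_missingness(ds, 0, rng_seed = 1), ds)

  out2 <- simulate_missingness(ds, 0.75, rng_seed = 2, target_omics = "omics3")
  expect_equal(sum(out2$mask[, "omics3"] == 0), 6L)
  expect_true(all(out2$mask[, 1:2] == 1))
  masked <- which(out2$mask[, "omics3"] == 0)
  expect_true(all(out2$blocks$omics3$values[masked, ] == 0))

  # determinism
  expect_identical(simulate_missingness(ds, 0.5, rng_seed = 9),
                   simulate_missingness(ds, 0.5, rng_seed = 9))

  # >= 1 available omics for every sample across many seeds and rates
  ds_big <- small_dataset(seed = 8, n = 40)$dataset
  for (s in 1:250) {
    rate <- runif(1, 0, 0.99)
    out <- simulate_missingness(ds_big, rate, rng_seed = s)
    expect_true(all(rowSums(out$mask) >= 1))
  }
})

test_that("stratified split is proportional, disjoint, exhaustive and deterministic", {
  ds <- small_dataset(seed = 10, n = 100)$dataset
  sp <- stratified_split(ds, 0.2, rng_seed = 3)
  expect_equal(sort(c(sp$train$sample_ids, sp$test$sample_ids)),
               sort(ds$sample_ids))
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  expect_true(all(table(sp$test$labels) == 5))  # 100 samples, 4 balanced classes

  sp2 <- stratified_split(ds, 0.2, rng_seed = 3)
  expect_identical(sp$test$sample_ids, sp2$test$sample_ids)

  # a singleton subtype cannot be stratified
  lab <- as.character(ds$labels)
  lab[ds$labels == "subtype4"] <- "subtype1"
  lab[1] <- "subtype4"
  ds$labels <- factor(lab)
  expect_error(stratified_split(ds, 0.2, rng_seed = 1), "subtype4")
})

test_that("dataset directory write/read round-trips values, mask, labels and ids", {
  ds <- simulate_missingness(small_dataset(seed = 12, n = 16)$dataset,
                             0.25, rng_seed = 4)
  dir <- tempfile()
  write_dataset(ds, dir, manifest = list(seed = 12))
  back <- read_dataset(dir)
  expect_equal(back$sample_ids, ds$sample_ids)
  expect_equal(unname(back$mask), unname(ds$mask))
  expect_equal(as.character(back$labels), as.character(ds$labels))
  for (nm in names(ds$blocks)) {
    expect_equal(back$blocks[[nm]]$values, ds$blocks[[nm]]$values,
                 tolerance = 1e-12)
  }
})
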