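# Diagnosis head: class weights, imputing encoder, weighted cross-entropy,
# loss composition, gradient routing and the training contract.

test_that("class weights follow N_tr / (N_s * N_y) and conserve mass", {
  w <- compute_class_weights(rep(c("A", "B"), c(8, 2)))
  expect_equal(w$weight[w$subtype == "A"], 0.625)
  expect_equal(w$weight[w$subtype == "B"], 2.5)
  expect_equal(sum(w$weight * w$n), 10)

  # balanced classes: all weights 1
  wb <- compute_class_weights(rep(c("A", "B", "C"), each = 7))
  expect_true(all(wb$weight == 1))

  # conservation holds for arbitrary label multisets
  set.seed(11)
  for (i in 1:20) {
    lab <- sample(letters[1:4], sample(10:80, 1), replace = TRUE)
    lab <- c(lab, letters[1:4])  # ensure every class occurs
    w <- compute_class_weights(lab)
    expect_equal(sum(w$weight * w$n), length(lab), tolerance = 1e-12)
  }

  expect_error(compute_class_weights(c("A", "A"), classes = c("A", "B")),
               "no training samples")
})

test_that("imputing encoder collapses to the plain encoder on complete samples", {
  lrn <- small_learner()
  X <- matrix(runif(3 * sum(lrn$input_dims)), 3)
  z_plain <- encode_patient(lrn, X)
  z_imp <- encode_with_imputation(lrn, X, matrix(1, 3, 3))
  expect_identical(z_plain, z_imp)  # bit-identical, Lambda all-ones
})

test_that("missing blocks are replaced by generator output before encoding", {
  lrn <- small_learner()
  dims <- lrn$input_dims
  x <- runif(sum(dims))
  ends <- cumsum(dims); starts <- ends - dims + 1
  mask <- c(1, 0, 1)
  # manual pipeline: generate omics 2 from the gated input, substitute,
  # then encode the composed vector
  gen <- generate_omics(lrn, x, mask, 2)
  x_sub <- x
  x_sub[starts[2]:ends[2]] <- gen
  expect_equal(encode_with_imputation(lrn, x, mask),
               encode_patient(lrn, x_sub), tolerance = 1e-12)

  # values stored inside the missing block are irrelevant
  x_junk <- x
  x_junk[starts[2]:ends[2]] <- 99
  expect_equal(encode_with_imputation(lrn, x, mask),
               encode_with_imputation(lrn, x_junk, mask),
               tolerance = 1e-14)
  expect_error(encode_with_imputation(lrn, x, c(0, 0, 0)), "no available")
})

test_that("diagnosis loss matches closed forms and manual arithmetic", {
  lrn <- small_learner()
  dims <- lrn$input_dims
  # uniform predictor over 4 balanced classes with unit weights: ln 4
  lrn0 <- lrn
  lrn0$params$head$W$value[] <- 0
  lrn0$params$head$b$value[] <- 0
  X <- matrix(runif(8 * sum(dims)), 8)
  mask <- matrix(1, 8, 3)
  y <- rep(paste0("subtype", 1:4), 2)
  expect_equal(diagnosis_loss(lrn0, X, mask, y), log(4), tolerance = 1e-12)

  # hand-computed weighted CE on a 3-sample batch with unequal weights
  X3 <- X[1:3, ]
  y3 <- c("subtype1", "subtype1", "subtype2")
  w <- compute_class_weights(y3, lrn$classes[1:2])
  z <- encode_with_imputation(lrn, X3, mask[1:3, ])
  logits <- z %*% omixfuse:::ad_value(lrn$params$head$W) +
    matrix(omixfuse:::ad_value(lrn$params$head$b), 3, 4, byrow = TRUE)
  P <- exp(logits) / rowSums(exp(logits))
  yi <- c(1, 1, 2)
  wi <- w$weight[match(y3, w$subtype)]
  manual <- mean(wi * -log(P[cbind(1:3, yi)]))
  expect_equal(diagnosis_loss(lrn, X3, mask[1:3, ], y3, weights = w),
               manual, tolerance = 1e-10)

  expect_error(diagnosis_loss(lrn, X3, mask[1:3, ], c("a", "b", "c")),
               "label")
})

test_that("the total loss is the weighted sum of its three components", {
  ds <- small_dataset(seed = 14, n = 24)$dataset
  ds <- simulate_missingness(ds, 0.25, rng_seed = 3)
  # lambda1 = lambda2 = 0 reduces to the diagnosis loss exactly
  lrn0 <- new_base_learner(omixfuse:::block_dims(ds), levels(ds$labels),
                           small_config(lambda1 = 0, lambda2 = 0), seed = 4)
  l0 <- base_loss(lrn0, ds, rng_seed = 5)
  X <- omixfuse:::concat_features(ds)
  expect_equal(as.numeric(l0),
               diagnosis_loss(lrn0, X, ds$mask, ds$labels),
               tolerance = 1e-12)

  # default lambdas: total equals the sum of the recorded components
  lrn1 <- new_base_learner(omixfuse:::block_dims(ds), levels(ds$labels),
                           small_config(), seed = 4)
  l1 <- base_loss(lrn1, ds, rng_seed = 5)
  comps <- attr(l1, "components")
  expect_equal(as.numeric(l1), sum(comps), tolerance = 1e-10)
  expect_true(all(comps >= 0))
})

test_that("each loss reaches only its own sub-networks", {
  ds <- small_dataset(seed = 15, n = 20)$dataset
  ds <- simulate_missingness(ds, 0.25, rng_seed = 1)
  lrn <- new_base_learner(omixfuse:::block_dims(ds), levels(ds$labels),
                          small_config(dropout = 0), seed = 6)
  set.seed(2)
  out <- omixfuse:::base_loss_node(lrn$params, lrn$config, lrn$input_dims,
                                   lrn$classes, ds, training = FALSE)
  g_con <- omixfuse:::ad_grad(out$components$contrastive, lrn$params)
  g_gen <- omixfuse:::ad_grad(out$components$generation, lrn$params)
  g_diag <- omixfuse:::ad_grad(out$components$diagnosis, lrn$params)

  # contrastive: encoder + projector only
  expect_equal(omixfuse:::max_abs_grad(g_con$generators), 0)
  expect_equal(omixfuse:::max_abs_grad(g_con$head), 0)
  expect_gt(omixfuse:::max_abs_grad(g_con$encoder), 0)
  expect_gt(omixfuse:::max_abs_grad(g_con$projector), 0)

  # generation: encoder + generators only
  expect_equal(omixfuse:::max_abs_grad(g_gen$head), 0)
  expect_equal(omixfuse:::max_abs_grad(g_gen$projector), 0)
  expect_gt(omixfuse:::max_abs_grad(g_gen$generators), 0)
  expect_gt(omixfuse:::max_abs_grad(g_gen$encoder), 0)

  # diagnosis: encoder + head; imputed values are detached, so the
  # generators receive nothing
  expect_equal(omixfuse:::max_abs_grad(g_diag$generators), 0)
  expect_equal(omixfuse:::max_abs_grad(g_diag$projector), 0)
  expect_gt(omixfuse:::max_abs_grad(g_diag$head), 0)
  expect_gt(omixfuse:::max_abs_grad(g_diag$encoder), 0)
})

test_that("training is deterministic and leaves unrouted parameters untouched", {
  g <- small_dataset(seed = 16, n = 40)
  cfg <- small_config(epochs = 3)
  a <- train_base_learner(g$dataset, cfg, seed = 8)
  b <- train_base_learner(g$dataset, cfg, seed = 8)
  fa <- omixfuse:::flatten_params(a$params)
  fb <- omixfuse:::flatten_params(b$params)
  for (k in names(fa)) expect_identical(fa[[k]]$value, fb[[k]]$value)

  # with lambda2 = 0 and complete data, generator parameters never move
  cfg2 <- small_config(epochs = 2, lambda2 = 0)
  init <- new_base_learner(omixfuse:::block_dims(g$dataset),
                           levels(g$dataset$labels), cfg2, seed = 9)
  before <- lapply(omixfuse:::flatten_params(init$params$generators),
                   function(p) p$value)
  trained <- train_base_learner(g$dataset, cfg2, seed = 9, learner = init)
  after <- lapply(omixfuse:::flatten_params(trained$params$generators),
                  function(p) p$value)
  expect_identical(before, after)
})

test_that("predictions satisfy the probability and argmax contracts", {
  fx <- trained_learner_fixture()
  preds <- predict_subtypes(fx$learner, fx$data$dataset)
  prob <- as.matrix(preds[, grep("^\\.prob_", names(preds))])
  score <- as.matrix(preds[, grep("^\\.score_", names(preds))])
  expect_true(all(abs(rowSums(prob) - 1) < 1e-6))
  expect_true(all(score > 0 & score < 1))
  # softmax and sigmoid share the argmax (both monotone in the logit)
  expect_equal(max.col(prob, ties.method = "first"),
               max.col(score, ties.method = "first"))
  expect_equal(as.character(preds$.pred),
               fx$learner$classes[max.col(prob, ties.method = "first")])

  # out-of-range input warns and clips
  bad <- fx$data$dataset
  bad$blocks[[1]]$values[1, 1] <- 3
  expect_warning(predict_subtypes(fx$learner, bad), "clipping")
})
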