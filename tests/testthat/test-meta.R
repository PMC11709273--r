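# Knowledge transfer: episodes, inner/outer loops, densities, divergences
# and the category-level contrastive loss.

test_that("episodes are exact N-way K-shot with disjoint support and query", {
  ds <- small_dataset(seed = 20, n = 120)$dataset  # 30 per subtype
  ep <- sample_episode(ds, ways = 4, shots = 10, rng_seed = 1)
  expect_length(ep$support$sample_ids, 40)
  expect_length(ep$query$sample_ids, 40)
  expect_length(intersect(ep$support$sample_ids, ep$query$sample_ids), 0)
  expect_true(all(table(ep$support$labels) == 10))
  expect_true(all(table(ep$query$labels) == 10))

  ep2 <- sample_episode(ds, 4, 10, rng_seed = 1)
  expect_identical(ep$support$sample_ids, ep2$support$sample_ids)
  expect_identical(ep$query$sample_ids, ep2$query$sample_ids)

  # a class with 15 samples cannot provide disjoint 10-shot sets
  ds15 <- subset_dataset_by_class_cap(ds, cap = 15)
  expect_error(sample_episode(ds15, 4, 10, rng_seed = 1), "fewer than 20")
  # ... unless with-replacement fallback is allowed
  ep3 <- sample_episode(ds15, 4, 10, rng_seed = 1, replace = TRUE)
  expect_true(all(table(ep3$support$labels) == 10))
})

test_that("inner adaptation is a plain gradient-descent step on the support loss", {
  ds <- small_dataset(seed = 22, n = 40)$dataset
  lrn <- new_base_learner(omixfuse:::block_dims(ds), levels(ds$labels),
                          small_config(dropout = 0), seed = 2)
  # alpha = 0: parameters unchanged
  a0 <- inner_adapt(lrn, ds, inner_rate = 0, rng_seed = 3)
  f0 <- omixfuse:::flatten_params(a0$params)
  f_ini <- omixfuse:::flatten_params(lrn$params)
  for (k in names(f0)) expect_equal(f0[[k]]$value, f_ini[[k]]$value)

  # one step at alpha = 0.1 matches an independently computed descent step
  alpha <- 0.1
  set.seed(7)
  out <- omixfuse:::base_loss_node(lrn$params, lrn$config, lrn$input_dims,
                                   lrn$classes, ds, training = FALSE)
  g <- omixfuse:::ad_grad(out$total, lrn$params)
  manual <- omixfuse:::sgd_update(lrn$params, g, alpha)
  adapted <- inner_adapt(lrn, ds, inner_rate = alpha, rng_seed = 7)
  fm <- omixfuse:::flatten_params(manual)
  fa <- omixfuse:::flatten_params(adapted$params)
  for (k in names(fm)) {
    expect_equal(fa[[k]]$value, fm[[k]]$value, tolerance = 1e-12)
  }
  # the original initialization is untouched
  for (k in names(f_ini)) {
    expect_identical(f_ini[[k]]$value,
                     omixfuse:::flatten_params(lrn$params)[[k]]$value)
  }
})

test_that("kernel density estimates are normalized with Scott bandwidths", {
  set.seed(23)
  pts <- matrix(rnorm(100 * 3), 100, 3)
  de <- fit_kde_density(pts)
  # per-dimension trapezoid integral is 1
  for (d in 1:3) {
    expect_equal(omixfuse:::trapz(de$grid[, d], de$density[, d]), 1,
                 tolerance = 1e-3)
  }
  # Scott's rule: h_d = n^(-1/5) * sd_d
  expect_equal(de$bandwidth, apply(pts, 2, sd) * 100^(-1 / 5),
               tolerance = 1e-12)
  # a tight cluster puts the mode at the cluster mean (grid resolution)
  tight <- matrix(rnorm(60, mean = 2, sd = 0.01), 30, 2)
  dt <- suppressWarnings(fit_kde_density(tight))  # bandwidth floor fires
  for (d in 1:2) {
    mode_at <- dt$grid[which.max(dt$density[, d]), d]
    expect_lt(abs(mode_at - mean(tight[, d])),
              diff(dt$grid[1:2, d]) * 2 + 0.01)
  }
  expect_error(fit_kde_density(matrix(1, 1, 2)), "at least 2")
  # the bandwidth floor warns once while fitting and once for the grid
  w <- testthat::capture_warnings(
    fit_kde_density(cbind(rnorm(20), rep(1, 20))))
  expect_true(any(grepl("bandwidth floored", w)))
})

test_that("Jensen-Shannon divergence matches its limits and a quadrature oracle", {
  set.seed(24)
  x <- matrix(rnorm(200), 100, 2)
  p <- fit_kde_density(x)
  expect_equal(js_divergence(p, p), 0, tolerance = 1e-12)

  # near-disjoint narrow distributions approach log 2
  a <- matrix(rnorm(100, 0, 0.05), 100, 1)
  b <- matrix(rnorm(100, 10, 0.05), 100, 1)
  grid <- omixfuse:::make_density_grid(list(a, b))
  expect_equal(js_divergence(fit_kde_density(a, grid),
                             fit_kde_density(b, grid)), log(2),
               tolerance = 1e-3)

  # N(0,1) vs N(1,1) samples: the 512-point grid integration agrees with a
  # 1e5-point quadrature of the same kernel density estimates
  set.seed(25)
  s1 <- matrix(rnorm(200, 0, 1), ncol = 1)
  s2 <- matrix(rnorm(200, 1, 1), ncol = 1)
  grid512 <- omixfuse:::make_density_grid(list(s1, s2), n_grid = 512)
  val <- js_divergence(fit_kde_density(s1, grid512),
                       fit_kde_density(s2, grid512))
  fine <- matrix(seq(grid512[1, 1], grid512[512, 1], length.out = 1e5),
                 ncol = 1)
  oracle <- js_divergence(fit_kde_density(s1, fine),
                          fit_kde_density(s2, fine))
  expect_equal(val, oracle, tolerance = 1e-3)
  # and the sample-based value sits near the analytic JSD of the two
  # generating normals
  g <- seq(-8, 9, length.out = 1e5)
  p1 <- stats::dnorm(g, 0, 1); p2 <- stats::dnorm(g, 1, 1)
  m <- (p1 + p2) / 2
  analytic <- 0.5 * (omixfuse:::trapz(g, p1 * log(p1 / m)) +
                       omixfuse:::trapz(g, p2 * log(p2 / m)))
  expect_lt(abs(val - analytic), 0.05)

  expect_error(js_divergence(fit_kde_density(a), fit_kde_density(b)),
               "share the evaluation grid")
})

test_that("JSD is symmetric, zero on identity and bounded by log 2 on random pairs", {
  set.seed(26)
  for (i in 1:500) {
    n <- sample(10:40, 1)
    mu <- runif(2, -3, 3); sd <- runif(2, 0.1, 2)
    a <- matrix(rnorm(n, mu[1], sd[1]), ncol = 1)
    b <- matrix(rnorm(n, mu[2], sd[2]), ncol = 1)
    grid <- omixfuse:::make_density_grid(list(a, b), n_grid = 128)
    p <- fit_kde_density(a, grid); q <- fit_kde_density(b, grid)
    d_pq <- js_divergence(p, q)
    expect_gte(d_pq, 0)
    expect_lte(d_pq, log(2) + 1e-9)
    expect_equal(d_pq, js_divergence(q, p), tolerance = 1e-12)
  }
})

test_that("identical class distributions give the uniform-softmax category loss", {
  # both cohorts carry the same point cloud for every class, so every
  # affinity is 0 and the softmax is uniform over 2|Y| terms
  dims <- c(o1 = 6, o2 = 5)
  set.seed(27)
  vals <- matrix(runif(10 * sum(dims)), 10)
  blocks_from <- function(v, prefix) {
    ids <- sprintf("%s%02d", prefix, seq_len(nrow(v)))
    rownames(v) <- ids
    list(o1 = omics_block(v[, 1:6, drop = FALSE], "o1"),
         o2 = omics_block(v[, 7:11, drop = FALSE], "o2"))
  }
  labels <- rep(paste0("c", 1:4), each = 10)
  big <- vals[rep(1:10, 4), ]  # the same cloud replicated for each class
  ds_ft <- multiomics_dataset(blocks_from(big, "a"), labels = labels)
  ds_t <- multiomics_dataset(blocks_from(big, "b"), labels = labels)
  lrn <- new_base_learner(dims, paste0("c", 1:4),
                          small_config(d_h = 4, dropout = 0), seed = 9)
  loss <- suppressWarnings(
    category_contrastive_loss(lrn, ds_ft, ds_t, kde_grid = 64))
  expect_equal(loss, log(2 * 4), tolerance = 1e-9)

  # invariance under a consistent relabeling of the classes
  relab <- c(c1 = "c3", c2 = "c4", c3 = "c1", c4 = "c2")
  ds_ft2 <- ds_ft; ds_t2 <- ds_t
  ds_ft2$labels <- factor(relab[as.character(ds_ft$labels)])
  ds_t2$labels <- factor(relab[as.character(ds_t$labels)])
  loss2 <- suppressWarnings(
    category_contrastive_loss(lrn, ds_ft2, ds_t2, kde_grid = 64))
  expect_equal(loss2, loss, tolerance = 1e-9)
})

test_that("aligning same-class clouds lowers the category loss", {
  dims <- c(o1 = 6, o2 = 5)
  set.seed(28)
  make_ds <- function(offsets, prefix) {
    v <- do.call(rbind, lapply(1:4, function(cl) {
      matrix(plogis(rnorm(8 * sum(dims), mean = offsets[cl], sd = 0.3)),
             8)
    }))
    rownames(v) <- sprintf("%s%02d", prefix, seq_len(nrow(v)))
    ds <- multiomics_dataset(
      list(o1 = omics_block(v[, 1:6, drop = FALSE], "o1"),
           o2 = omics_block(v[, 7:11, drop = FALSE], "o2")),
      labels = rep(paste0("c", 1:4), each = 8))
  }
  offs <- c(-2, -0.5, 0.5, 2)
  target <- make_ds(offs, "t")
  aligned <- make_ds(offs, "a")       # same per-class distributions
  shifted <- make_ds(rev(offs), "s")  # classes displaced onto other modes
  lrn <- new_base_learner(dims, paste0("c", 1:4),
                          small_config(d_h = 4, dropout = 0), seed = 10)
  l_aligned <- suppressWarnings(
    category_contrastive_loss(lrn, target, aligned, kde_grid = 64))
  l_shifted <- suppressWarnings(
    category_contrastive_loss(lrn, target, shifted, kde_grid = 64))
  expect_lt(l_aligned, l_shifted)

  # the literal printed sign reverses the preference
  l_aligned_lit <- suppressWarnings(category_contrastive_loss(
    lrn, target, aligned, kde_grid = 64, literal_sign = TRUE))
  l_shifted_lit <- suppressWarnings(category_contrastive_loss(
    lrn, target, shifted, kde_grid = 64, literal_sign = TRUE))
  expect_gt(l_aligned_lit, l_shifted_lit)
})

test_that("the category loss only reaches the encoder; the outer step applies it", {
  ds <- small_dataset(seed = 30, n = 64, dims = c(8, 6))$dataset
  lrn <- new_base_learner(omixfuse:::block_dims(ds), levels(ds$labels),
                          small_config(d_h = 4, dropout = 0), seed = 11)
  ep <- sample_episode(ds, 4, 4, rng_seed = 1)
  q_ft <- sample_episode(ds, 4, 4, rng_seed = 2)$query
  clc <- suppressWarnings(
    omixfuse:::clc_node(lrn$params, lrn$config, lrn$input_dims, q_ft,
                        ep$query, n_grid = 48))
  g <- omixfuse:::ad_grad(clc, lrn$params)
  expect_equal(omixfuse:::max_abs_grad(g$head), 0)
  expect_equal(omixfuse:::max_abs_grad(g$projector), 0)
  expect_equal(omixfuse:::max_abs_grad(g$generators), 0)
  expect_gt(omixfuse:::max_abs_grad(g$encoder), 0)

  # beta = 0 leaves the initialization unchanged
  adapted <- list(list(params = omixfuse:::clone_params(lrn$params),
                       query = ep$query))
  mc0 <- meta_config(outer_rate = 0, kde_grid = 48)
  same <- suppressWarnings(outer_step(lrn, adapted, q_ft, mc0,
                                      rng_seed = 5))
  f1 <- omixfuse:::flatten_params(lrn$params)
  f2 <- omixfuse:::flatten_params(same$params)
  for (k in names(f1)) expect_equal(f2[[k]]$value, f1[[k]]$value)
})

test_that("the outer update equals the independently accumulated gradient step", {
  ds <- small_dataset(seed = 31, n = 64, dims = c(8, 6))$dataset
  lrn <- new_base_learner(omixfuse:::block_dims(ds), levels(ds$labels),
                          small_config(d_h = 4, dropout = 0, lambda1 = 0,
                                       lambda2 = 0), seed = 12)
  eps <- lapply(1:2, function(i) {
    e <- sample_episode(ds, 4, 4, rng_seed = i)
    list(params = omixfuse:::clone_params(lrn$params), query = e$query)
  })
  q_ft <- sample_episode(ds, 4, 4, rng_seed = 9)$query
  mc <- meta_config(outer_rate = 0.05, kde_grid = 48, clip_norm = 1e9)
  stepped <- suppressWarnings(outer_step(lrn, eps, q_ft, mc, rng_seed = 3))
  # manual accumulation over the two episodes (deterministic: no
  # contrastive/generation randomness with the lambdas at 0)
  total <- NULL
  for (ep in eps) {
    out <- omixfuse:::base_loss_node(ep$params, lrn$config,
                                     lrn$input_dims, lrn$classes,
                                     ep$query, training = FALSE)
    gb <- omixfuse:::ad_grad(out$total, ep$params)
    clc <- suppressWarnings(
      omixfuse:::clc_node(ep$params, lrn$config, lrn$input_dims, q_ft,
                          ep$query, n_grid = 48))
    gc <- omixfuse:::ad_grad(clc, ep$params)
    gc$projector <- omixfuse:::zero_grads_like(ep$params$projector)
    gc$generators <- omixfuse:::zero_grads_like(ep$params$generators)
    gc$head <- omixfuse:::zero_grads_like(ep$params$head)
    total <- omixfuse:::add_grads(total, omixfuse:::add_grads(gb, gc))
  }
  manual <- omixfuse:::sgd_update(lrn$params, total, 0.05)
  fm <- omixfuse:::flatten_params(manual)
  fs <- omixfuse:::flatten_params(stepped$params)
  for (k in names(fm)) {
    expect_equal(fs[[k]]$value, fm[[k]]$value, tolerance = 1e-10)
  }
})

test_that("meta-training is reproducible and validates label spaces", {
  pair <- generate_domain_shifted_pair(synthetic_spec(
    n_samples = 64, dims = c(8, 6), n_subtypes = 4, latent_dim = 4,
    separation = 2.5, shift = 0.5, rng_seed = 33))
  cfg <- small_config(d_h = 4, dropout = 0)
  mc <- meta_config(ways = 4, shots = 4, n_outer = 2, n_sub = 1,
                    kde_grid = 48, finetune_epochs = 3)
  a <- suppressWarnings(meta_train_and_finetune(pair$external,
                                                pair$target, cfg, mc,
                                                seed = 4))
  b <- suppressWarnings(meta_train_and_finetune(pair$external,
                                                pair$target, cfg, mc,
                                                seed = 4))
  expect_identical(a$report, b$report)
  expect_identical(a$finetune_ids, b$finetune_ids)

  bad <- pair$target
  levels(bad$labels) <- paste0("x", 1:4)
  expect_error(
    suppressWarnings(meta_train_and_finetune(pair$external, bad, cfg, mc)),
    "label space")
})
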