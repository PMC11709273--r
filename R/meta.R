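# Knowledge transfer: episodic bi-level optimization (MAML-style,
# first-order) with a distribution-level category contrastive loss.
#
# Episodes are N-way K-shot support/query pairs from an external cohort.
# The inner loop adapts the initialization to an episode's support set;
# the outer loop updates the initialization from the query losses plus a
# category-level contrastive loss that aligns, per subtype, the kernel
# density estimates of target and external representations (affinity
# F = -JSD so minimizing the loss pulls same-subtype distributions
# together). The target's fine-tuning query set only ever touches the
# encoder parameters through this loss.

#' Sample an N-way K-shot episode
#'
#' Support and query sets each contain exactly K samples of each of N
#' subtypes, disjoint from one another. Deterministic given `rng_seed`.
#'
#' @param dataset A labeled [multiomics_dataset()].
#' @param ways Number of subtypes N (must not exceed the classes present).
#' @param shots Samples per subtype K in each set.
#' @param rng_seed Integer seed.
#' @param replace Allow with-replacement sampling when a class has fewer
#'   than 2K samples (off by default).
#' @return A list with `support` and `query` datasets and the sampled
#'   `classes`.
#' @export
sample_episode <- function(dataset, ways, shots, rng_seed,
                           replace = FALSE) {
  stopifnot(!is.null(dataset$labels))
  counts <- table(dataset$labels)
  force(ways); force(shots); force(rng_seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  classes <- names(counts)
  if (ways < length(classes)) classes <- sample(classes, ways)
  if (ways > length(classes)) {
    stop("requested ", ways, " ways but only ", length(classes),
         " subtypes exist")
  }
  short <- classes[counts[classes] < 2 * shots]
  if (length(short) && !replace) {
    stop("subtype(s) with fewer than ", 2 * shots,
         " samples (needed for disjoint ", shots, "-shot support and ",
         "query): ", paste(short, collapse = ", "))
  }
  sup <- integer(0); qry <- integer(0)
  for (cl in classes) {
    rows <- which(dataset$labels == cl)
    take <- sample(rows, 2 * shots, replace = replace)
    sup <- c(sup, take[seq_len(shots)])
    qry <- c(qry, take[shots + seq_len(shots)])
  }
  list(support = subset_dataset(dataset, sort(sup)),
       query = subset_dataset(dataset, sort(qry)),
       classes = sort(classes))
}

# One stratified N-way K-shot set plus the remaining samples.
sample_nway_kshot <- function(dataset, ways, shots, rng_seed) {
  ep <- sample_episode(dataset, ways, shots, rng_seed)
  taken <- match(ep$support$sample_ids, dataset$sample_ids)
  list(set = ep$support,
       rest = subset_dataset(dataset,
                             setdiff(seq_len(n_samples(dataset)), taken)))
}

#' Inner-loop adaptation
#'
#' One (or more) plain gradient-descent step(s) of the total training loss
#' on an episode's support set: `psi' = psi - alpha * grad L(support)`.
#' The learner's own initialization is left untouched.
#'
#' @param learner A base learner holding the initialization psi.
#' @param support A labeled [multiomics_dataset()].
#' @param inner_rate Learning rate alpha.
#' @param inner_steps Number of descent steps (default 1).
#' @param rng_seed Seed of the stochastic loss terms.
#' @return A learner copy with adapted parameters.
#' @export
inner_adapt <- function(learner, support, inner_rate, inner_steps = 1,
                        rng_seed = 1, clip_norm = Inf) {
  force(learner); force(support); force(inner_rate); force(rng_seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  params <- clone_params(learner$params)
  for (s in seq_len(inner_steps)) {
    out <- base_loss_node(params, learner$config, learner$input_dims,
                          learner$classes, support, training = FALSE)
    if (!is.finite(ad_value(out$total)[1L])) {
      stop("inner adaptation failed: non-finite loss")
    }
    grads <- ad_grad(out$total, params)
    if (is.finite(clip_norm)) grads <- clip_grads(grads, clip_norm)
    params <- sgd_update(params, grads, inner_rate)
  }
  adapted <- learner
  adapted$params <- params
  adapted
}

#' Per-dimension Gaussian kernel density estimate
#'
#' Univariate Gaussian KDE of each representation dimension with Scott's
#' bandwidth `n^(-1/5) * sd`, evaluated on a shared grid spanning the
#' pooled range plus/minus 3 bandwidths, and normalized to integrate to 1
#' (trapezoid rule) on the grid.
#'
#' @param points n x d matrix of representation vectors (n >= 2).
#' @param grid Optional G x d evaluation grid shared across estimates that
#'   will be compared; auto-generated from `points` when omitted.
#' @param n_grid Grid resolution when auto-generating (default 512).
#' @return An object of class `density_estimate` with fields `grid`
#'   (G x d), `density` (G x d) and `bandwidth` (length d).
#' @export
fit_kde_density <- function(points, grid = NULL, n_grid = 512) {
  points <- as_mat(points)
  if (nrow(points) < 2) {
    stop("at least 2 points are required for a density estimate")
  }
  bw <- kde_bandwidths(points)
  if (is.null(grid)) {
    grid <- make_density_grid(list(points), n_grid = n_grid)
  }
  stopifnot(ncol(grid) == ncol(points))
  dens <- matrix(0, nrow(grid), ncol(points))
  for (d in seq_len(ncol(points))) {
    dens[, d] <- kde_eval(points[, d], bw[d], grid[, d])
  }
  structure(list(grid = grid, density = dens, bandwidth = bw),
            class = "density_estimate")
}

kde_bandwidths <- function(points, floor = 1e-3) {
  n <- nrow(points)
  bw <- apply(points, 2L, stats::sd) * n^(-1 / 5)
  if (any(bw < floor)) {
    warning("zero/near-zero variance dimension(s); bandwidth floored at ",
            floor)
    bw <- pmax(bw, floor)
  }
  bw
}

# Shared per-dimension grid across several point sets.
make_density_grid <- function(point_sets, n_grid = 512) {
  d <- ncol(point_sets[[1]])
  bws <- lapply(point_sets, kde_bandwidths)
  grid <- matrix(0, n_grid, d)
  for (j in seq_len(d)) {
    vals <- unlist(lapply(point_sets, function(p) p[, j]))
    pad <- 3 * max(vapply(bws, `[[`, numeric(1), j))
    grid[, j] <- seq(min(vals) - pad, max(vals) + pad,
                     length.out = n_grid)
  }
  grid
}

kde_eval <- function(x, h, grid) {
  D <- outer(grid, x, "-")
  p <- rowMeans(exp(-D^2 / (2 * h^2))) / (h * sqrt(2 * pi))
  p / trapz(grid, p)
}

trapz <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

#' Jensen-Shannon divergence between density estimates
#'
#' Mean over dimensions of the JSD (natural log) of the per-dimension
#' densities, integrated on the shared grid. Symmetric and bounded by
#' `log(2)`.
#'
#' @param p,q [fit_kde_density()] objects sharing the same grid.
#' @return Non-negative scalar in \[0, log 2\].
#' @export
js_divergence <- function(p, q) {
  if (!isTRUE(all.equal(p$grid, q$grid))) {
    stop("density estimates must share the evaluation grid")
  }
  vals <- vapply(seq_len(ncol(p$grid)), function(d) {
    jsd_1d(p$grid[, d], p$density[, d], q$density[, d])
  }, numeric(1))
  mean(vals)
}

jsd_1d <- function(grid, p, q, eps = 1e-12) {
  m <- (p + q) / 2
  kl <- function(a) trapz(grid, a * (log(a + eps) - log(m + eps)))
  max(0, (kl(p) + kl(q)) / 2)
}

# --- differentiable density machinery for the category loss ---------------

# Gaussian KDE of a column node on a fixed grid, trapezoid-normalized;
# gradients flow through the sample positions only (grid and bandwidth are
# constants, by design).
density_node <- function(zcol, h, grid, w) {
  D <- ad_outer_diff(grid, zcol)
  K <- ad_exp(ad_scale(ad_square(D), -1 / (2 * h^2)))
  n <- ncol(ad_value(K))
  p_raw <- ad_scale(ad_rowsums(K), 1 / (n * h * sqrt(2 * pi)))
  s <- ad_sum(ad_cmul(p_raw, matrix(w, ncol = 1L)))
  ad_div(p_raw, s)
}

jsd_node <- function(p, q, w, eps = 1e-12) {
  m <- ad_scale(ad_add(p, q), 0.5)
  lm <- ad_log(m, eps)
  t1 <- ad_mul(p, ad_sub(ad_log(p, eps), lm))
  t2 <- ad_mul(q, ad_sub(ad_log(q, eps), lm))
  ad_scale(ad_sum(ad_cmul(ad_add(t1, t2), matrix(w, ncol = 1L))), 0.5)
}

#' Category-level contrastive loss
#'
#' Softmax contrast over distribution affinities: for every subtype l, the
#' target fine-tuning subset's representation density is pulled toward the
#' same subtype's density in the external query set against all subtype
#' densities of both sets:
#' `(1/|Y|) sum_l -log exp(F(Qft^l, Qt^l)) / sum_k sum_{Q in {Qft^k, Qt^k}}
#' exp(F(Qft^l, Q^k))`, with affinity `F = -JSD` of the per-dimension
#' kernel density estimates of the encoded representations.
#'
#' @param learner A base learner (its encoder is used).
#' @param q_ft Target fine-tuning query set (labeled dataset covering all
#'   classes with >= 2 samples each).
#' @param q_t External query set (same coverage requirement).
#' @param kde_grid Grid resolution of the density estimates.
#' @param literal_sign Use `F = +JSD` instead of the default `F = -JSD`.
#' @return Scalar loss.
#' @export
category_contrastive_loss <- function(learner, q_ft, q_t, kde_grid = 512,
                                      literal_sign = FALSE) {
  node <- clc_node(learner$params, learner$config, learner$input_dims,
                   q_ft, q_t, n_grid = kde_grid,
                   literal_sign = literal_sign)
  ad_value(node)[1L]
}

clc_node <- function(params, config, dims, q_ft, q_t, n_grid = 512,
                     literal_sign = FALSE) {
  classes <- sort(unique(c(levels(q_ft$labels), levels(q_t$labels))))
  for (ds_name in c("q_ft", "q_t")) {
    ds <- if (ds_name == "q_ft") q_ft else q_t
    cov <- table(factor(ds$labels, levels = classes))
    if (any(cov < 2)) {
      stop("class(es) with fewer than 2 samples in ", ds_name, ": ",
           paste(names(cov)[cov < 2], collapse = ", "))
    }
  }
  Zft <- encode_node(params$encoder, config, dims,
                     ad_input(concat_features(q_ft)), training = FALSE)
  Zt <- encode_node(params$encoder, config, dims,
                    ad_input(concat_features(q_t)), training = FALSE)
  d_h <- ncol(ad_value(Zft))
  # one density set per (cohort, class); grid/bandwidths fixed off-tape
  sets <- list()
  for (cl in classes) {
    sets[[paste0("ft.", cl)]] <- list(node = Zft,
                                      idx = which(q_ft$labels == cl))
    sets[[paste0("t.", cl)]] <- list(node = Zt,
                                     idx = which(q_t$labels == cl))
  }
  vals <- lapply(sets, function(s) ad_value(s$node)[s$idx, , drop = FALSE])
  grid <- make_density_grid(vals, n_grid = n_grid)
  bws <- lapply(vals, kde_bandwidths)
  dens <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    lapply(seq_len(d_h), function(d) {
      density_node(ad_cols(ad_rows(s$node, s$idx), d), bws[[nm]][d],
                   grid[, d], trapz_weights(grid[, d]))
    })
  })
  names(dens) <- names(sets)
  wlist <- lapply(seq_len(d_h), function(d) trapz_weights(grid[, d]))
  # JSD is symmetric and zero (with zero gradient) on identical sets, so
  # affinities are memoized by unordered pair
  memo <- new.env(parent = emptyenv())
  affinity <- function(a, b) {
    if (a == b) return(ad_input(matrix(0, 1L, 1L)))
    key <- paste(sort(c(a, b)), collapse = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    acc <- NULL
    for (d in seq_len(d_h)) {
      j <- jsd_node(dens[[a]][[d]], dens[[b]][[d]], wlist[[d]])
      acc <- if (is.null(acc)) j else ad_add(acc, j)
    }
    out <- ad_scale(acc, if (literal_sign) 1 / d_h else -1 / d_h)
    memo[[key]] <- out
    out
  }
  loss <- NULL
  for (cl in classes) {
    pos <- affinity(paste0("ft.", cl), paste0("t.", cl))
    den <- NULL
    for (k in classes) {
      for (coh in c("ft.", "t.")) {
        term <- ad_exp(affinity(paste0("ft.", cl), paste0(coh, k)))
        den <- if (is.null(den)) term else ad_add(den, term)
      }
    }
    l_cl <- ad_sub(ad_log(den), pos)
    loss <- if (is.null(loss)) l_cl else ad_add(loss, l_cl)
  }
  ad_scale(loss, 1 / length(classes))
}

#' Outer meta-update
#'
#' First-order MAML step: for each inner-adapted episode, the query-set
#' training loss plus the category-level contrastive loss (gradients
#' restricted to the encoder) are differentiated at the adapted
#' parameters, summed over episodes, and applied to the initialization:
#' `psi_ini <- psi_ini - beta * sum_t grad[L(Q_t; psi'_t) +
#' L_clc(Qft, Q_t; theta'_t)]`.
#'
#' @param learner Base learner holding the initialization psi_ini.
#' @param adapted List of episodes, each a list with `params` (the
#'   inner-adapted parameter tree) and `query` (the episode's query
#'   dataset).
#' @param q_ft Target fine-tuning query set.
#' @param meta A [meta_config()].
#' @param rng_seed Seed of the stochastic loss terms.
#' @return The learner with updated initialization.
#' @export
outer_step <- function(learner, adapted, q_ft, meta = meta_config(),
                       rng_seed = 1) {
  force(learner); force(adapted); force(q_ft); force(meta); force(rng_seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  total <- NULL
  for (ep in adapted) {
    out <- base_loss_node(ep$params, learner$config, learner$input_dims,
                          learner$classes, ep$query, training = FALSE)
    g_base <- ad_grad(out$total, ep$params)
    clc <- clc_node(ep$params, learner$config, learner$input_dims,
                    q_ft, ep$query, n_grid = meta$kde_grid,
                    literal_sign = meta$literal_sign)
    g_clc <- ad_grad(clc, ep$params)
    # the category loss only optimizes the encoder subset theta
    g_clc$projector <- zero_grads_like(ep$params$projector)
    g_clc$generators <- zero_grads_like(ep$params$generators)
    g_clc$head <- zero_grads_like(ep$params$head)
    g <- clip_grads(add_grads(g_base, g_clc), meta$clip_norm)
    total <- add_grads(total, g)
    if (!is.finite(max_abs_grad(g))) stop("meta step failed: non-finite ",
                                          "gradient")
  }
  learner$params <- sgd_update(learner$params, total, meta$outer_rate)
  learner
}

#' Meta-train on external cohorts and fine-tune on the target
#'
#' Loops episode sampling, inner adaptation and outer updates over the
#' external dataset(s); with several externals the category loss is always
#' computed target-vs-external (never external-vs-external). The learned
#' initialization is then fully fine-tuned on the target's N-way K-shot
#' fine-tuning set and evaluated on the remaining target samples.
#' Deterministic given `seed`.
#'
#' @param external A labeled [multiomics_dataset()] or list of them.
#' @param target A labeled [multiomics_dataset()] sharing the label space.
#' @param config A [learner_config()].
#' @param meta A [meta_config()].
#' @param seed Integer seed.
#' @return An object of class `omix_transfer`: the fine-tuned `learner`,
#'   the one-row evaluation `report`, the fine-tuning set ids and the held
#'   out `eval_set`.
#' @export
meta_train_and_finetune <- function(external, target,
                                    config = learner_config(),
                                    meta = meta_config(), seed = 1) {
  if (inherits(external, "multiomics_dataset")) external <- list(external)
  tgt_classes <- levels(target$labels)
  for (ext in external) {
    if (!identical(levels(ext$labels), tgt_classes)) {
      stop("external and target datasets must share the label space")
    }
    if (!identical(block_dims(ext), block_dims(target))) {
      stop("external and target datasets must share the feature space")
    }
  }
  force(config); force(meta); force(seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  split_ft <- sample_nway_kshot(target, meta$ways, meta$shots,
                                rng_seed = sample.int(1e8, 1))
  q_ft <- split_ft$set
  learner <- new_base_learner(block_dims(target), tgt_classes, config,
                              seed = sample.int(1e8, 1))
  for (it in seq_len(meta$n_outer)) {
    adapted <- vector("list", meta$n_sub)
    for (t in seq_len(meta$n_sub)) {
      ext <- external[[(it * meta$n_sub + t) %% length(external) + 1L]]
      ep <- sample_episode(ext, meta$ways, meta$shots,
                           rng_seed = sample.int(1e8, 1))
      ad_learner <- inner_adapt(learner, ep$support, meta$inner_rate,
                                meta$inner_steps,
                                rng_seed = sample.int(1e8, 1),
                                clip_norm = meta$clip_norm)
      adapted[[t]] <- list(params = ad_learner$params, query = ep$query)
    }
    learner <- outer_step(learner, adapted, q_ft, meta,
                          rng_seed = sample.int(1e8, 1))
  }
  ft_config <- learner$config
  ft_config$epochs <- meta$finetune_epochs
  ft_config$lr <- meta$finetune_lr
  learner$config <- ft_config
  learner <- train_base_learner(q_ft, seed = sample.int(1e8, 1),
                                learner = learner)
  preds <- predict_subtypes(learner, split_ft$rest)
  report <- evaluate_metrics(split_ft$rest$labels, preds)
  structure(list(learner = learner, report = report,
                 finetune_ids = q_ft$sample_ids, eval_set = split_ft$rest,
                 meta = meta),
            class = "omix_transfer")
}

#' @export
print.omix_transfer <- function(x, ...) {
  cat("<omix_transfer> fine-tuned on", length(x$finetune_ids),
      "target samples; evaluated on", length(x$eval_set$sample_ids), "\n")
  print(x$report)
  invisible(x)
}
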