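# Missing-omics imputation: contrastive view agreement plus
# masking-and-reconstruction (MAR) generators.
#
# Complete samples are augmented into two views by zeroing different omics
# subsets; the NT-Xent loss pulls the projected representations of the two
# views of one patient together against all other views in the batch. The
# omics-specific generators learn to reconstruct blocks from the fused
# representation of the remaining ones, so a truly missing block can be
# imputed at diagnosis time.

#' Two augmented views of a complete sample
#'
#' Draws two distinct omics-level masks uniformly from the masks that keep
#' at least one omics and hide at least one, and zero-fills the hidden
#' blocks. Deterministic given `rng_seed`.
#'
#' @param sample Concatenated multi-omics vector (all M omics available).
#' @param dims Integer vector of per-omics feature counts.
#' @param rng_seed Integer seed.
#' @return A list with `view_a`, `view_b` (masked copies of `sample`) and
#'   `mask_a`, `mask_b` (binary length-M keep-vectors).
#' @export
make_augmented_views <- function(sample, dims, rng_seed) {
  M <- length(dims)
  if (M < 2) {
    stop("augmentation requires at least 2 omics; with M = 1 no proper ",
         "view masks exist")
  }
  force(sample); force(rng_seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  masks <- draw_view_masks(1L, M)
  apply_view <- function(keep) {
    v <- sample
    ends <- cumsum(dims)
    starts <- ends - dims + 1L
    for (m in which(keep == 0L)) v[starts[m]:ends[m]] <- 0
    v
  }
  list(view_a = apply_view(masks$a[1L, ]), view_b = apply_view(masks$b[1L, ]),
       mask_a = masks$a[1L, ], mask_b = masks$b[1L, ])
}

# All binary keep-masks of length M with >= 1 kept and >= 1 hidden omics.
proper_view_masks <- function(M) {
  grid <- as.matrix(expand.grid(rep(list(0:1), M)))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "double"
  grid[rowSums(grid) >= 1 & rowSums(grid) <= M - 1, , drop = FALSE]
}

# Draw n pairs of distinct keep-masks from the proper-mask pool (uses the
# caller's RNG stream).
draw_view_masks <- function(n, M) {
  pool <- proper_view_masks(M)
  a_idx <- sample(nrow(pool), n, replace = TRUE)
  b_idx <- vapply(a_idx, function(i) {
    sample(setdiff(seq_len(nrow(pool)), i), 1L)
  }, integer(1))
  list(a = pool[a_idx, , drop = FALSE], b = pool[b_idx, , drop = FALSE])
}

# Expand an n x M omics-level mask into an n x sum(dims) feature-level mask.
expand_omics_mask <- function(mask, dims) {
  mask <- as_mat(mask)
  do.call(cbind, lapply(seq_along(dims), function(m) {
    matrix(mask[, m], nrow(mask), dims[m])
  }))
}

cosine_sim <- function(a, b, eps = 1e-12) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < eps || nb < eps) stop("cosine similarity undefined for a ",
                                 "zero-norm vector")
  sum(a * b) / (na * nb)
}

#' NT-Xent loss of one ordered projection pair
#'
#' The normalized temperature-scaled cross-entropy term
#' `-log exp(cos(u_a, u_b)/tau) / sum_{u != u_a} exp(cos(u_a, u)/tau)`
#' where the sum runs over the whole projection pool excluding `u_a`
#' itself (the positive partner stays in the denominator). Asymmetric in
#' its arguments.
#'
#' @param u_a,u_b Projection vectors, both rows of `pool`.
#' @param pool Numeric matrix of all 2N batch projections (one per row).
#' @param tau Positive temperature.
#' @return Non-negative scalar loss.
#' @export
ntxent_pair_loss <- function(u_a, u_b, pool, tau) {
  stopifnot(tau > 0, nrow(pool) >= 4)
  row_match <- function(u) {
    hit <- which(apply(pool, 1L, function(r) isTRUE(all.equal(r, u,
      check.attributes = FALSE))))
    if (!length(hit)) stop("projection vector not found in the pool")
    hit[1L]
  }
  i <- row_match(u_a)
  sims <- apply(pool, 1L, function(r) cosine_sim(u_a, r))
  pos <- cosine_sim(u_a, u_b)
  denom <- sum(exp(sims[-i] / tau))
  -log(exp(pos / tau) / denom)
}

#' Instance-level contrastive loss over a complete-data batch
#'
#' Averages the two ordered NT-Xent terms of every positive pair:
#' `(1 / 2N) * sum_i [l(u'_i, u''_i) + l(u''_i, u'_i)]`.
#'
#' @param proj_a,proj_b N x d matrices of the two views' projections, rows
#'   aligned by sample.
#' @param tau Positive temperature.
#' @return Non-negative scalar loss.
#' @export
instance_contrastive_loss <- function(proj_a, proj_b, tau) {
  stopifnot(nrow(proj_a) == nrow(proj_b), tau > 0)
  n <- nrow(proj_a)
  if (n < 2) stop("at least 2 complete samples are required: a single ",
                  "pair has no negatives")
  ad_value(ntxent_loss_node(ad_input(proj_a), ad_input(proj_b), tau))[1L]
}

# Differentiable batched NT-Xent. Pool rows are [U_a; U_b], partner(i) is
# i +/- n; each row's denominator excludes only itself.
ntxent_loss_node <- function(ua, ub, tau, eps = 1e-12) {
  n <- nrow(ad_value(ua))
  U <- ad_rbind(list(ua, ub))
  norms <- ad_sqrt(ad_cadd(ad_rowsums(ad_square(U)), eps))
  Un <- ad_divcol(U, norms)
  S <- ad_scale(ad_matmul(Un, ad_t(Un)), 1 / tau)
  E <- ad_exp(S)
  eye <- diag(2 * n)
  denom <- ad_sub(ad_rowsums(E), ad_rowsums(ad_cmul(E, eye)))
  partner <- matrix(0, 2 * n, 2 * n)
  partner[cbind(seq_len(n), n + seq_len(n))] <- 1
  partner[cbind(n + seq_len(n), seq_len(n))] <- 1
  pos <- ad_rowsums(ad_cmul(S, partner))
  ad_mean(ad_sub(ad_log(denom), pos))
}

#' Impute one omics block from the available ones
#'
#' Encodes the mask-gated concatenation (unavailable blocks zeroed) and
#' applies the target omics' generator.
#'
#' @param learner A base learner (see [new_base_learner()]).
#' @param x Concatenated multi-omics vector or matrix (n x sum(d_m)).
#' @param mask Availability row(s): binary length-M vector or n x M matrix
#'   with at least one available omics per sample.
#' @param target_omics Index or name of the omics to generate.
#' @return Numeric matrix n x d_m of generated values in \[0, 1\].
#' @export
generate_omics <- function(learner, x, mask, target_omics) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  mask <- as_mat(mask)
  if (nrow(mask) == 1L && nrow(x) > 1L) {
    mask <- matrix(mask, nrow(x), ncol(mask), byrow = TRUE)
  }
  if (any(rowSums(mask) == 0)) {
    stop("sample(s) with no available omics carry no information to ",
         "impute from")
  }
  if (is.character(target_omics)) {
    target_omics <- match(target_omics, names(learner$input_dims))
  }
  gated <- x * expand_omics_mask(mask, learner$input_dims)
  z <- encode_node(learner$params$encoder, learner$config,
                   learner$input_dims, ad_input(gated), training = FALSE)
  out <- mlp_forward(learner$params$generators[[target_omics]], z,
                     activation = learner$config$activation,
                     out_activation = "sigmoid", training = FALSE)
  ad_value(out)
}

#' Masking-and-reconstruction generation loss
#'
#' Sum of the complete-data term (reconstruct all omics of view-masked
#' complete samples) and the incomplete-data term (availability-gated
#' reconstruction of observed omics only):
#' `L_generation = l_cp + l_inc`. Either batch may be empty, contributing 0.
#'
#' @param learner A base learner.
#' @param complete Matrix of fully observed concatenated samples (may have
#'   zero rows).
#' @param mar_masks Binary keep-matrix V (rows match `complete`): 0 hides an
#'   omics block from the encoder; reconstruction targets the original
#'   values.
#' @param incomplete Matrix of incomplete concatenated samples (may have
#'   zero rows); values inside unavailable blocks are ignored.
#' @param incomplete_mask Availability matrix Lambda for `incomplete`.
#' @return Non-negative scalar loss.
#' @export
generation_loss <- function(learner, complete, mar_masks = NULL,
                            incomplete = NULL, incomplete_mask = NULL) {
  n_cp <- if (is.null(complete)) 0L else nrow(complete)
  n_inc <- if (is.null(incomplete)) 0L else nrow(incomplete)
  if (n_cp == 0L && n_inc == 0L) {
    stop("both batches are empty: nothing to reconstruct")
  }
  node <- generation_loss_node(
    learner$params, learner$config, learner$input_dims,
    complete = if (n_cp) ad_input(complete) else NULL,
    mar_masks = mar_masks,
    incomplete = if (n_inc) ad_input(incomplete) else NULL,
    incomplete_mask = incomplete_mask, training = FALSE)
  ad_value(node)[1L]
}

# Differentiable Eq "l_cp + l_inc" shared by training and evaluation.
generation_loss_node <- function(params, config, dims, complete = NULL,
                                 mar_masks = NULL, incomplete = NULL,
                                 incomplete_mask = NULL, training = FALSE) {
  ends <- cumsum(dims)
  starts <- ends - dims + 1L
  per_sample_mse <- function(x_node, gate, omics_weight) {
    # x_node: inputs already gated for the encoder; reconstruction targets
    # are the raw x values. omics_weight: n x M multiplier per omics term.
    z <- encode_node(params$encoder, config, dims,
                     ad_cmul(x_node, expand_omics_mask(gate, dims)),
                     training = training)
    total <- NULL
    for (m in seq_along(dims)) {
      pred <- mlp_forward(params$generators[[m]], z,
                          activation = config$activation,
                          out_activation = "sigmoid", training = training)
      target <- ad_value(x_node)[, starts[m]:ends[m], drop = FALSE]
      err <- ad_square(ad_sub(pred, ad_input(target)))
      mse_m <- ad_scale(ad_rowsums(err), 1 / dims[m])
      mse_m <- ad_cmul(mse_m, matrix(omics_weight[, m], ncol = 1L))
      total <- if (is.null(total)) mse_m else ad_add(total, mse_m)
    }
    ad_scale(ad_sum(total), 1 / nrow(ad_value(x_node)))
  }
  loss <- NULL
  if (!is.null(complete)) {
    n <- nrow(ad_value(complete))
    V <- if (is.null(mar_masks)) matrix(1L, n, length(dims)) else
      as_mat(mar_masks)
    w <- if (config$mar_targets == "masked") 1 - V else
      matrix(1, n, length(dims))
    loss <- per_sample_mse(complete, V, w)
  }
  if (!is.null(incomplete)) {
    n <- nrow(ad_value(incomplete))
    Lam <- as_mat(incomplete_mask)
    stopifnot(nrow(Lam) == n)
    l_inc <- per_sample_mse(incomplete, Lam, Lam)
    loss <- if (is.null(loss)) l_inc else ad_add(loss, l_inc)
  }
  loss
}
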