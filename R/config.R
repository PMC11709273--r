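# Model and training configuration.

#' Configuration of the base learner
#'
#' Collects every tunable of the backbone: encoder and fusion dimensions,
#' imputation-head settings, loss trade-offs and optimization parameters.
#' Defaults follow the package's reference architecture; desk-scale
#' experiments typically shrink `hidden`, `d_e` and `d_h`.
#'
#' @param d_e Per-omics embedding dimension of the feature extractors.
#' @param d_h Dimension of the fused patient representation.
#' @param rank Number of low-rank factors R of the fusion tensor.
#' @param hidden Hidden width of the two-layer extractors and generators.
#' @param activation Smooth nonlinearity of the hidden layers (`"tanh"`).
#' @param dropout Dropout probability between extractor layers (training
#'   only).
#' @param proj_hidden,proj_dim Projection head architecture
#'   (`d_h -> proj_hidden -> proj_dim`) for the contrastive task.
#' @param tau Temperature of the normalized-temperature cross-entropy
#'   (NT-Xent) contrastive loss; must be positive.
#' @param lambda1,lambda2 Trade-off weights of the contrastive and
#'   generation losses in the total training loss (both default 1).
#' @param mar_rate Probability that a complete sample is view-masked in the
#'   masking-and-reconstruction task each batch.
#' @param mar_targets `"all"` reconstructs every omics of a masked sample
#'   (the reference behaviour); `"masked"` restricts the reconstruction loss
#'   to the masked blocks.
#' @param detach_imputed If `TRUE` (default) generator outputs are detached
#'   when imputing for diagnosis, so the diagnosis loss cannot reach the
#'   generators through the imputed values.
#' @param lr,batch_size,epochs Adam learning rate, mini-batch size and
#'   training epochs.
#' @return A named list of class `omix_config`.
#' @export
learner_config <- function(d_e = 64, d_h = 64, rank = 4, hidden = 256,
                           activation = "tanh", dropout = 0.2,
                           proj_hidden = 64, proj_dim = 32, tau = 0.5,
                           lambda1 = 1, lambda2 = 1, mar_rate = 0.5,
                           mar_targets = c("all", "masked"),
                           detach_imputed = TRUE, lr = 1e-3,
                           batch_size = 32, epochs = 200) {
  stopifnot(tau > 0, lambda1 >= 0, lambda2 >= 0, dropout >= 0, dropout < 1)
  structure(list(
    d_e = d_e, d_h = d_h, rank = rank, hidden = hidden,
    activation = activation, dropout = dropout, proj_hidden = proj_hidden,
    proj_dim = proj_dim, tau = tau, lambda1 = lambda1, lambda2 = lambda2,
    mar_rate = mar_rate, mar_targets = match.arg(mar_targets),
    detach_imputed = detach_imputed, lr = lr, batch_size = batch_size,
    epochs = epochs
  ), class = "omix_config")
}

#' Configuration of the meta learner
#'
#' @param ways,shots Episode shape: `ways`-way `shots`-shot support and
#'   query sets.
#' @param inner_rate Inner-loop (episode adaptation) learning rate alpha.
#' @param outer_rate Outer-loop (initialization update) learning rate beta.
#' @param inner_steps Gradient steps of the inner adaptation (default 1).
#' @param n_sub Episodes per outer step (the meta batch size).
#' @param n_outer Outer-loop iterations.
#' @param kde_grid Number of evaluation points of the per-dimension kernel
#'   density estimates in the category-level contrastive loss.
#' @param clip_norm Global L2 gradient-clipping norm of the inner and outer
#'   meta updates (plain SGD through the multiplicative fusion is otherwise
#'   prone to blow-ups).
#' @param literal_sign If `TRUE`, uses the raw divergence (rather than its
#'   negation) as the affinity inside the category-level contrastive
#'   softmax. The default `FALSE` aligns same-class distributions.
#' @param finetune_epochs Epochs of full fine-tuning on the target
#'   fine-tuning query set after meta-training.
#' @param finetune_lr Learning rate of the fine-tuning phase.
#' @return A named list of class `omix_meta_config`.
#' @export
meta_config <- function(ways = 4, shots = 10, inner_rate = 0.01,
                        outer_rate = 0.001, inner_steps = 1, n_sub = 4,
                        n_outer = 50, kde_grid = 512, clip_norm = 10,
                        literal_sign = FALSE,
                        finetune_epochs = 100, finetune_lr = 1e-3) {
  stopifnot(inner_rate >= 0, outer_rate >= 0, inner_steps >= 1, n_sub >= 1,
            clip_norm > 0)
  structure(list(
    ways = ways, shots = shots, inner_rate = inner_rate,
    outer_rate = outer_rate, inner_steps = inner_steps, n_sub = n_sub,
    n_outer = n_outer, kde_grid = kde_grid, clip_norm = clip_norm,
    literal_sign = literal_sign,
    finetune_epochs = finetune_epochs, finetune_lr = finetune_lr
  ), class = "omix_meta_config")
}
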