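# Shared patient feature encoder: omics-specific extractors followed by
# low-rank multimodal tensor fusion.
#
# Each omics vector x^m is embedded by a two-layer feedforward extractor,
# a constant 1 is appended (h_tilde = [h; 1], which preserves every omics'
# linear terms through the Hadamard product), and the fused representation is
#
#   z = sum_r Hadamard_m [ (w_r^m)' h_tilde^m ] + b
#
# which is exactly the contraction of the rank-R decomposed (M+1)-order
# tensor W = sum_r outer_m w_r^m with the outer product of the h_tilde^m,
# computed in factored form. The full tensor is never materialized outside
# the test oracle.

#' Construct a fusion encoder
#'
#' @param input_dims Named integer vector of per-omics feature counts, in
#'   block order.
#' @param config A [learner_config()]; `d_e`, `d_h`, `rank`, `hidden`,
#'   `activation` and `dropout` apply.
#' @param seed Integer seed of the variance-scaled parameter
#'   initialization.
#' @return An object of class `fusion_encoder` carrying the extractor and
#'   fusion parameters.
#' @export
new_fusion_encoder <- function(input_dims, config = learner_config(),
                               seed = 1) {
  force(input_dims); force(config); force(seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  params <- init_encoder_params(input_dims, config)
  structure(list(params = params, config = config, input_dims = input_dims,
                 seed = seed),
            class = "fusion_encoder")
}

init_encoder_params <- function(input_dims, config) {
  extractors <- lapply(input_dims, function(d) {
    init_mlp(d, config$hidden, config$d_e)
  })
  names(extractors) <- names(input_dims)
  factors <- lapply(input_dims, function(d) {
    lapply(seq_len(config$rank), function(r) {
      sd <- sqrt(2 / (config$d_e + 1 + config$d_h))
      ad_input(matrix(stats::rnorm((config$d_e + 1) * config$d_h, sd = sd),
                      config$d_e + 1, config$d_h), requires = TRUE)
    })
  })
  names(factors) <- names(input_dims)
  list(
    extractors = extractors,
    fusion = list(factors = factors,
                  bias = ad_input(matrix(0, 1L, config$d_h), requires = TRUE))
  )
}

#' Extract one omics' embedding
#'
#' Runs a single omics vector (or samples x d_m matrix) through its
#' feature extractor in evaluation mode (no dropout).
#'
#' @param encoder A [new_fusion_encoder()] or trained learner.
#' @param x Numeric vector of length d_m, or matrix with d_m columns.
#' @param omics_index Block index m.
#' @return Numeric matrix of embeddings (rows = samples, d_e columns).
#' @export
extract_omics_features <- function(encoder, x, omics_index) {
  enc <- encoder_params_of(encoder)
  d_m <- encoder$input_dims[omics_index]
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != d_m) {
    stop("omics ", omics_index, " expects vectors of length ", d_m,
         ", got ", ncol(x))
  }
  node <- mlp_forward(enc$extractors[[omics_index]], ad_input(x),
                      activation = encoder$config$activation,
                      training = FALSE)
  ad_value(node)
}

encoder_params_of <- function(obj) {
  if (!is.null(obj$params$extractors)) obj$params else obj$params$encoder
}

# Append the constant-1 channel: h_tilde = [h; 1].
augment_bias <- function(h) {
  if (inherits(h, "ad_node")) {
    ad_cbind(list(h, matrix(1, nrow(ad_value(h)), 1L)))
  } else {
    cbind(as_mat(h), 1)
  }
}

#' Low-rank multimodal fusion
#'
#' Fuses M bias-augmented embeddings through the factored tensor form: per
#' rank, the elementwise (Hadamard) product over omics of the projected
#' embeddings, summed over the R ranks, plus bias — identically the
#' contraction of the rank-decomposed fusion tensor with the outer product
#' of the embeddings. With a single omics the result degenerates to an
#' affine map.
#'
#' @param factors Either a `fusion_encoder` / trained learner, or a list
#'   with elements `factors` (per-omics lists of (d_e+1) x d_h matrices)
#'   and `bias` (length-d_h vector or 1 x d_h matrix).
#' @param embeddings List of M bias-augmented embedding matrices, each
#'   n x (d_e^m + 1) with the final column identically 1.
#' @return Numeric n x d_h matrix of fused representations.
#' @export
lmf_fuse <- function(factors, embeddings) {
  if (inherits(factors, c("fusion_encoder", "omix_learner"))) {
    factors <- encoder_params_of(factors)$fusion
  }
  if (length(embeddings) < 1) stop("at least one omics embedding required")
  node <- lmf_fuse_node(as_fusion_params(factors),
                        lapply(embeddings, as_node))
  ad_value(node)
}

as_fusion_params <- function(fusion) {
  fusion$factors <- lapply(fusion$factors, function(fl) lapply(fl, as_node))
  fusion$bias <- as_node(fusion$bias)
  fusion
}

# AD path shared by training and evaluation: per rank, the Hadamard
# product over omics of the projected embeddings; ranks are summed.
lmf_fuse_node <- function(fusion, embeddings) {
  M <- length(embeddings)
  R <- length(fusion$factors[[1]])
  acc <- NULL
  for (r in seq_len(R)) {
    prod_node <- NULL
    for (m in seq_len(M)) {
      term <- ad_matmul(embeddings[[m]], fusion$factors[[m]][[r]])
      prod_node <- if (is.null(prod_node)) term else
        ad_mul(prod_node, term)
    }
    acc <- if (is.null(acc)) prod_node else ad_add(acc, prod_node)
  }
  ad_add(acc, fusion$bias)
}

#' Encode patients into the fused representation
#'
#' Splits a concatenated multi-omics matrix by the recorded block
#' boundaries, embeds each block, bias-augments and fuses. Missing blocks
#' must already be zero-filled or imputed by the caller.
#'
#' @param encoder A [new_fusion_encoder()] or trained learner.
#' @param x Numeric vector of length sum(d_m) or matrix with sum(d_m)
#'   columns (concatenation in block order).
#' @return Numeric n x d_h matrix of representations z.
#' @export
encode_patient <- function(encoder, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  total <- sum(encoder$input_dims)
  if (ncol(x) != total) {
    stop("expected concatenated vectors of length ", total, ", got ",
         ncol(x))
  }
  node <- encode_node(encoder_params_of(encoder), encoder$config,
                      encoder$input_dims, ad_input(x), training = FALSE)
  ad_value(node)
}

# Batched AD forward of the whole encoder; `x` may be a node or matrix.
encode_node <- function(enc_params, config, input_dims, x,
                        training = FALSE) {
  x <- as_node(x)
  ends <- cumsum(input_dims)
  starts <- ends - input_dims + 1L
  embeddings <- vector("list", length(input_dims))
  for (m in seq_along(input_dims)) {
    xm <- ad_cols(x, starts[m]:ends[m])
    hm <- mlp_forward(enc_params$extractors[[m]], xm,
                      activation = config$activation,
                      dropout = config$dropout, training = training)
    embeddings[[m]] <- augment_bias(hm)
  }
  lmf_fuse_node(enc_params$fusion, embeddings)
}
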