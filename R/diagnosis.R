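# Subtype diagnosis: class-weighted cross-entropy on the fused
# representation of available-plus-imputed omics, and single-stage joint
# training of the whole backbone.
#
# The three losses are routed to disjoint sub-networks by construction of
# the computation graph: the contrastive loss reaches the encoder and
# projector, the generation loss the encoder and generators, and the
# diagnosis loss the encoder and classification head (imputed values are
# detached by default, so the diagnosis loss cannot leak into the
# generators).

#' Class weights for imbalanced subtype training
#'
#' `w_y = N_tr / (N_s * N_y)` for every subtype y: the number of training
#' samples over the number of subtypes times the subtype's count. Summed
#' over training samples the weights add up to `N_tr` exactly.
#'
#' @param labels Factor/character vector of training labels.
#' @param classes Label space; defaults to the levels present. Every class
#'   must occur in `labels`.
#' @return A tibble with columns `subtype`, `n` and `weight`.
#' @export
compute_class_weights <- function(labels, classes = NULL) {
  labels <- if (is.null(classes)) factor(labels) else
    factor(labels, levels = classes)
  if (anyNA(labels)) stop("labels outside the declared label space")
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("subtype(s) with no training samples: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  n_tr <- length(labels)
  n_s <- length(counts)
  tibble::tibble(
    subtype = names(counts),
    n = as.integer(counts),
    weight = n_tr / (n_s * as.integer(counts))
  )
}

#' Construct an untrained base learner
#'
#' Assembles the full backbone: fusion encoder, projection head, omics
#' generators and diagnosis head, with variance-scaled random
#' initialization.
#'
#' @param input_dims Named integer vector of per-omics feature counts.
#' @param classes Character vector of subtype labels.
#' @param config A [learner_config()].
#' @param seed Integer initialization seed.
#' @return An object of class `omix_learner`.
#' @export
new_base_learner <- function(input_dims, classes,
                             config = learner_config(), seed = 1) {
  stopifnot(length(classes) >= 2)
  force(input_dims); force(config); force(seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  params <- list(
    encoder = init_encoder_params(input_dims, config),
    projector = init_mlp(config$d_h, config$proj_hidden, config$proj_dim),
    generators = stats::setNames(lapply(input_dims, function(d) {
      init_mlp(config$d_h, config$hidden, d)
    }), names(input_dims)),
    head = init_linear(config$d_h, length(classes))
  )
  structure(list(params = params, config = config, input_dims = input_dims,
                 classes = as.character(classes), seed = seed, trace = NULL,
                 trained = FALSE),
            class = "omix_learner")
}

#' @export
print.omix_learner <- function(x, ...) {
  cat("<omix_learner> ", if (x$trained) "trained" else "untrained",
      "; omics: ", paste(names(x$input_dims), x$input_dims, sep = "=",
                         collapse = ", "),
      "; classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  cat("  d_e=", x$config$d_e, " d_h=", x$config$d_h, " rank=",
      x$config$rank, " hidden=", x$config$hidden, "\n", sep = "")
  invisible(x)
}

#' Encode with imputation of missing blocks
#'
#' `z = f_enc( (+)_m [ Lambda^m x^m + (1 - Lambda^m) xtilde^m ] )`: available
#' blocks pass through, missing blocks are replaced by generator output
#' computed from the available ones. For fully observed samples this is
#' identical to [encode_patient()].
#'
#' @param learner A base learner.
#' @param x Concatenated multi-omics vector or n x sum(d_m) matrix.
#' @param mask Availability vector/matrix (n x M).
#' @return Numeric n x d_h representation matrix.
#' @export
encode_with_imputation <- function(learner, x, mask) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  mask <- as_mat(mask)
  if (nrow(mask) == 1L && nrow(x) > 1L) {
    mask <- matrix(mask, nrow(x), ncol(mask), byrow = TRUE)
  }
  node <- encode_impute_node(learner$params, learner$config,
                             learner$input_dims, ad_input(x), mask,
                             training = FALSE,
                             detach = learner$config$detach_imputed)
  ad_value(node)
}

# Differentiable imputing encoder. Values stored inside unavailable blocks
# never reach the graph: the input is Lambda-gated before both the
# imputation pass and the final composition.
encode_impute_node <- function(params, config, dims, x, mask,
                               training = FALSE, detach = TRUE) {
  x <- as_node(x)
  mask <- as_mat(mask)
  if (any(rowSums(mask) == 0)) {
    stop("sample(s) with no available omics cannot be encoded")
  }
  fmask <- expand_omics_mask(mask, dims)
  gated <- ad_cmul(x, fmask)
  if (all(mask == 1)) {
    return(encode_node(params$encoder, config, dims, gated,
                       training = training))
  }
  z0 <- encode_node(params$encoder, config, dims, gated,
                    training = training)
  gen <- vector("list", length(dims))
  for (m in seq_along(dims)) {
    if (all(mask[, m] == 1)) next  # nothing to impute for this omics
    g <- mlp_forward(params$generators[[m]], z0,
                     activation = config$activation,
                     out_activation = "sigmoid", training = training)
    gen[[m]] <- if (detach) ad_detach(g) else g
  }
  ends <- cumsum(dims)
  starts <- ends - dims + 1L
  pieces <- vector("list", length(dims))
  for (m in seq_along(dims)) {
    xm <- ad_cols(gated, starts[m]:ends[m])
    if (is.null(gen[[m]])) {
      pieces[[m]] <- xm
    } else {
      inv <- matrix(1 - mask[, m], nrow(mask), dims[m])
      pieces[[m]] <- ad_add(xm, ad_cmul(gen[[m]], inv))
    }
  }
  encode_node(params$encoder, config, dims, ad_cbind(pieces),
              training = training)
}

#' Class-weighted diagnosis loss
#'
#' Mean over the batch of `w_{y_i} * CE(f_diag(z_i), y_i)` with z obtained
#' through the imputing encoder.
#'
#' @param learner A base learner.
#' @param x Concatenated sample matrix.
#' @param mask Availability matrix.
#' @param labels Factor/character labels within the learner's label space.
#' @param weights Optional [compute_class_weights()] tibble; computed from
#'   `labels` when omitted.
#' @return Non-negative scalar loss.
#' @export
diagnosis_loss <- function(learner, x, mask, labels, weights = NULL) {
  node <- diagnosis_loss_node(learner$params, learner$config,
                              learner$input_dims, learner$classes,
                              ad_input(as_mat(x)), as_mat(mask), labels,
                              weights, training = FALSE,
                              detach = learner$config$detach_imputed)
  ad_value(node)[1L]
}

diagnosis_loss_node <- function(params, config, dims, classes, x, mask,
                                labels, weights = NULL, training = FALSE,
                                detach = TRUE) {
  y <- match(as.character(labels), classes)
  if (anyNA(y)) {
    stop("label(s) outside the label space: ",
         paste(unique(as.character(labels)[is.na(y)]), collapse = ", "))
  }
  if (is.null(weights)) weights <- compute_class_weights(labels, classes)
  w <- weights$weight[match(as.character(labels), weights$subtype)]
  z <- encode_impute_node(params, config, dims, x, mask,
                          training = training, detach = detach)
  logits <- ad_add(ad_matmul(z, params$head$W), params$head$b)
  ad_weighted_ce(logits, y, w)
}

#' Total training loss of the base learner
#'
#' `L = lambda1 * L_contrastive + lambda2 * L_generation + L_diagnosis`,
#' each term computed by its module on the appropriate subset of the batch
#' (contrastive and the complete MAR term on fully observed samples, the
#' incomplete reconstruction term on the rest, diagnosis on everything).
#'
#' @param learner A base learner.
#' @param batch A labeled [multiomics_dataset()].
#' @param rng_seed Seed of the stochastic view and MAR masks.
#' @param weights Optional class-weight tibble.
#' @return Scalar loss; the three components are attached as the
#'   `"components"` attribute.
#' @export
base_loss <- function(learner, batch, rng_seed = 1, weights = NULL) {
  force(learner); force(batch); force(rng_seed); force(weights)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  out <- base_loss_node(learner$params, learner$config, learner$input_dims,
                        learner$classes, batch, weights = weights,
                        training = FALSE)
  total <- ad_value(out$total)[1L]
  attr(total, "components") <- vapply(out$components, function(n) {
    if (is.null(n)) 0 else ad_value(n)[1L]
  }, numeric(1))
  total
}

# Builds the loss graph for one batch; draws view and MAR masks from the
# caller's RNG stream.
base_loss_node <- function(params, config, dims, classes, batch,
                           weights = NULL, training = FALSE) {
  X <- concat_features(batch)
  mask <- batch$mask
  cp <- which(rowSums(mask) == ncol(mask))
  inc <- setdiff(seq_len(nrow(X)), cp)
  M <- length(dims)

  l_con <- NULL
  if (config$lambda1 > 0 && length(cp) >= 2 && M >= 2) {
    vm <- draw_view_masks(length(cp), M)
    Xcp <- X[cp, , drop = FALSE]
    xa <- Xcp * expand_omics_mask(vm$a, dims)
    xb <- Xcp * expand_omics_mask(vm$b, dims)
    za <- encode_node(params$encoder, config, dims, ad_input(xa),
                      training = training)
    zb <- encode_node(params$encoder, config, dims, ad_input(xb),
                      training = training)
    ua <- mlp_forward(params$projector, za, activation = config$activation,
                      training = training)
    ub <- mlp_forward(params$projector, zb, activation = config$activation,
                      training = training)
    l_con <- ntxent_loss_node(ua, ub, config$tau)
  }

  l_gen <- NULL
  if (config$lambda2 > 0 && (length(cp) > 0 || length(inc) > 0)) {
    V <- NULL
    if (length(cp) > 0) {
      V <- matrix(1L, length(cp), M)
      sel <- stats::runif(length(cp)) < config$mar_rate
      if (M >= 2 && any(sel)) {
        hide <- sample(M, sum(sel), replace = TRUE)
        V[cbind(which(sel), hide)] <- 0L
      }
    }
    l_gen <- generation_loss_node(
      params, config, dims,
      complete = if (length(cp)) ad_input(X[cp, , drop = FALSE]) else NULL,
      mar_masks = V,
      incomplete = if (length(inc)) ad_input(X[inc, , drop = FALSE]) else
        NULL,
      incomplete_mask = if (length(inc)) mask[inc, , drop = FALSE] else
        NULL,
      training = training)
  }

  l_diag <- diagnosis_loss_node(params, config, dims, classes,
                                ad_input(X), mask, batch$labels, weights,
                                training = training,
                                detach = config$detach_imputed)

  total <- l_diag
  if (!is.null(l_con)) total <- ad_add(total, ad_scale(l_con,
                                                       config$lambda1))
  if (!is.null(l_gen)) total <- ad_add(total, ad_scale(l_gen,
                                                       config$lambda2))
  list(total = total,
       components = list(contrastive = l_con, generation = l_gen,
                         diagnosis = l_diag))
}

#' Train the base learner
#'
#' Single-stage joint optimization (Adam) of the contrastive, generation
#' and diagnosis losses. Class weights are computed once from the full
#' training set. Deterministic given `seed`.
#'
#' @param train_set A labeled [multiomics_dataset()].
#' @param config A [learner_config()].
#' @param seed Integer seed controlling initialization, batching, view
#'   masks and dropout.
#' @param learner Optional pre-built learner to continue training.
#' @return A trained `omix_learner`; `$trace` holds the per-epoch loss
#'   tibble.
#' @export
train_base_learner <- function(train_set, config = learner_config(),
                               seed = 1, learner = NULL) {
  stopifnot(!is.null(train_set$labels))
  classes <- levels(train_set$labels)
  if (length(classes) < 2) stop("training requires at least 2 subtypes")
  if (is.null(learner)) {
    learner <- new_base_learner(block_dims(train_set), classes, config,
                                seed = seed)
  } else {
    config <- learner$config
  }
  weights <- compute_class_weights(train_set$labels, classes)
  force(seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(seed + 1L)
  n <- n_samples(train_set)
  opt <- adam_state(learner$params)
  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    comp_sum <- c(total = 0, contrastive = 0, generation = 0,
                  diagnosis = 0)
    for (b in batches) {
      batch <- subset_dataset(train_set, b)
      out <- base_loss_node(learner$params, config, learner$input_dims,
                            classes, batch, weights = weights,
                            training = TRUE)
      if (!is.finite(ad_value(out$total)[1L])) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      }
      grads <- ad_grad(out$total, learner$params)
      opt <- adam_step(learner$params, grads, opt, rate = config$lr)
      comp_sum <- comp_sum + c(
        ad_value(out$total)[1L],
        vapply(out$components, function(x) {
          if (is.null(x)) 0 else ad_value(x)[1L]
        }, numeric(1)))
    }
    trace[[epoch]] <- comp_sum / length(batches)
  }
  learner$trace <- dplyr::bind_rows(lapply(seq_along(trace), function(e) {
    tibble::tibble(epoch = e, loss = trace[[e]][["total"]],
                   contrastive = trace[[e]][["contrastive"]],
                   generation = trace[[e]][["generation"]],
                   diagnosis = trace[[e]][["diagnosis"]])
  }))
  learner$trained <- TRUE
  learner
}

#' Predict subtypes
#'
#' Returns per-sample softmax probabilities (summing to 1), sigmoid scores
#' (each in (0, 1), used by the integrated risk score) and the argmax
#' label. Out-of-range inputs trigger a warning and are clipped to
#' \[0, 1\].
#'
#' @param learner A trained base learner.
#' @param dataset A [multiomics_dataset()] preprocessed with the training
#'   statistics.
#' @return A tibble: `sample_id`, `.pred`, one `.prob_<class>` and one
#'   `.score_<class>` column per class.
#' @export
predict_subtypes <- function(learner, dataset) {
  X <- concat_features(dataset)
  if (any(X < -1e-8 | X > 1 + 1e-8)) {
    warning("input values outside [0, 1]; clipping — was the dataset ",
            "preprocessed with the training statistics?")
    X <- pmin(pmax(X, 0), 1)
  }
  z <- encode_with_imputation(learner, X, dataset$mask)
  logits <- z %*% ad_value(learner$params$head$W) +
    matrix(ad_value(learner$params$head$b), nrow(z),
           length(learner$classes), byrow = TRUE)
  E <- exp(logits - apply(logits, 1L, max))
  prob <- E / rowSums(E)
  score <- 1 / (1 + exp(-logits))
  colnames(prob) <- paste0(".prob_", learner$classes)
  colnames(score) <- paste0(".score_", learner$classes)
  tibble::tibble(
    sample_id = dataset$sample_ids,
    .pred = factor(learner$classes[max.col(prob, ties.method = "first")],
                   levels = learner$classes)
  ) |>
    dplyr::bind_cols(tibble::as_tibble(prob), tibble::as_tibble(score))
}
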