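# Shared fixtures, built in code. Heavyweight objects (a small trained
# learner) are created once per test run and memoized.

.fix <- new.env(parent = emptyenv())

# A small, easy synthetic dataset: 3 omics, 4 subtypes, high separation.
small_dataset <- function(seed = 11, n = 120, dims = c(12, 10, 8),
                          separation = 3, ...) {
  generate_multiomics_dataset(synthetic_spec(
    n_samples = n, dims = dims, n_subtypes = 4, latent_dim = 4,
    separation = separation, rng_seed = seed, ...))
}

small_config <- function(...) {
  base <- list(d_e = 6, d_h = 6, rank = 2, hidden = 12, proj_hidden = 8,
               proj_dim = 4, epochs = 5, batch_size = 32)
  do.call(learner_config, utils::modifyList(base, list(...)))
}

# An untrained learner matched to small_dataset().
small_learner <- function(seed = 3, dims = c(12, 10, 8), ...) {
  new_base_learner(
    stats::setNames(dims, paste0("omics", seq_along(dims))),
    paste0("subtype", 1:4), small_config(...), seed = seed)
}

# One trained learner shared across tests that only need "some trained
# model" (deterministic: fixed seeds).
trained_learner_fixture <- function() {
  if (is.null(.fix$trained)) {
    g <- small_dataset()
    cfg <- small_config(epochs = 30)
    .fix$trained_data <- g
    .fix$trained <- train_base_learner(g$dataset, cfg, seed = 5)
  }
  list(learner = .fix$trained, data = .fix$trained_data)
}

# Keep at most `cap` samples of each subtype.
subset_dataset_by_class_cap <- function(ds, cap) {
  keep <- unlist(lapply(split(seq_along(ds$labels), ds$labels),
                        function(i) i[seq_len(min(cap, length(i)))]))
  omixfuse:::subset_dataset(ds, sort(unname(keep)))
}

# Brute-force NT-Xent: explicit cosine table and softmax, the oracle the
# batched implementation is checked against.
brute_force_ntxent <- function(ua, ub, tau) {
  U <- rbind(ua, ub)
  n <- nrow(ua)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  S <- outer(seq_len(2 * n), seq_len(2 * n),
             Vectorize(function(i, j) cs(U[i, ], U[j, ])))
  partner <- c(n + seq_len(n), seq_len(n))
  total <- 0
  for (i in seq_len(2 * n)) {
    denom <- sum(exp(S[i, -i] / tau))
    total <- total - log(exp(S[i, partner[i]] / tau) / denom)
  }
  total / (2 * n)
}

# Explicit (M+1)-order tensor contraction oracle for the low-rank fusion:
# reconstruct W = sum_r outer_m w_r^m and contract with outer_m h_m.
brute_force_lmf <- function(factors, bias, embeddings) {
  R <- length(factors[[1]])
  M <- length(factors)
  d_h <- ncol(factors[[1]][[1]])
  z <- numeric(d_h)
  for (k in seq_len(d_h)) {
    # W_k = sum_r outer product over omics of the k-th factor columns
    acc <- 0
    for (r in seq_len(R)) {
      outer_prod <- 1
      for (m in seq_len(M)) {
        outer_prod <- outer(outer_prod, factors[[m]][[r]][, k])
      }
      acc <- acc + outer_prod
    }
    # contract with outer product of the embeddings
    h_outer <- 1
    for (m in seq_len(M)) h_outer <- outer(h_outer, embeddings[[m]])
    z[k] <- sum(acc * h_outer)
  }
  z + bias
}

# Finite-difference gradient of f (scalar-valued) wrt one ad_node parameter.
numeric_grad <- function(f, param, eps = 1e-6) {
  g <- array(0, dim(param$value))
  for (i in seq_along(param$value)) {
    orig <- param$value[i]
    param$value[i] <- orig + eps
    up <- f()
    param$value[i] <- orig - eps
    dn <- f()
    param$value[i] <- orig
    g[i] <- (up - dn) / (2 * eps)
  }
  g
}
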