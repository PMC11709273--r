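# Synthetic multi-omics generator.
#
# Emulates the statistical structure the model assumes: every subtype has a
# latent factor mean, each omics expresses the shared latent through its own
# random loading matrix onto an informative subset of features, Gaussian
# noise is added, and values are squashed into [0, 1]. Because all omics
# share the latent, missing blocks are reconstructible from the observed
# ones — exactly the property the imputation generators exploit. A shifted
# "target" variant displaces the latent means and perturbs the loadings to
# emulate cross-cohort distribution shift.

#' Specification for a synthetic multi-omics dataset
#'
#' @param n_samples Number of samples.
#' @param dims Integer vector of per-omics feature counts (length M).
#' @param n_subtypes Number of subtypes.
#' @param latent_dim Dimension of the shared latent factor.
#' @param separation Scale of between-subtype latent mean distance; 0 removes
#'   all class structure.
#' @param noise_sd Standard deviation of additive feature noise (on the
#'   pre-squash scale).
#' @param informative_frac Fraction of each omics' features loaded on the
#'   latent; the rest are pure noise.
#' @param missing_rate Fraction of samples degraded by block-wise
#'   missingness (one omics each), as in [simulate_missingness()].
#' @param shift Displacement of the target cohort in
#'   [generate_domain_shifted_pair()]; 0 = identical generative parameters.
#' @param rng_seed Integer seed; the whole generative process is
#'   deterministic given the spec.
#' @param omics_names Names of the M omics.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 200, dims = c(50, 50, 50),
                           n_subtypes = 4, latent_dim = 8, separation = 3,
                           noise_sd = 0.3, informative_frac = 0.6,
                           missing_rate = 0, shift = 0, rng_seed = 1,
                           omics_names = NULL) {
  stopifnot(separation >= 0, noise_sd >= 0, shift >= 0, all(dims >= 1),
            informative_frac > 0, informative_frac <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(omics_names)) {
    omics_names <- paste0("omics", seq_along(dims))
  }
  stopifnot(length(omics_names) == length(dims))
  structure(list(n_samples = n_samples, dims = dims,
                 n_subtypes = n_subtypes, latent_dim = latent_dim,
                 separation = separation, noise_sd = noise_sd,
                 informative_frac = informative_frac,
                 missing_rate = missing_rate, shift = shift,
                 rng_seed = rng_seed, omics_names = omics_names),
            class = "synthetic_spec")
}

# Draw the generative parameters (subtype means, loadings, informative ids)
# for one cohort.
.draw_generative_params <- function(spec) {
  K <- spec$n_subtypes
  L <- spec$latent_dim
  means <- matrix(stats::rnorm(K * L), K, L) * spec$separation
  loadings <- vector("list", length(spec$dims))
  informative <- vector("list", length(spec$dims))
  for (m in seq_along(spec$dims)) {
    d <- spec$dims[m]
    n_inf <- max(1L, floor(spec$informative_frac * d))
    informative[[m]] <- sort(sample(d, n_inf))
    W <- matrix(0, L, d)
    W[, informative[[m]]] <- stats::rnorm(L * n_inf, sd = 1 / sqrt(L))
    loadings[[m]] <- W
  }
  list(means = means, loadings = loadings, informative = informative)
}

# Displace a cohort's generative parameters by `shift`, preserving the
# overall spread of the subtype means (so the target task is not made
# easier or harder, only decorrelated from the external cohort) and
# perturbing the loadings proportionally on their support.
.shift_params <- function(spec, base) {
  if (spec$shift == 0) return(base)
  K <- nrow(base$means); L <- ncol(base$means)
  raw <- base$means + matrix(stats::rnorm(K * L), K, L) * spec$shift
  base_scale <- sqrt(mean(base$means^2))
  raw_scale <- sqrt(mean(raw^2))
  out <- base
  out$means <- if (raw_scale > 0) raw * (base_scale / raw_scale) else raw
  out$loadings <- lapply(base$loadings, function(W) {
    support <- W != 0
    pert <- W + matrix(stats::rnorm(length(W), sd = 0.1 * spec$shift),
                       nrow(W), ncol(W)) * support
    w_scale <- sqrt(mean(W[support]^2))
    p_scale <- sqrt(mean(pert[support]^2))
    if (p_scale > 0) pert * (w_scale / p_scale) else pert
  })
  out
}

.generate_from_params <- function(spec, params, id_prefix = "s",
                                  seed_offset = 0L) {
  N <- spec$n_samples
  K <- spec$n_subtypes
  y <- factor(paste0("subtype", rep_len(seq_len(K), N)),
              levels = paste0("subtype", seq_len(K)))
  Z <- params$means[as.integer(y), , drop = FALSE] +
    matrix(stats::rnorm(N * spec$latent_dim), N, spec$latent_dim)
  ids <- sprintf("%s%03d", id_prefix, seq_len(N))
  blocks <- vector("list", length(spec$dims))
  for (m in seq_along(spec$dims)) {
    X <- Z %*% params$loadings[[m]] +
      matrix(stats::rnorm(N * spec$dims[m], sd = spec$noise_sd), N,
             spec$dims[m])
    X <- 1 / (1 + exp(-X))  # smooth squash into (0, 1)
    dimnames(X) <- list(ids, sprintf("%s_f%03d", spec$omics_names[m],
                                     seq_len(spec$dims[m])))
    blocks[[m]] <- omics_block(X, spec$omics_names[m])
  }
  names(blocks) <- spec$omics_names
  names(y) <- ids
  ds <- multiomics_dataset(blocks, labels = y)
  if (spec$missing_rate > 0) {
    ds <- simulate_missingness(ds, spec$missing_rate,
                               rng_seed = spec$rng_seed + 7919L + seed_offset)
  }
  ds
}

#' Generate a synthetic multi-omics dataset with known subtype structure
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `dataset` (a [multiomics_dataset()]) and `truth` (the
#'   latent factors, loading matrices and informative feature ids used to
#'   generate it).
#' @export
generate_multiomics_dataset <- function(spec) {
  force(spec)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(spec$rng_seed)
  params <- .draw_generative_params(spec)
  ds <- .generate_from_params(spec, params)
  truth <- list(
    means = params$means,
    loadings = params$loadings,
    informative_ids = lapply(seq_along(spec$dims), function(m) {
      colnames(ds$blocks[[m]]$values)[params$informative[[m]]]
    })
  )
  names(truth$informative_ids) <- spec$omics_names
  list(dataset = ds, truth = truth)
}

#' Generate an external/target cohort pair with controllable shift
#'
#' Both cohorts share the subtype latent structure and label space; the
#' target cohort's latent means are displaced by `spec$shift` (with the
#' overall spread of the means preserved, so the displacement decorrelates
#' the cohorts without changing the target task's intrinsic difficulty)
#' and its loadings are perturbed proportionally on their support.
#' `shift = 0` reproduces identical generative parameters for both
#' cohorts.
#'
#' @param spec A [synthetic_spec()]; `shift` controls the displacement.
#' @return A list with `external` and `target` datasets plus their `truth`
#'   records.
#' @export
generate_domain_shifted_pair <- function(spec) {
  force(spec)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(spec$rng_seed)
  base <- .draw_generative_params(spec)
  target_params <- .shift_params(spec, base)
  external <- .generate_from_params(spec, base, id_prefix = "ext")
  target <- .generate_from_params(spec, target_params, id_prefix = "tgt",
                                  seed_offset = 101L)
  list(external = external, target = target,
       truth = list(external = base, target = target_params))
}
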