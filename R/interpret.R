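# Interpretation: permutation feature importance and the integrated
# prognostic risk score.

#' Permutation feature importance
#'
#' For every input feature, its column is shuffled across the test samples,
#' the class-weighted diagnosis loss is recomputed, and the increase over
#' the unpermuted baseline is recorded; the procedure is repeated
#' `repeats` times (default 10) with independent permutations and
#' averaged. With `per_subtype = TRUE` the test set is additionally
#' partitioned by true subtype, features are permuted within each
#' partition, and a per-subtype loss increase (plain cross-entropy within
#' the partition) is reported alongside.
#'
#' @param learner A trained base learner.
#' @param test_set A labeled [multiomics_dataset()].
#' @param repeats Number of random permutations per feature.
#' @param rng_seed Integer seed.
#' @param per_subtype Also compute within-subtype importances.
#' @return A tibble of class `omix_importance`: `omics`, `feature_id`,
#'   `mean_importance`, `repeat_1` .. `repeat_R`, and (with
#'   `per_subtype`) one `importance_<subtype>` column per class.
#' @export
permutation_importance <- function(learner, test_set, repeats = 10,
                                   rng_seed = 1, per_subtype = FALSE) {
  stopifnot(learner$trained, !is.null(test_set$labels))
  force(repeats); force(rng_seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  X <- concat_features(test_set)
  mask <- test_set$mask
  labels <- test_set$labels
  classes <- learner$classes
  weights <- compute_class_weights(labels, classes)
  dims <- learner$input_dims
  omics_of <- rep(names(dims), dims)
  feat_ids <- colnames(X)
  n_feat <- ncol(X)
  y <- match(as.character(labels), classes)

  loss_of <- function(Xmat) {
    z <- encode_with_imputation(learner, Xmat, mask)
    logits <- z %*% ad_value(learner$params$head$W) +
      matrix(ad_value(learner$params$head$b), nrow(z), length(classes),
             byrow = TRUE)
    E <- exp(logits - apply(logits, 1L, max))
    P <- E / rowSums(E)
    ll <- -log(P[cbind(seq_len(nrow(P)), y)])
    w <- weights$weight[match(as.character(labels), weights$subtype)]
    overall <- mean(w * ll)
    by_class <- vapply(classes, function(cl) {
      mean(ll[labels == cl])
    }, numeric(1))
    list(overall = overall, by_class = by_class)
  }

  parts <- if (per_subtype) split(seq_len(nrow(X)), labels) else
    list(all = seq_len(nrow(X)))
  base <- loss_of(X)
  inc <- matrix(0, n_feat, repeats)
  inc_cls <- if (per_subtype) {
    matrix(0, n_feat, length(classes), dimnames = list(NULL, classes))
  } else NULL
  for (r in seq_len(repeats)) {
    for (j in seq_len(n_feat)) {
      Xp <- X
      for (rows in parts) {
        Xp[rows, j] <- Xp[sample(rows), j]
      }
      perm <- loss_of(Xp)
      inc[j, r] <- perm$overall - base$overall
      if (per_subtype) {
        inc_cls[j, ] <- inc_cls[j, ] + (perm$by_class - base$by_class)
      }
    }
  }
  out <- tibble::tibble(
    omics = omics_of,
    feature_id = feat_ids,
    mean_importance = rowMeans(inc)
  )
  rep_cols <- tibble::as_tibble(inc, .name_repair = ~ paste0("repeat_",
                                                             seq_len(repeats)))
  out <- dplyr::bind_cols(out, rep_cols)
  if (per_subtype) {
    cls_cols <- tibble::as_tibble(inc_cls / repeats,
                                  .name_repair = ~ paste0("importance_",
                                                          classes))
    out <- dplyr::bind_cols(out, cls_cols)
  }
  class(out) <- c("omix_importance", class(out))
  out
}

#' Top-ranked features per omics
#'
#' @param importance An [permutation_importance()] table.
#' @param n Number of features per omics (ignored when `prop` is given).
#' @param prop Optional top fraction per omics (e.g. 0.1 for the top 10%).
#' @return The filtered importance tibble, ranked within omics.
#' @export
top_features <- function(importance, n = 10, prop = NULL) {
  importance |>
    dplyr::group_by(.data$omics) |>
    dplyr::arrange(dplyr::desc(.data$mean_importance), .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() <=
                    if (is.null(prop)) n else
                      max(1L, floor(prop * dplyr::n()))) |>
    dplyr::ungroup()
}

#' Integrated subtype risk score
#'
#' Aggregates the per-subtype sigmoid scores of the gastric cancer label
#' set into a prognostic risk summary:
#' `ICS_raw = CIN + (1 - MSI) + 2 * GS + (1 - EBV)`, `ICS = exp(ICS_raw)`.
#' MSI and EBV enter inverted (favourable prognosis), GS is double-weighted
#' (strongly unfavourable), CIN enters unchanged. ICS_raw lies in (0, 5)
#' and ICS in (1, e^5). For other label spaces supply `coefficients` and
#' `offsets` generalizing the linear combination
#' `ICS_raw = sum_c coefficients[c] * score_c + offsets[c]`.
#'
#' @param scores Data frame or matrix of per-patient sigmoid subtype
#'   scores, columns named by subtype, all values strictly inside (0, 1).
#'   Columns prefixed `.score_` (as produced by [predict_subtypes()]) are
#'   accepted. An optional `sample_id` column is carried through.
#' @param coefficients,offsets Named numeric vectors (one entry per score
#'   column) overriding the gastric defaults
#'   (CIN 1/0, MSI -1/1, GS 2/0, EBV -1/1).
#' @return A tibble of class `omix_ics`: the scores plus `ics_raw` and
#'   `ics`.
#' @export
integrated_subtype_score <- function(scores, coefficients = NULL,
                                     offsets = NULL) {
  scores <- tibble::as_tibble(scores)
  ids <- if ("sample_id" %in% names(scores)) scores$sample_id else NULL
  scores <- scores[, setdiff(names(scores), "sample_id"), drop = FALSE]
  names(scores) <- sub("^\\.score_", "", names(scores))
  smat <- as.matrix(scores)
  if (any(smat <= 0 | smat >= 1)) {
    stop("subtype scores must lie strictly inside (0, 1); softmax ",
         "probabilities are not accepted — use the sigmoid scores ",
         "(.score_* columns of predict_subtypes())")
  }
  if (is.null(coefficients)) {
    needed <- c("CIN", "MSI", "GS", "EBV")
    if (!all(needed %in% colnames(smat))) {
      stop("default coefficients are defined for the gastric subtype set ",
           "{CIN, MSI, GS, EBV}; supply `coefficients` and `offsets` for ",
           "other label spaces")
    }
    coefficients <- c(CIN = 1, MSI = -1, GS = 2, EBV = -1)
    offsets <- c(CIN = 0, MSI = 1, GS = 0, EBV = 1)
  }
  stopifnot(all(names(coefficients) %in% colnames(smat)),
            identical(sort(names(coefficients)), sort(names(offsets))))
  cls <- names(coefficients)
  raw <- as.vector(smat[, cls, drop = FALSE] %*% coefficients[cls] +
                     sum(offsets[cls]))
  out <- tibble::as_tibble(smat)
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                                             out)
  out$ics_raw <- raw
  out$ics <- exp(raw)
  class(out) <- c("omix_ics", class(out))
  out
}
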