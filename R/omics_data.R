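# Multi-omics data containers, preprocessing and masking.
#
# An `omics_block` is one modality's samples x features matrix (e.g. DNA
# methylation beta values, log-scaled miRNA/mRNA expression). A
# `multiomics_dataset` aligns M blocks on a shared sample index, carries a
# binary availability mask (1 = omics measured for that sample) and optional
# subtype labels. Missing blocks are stored as all-zero rows and flagged 0 in
# the mask, so downstream encoders can gate on the mask alone.

#' Construct an omics block
#'
#' @param values Numeric matrix, samples in rows; rownames are sample ids and
#'   colnames feature ids.
#' @param name Modality name (e.g. `"methylation"`, `"miRNA"`, `"mRNA"`).
#'   The name selects preprocessing conventions such as the default variance
#'   threshold.
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(values, name) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(name, "_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate sample identifier(s) in block '", name, "': ",
         paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate feature identifier(s) in block '", name, "': ",
         paste(dup, collapse = ", "))
  }
  structure(list(name = name, values = values), class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat("<omics_block> ", x$name, ": ", nrow(x$values), " samples x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

#' Load one omics matrix from delimited text
#'
#' Reads a CSV/TSV file with an identifier header and returns the block with
#' samples in rows regardless of how the file is oriented on disk. Empty
#' cells become `NA` (a sample whose whole row is `NA` is later treated as a
#' missing omics); any other non-numeric cell is a parse error reported with
#' its row and column.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma).
#' @param omics_name Modality name attached to the block.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @return An [omics_block()].
#' @export
load_omics_matrix <- function(path, omics_name,
                              orientation = c("samples_in_rows",
                                              "features_in_rows")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  ids <- as.character(raw[[1]])
  body <- as.data.frame(raw[, -1, drop = FALSE])
  num <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & is.na(parsed))
    if (length(bad)) {
      stop("non-numeric cell in ", path, " at row ", bad[1] + 1L,
           ", column ", j + 1L, ": '", cell[bad[1]], "'")
    }
    num[, j] <- parsed
  }
  if (orientation == "features_in_rows") num <- t(num)
  omics_block(num, omics_name)
}

#' Preprocess an omics block
#'
#' Applies the expression-data convention `x <- log2(x + 1)` when `do_log2`
#' (methylation beta values, already in \[0, 1\], skip it), then per-feature
#' min-max scaling to \[0, 1\]. At training time the min/max statistics are
#' computed from the block itself; at test time pass the training `fit_stats`
#' so the same affine map is reused, with values clipped into \[0, 1\].
#' Constant features map to 0.
#'
#' @param block An [omics_block()].
#' @param do_log2 Apply `log2(x + 1)` before scaling; requires non-negative
#'   values.
#' @param fit_stats Optional tibble (`feature_id`, `min`, `max`) from a
#'   previous call, to normalize held-out data with training statistics.
#' @return A list with elements `block` (the preprocessed block) and `stats`
#'   (a tibble of per-feature min/max usable as `fit_stats`).
#' @export
preprocess_omics <- function(block, do_log2 = FALSE, fit_stats = NULL) {
  v <- block$values
  if (do_log2) {
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative values in block '", block$name,
           "' are incompatible with the log2 transform")
    }
    v <- log2(v + 1)
  }
  if (is.null(fit_stats)) {
    mins <- apply(v, 2L, min, na.rm = TRUE)
    maxs <- apply(v, 2L, max, na.rm = TRUE)
    clip <- FALSE
  } else {
    stopifnot(all(colnames(v) %in% fit_stats$feature_id))
    idx <- match(colnames(v), fit_stats$feature_id)
    mins <- fit_stats$min[idx]
    maxs <- fit_stats$max[idx]
    clip <- TRUE
  }
  rng <- maxs - mins
  scaled <- sweep(v, 2L, mins, "-")
  ok <- rng > 0
  scaled[, ok] <- sweep(scaled[, ok, drop = FALSE], 2L, rng[ok], "/")
  scaled[, !ok] <- 0
  if (clip) scaled <- pmin(pmax(scaled, 0), 1)
  list(
    block = omics_block(scaled, block$name),
    stats = tibble::tibble(feature_id = colnames(v), min = unname(mins),
                           max = unname(maxs))
  )
}

# Variance thresholds used when none is supplied, keyed by modality name.
default_variance_thresholds <- c(methylation = 0.2, miRNA = 0.1, mRNA = 0.8)

#' Filter low-variance features
#'
#' Keeps features whose sample variance is at least `threshold`. Intended to
#' run after the log2 transform and before min-max normalization. When
#' `threshold` is omitted the modality-name default applies
#' (methylation 0.2, miRNA 0.1, mRNA 0.8).
#'
#' @param block An [omics_block()].
#' @param threshold Non-negative variance cutoff, or `NULL` for the default.
#' @return The filtered [omics_block()].
#' @export
variance_filter <- function(block, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- default_variance_thresholds[[block$name]]
    if (is.null(threshold)) {
      stop("no default variance threshold for omics '", block$name,
           "'; supply one explicitly")
    }
  }
  stopifnot(threshold >= 0)
  vars <- apply(block$values, 2L, stats::var, na.rm = TRUE)
  keep <- which(!is.na(vars) & vars >= threshold)
  if (!length(keep)) {
    stop("variance filter at threshold ", threshold, " removed every ",
         "feature of block '", block$name, "'; lower the threshold")
  }
  omics_block(block$values[, keep, drop = FALSE], block$name)
}

#' Build the sample x omics availability mask
#'
#' A sample's entry for omics m is 0 iff its entire row in block m is
#' missing (all `NA`, policy `"all_nan_row"`) or it is flagged 0 in a
#' user-supplied mask. Flagged rows are zero-filled in the blocks.
#'
#' @param blocks Named list of [omics_block()]s aligned on samples.
#' @param mask Optional explicit 0/1 matrix (samples x omics) overriding the
#'   all-NA detection.
#' @return A list `blocks` (zero-filled) and `mask` (binary matrix).
#' @export
build_missingness_mask <- function(blocks, mask = NULL) {
  ids <- rownames(blocks[[1]]$values)
  M <- length(blocks)
  out_mask <- matrix(1L, length(ids), M,
                     dimnames = list(ids, vapply(blocks, `[[`, "", "name")))
  for (m in seq_len(M)) {
    all_na <- apply(blocks[[m]]$values, 1L, function(r) all(is.na(r)))
    out_mask[all_na, m] <- 0L
  }
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    stopifnot(all(dim(mask) == dim(out_mask)))
    out_mask <- out_mask * (mask != 0)
    storage.mode(out_mask) <- "integer"
  }
  dead <- rowSums(out_mask) == 0
  if (any(dead)) {
    stop("sample(s) with no available omics: ",
         paste(ids[dead], collapse = ", "))
  }
  for (m in seq_len(M)) {
    v <- blocks[[m]]$values
    v[out_mask[, m] == 0L, ] <- 0
    v[is.na(v)] <- 0
    blocks[[m]]$values <- v
  }
  list(blocks = blocks, mask = out_mask)
}

#' Assemble a multi-omics dataset
#'
#' Aligns blocks on their shared sample index, derives (or accepts) the
#' availability mask, zero-fills missing blocks, and attaches subtype labels.
#'
#' @param blocks Named list of [omics_block()]s with identical sample sets.
#' @param labels Optional factor/character vector of subtype labels, named by
#'   sample id or in block row order.
#' @param mask Optional explicit availability matrix (see
#'   [build_missingness_mask()]).
#' @return An object of class `multiomics_dataset`.
#' @export
multiomics_dataset <- function(blocks, labels = NULL, mask = NULL) {
  stopifnot(length(blocks) >= 1)
  if (is.null(names(blocks))) {
    names(blocks) <- vapply(blocks, `[[`, "", "name")
  }
  ids <- rownames(blocks[[1]]$values)
  for (b in blocks) {
    if (!identical(sort(rownames(b$values)), sort(ids))) {
      stop("blocks do not share the same sample set")
    }
  }
  blocks <- lapply(blocks, function(b) {
    b$values <- b$values[ids, , drop = FALSE]
    b
  })
  built <- build_missingness_mask(blocks, mask)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[ids]
    stopifnot(length(labels) == length(ids))
    labels <- factor(labels)
    names(labels) <- ids
  }
  structure(list(blocks = built$blocks, mask = built$mask, labels = labels,
                 sample_ids = ids),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat("<multiomics_dataset> ", length(x$sample_ids), " samples, ",
      length(x$blocks), " omics (",
      paste(names(x$blocks), collapse = ", "), ")\n", sep = "")
  dims <- vapply(x$blocks, function(b) ncol(b$values), integer(1))
  cat("  features:", paste(dims, collapse = " + "), "\n")
  cat("  complete samples:", sum(rowSums(x$mask) == ncol(x$mask)), "\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  subtypes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

n_samples <- function(dataset) length(dataset$sample_ids)

block_dims <- function(dataset) {
  vapply(dataset$blocks, function(b) ncol(b$values), integer(1))
}

# Row indices of samples with every omics available.
complete_indices <- function(dataset) {
  which(rowSums(dataset$mask) == ncol(dataset$mask))
}

# Concatenated N x sum(d_m) matrix in block order (missing blocks are zero).
concat_features <- function(dataset) {
  do.call(cbind, lapply(dataset$blocks, function(b) b$values))
}

# Subset a dataset by sample indices, preserving class and alignment.
subset_dataset <- function(dataset, idx) {
  blocks <- lapply(dataset$blocks, function(b) {
    b$values <- b$values[idx, , drop = FALSE]
    b
  })
  structure(list(
    blocks = blocks,
    mask = dataset$mask[idx, , drop = FALSE],
    labels = if (is.null(dataset$labels)) NULL else dataset$labels[idx],
    sample_ids = dataset$sample_ids[idx]
  ), class = "multiomics_dataset")
}

#' Simulate block-wise omics missingness
#'
#' Emulates the evaluation protocol of incomplete-data experiments: from the
#' complete-data subset, `round(rate * N_cp)` samples are drawn uniformly at
#' random and for each one omics block (uniform, or `target_omics`) is zeroed
#' and flagged 0 in the mask. Every sample keeps at least one available
#' omics. Deterministic given `rng_seed`.
#'
#' @param dataset A [multiomics_dataset()].
#' @param rate Fraction in \[0, 1) of complete samples to degrade.
#' @param rng_seed Integer seed.
#' @param target_omics Optional modality name to mask instead of a random one.
#' @return The degraded [multiomics_dataset()].
#' @export
simulate_missingness <- function(dataset, rate, rng_seed,
                                 target_omics = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(dataset)
  M <- length(dataset$blocks)
  if (M < 2) {
    stop("cannot simulate missingness with a single omics: every sample ",
         "must keep at least one available block")
  }
  cp <- complete_indices(dataset)
  n_mask <- round(rate * length(cp))
  if (n_mask == 0) return(dataset)
  force(rng_seed); force(target_omics)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  chosen <- sample(cp, n_mask)
  if (!is.null(target_omics)) {
    m_idx <- rep(match(target_omics, names(dataset$blocks)), n_mask)
    if (anyNA(m_idx)) stop("unknown omics: ", target_omics)
  } else {
    m_idx <- sample(M, n_mask, replace = TRUE)
  }
  for (k in seq_len(n_mask)) {
    i <- chosen[k]; m <- m_idx[k]
    dataset$blocks[[m]]$values[i, ] <- 0
    dataset$mask[i, m] <- 0L
  }
  stopifnot(all(rowSums(dataset$mask) >= 1))
  dataset
}

#' Stratified train/test split
#'
#' Splits per subtype so both partitions contain every class in proportion,
#' which the class-weighted diagnosis loss presumes. Deterministic given
#' `rng_seed`.
#'
#' @param dataset A labeled [multiomics_dataset()].
#' @param test_fraction Fraction of each subtype assigned to the test set.
#' @param rng_seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
stratified_split <- function(dataset, test_fraction, rng_seed) {
  stopifnot(!is.null(dataset$labels), test_fraction > 0, test_fraction < 1)
  counts <- table(dataset$labels)
  if (any(counts < 2)) {
    stop("subtype(s) with fewer than 2 samples cannot be stratified: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  force(rng_seed)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(rng_seed)
  test_idx <- integer(0)
  for (cl in names(counts)) {
    rows <- which(dataset$labels == cl)
    n_test <- max(1L, round(test_fraction * length(rows)))
    test_idx <- c(test_idx, sample(rows, n_test))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n_samples(dataset)), test_idx)
  list(train = subset_dataset(dataset, train_idx),
       test = subset_dataset(dataset, test_idx))
}

#' Write / read a dataset directory
#'
#' One CSV per omics block (samples in rows), `mask.csv`, `labels.csv` and a
#' JSON manifest. Round-trips values, mask, labels and identifiers.
#'
#' @param dataset A [multiomics_dataset()].
#' @param dir Target directory (created if needed).
#' @param manifest Optional named list merged into the manifest JSON (e.g.
#'   preprocessing thresholds, min/max statistics, seeds).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, manifest = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in dataset$blocks) {
    df <- tibble::as_tibble(b$values, rownames = "sample_id")
    readr::write_csv(df, file.path(dir, paste0(b$name, ".csv")))
  }
  readr::write_csv(tibble::as_tibble(dataset$mask, rownames = "sample_id"),
                   file.path(dir, "mask.csv"))
  if (!is.null(dataset$labels)) {
    readr::write_csv(
      tibble::tibble(sample_id = dataset$sample_ids,
                     subtype = as.character(dataset$labels)),
      file.path(dir, "labels.csv"))
  }
  manifest$omics <- names(dataset$blocks)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  blocks <- lapply(manifest$omics, function(nm) {
    load_omics_matrix(file.path(dir, paste0(nm, ".csv")), nm)
  })
  names(blocks) <- manifest$omics
  mask_df <- readr::read_csv(file.path(dir, "mask.csv"),
                             col_types = readr::cols(), progress = FALSE)
  mask <- as.matrix(mask_df[, -1])
  rownames(mask) <- mask_df$sample_id
  labels <- NULL
  lab_path <- file.path(dir, "labels.csv")
  if (file.exists(lab_path)) {
    lab_df <- readr::read_csv(lab_path, col_types = readr::cols(),
                              progress = FALSE)
    labels <- stats::setNames(lab_df$subtype, lab_df$sample_id)
  }
  multiomics_dataset(blocks, labels = labels, mask = mask)
}

# RNG bookkeeping so seeded helpers do not disturb the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}
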