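#' Golden-ratio imputation level
#'
#' The reference operating point for the imputation level: the fraction
#' `2 - phi` of entries receive imputed values, where `phi = (1 + sqrt(5))/2`
#' is the golden ratio, giving the 38.2% imputed : 61.8% retained split.
#'
#' @return `2 - (1 + sqrt(5)) / 2`, approximately 0.382.
#' @export
golden_imputation_level <- function() 2 - (1 + sqrt(5)) / 2

#' Amplification configuration
#'
#' @param replication_factors Either a single positive integer K applied to
#'   every group, or a named vector mapping group label to its own K (used to
#'   balance strongly unequal group sizes; pattern-discovery tools work best
#'   when classes have comparable instance counts).
#' @param imputation_level Selection threshold r in `[0, 1]`: the probability
#'   that an entry of the replicated matrix is replaced by an imputed value,
#'   hence the expected imputed fraction. Defaults to the golden-ratio level
#'   `2 - phi` (0.382).
#' @param seed Integer seed; the whole amplification is a deterministic
#'   function of (dataset, config).
#' @param stats_scope `"global"` (feature ranges pooled over all subjects) or
#'   `"per_group"` (ranges recomputed within each group before imputing that
#'   group's rows).
#' @param keep_originals If `TRUE`, the untouched source rows are prepended to
#'   the amplified matrix (replicate index -1). By default they are not: the
#'   method masks the whole replicated matrix, so even the first replicate of
#'   a subject may receive imputed entries.
#' @param exact_fraction If `TRUE`, exactly `floor(r * n * m)` entries are
#'   masked via a random permutation instead of independent thresholding, so
#'   the realized imputed fraction is deterministic rather than binomial.
#' @param save_mask If `TRUE`, the amplified dataset retains the imputation
#'   mask for audit.
#' @return A list of class `amplify_config`.
#' @export
amplify_config <- function(replication_factors = 1L,
                           imputation_level = 0.382,
                           seed = 1L,
                           stats_scope = c("global", "per_group"),
                           keep_originals = FALSE,
                           exact_fraction = FALSE,
                           save_mask = FALSE) {
  stats_scope <- match.arg(stats_scope)
  if (imputation_level < 0 || imputation_level > 1) {
    stop("imputation_level must lie in [0, 1]", call. = FALSE)
  }
  if (any(replication_factors < 1) ||
      any(replication_factors != round(replication_factors))) {
    stop("replication factors must be positive integers", call. = FALSE)
  }
  structure(list(replication_factors = replication_factors,
                 imputation_level = imputation_level,
                 seed = as.integer(seed),
                 stats_scope = stats_scope,
                 keep_originals = keep_originals,
                 exact_fraction = exact_fraction,
                 save_mask = save_mask),
            class = "amplify_config")
}

#' Replicate subjects group-wise
#'
#' Each subject's row is repeated K times, where K is the replication factor
#' of the subject's group. Output rows are ordered by group, then subject,
#' then replicate index `0 .. K-1`, and carry full provenance.
#'
#' @param dataset An [omics_dataset()].
#' @param factors A single positive integer K for all groups, or a named
#'   vector mapping every group label in the dataset to its K.
#' @return A list with `values` (replicated matrix), `source_subject_id`,
#'   `replicate_index` and `group_labels`, each per output row.
#' @export
replicate_subjects <- function(dataset, factors) {
  validate_omics_dataset(dataset)
  groups <- unique(dataset$group_labels)
  if (is.null(names(factors))) {
    if (length(factors) != 1L) {
      stop("unnamed `factors` must be a single uniform K", call. = FALSE)
    }
    factors <- stats::setNames(rep(factors, length(groups)), groups)
  }
  unknown <- setdiff(groups, names(factors))
  if (length(unknown)) {
    stop("no replication factor for group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(factors < 1) || any(factors != round(factors))) {
    stop("replication factors must be positive integers", call. = FALSE)
  }
  row_order <- order(match(dataset$group_labels, groups))
  src_rows <- integer(0)
  rep_idx <- integer(0)
  for (i in row_order) {
    k <- factors[[dataset$group_labels[i]]]
    src_rows <- c(src_rows, rep(i, k))
    rep_idx <- c(rep_idx, seq_len(k) - 1L)
  }
  list(values = dataset$values[src_rows, , drop = FALSE],
       source_subject_id = dataset$subject_ids[src_rows],
       replicate_index = rep_idx,
       group_labels = dataset$group_labels[src_rows])
}

#' Allocate the imputation mask
#'
#' Draws a uniform random matrix of the requested shape in one batch and marks
#' every entry whose draw is strictly below the selection threshold with 1
#' ("use imputed value"); the rest keep 0 ("retain source value"). Because the
#' draws are uniform on `[0, 1)`, the expected fraction of ones equals the
#' threshold.
#'
#' @param n_rows,n_cols Matrix dimensions (non-negative integers).
#' @param threshold Selection threshold r in `[0, 1]`.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream
#'   (used internally so that one seed governs an entire amplification).
#' @param exact_fraction If `TRUE`, place exactly `floor(r * n_rows * n_cols)`
#'   ones at uniformly random positions instead of thresholding.
#' @return An integer 0/1 matrix of shape `n_rows` by `n_cols`.
#' @export
#' @examples
#' m <- allocate_mask(100, 100, threshold = 0.2, seed = 7)
#' mean(m)  # close to 0.2
allocate_mask <- function(n_rows, n_cols, threshold, seed = NULL,
                          exact_fraction = FALSE) {
  if (n_rows < 0 || n_cols < 0) stop("dimensions must be >= 0", call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_rows * n_cols
  if (exact_fraction) {
    mask <- matrix(0L, n_rows, n_cols)
    n_ones <- floor(threshold * n)
    if (n_ones > 0) mask[sample.int(n, n_ones)] <- 1L
    return(mask)
  }
  # row-major draw order: fill by row so entry (i, j) gets draw (i-1)*m + j
  u <- matrix(stats::runif(n), nrow = n_rows, byrow = TRUE)
  mask <- matrix(0L, n_rows, n_cols)
  mask[u < threshold] <- 1L
  mask
}

# Expand per-feature (or per group x feature) stats into full min/range
# matrices aligned with the replicated rows.
.stats_matrices <- function(stats, n_rows, feature_ids, group_labels = NULL) {
  scope <- attr(stats, "scope")
  if (is.null(scope)) scope <- if ("group" %in% names(stats)) "per_group" else "global"
  m <- length(feature_ids)
  if (scope == "global") {
    ord <- match(feature_ids, stats$feature_id)
    if (anyNA(ord)) stop("stats do not cover every feature", call. = FALSE)
    min_mat <- matrix(stats$min[ord], n_rows, m, byrow = TRUE)
    rng_mat <- matrix(stats$range[ord], n_rows, m, byrow = TRUE)
  } else {
    if (is.null(group_labels)) {
      stop("per-group stats require group labels", call. = FALSE)
    }
    min_mat <- matrix(NA_real_, n_rows, m)
    rng_mat <- matrix(NA_real_, n_rows, m)
    for (g in unique(group_labels)) {
      s <- stats[stats$group == g, , drop = FALSE]
      if (nrow(s) == 0L) stop("no stats for group ", g, call. = FALSE)
      ord <- match(feature_ids, s$feature_id)
      if (anyNA(ord)) stop("stats do not cover every feature", call. = FALSE)
      rows <- group_labels == g
      min_mat[rows, ] <- matrix(s$min[ord], sum(rows), m, byrow = TRUE)
      rng_mat[rows, ] <- matrix(s$range[ord], sum(rows), m, byrow = TRUE)
    }
  }
  list(min = min_mat, range = rng_mat)
}

#' Impute masked entries from each feature's observed range
#'
#' Computes an imputation value for every entry of the replicated matrix in
#' one batch — `min_j + u * range_j`, `u ~ U[0, 1)` — and applies it at
#' mask-1 positions only. Mask-0 entries are returned bit-identical to the
#' input. The batch computes values even where they are discarded: the
#' vectorized whole-matrix arithmetic is faster than conditional per-entry
#' work, which is the point of the mask formulation.
#'
#' @param replicated Numeric matrix (e.g. from [replicate_subjects()]).
#' @param mask 0/1 matrix of the same shape from [allocate_mask()].
#' @param stats A `column_stats` table from [compute_column_stats()] covering
#'   every column of `replicated` (matched by `feature_ids`).
#' @param feature_ids Character vector naming the columns of `replicated`.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @param group_labels Per-row group labels; required when `stats` were
#'   computed with `scope = "per_group"`.
#' @return Matrix of the same shape with imputed values at mask-1 positions.
#' @export
impute_masked <- function(replicated, mask, stats,
                          feature_ids = colnames(replicated),
                          seed = NULL, group_labels = NULL) {
  if (!identical(dim(replicated), dim(mask))) {
    stop("mask shape must equal matrix shape", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(replicated)
  sm <- .stats_matrices(stats, n, feature_ids, group_labels)
  u <- matrix(stats::runif(length(replicated)), nrow = n, byrow = TRUE)
  imputed <- sm$min + u * sm$range
  sel <- mask == 1L
  out <- replicated
  out[sel] <- imputed[sel]
  out
}

#' Amplify a multi-omics dataset
#'
#' The full pipeline: per-feature range statistics, group-wise replication,
#' batched random-mask allocation at the configured imputation level, and
#' uniform-within-range imputation at the masked entries. A single seeded
#' random stream drives the run (mask draws first, imputation draws second,
#' both in row-major order), so identical inputs give bit-identical output.
#'
#' @param dataset A preprocessed [omics_dataset()] (no missing flags; see
#'   [preprocess_dataset()]).
#' @param config An [amplify_config()].
#' @return An object of class `amplified_dataset`: a list with `values`
#'   (the amplified matrix), `source_subject_id`, `replicate_index`,
#'   `group_labels`, `feature_ids`, `feature_block`, `config`, the realized
#'   `imputed_fraction`, and `mask` when `config$save_mask` is `TRUE`.
#' @export
#' @examples
#' d <- generate_quadra_omics(synthetic_config(
#'   feature_counts = c(proteomics = 10, transcriptomics = 5,
#'                      metabolomics = 3, lipidomics = 2),
#'   n_planted = 2, missing_rate = 0, exception_rate = 0))$dataset
#' a <- amplify_dataset(d, amplify_config(replication_factors = 10,
#'                                        imputation_level = 0.4, seed = 1))
#' dim(a$values)  # 90 x 20
amplify_dataset <- function(dataset, config = amplify_config()) {
  validate_omics_dataset(dataset)
  if (any(dataset$missing)) {
    stop("dataset has missing flags; run preprocess_dataset() first",
         call. = FALSE)
  }
  stats <- compute_column_stats(dataset, scope = config$stats_scope)
  rep_out <- replicate_subjects(dataset, config$replication_factors)
  n <- nrow(rep_out$values)
  m <- ncol(rep_out$values)
  set.seed(config$seed)
  mask <- allocate_mask(n, m, config$imputation_level, seed = NULL,
                        exact_fraction = config$exact_fraction)
  values <- impute_masked(rep_out$values, mask, stats,
                          feature_ids = dataset$feature_ids, seed = NULL,
                          group_labels = rep_out$group_labels)
  src_id <- rep_out$source_subject_id
  rep_idx <- rep_out$replicate_index
  grp <- rep_out$group_labels
  if (config$keep_originals) {
    values <- rbind(dataset$values, values)
    src_id <- c(dataset$subject_ids, src_id)
    rep_idx <- c(rep(-1L, nrow(dataset$values)), rep_idx)
    grp <- c(dataset$group_labels, grp)
  }
  structure(
    list(values = values,
         source_subject_id = src_id,
         replicate_index = rep_idx,
         group_labels = grp,
         feature_ids = dataset$feature_ids,
         feature_block = dataset$feature_block,
         config = config,
         imputed_fraction = mean(mask),
         mask = if (config$save_mask) mask else NULL),
    class = "amplified_dataset")
}

#' @export
print.amplified_dataset <- function(x, ...) {
  cat(sprintf("amplified_dataset: %d virtual subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("imputation level r = %g; realized imputed fraction = %.5f\n",
              x$config$imputation_level, x$imputed_fraction))
  cat("groups: ",
      paste(sprintf("%s=%d", names(table(x$group_labels)),
                    table(x$group_labels)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
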