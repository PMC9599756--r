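#' Configuration for the synthetic quadra-omics generator
#'
#' Defaults emulate the structure of the study dataset the amplifier targets:
#' nine subjects in three groups (4 healthy, 3 at high risk, 2 new-onset) and
#' 2736 features across four omics blocks (2292 proteins, 328 miRNAs, 75
#' metabolites, 41 lipids), strictly positive abundances, and sporadic missing
#' values and abnormal entries.
#'
#' @param group_sizes Named vector of subjects per group.
#' @param feature_counts Named vector of features per omics block.
#' @param n_planted Number of differential features planted per contrast
#'   (high_risk vs healthy, and new_onset vs healthy; disjoint sets).
#' @param effect_size Log2 fold-change of planted features: the affected
#'   group's values are multiplied by `2^effect_size`.
#' @param meanlog,sdlog Log-normal abundance parameters, either scalars or
#'   named per omics block. Abundances are `rlnorm(meanlog_block, sdlog_block)`
#'   so they are strictly positive.
#' @param missing_rate Fraction of entries flagged missing (uniformly at
#'   random).
#' @param exception_rate Fraction of entries replaced by abnormal values
#'   (negative or infinite), drawn from entries not already missing.
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    group_sizes = c(healthy = 4L, high_risk = 3L, new_onset = 2L),
    feature_counts = c(proteomics = 2292L, transcriptomics = 328L,
                       metabolomics = 75L, lipidomics = 41L),
    n_planted = 50L,
    effect_size = 1,
    meanlog = 2,
    sdlog = 1,
    missing_rate = 0.01,
    exception_rate = 0.002,
    seed = 1L) {
  stopifnot(all(group_sizes >= 0), all(feature_counts >= 0),
            missing_rate >= 0, missing_rate <= 1,
            exception_rate >= 0, exception_rate <= 1,
            n_planted >= 0)
  structure(list(group_sizes = group_sizes,
                 feature_counts = feature_counts,
                 n_planted = as.integer(n_planted),
                 effect_size = effect_size,
                 meanlog = meanlog, sdlog = sdlog,
                 missing_rate = missing_rate,
                 exception_rate = exception_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.block_param <- function(p, blocks) {
  if (length(p) == 1L && is.null(names(p))) {
    return(stats::setNames(rep(p, length(blocks)), blocks))
  }
  if (!all(blocks %in% names(p))) {
    stop("per-block parameter must name every omics block", call. = FALSE)
  }
  p[blocks]
}

#' Generate a synthetic quadra-omics dataset with known ground truth
#'
#' Abundances are drawn i.i.d. log-normal per omics block, so all clean
#' values are strictly positive. For each of the two disease contrasts a
#' disjoint set of `n_planted` features is chosen and the affected group's
#' values for those features are multiplied by `2^effect_size`. Missing flags
#' and abnormal values (negative, or `Inf`) are then injected uniformly at
#' random at the configured rates, and every injected address is recorded so
#' preprocessing reports can be verified exactly.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{dataset}{A validated [omics_dataset()].}
#'     \item{truth}{A list of class `synthetic_truth` with `planted` (named
#'       list per contrast of feature ids), `log2_fc` (planted effect sizes),
#'       `missing_addresses` and `exception_addresses` (0-row-capable
#'       two-column matrices of row/col indices).}
#'   }
#' @export
#' @examples
#' g <- generate_quadra_omics(synthetic_config(seed = 7))
#' dim(g$dataset)            # 9 x 2736
#' table(g$dataset$feature_block)
generate_quadra_omics <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  groups <- names(config$group_sizes)
  blocks <- names(config$feature_counts)
  n <- sum(config$group_sizes)
  m <- sum(config$feature_counts)
  if (2L * config$n_planted > m) {
    stop("n_planted exceeds the number of available features", call. = FALSE)
  }
  group_labels <- rep(groups, config$group_sizes)
  subject_ids <- sprintf("S%02d", seq_len(n))
  feature_block <- rep(blocks, config$feature_counts)
  feature_ids <- unlist(lapply(blocks, function(b) {
    sprintf("%s_%04d", b, seq_len(config$feature_counts[[b]]))
  }), use.names = FALSE)
  ml <- .block_param(config$meanlog, blocks)
  sl <- .block_param(config$sdlog, blocks)
  values <- matrix(NA_real_, n, m)
  for (b in blocks) {
    cols <- feature_block == b
    values[, cols] <- stats::rlnorm(n * sum(cols), ml[[b]], sl[[b]])
  }
  # plant disjoint differential features for the two disease contrasts
  contrasts <- list(high_risk_vs_healthy = "high_risk",
                    new_onset_vs_healthy = "new_onset")
  contrasts <- contrasts[unlist(contrasts) %in% groups]
  planted <- list()
  log2_fc <- list()
  pool <- seq_len(m)
  for (cn in names(contrasts)) {
    sel <- sort(sample(pool, config$n_planted))
    pool <- setdiff(pool, sel)
    rows <- group_labels == contrasts[[cn]]
    values[rows, sel] <- values[rows, sel] * 2^config$effect_size
    planted[[cn]] <- feature_ids[sel]
    log2_fc[[cn]] <- rep(config$effect_size, length(sel))
  }
  # inject missingness, then exceptions at distinct addresses
  total <- n * m
  miss_idx <- sort(sample.int(total, round(config$missing_rate * total)))
  remaining <- setdiff(seq_len(total), miss_idx)
  exc_idx <- sort(sample(remaining, round(config$exception_rate * total)))
  missing <- matrix(FALSE, n, m)
  missing[miss_idx] <- TRUE
  values[miss_idx] <- NA_real_
  if (length(exc_idx)) {
    # half negated, half infinite: both impossible for abundances
    neg <- exc_idx[seq_along(exc_idx) %% 2L == 1L]
    inf <- setdiff(exc_idx, neg)
    values[neg] <- -abs(values[neg])
    values[inf] <- Inf
  }
  addr <- function(idx) {
    a <- cbind(row = (idx - 1L) %% n + 1L, col = (idx - 1L) %/% n + 1L)
    a[order(a[, 1], a[, 2]), , drop = FALSE]
  }
  dataset <- omics_dataset(values, subject_ids, group_labels, feature_ids,
                           feature_block, missing = missing)
  truth <- structure(list(planted = planted,
                          log2_fc = log2_fc,
                          missing_addresses = addr(miss_idx),
                          exception_addresses = addr(exc_idx)),
                     class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Serialize synthetic ground truth to JSON
#'
#' @param truth A `synthetic_truth` from [generate_quadra_omics()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(planted = truth$planted,
         log2_fc = truth$log2_fc,
         missing_addresses = unname(apply(truth$missing_addresses, 1,
                                          function(r) r - 1L,
                                          simplify = FALSE)),
         exception_addresses = unname(apply(truth$exception_addresses, 1,
                                            function(r) r - 1L,
                                            simplify = FALSE))),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
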