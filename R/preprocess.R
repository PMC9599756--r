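#' Per-feature distribution profile
#'
#' For every feature, computes the minimum, maximum, range, median and a
#' randomness score over its usable entries. Usable means neither flagged
#' missing nor equal to the exception sentinel 0 (abundances are strictly
#' positive, so 0 can only be a sentinel placed by [handle_exceptions()]).
#' The range drives the uniform imputation step; the randomness score records
#' whether a feature's values are concentrated on a few points or spread
#' evenly across its range.
#'
#' The randomness score is the Shannon entropy of a 32-bin equal-width
#' histogram over `[min, max]`, normalized by `log(32)`, so it lies in
#' `[0, 1]`; a constant feature scores 0 and a feature uniform over its range
#' scores close to 1.
#'
#' A feature whose usable entries are all sentinels gets
#' `min = max = median = 0` and `range = 0`, so any value imputed for it is 0
#' and remains trackable. A feature with no observed (non-missing) entries at
#' all is an error.
#'
#' @param dataset An [omics_dataset()].
#' @param scope `"global"` (default) pools all subjects; `"per_group"`
#'   computes one profile per subject group.
#' @return A `data.frame` with columns `feature_id`, `min`, `max`, `range`,
#'   `median`, `randomness`, `n_used` (and `group` when `scope = "per_group"`),
#'   of class `column_stats` with attribute `scope`.
#' @export
#' @examples
#' d <- omics_dataset(matrix(c(1, 2, 3, 5, 5, 5), ncol = 2),
#'                    subject_ids = c("a", "b", "c"),
#'                    group_labels = rep("g", 3),
#'                    feature_ids = c("F1", "F2"),
#'                    feature_block = rep("proteomics", 2))
#' compute_column_stats(d)
compute_column_stats <- function(dataset, scope = c("global", "per_group")) {
  scope <- match.arg(scope)
  validate_omics_dataset(dataset)
  if (scope == "global") {
    out <- .stats_for_rows(dataset, seq_len(nrow(dataset$values)))
  } else {
    groups <- unique(dataset$group_labels)
    out <- do.call(rbind, lapply(groups, function(g) {
      s <- .stats_for_rows(dataset, which(dataset$group_labels == g))
      s$group <- g
      s
    }))
  }
  class(out) <- c("column_stats", "data.frame")
  attr(out, "scope") <- scope
  out
}

.stats_for_rows <- function(dataset, rows) {
  v <- dataset$values[rows, , drop = FALSE]
  miss <- dataset$missing[rows, , drop = FALSE]
  m <- ncol(v)
  mins <- maxs <- meds <- rnds <- numeric(m)
  n_used <- integer(m)
  for (j in seq_len(m)) {
    col <- v[, j][!miss[, j]]
    if (length(col) == 0L) {
      stop("feature '", dataset$feature_ids[j],
           "' has no observed entries", call. = FALSE)
    }
    usable <- col[col != 0]   # drop exception sentinels
    if (length(usable) == 0L) {
      mins[j] <- maxs[j] <- meds[j] <- rnds[j] <- 0
      n_used[j] <- 0L
      next
    }
    mins[j] <- min(usable)
    maxs[j] <- max(usable)
    meds[j] <- stats::median(usable)
    rnds[j] <- .randomness(usable, mins[j], maxs[j])
    n_used[j] <- length(usable)
  }
  data.frame(feature_id = dataset$feature_ids,
             min = mins, max = maxs, range = maxs - mins,
             median = meds, randomness = rnds, n_used = n_used,
             stringsAsFactors = FALSE)
}

# Normalized Shannon entropy of a 32-bin equal-width histogram on [lo, hi].
.randomness <- function(x, lo, hi, n_bins = 32L) {
  if (hi <= lo) return(0)
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_bins)
}

.new_report <- function(missing_filled, exceptions_zeroed, feature_ids) {
  counts <- function(addr) {
    n <- integer(length(feature_ids))
    if (nrow(addr)) {
      t <- table(addr[, 2])
      n[as.integer(names(t))] <- as.integer(t)
    }
    n
  }
  structure(
    list(missing_filled = missing_filled,
         exceptions_zeroed = exceptions_zeroed,
         counts = data.frame(feature_id = feature_ids,
                             n_missing_filled = counts(missing_filled),
                             n_exceptions_zeroed = counts(exceptions_zeroed),
                             stringsAsFactors = FALSE)),
    class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess_report: %d missing filled, %d exceptions zeroed\n",
              nrow(x$missing_filled), nrow(x$exceptions_zeroed)))
  invisible(x)
}

#' Fill missing entries with the feature median
#'
#' Each flagged-missing entry is replaced by the median of that feature's
#' observed plausible values (positive and finite: sentinels and abnormal
#' entries are excluded so errors never leak into fills), and the missing
#' flag is cleared. Every filled address is recorded in the report.
#'
#' @param dataset An [omics_dataset()].
#' @return A list with elements `dataset` (no missing flags remain) and
#'   `report` (a `preprocess_report`).
#' @export
#' @examples
#' d <- omics_dataset(matrix(c(1, NA, 3), ncol = 1),
#'                    subject_ids = c("a", "b", "c"),
#'                    group_labels = rep("g", 3),
#'                    feature_ids = "F1", feature_block = "proteomics")
#' fill_missing(d)$dataset$values  # the NA becomes median(1, 3) = 2
fill_missing <- function(dataset) {
  validate_omics_dataset(dataset)
  v <- dataset$values
  miss <- dataset$missing
  filled <- which(miss, arr.ind = TRUE)
  dimnames(filled) <- list(NULL, c("row", "col"))
  for (j in unique(filled[, "col"])) {
    obs <- v[, j][!miss[, j]]
    if (length(obs) == 0L) {
      stop("feature '", dataset$feature_ids[j],
           "' has no observed values to define a median", call. = FALSE)
    }
    # median over plausible abundances only: sentinels and abnormal values
    # (non-positive, non-finite) must not leak into fills
    usable <- obs[obs > 0 & is.finite(obs)]
    v[miss[, j], j] <- if (length(usable)) stats::median(usable) else 0
  }
  out <- dataset
  out$values <- v
  out$missing <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  list(dataset = validate_omics_dataset(out),
       report = .new_report(filled,
                            matrix(integer(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col"))),
                            dataset$feature_ids))
}

#' Zero out abnormal entries
#'
#' Classifies an entry as abnormal when it is non-finite (`NaN`, `Inf`,
#' `-Inf`) or non-positive: analyte abundances cannot be zero or negative, so
#' such values can only be acquisition or preprocessing errors. Abnormal
#' entries are replaced by the sentinel 0, which downstream statistics and
#' imputation exclude, and which remains trackable in the amplified output
#' precisely because genuine abundances are never 0. Run after
#' [fill_missing()].
#'
#' @param dataset An [omics_dataset()] with no remaining missing flags.
#' @return A list with elements `dataset` and `report`.
#' @export
handle_exceptions <- function(dataset) {
  validate_omics_dataset(dataset)
  v <- dataset$values
  abnormal <- (!is.finite(v) | v <= 0) & !dataset$missing
  zeroed <- which(abnormal, arr.ind = TRUE)
  dimnames(zeroed) <- list(NULL, c("row", "col"))
  v[abnormal] <- 0
  out <- dataset
  out$values <- v
  list(dataset = validate_omics_dataset(out),
       report = .new_report(matrix(integer(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col"))),
                            zeroed, dataset$feature_ids))
}

#' Clean a dataset: median-fill missing entries, then zero exceptions
#'
#' Convenience pipeline running [fill_missing()] followed by
#' [handle_exceptions()], merging the two reports.
#'
#' @param dataset An [omics_dataset()].
#' @return A list with elements `dataset` and `report`.
#' @export
preprocess_dataset <- function(dataset) {
  a <- fill_missing(dataset)
  b <- handle_exceptions(a$dataset)
  list(dataset = b$dataset,
       report = .new_report(a$report$missing_filled,
                            b$report$exceptions_zeroed,
                            dataset$feature_ids))
}

#' Serialize a preprocess report to JSON
#'
#' Addresses are written as 0-based `[row, col]` pairs.
#'
#' @param report A `preprocess_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(report, path) {
  addr0 <- function(m) {
    if (nrow(m) == 0L) return(list())
    unname(lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]) - 1L))
  }
  jsonlite::write_json(
    list(missing_filled = addr0(report$missing_filled),
         exceptions_zeroed = addr0(report$exceptions_zeroed),
         counts = report$counts),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
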