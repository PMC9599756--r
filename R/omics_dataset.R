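#' Construct a multi-omics dataset
#'
#' The central container of the package: a numeric subject-by-analyte matrix
#' together with subject group labels, per-feature omics-block annotations and
#' an explicit per-entry missingness flag. Missingness is kept distinct from
#' the value 0 because abundances can never be exactly zero; the preprocessing
#' step reserves 0 as the sentinel for exception-handled entries.
#'
#' @param values Numeric matrix, one row per subject, one column per feature.
#'   Entries flagged missing must be `NA`.
#' @param subject_ids Character vector of unique subject identifiers, one per
#'   row.
#' @param group_labels Vector (coerced to character) of group labels, one per
#'   row, e.g. `"healthy"`, `"high_risk"`, `"new_onset"`.
#' @param feature_ids Character vector of unique feature identifiers, one per
#'   column.
#' @param feature_block Vector (coerced to character) of omics-block labels,
#'   one per column, e.g. `"proteomics"`, `"transcriptomics"`,
#'   `"metabolomics"`, `"lipidomics"`.
#' @param missing Optional logical matrix of the same shape flagging missing
#'   entries. Defaults to `is.na(values)`.
#'
#' @return An object of class `omics_dataset`: a list with elements `values`,
#'   `subject_ids`, `group_labels`, `feature_ids`, `feature_block`, `missing`.
#' @export
#' @examples
#' d <- omics_dataset(
#'   values = matrix(c(1, 2, 3, 4), nrow = 2,
#'                   dimnames = list(NULL, c("F1", "F2"))),
#'   subject_ids = c("s1", "s2"),
#'   group_labels = c("healthy", "high_risk"),
#'   feature_ids = c("F1", "F2"),
#'   feature_block = c("proteomics", "metabolomics")
#' )
#' dim(d)
omics_dataset <- function(values, subject_ids, group_labels, feature_ids,
                          feature_block, missing = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  # NA means missing; NaN is an abnormal *value* left to exception handling
  if (is.null(missing)) missing <- is.na(values) & !is.nan(values)
  dimnames(values) <- list(subject_ids, feature_ids)
  dimnames(missing) <- dimnames(values)
  x <- structure(
    list(
      values = values,
      subject_ids = as.character(subject_ids),
      group_labels = as.character(group_labels),
      feature_ids = as.character(feature_ids),
      feature_block = as.character(feature_block),
      missing = missing
    ),
    class = "omics_dataset"
  )
  validate_omics_dataset(x)
}

#' Validate an omics_dataset
#'
#' Checks the structural invariants: dimension agreement, identifier
#' uniqueness, and that no entry is simultaneously flagged missing and
#' carrying a finite value.
#'
#' @param x An `omics_dataset`.
#' @return `x`, invisibly-unchanged, if valid; otherwise an error.
#' @export
validate_omics_dataset <- function(x) {
  stopifnot(inherits(x, "omics_dataset"))
  v <- x$values
  if (!is.matrix(v) || !is.numeric(v)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(v) != length(x$subject_ids) || nrow(v) != length(x$group_labels)) {
    stop("row count must equal length(subject_ids) and length(group_labels)",
         call. = FALSE)
  }
  if (ncol(v) != length(x$feature_ids) || ncol(v) != length(x$feature_block)) {
    stop("column count must equal length(feature_ids) and length(feature_block)",
         call. = FALSE)
  }
  dup_s <- unique(x$subject_ids[duplicated(x$subject_ids)])
  if (length(dup_s)) {
    stop("duplicate subject_ids: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  dup_f <- unique(x$feature_ids[duplicated(x$feature_ids)])
  if (length(dup_f)) {
    stop("duplicate feature_ids: ", paste(dup_f, collapse = ", "),
         call. = FALSE)
  }
  if (!is.logical(x$missing) || !identical(dim(x$missing), dim(v))) {
    stop("`missing` must be a logical matrix with the same shape as `values`",
         call. = FALSE)
  }
  bad <- x$missing & is.finite(v)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "entry [%d, %d] is flagged missing but carries the finite value %g",
      idx[1], idx[2], v[idx[1], idx[2]]), call. = FALSE)
  }
  x
}

#' @export
dim.omics_dataset <- function(x) dim(x$values)

#' @export
print.omics_dataset <- function(x, ...) {
  cat(sprintf("omics_dataset: %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat("groups: ",
      paste(sprintf("%s=%d", names(table(x$group_labels)),
                    table(x$group_labels)), collapse = ", "), "\n", sep = "")
  cat("blocks: ",
      paste(sprintf("%s=%d", names(table(x$feature_block)),
                    table(x$feature_block)), collapse = ", "), "\n", sep = "")
  cat(sprintf("missing entries: %d\n", sum(x$missing)))
  invisible(x)
}

# 17 significant digits: lossless for IEEE doubles, so CSV round trips exactly.
.fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- NA_character_  # NaN survives as "NaN"
  out
}

#' Read a multi-omics dataset from disk
#'
#' Supported formats:
#' \describe{
#'   \item{csv_wide}{One subject per row; columns `subject_id`, `group`, then
#'     one column per feature. The literal token `NA` (case-sensitive) marks a
#'     missing entry. An optional sidecar CSV with columns `feature_id,block`
#'     supplies the omics-block annotation; without it every feature is
#'     assigned the block `"unknown"`.}
#'   \item{hdf5}{Layout written by [write_dataset()]: datasets `/values`,
#'     `/missing`, `/subject_ids`, `/group_labels`, `/feature_ids`,
#'     `/feature_block`. Requires the `rhdf5` package.}
#' }
#'
#' @param path Path to the file.
#' @param format `"csv_wide"` or `"hdf5"`.
#' @param block_sidecar Optional path to a feature-block sidecar CSV
#'   (`csv_wide` only).
#' @param na_token String marking missing entries in CSV. Default `"NA"`.
#' @return A validated [omics_dataset()].
#' @export
read_dataset <- function(path, format = c("csv_wide", "hdf5"),
                         block_sidecar = NULL, na_token = "NA") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    csv_wide = .read_csv_wide(path, block_sidecar, na_token),
    hdf5 = .read_hdf5(path)
  )
}

.read_csv_wide <- function(path, block_sidecar, na_token) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "subject_id" || header[2] != "group") {
    stop("wide CSV must start with columns subject_id, group", call. = FALSE)
  }
  feature_ids <- header[-(1:2)]
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup)) {
    stop("duplicate feature_ids in header: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  dt <- data.table::fread(path, sep = ",", header = TRUE, na.strings = NULL,
                          colClasses = list(character = seq_along(header)),
                          check.names = FALSE, data.table = TRUE)
  data.table::setnames(dt, header)
  subject_ids <- dt[["subject_id"]]
  group_labels <- dt[["group"]]
  n <- nrow(dt)
  m <- length(feature_ids)
  values <- matrix(NA_real_, n, m)
  missing <- matrix(FALSE, n, m)
  for (j in seq_len(m)) {
    raw <- dt[[j + 2L]]
    is_na <- raw == na_token
    num <- suppressWarnings(as.numeric(raw))
    # tokens allowed besides numbers: the NA token and IEEE specials
    bad <- !is_na & is.na(num) & !(raw %in% c("Inf", "-Inf", "NaN"))
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("cannot parse cell at row %d, column '%s': '%s'",
                   i, feature_ids[j], raw[i]), call. = FALSE)
    }
    num[is_na] <- NA_real_
    values[, j] <- num
    missing[, j] <- is_na
  }
  block <- rep("unknown", m)
  if (!is.null(block_sidecar)) {
    sc <- utils::read.csv(block_sidecar, stringsAsFactors = FALSE)
    block <- sc$block[match(feature_ids, sc$feature_id)]
    if (anyNA(block)) {
      stop("feature-block sidecar does not cover all features", call. = FALSE)
    }
  }
  omics_dataset(values, subject_ids, group_labels, feature_ids, block,
                missing = missing)
}

.require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("HDF5 support requires the 'rhdf5' package; use format = \"csv_wide\"",
         call. = FALSE)
  }
}

.read_hdf5 <- function(path) {
  .require_rhdf5()
  values <- rhdf5::h5read(path, "values")
  missing <- rhdf5::h5read(path, "missing") != 0L
  dim(missing) <- dim(values)
  values[missing] <- NA_real_
  x <- omics_dataset(
    values = values,
    subject_ids = as.character(rhdf5::h5read(path, "subject_ids")),
    group_labels = as.character(rhdf5::h5read(path, "group_labels")),
    feature_ids = as.character(rhdf5::h5read(path, "feature_ids")),
    feature_block = as.character(rhdf5::h5read(path, "feature_block")),
    missing = missing
  )
  rhdf5::h5closeAll()
  x
}

#' Write a multi-omics dataset to disk
#'
#' CSV output prints numeric values with 17 significant digits so that reading
#' the file back reproduces the doubles exactly; flagged-missing entries are
#' written as the NA token. HDF5 output is bit-exact on round trip.
#'
#' @param dataset An [omics_dataset()].
#' @param path Output file path.
#' @param format `"csv_wide"` or `"hdf5"`.
#' @param block_sidecar Optional path; when given (with `csv_wide`), a
#'   `feature_id,block` sidecar CSV is written there.
#' @param na_token String written at missing entries in CSV. Default `"NA"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("csv_wide", "hdf5"),
                          block_sidecar = NULL, na_token = "NA") {
  format <- match.arg(format)
  validate_omics_dataset(dataset)
  switch(format,
    csv_wide = .write_csv_wide(dataset, path, block_sidecar, na_token),
    hdf5 = .write_hdf5(dataset, path)
  )
  invisible(path)
}

.write_csv_wide <- function(dataset, path, block_sidecar, na_token) {
  v <- dataset$values
  cols <- c(
    list(subject_id = dataset$subject_ids, group = dataset$group_labels),
    lapply(seq_len(ncol(v)), function(j) {
      s <- .fmt_double(v[, j])
      s[dataset$missing[, j]] <- na_token
      s
    })
  )
  names(cols)[-(1:2)] <- dataset$feature_ids
  dt <- data.table::setDT(cols)
  data.table::fwrite(dt, path, sep = ",", quote = FALSE, na = na_token)
  if (!is.null(block_sidecar)) {
    utils::write.csv(
      data.frame(feature_id = dataset$feature_ids,
                 block = dataset$feature_block),
      block_sidecar, row.names = FALSE, quote = FALSE)
  }
}

.write_hdf5 <- function(dataset, path) {
  .require_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  v <- dataset$values
  v[dataset$missing] <- 0  # payload at missing slots is irrelevant; mask rules
  rhdf5::h5write(v, path, "values")
  rhdf5::h5write(matrix(as.integer(dataset$missing), nrow(v), ncol(v)),
                 path, "missing")
  rhdf5::h5write(dataset$subject_ids, path, "subject_ids")
  rhdf5::h5write(dataset$group_labels, path, "group_labels")
  rhdf5::h5write(dataset$feature_ids, path, "feature_ids")
  rhdf5::h5write(dataset$feature_block, path, "feature_block")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute("1.0", fid, "format_version")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
}
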