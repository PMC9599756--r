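#' @section Block storage:
#' Amplified matrices can be far larger than a single flat file should hold;
#' output is partitioned into fixed-instance-count blocks, 10,000 instances
#' per block by default, with all features of a subject kept in its block and
#' one imputation level per block set. CSV blocks are capped at 30 million
#' entries (e.g. 10,000 instances of 3,000 features); HDF5 blocks carry no
#' size cap. A JSON manifest records block order, row counts and checksums so
#' the set can be reassembled and verified.
#' @name storage
#' @keywords internal
NULL

.csv_entry_cap <- 30e6

.block_checksum <- function(path) unname(tools::md5sum(path))

#' Write an amplified dataset as a set of fixed-size blocks
#'
#' Rows are partitioned in order into blocks of `instances_per_block` rows
#' (the last block may be short; instances are never padded). Each block file
#' is self-describing: provenance columns (`source_subject_id`,
#' `replicate_index`, `group`) travel with the feature columns. A
#' `manifest.json` written alongside records the block files in order, their
#' row counts and MD5 checksums, the shared imputation level, and the feature
#' annotation needed to reassemble the dataset.
#'
#' @param amplified An `amplified_dataset` from [amplify_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` or `"hdf5"`. CSV refuses block sizes above the
#'   30-million-entry cap (`instances_per_block * n_features`); HDF5 has no
#'   cap.
#' @param instances_per_block Rows per block; default 10000.
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
write_blocks <- function(amplified, out_dir, format = c("csv", "hdf5"),
                         instances_per_block = 10000L) {
  format <- match.arg(format)
  stopifnot(inherits(amplified, "amplified_dataset"))
  if (instances_per_block < 1) {
    stop("instances_per_block must be >= 1", call. = FALSE)
  }
  m <- ncol(amplified$values)
  if (format == "csv" && instances_per_block * m > .csv_entry_cap) {
    stop(sprintf(paste0(
      "CSV blocks are limited to %s entries; %d instances x %d features = %s.",
      " Choose instances_per_block <= %d or use format = \"hdf5\"."),
      format(.csv_entry_cap, big.mark = ",", scientific = FALSE),
      instances_per_block, m,
      format(instances_per_block * m, big.mark = ",", scientific = FALSE),
      floor(.csv_entry_cap / m)), call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- nrow(amplified$values)
  n_blocks <- max(1L, ceiling(n / instances_per_block))
  ext <- if (format == "csv") "csv" else "h5"
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- seq.int((b - 1L) * instances_per_block + 1L,
                    min(b * instances_per_block, n))
    file <- sprintf("block_%05d.%s", b, ext)
    path <- file.path(out_dir, file)
    if (format == "csv") {
      .write_block_csv(amplified, rows, path)
    } else {
      .write_block_hdf5(amplified, rows, path)
    }
    blocks[[b]] <- list(file = file, n_rows = length(rows),
                        checksum = .block_checksum(path))
  }
  manifest <- list(
    manifest_version = "1.0",
    format = format,
    instances_per_block = as.integer(instances_per_block),
    imputation_level = amplified$config$imputation_level,
    seed = amplified$config$seed,
    total_instances = n,
    total_features = m,
    feature_ids = amplified$feature_ids,
    feature_block = amplified$feature_block,
    blocks = blocks
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.write_block_csv <- function(amplified, rows, path) {
  v <- amplified$values[rows, , drop = FALSE]
  cols <- c(
    list(source_subject_id = amplified$source_subject_id[rows],
         replicate_index = amplified$replicate_index[rows],
         group = amplified$group_labels[rows]),
    lapply(seq_len(ncol(v)), function(j) .fmt_double(v[, j]))
  )
  names(cols)[-(1:3)] <- amplified$feature_ids
  data.table::fwrite(data.table::setDT(cols), path, sep = ",", quote = FALSE)
}

.write_block_hdf5 <- function(amplified, rows, path) {
  .require_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(amplified$values[rows, , drop = FALSE], path, "values")
  rhdf5::h5createGroup(path, "provenance")
  rhdf5::h5write(amplified$source_subject_id[rows], path,
                 "provenance/source_subject_id")
  rhdf5::h5write(as.integer(amplified$replicate_index[rows]), path,
                 "provenance/replicate_index")
  rhdf5::h5write(amplified$group_labels[rows], path, "provenance/group")
  rhdf5::h5closeAll()
}

#' Read a block set back into one amplified dataset
#'
#' Verifies that every block file listed in the manifest exists and matches
#' its recorded checksum, then concatenates the blocks in manifest order.
#'
#' @param manifest_path Path to a `manifest.json` written by [write_blocks()].
#' @return An `amplified_dataset` (its `config` reduced to the imputation
#'   level and seed recorded in the manifest).
#' @export
read_blocks <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  paths <- file.path(dir, man$blocks$file)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing block file(s): ",
         paste(man$blocks$file[missing], collapse = ", "), call. = FALSE)
  }
  sums <- vapply(paths, .block_checksum, character(1))
  bad <- sums != man$blocks$checksum
  if (any(bad)) {
    stop("checksum mismatch for block(s): ",
         paste(man$blocks$file[bad], collapse = ", "), call. = FALSE)
  }
  parts <- lapply(paths, function(p) {
    if (man$format == "csv") .read_block_csv(p, man) else .read_block_hdf5(p)
  })
  values <- do.call(rbind, lapply(parts, `[[`, "values"))
  colnames(values) <- man$feature_ids
  structure(
    list(values = values,
         source_subject_id = unlist(lapply(parts, `[[`, "source_subject_id")),
         replicate_index = unlist(lapply(parts, `[[`, "replicate_index")),
         group_labels = unlist(lapply(parts, `[[`, "group_labels")),
         feature_ids = man$feature_ids,
         feature_block = man$feature_block,
         config = amplify_config(imputation_level = man$imputation_level,
                                 seed = man$seed),
         imputed_fraction = NA_real_,
         mask = NULL),
    class = "amplified_dataset")
}

.read_block_csv <- function(path, man) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  feat <- as.matrix(dt[, man$feature_ids, drop = FALSE])
  storage.mode(feat) <- "double"
  list(values = feat,
       source_subject_id = as.character(dt$source_subject_id),
       replicate_index = as.integer(dt$replicate_index),
       group_labels = as.character(dt$group))
}

.read_block_hdf5 <- function(path) {
  .require_rhdf5()
  out <- list(
    values = rhdf5::h5read(path, "values"),
    source_subject_id = as.character(
      rhdf5::h5read(path, "provenance/source_subject_id")),
    replicate_index = as.integer(
      rhdf5::h5read(path, "provenance/replicate_index")),
    group_labels = as.character(rhdf5::h5read(path, "provenance/group")))
  rhdf5::h5closeAll()
  out
}
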