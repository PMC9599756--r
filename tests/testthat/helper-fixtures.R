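# Small fixtures built in code; no files on disk.

tiny_dataset <- function(values = matrix(c(1, 2, 3, 4, 5, 6), nrow = 3),
                         groups = c("g1", "g1", "g2"),
                         blocks = NULL) {
  m <- ncol(values)
  omics_dataset(
    values = values,
    subject_ids = sprintf("s%d", seq_len(nrow(values))),
    group_labels = groups,
    feature_ids = sprintf("F%d", seq_len(m)),
    feature_block = if (is.null(blocks)) rep("proteomics", m) else blocks
  )
}

# a scaled-down generator config used across tests (fast but realistic shape)
small_config <- function(missing_rate = 0, exception_rate = 0, ...) {
  synthetic_config(
    feature_counts = c(proteomics = 30, transcriptomics = 10,
                       metabolomics = 6, lipidomics = 4),
    n_planted = 5, missing_rate = missing_rate,
    exception_rate = exception_rate, ...)
}

# independent oracle for the randomness score: histogram entropy via cut()
oracle_entropy32 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(0)
  f <- cut(x, breaks = seq(lo, hi, length.out = 33), include.lowest = TRUE)
  p <- as.vector(table(f)) / length(x)
  p <- p[p > 0]
  -sum(p * log(p)) / log(32)
}

# independent brute-force BH step-up: largest k with p_(k) <= k/m * alpha
oracle_bh_calls <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= seq_len(m) / m * alpha)
  calls <- logical(m)
  if (length(ok)) calls[o[seq_len(max(ok))]] <- TRUE
  calls
}
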