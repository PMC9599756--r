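test_that("replication repeats each subject by its group factor with provenance", {
  d <- generate_quadra_omics(small_config(seed = 2))$dataset
  r <- replicate_subjects(d, 10)
  expect_equal(nrow(r$values), 90)
  expect_equal(unname(table(r$group_labels)[c("healthy", "high_risk", "new_onset")]),
               c(40, 30, 20), ignore_attr = TRUE)
  # provenance pairs unique, replicate indices 0..K-1 per subject
  expect_false(any(duplicated(paste(r$source_subject_id, r$replicate_index))))
  expect_equal(sort(unique(r$replicate_index)), 0:9)
  # K = 1 is the identity on values
  r1 <- replicate_subjects(d, 1)
  expect_equal(r1$values[order(match(r1$source_subject_id, d$subject_ids)), ],
               d$values, ignore_attr = TRUE)
  expect_true(all(r1$replicate_index == 0))
})

test_that("per-group replication factors give sum(n_g * K_g) rows", {
  d <- tiny_dataset(values = matrix(1:6, nrow = 3),
                    groups = c("A", "A", "B"))
  r <- replicate_subjects(d, c(A = 2, B = 3))
  expect_equal(nrow(r$values), 2 * 2 + 1 * 3)
  expect_error(replicate_subjects(d, c(A = 2)), "group.*B")
  expect_error(replicate_subjects(d, c(A = 0, B = 1)), "positive")
})

test_that("mask allocation hits the degenerate thresholds exactly", {
  expect_true(all(allocate_mask(20, 30, 0, seed = 1) == 0))
  expect_true(all(allocate_mask(20, 30, 1, seed = 1) == 1))
  expect_error(allocate_mask(-1, 5, 0.5, seed = 1), ">= 0")
  expect_error(allocate_mask(5, 5, 1.5, seed = 1), "\\[0, 1\\]")
})

test_that("mask fraction at threshold 0.2 is binomial around 20%", {
  mask <- allocate_mask(1000, 1000, 0.2, seed = 77)
  frac <- mean(mask)
  tol <- 4 * sqrt(0.2 * 0.8 / 1e6)
  expect_lt(abs(frac - 0.2), tol)
})

test_that("exact-fraction mode places exactly floor(r*n*m) ones", {
  mask <- allocate_mask(100, 40, 0.382, seed = 5, exact_fraction = TRUE)
  expect_equal(sum(mask), floor(0.382 * 4000))
})

test_that("imputation preserves mask-0 entries bit-exactly and fills in range", {
  g <- generate_quadra_omics(small_config(seed = 4))
  d <- preprocess_dataset(g$dataset)$dataset
  stats <- compute_column_stats(d)
  r <- replicate_subjects(d, 20)
  mask <- allocate_mask(nrow(r$values), ncol(r$values), 0.4, seed = 9)
  out <- impute_masked(r$values, mask, stats, feature_ids = d$feature_ids,
                       seed = 10)
  sel <- mask == 1
  expect_identical(out[!sel], r$values[!sel])
  lo <- matrix(stats$min, nrow(out), ncol(out), byrow = TRUE)
  hi <- matrix(stats$max, nrow(out), ncol(out), byrow = TRUE)
  expect_true(all(out[sel] >= lo[sel] & out[sel] <= hi[sel]))
})

test_that("all-zero mask is the identity; constant features impute to the constant", {
  v <- cbind(c(2, 4), c(7, 7))
  d <- tiny_dataset(values = v, groups = c("g", "g"))
  stats <- compute_column_stats(d)
  r <- replicate_subjects(d, 5)
  zero <- matrix(0L, 10, 2)
  expect_identical(impute_masked(r$values, zero, stats,
                                 feature_ids = d$feature_ids, seed = 1),
                   r$values)
  one <- matrix(1L, 10, 2)
  out <- impute_masked(r$values, one, stats, feature_ids = d$feature_ids,
                       seed = 1)
  expect_true(all(out[, 2] == 7))  # range 0 => min + u*0
  expect_error(impute_masked(r$values, matrix(0L, 3, 2), stats,
                             feature_ids = d$feature_ids), "shape")
})

test_that("imputed values match U[min, max) moments on a known feature", {
  # feature with min 10, max 20: 1e5 imputed draws; mean 15 +/- 4 sd of mean
  d <- tiny_dataset(values = matrix(c(10, 20), ncol = 1),
                    groups = c("g", "g"))
  stats <- compute_column_stats(d)
  r <- replicate_subjects(d, 50000)
  mask <- matrix(1L, 1e5, 1)
  out <- impute_masked(r$values, mask, stats, feature_ids = d$feature_ids,
                       seed = 123)
  expect_true(all(out >= 10 & out < 20))
  tol <- 4 * (10 / sqrt(12)) / sqrt(1e5)
  expect_lt(abs(mean(out) - 15), tol)
})

test_that("imputed-only values are Kolmogorov-Smirnov uniform over the range", {
  d <- tiny_dataset(values = matrix(c(10, 20), ncol = 1),
                    groups = c("g", "g"))
  stats <- compute_column_stats(d)
  r <- replicate_subjects(d, 50000)
  out <- impute_masked(r$values, matrix(1L, 1e5, 1), stats,
                       feature_ids = d$feature_ids, seed = 31)
  ks <- suppressWarnings(stats::ks.test(out[, 1], "punif", 10, 20))
  expect_gt(ks$p.value, 0.001)
})

test_that("amplification is a deterministic function of dataset and config", {
  g <- generate_quadra_omics(small_config(seed = 6))
  d <- preprocess_dataset(g$dataset)$dataset
  cfg <- amplify_config(replication_factors = 50, imputation_level = 0.382,
                        seed = 99, save_mask = TRUE)
  a1 <- amplify_dataset(d, cfg)
  a2 <- amplify_dataset(d, cfg)
  expect_identical(a1$values, a2$values)
  expect_identical(a1$mask, a2$mask)
  a3 <- amplify_dataset(d, amplify_config(replication_factors = 50,
                                          imputation_level = 0.382,
                                          seed = 100))
  expect_false(identical(a1$values, a3$values))
})

test_that("amplified output conserves source values at mask-0 positions", {
  g <- generate_quadra_omics(small_config(seed = 13))
  d <- preprocess_dataset(g$dataset)$dataset
  a <- amplify_dataset(d, amplify_config(replication_factors = 30,
                                         imputation_level = 0.382,
                                         seed = 7, save_mask = TRUE))
  src <- d$values[match(a$source_subject_id, d$subject_ids), ]
  keep <- a$mask == 0
  expect_identical(a$values[keep], src[keep])
  # and imputed entries stay within each feature's observed range
  stats <- compute_column_stats(d)
  lo <- matrix(stats$min, nrow(a$values), ncol(a$values), byrow = TRUE)
  hi <- matrix(stats$max, nrow(a$values), ncol(a$values), byrow = TRUE)
  expect_true(all(a$values[!keep] >= lo[!keep] & a$values[!keep] <= hi[!keep]))
})

test_that("r = 0 reproduces each source row; default level is 0.382", {
  g <- generate_quadra_omics(small_config(seed = 21))
  d <- preprocess_dataset(g$dataset)$dataset
  a <- amplify_dataset(d, amplify_config(replication_factors = 5,
                                         imputation_level = 0, seed = 1))
  src <- d$values[match(a$source_subject_id, d$subject_ids), ]
  expect_equal(a$values, src, ignore_attr = TRUE)
  expect_equal(amplify_config()$imputation_level, 0.382)
})

test_that("per-feature amplified mean obeys (1-r)*mean + r*(min+max)/2", {
  g <- generate_quadra_omics(small_config(seed = 17))
  d <- preprocess_dataset(g$dataset)$dataset
  r <- 0.4; K <- 1000
  a <- amplify_dataset(d, amplify_config(replication_factors = K,
                                         imputation_level = r, seed = 55))
  stats <- compute_column_stats(d)
  expected <- (1 - r) * colMeans(d$values) + r * (stats$min + stats$max) / 2
  # per-feature sd of the amplified mean, brute force from the mixture:
  # entry = source value (kept, prob 1-r) or U[min,max) (prob r)
  n <- nrow(a$values)
  src_var <- apply(d$values, 2, function(col) mean((col - mean(col))^2))
  unif_mean <- (stats$min + stats$max) / 2
  unif_var <- stats$range^2 / 12
  mix_mean <- (1 - r) * colMeans(d$values) + r * unif_mean
  entry_var <- (1 - r) * (src_var + (colMeans(d$values) - mix_mean)^2) +
    r * (unif_var + (unif_mean - mix_mean)^2)
  sd_mean <- sqrt(entry_var / n)
  dev <- abs(colMeans(a$values) - expected)
  expect_true(all(dev <= 5 * sd_mean + 1e-12))
})

test_that("keep_originals prepends the untouched source rows", {
  g <- generate_quadra_omics(small_config(seed = 30))
  d <- preprocess_dataset(g$dataset)$dataset
  a <- amplify_dataset(d, amplify_config(replication_factors = 3,
                                         imputation_level = 0.5, seed = 2,
                                         keep_originals = TRUE))
  n <- nrow(d$values)
  expect_equal(nrow(a$values), n + 3 * n)
  expect_equal(a$values[seq_len(n), ], d$values, ignore_attr = TRUE)
  expect_true(all(a$replicate_index[seq_len(n)] == -1))
})

test_that("per-group stats scope keeps imputed values inside group ranges", {
  v <- cbind(c(1, 2, 100, 200), c(5, 6, 7, 8))
  d <- tiny_dataset(values = v, groups = c("a", "a", "b", "b"))
  a <- amplify_dataset(d, amplify_config(replication_factors = 500,
                                         imputation_level = 1, seed = 3,
                                         stats_scope = "per_group"))
  f1_a <- a$values[a$group_labels == "a", 1]
  f1_b <- a$values[a$group_labels == "b", 1]
  expect_true(all(f1_a >= 1 & f1_a <= 2))
  expect_true(all(f1_b >= 100 & f1_b <= 200))
})

test_that("class-balancing factors equalize amplified group counts", {
  d <- tiny_dataset(values = matrix(stats::rlnorm(12), nrow = 6),
                    groups = rep(c("big", "small"), c(5, 1)))
  # K_g proportional to 1/n_g: 5-subject group gets K=2, singleton gets K=10
  a <- replicate_subjects(d, c(big = 2, small = 10))
  counts <- table(a$group_labels)
  expect_lte(max(counts) - min(counts), 10)
})
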