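test_that("replicate aggregation takes the geometric mean on the pseudocounted scale", {
  samples <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "liver",
                            site = c("A", "B"))
  # (FPKM + 0.1) of 0.4 and 0.9 -> sqrt(0.36) = 0.6 -> FPKM 0.5
  expr <- tibble::tibble(transcript_id = "t1", s1 = 0.3, s2 = 0.8)
  tm <- aggregate_replicates(expr, samples)
  expect_equal(tm$liver, 0.5)
  # identical replicates: identity
  expr2 <- tibble::tibble(transcript_id = c("t1", "t2"),
                          s1 = c(2.5, 0), s2 = c(2.5, 0))
  expect_equal(aggregate_replicates(expr2, samples)$liver, c(2.5, 0))
  # arithmetic alternative
  expect_equal(aggregate_replicates(expr, samples, method = "arithmetic")$liver,
               0.55)
})

test_that("aggregation with zero replicate noise reproduces the tissue-level truth", {
  sim <- simulate_expression(small_config(replicate_noise_sd = 0))
  tm <- aggregate_replicates(sim$expression, sim$samples)
  truth <- sim$truth$tissue_fpkm
  expect_equal(as.matrix(tm[-1]), as.matrix(truth[-1]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("low-expression filter uses an inclusive geometric-mean boundary", {
  tm <- tibble::tibble(transcript_id = c("boundary", "zero", "high"),
                       a = c(0.9, 0, 50), b = c(0.9, 0, 60), c = c(0.9, 0, 70))
  res <- filter_low_expression(tm)
  # geometric mean of (0.9 + 0.1) is exactly 1: retained, not removed
  expect_true("boundary" %in% res$retained$transcript_id)
  expect_equal(res$removed_ids, "zero")
  expect_equal(unname(res$geometric_mean["zero"]), 0.1)
})

test_that("single-tissue expressors follow the closed-form filter boundary", {
  # 13 tissues at 0 and one at x: retained iff (x + 0.1) >= 10^13
  below <- 1e13 - 0.1 - 1e4
  above <- 1e13 - 0.1 + 1e4
  tm <- tibble::tibble(transcript_id = c("below", "above"))
  for (i in 1:13) tm[[paste0("t", i)]] <- c(0, 0)
  tm$t14 <- c(below, above)
  res <- filter_low_expression(tm)
  expect_equal(res$removed_ids, "below")
  expect_equal(res$retained$transcript_id, "above")
})

test_that("raising a tissue value never removes a retained transcript", {
  set.seed(7)
  tm <- matrix_to_expr(matrix(rexp(200, rate = 1), 50,
                              dimnames = list(sprintf("t%02d", 1:50), NULL)))
  names(tm)[-1] <- paste0("tis", 1:4)
  kept <- filter_low_expression(tm)$retained$transcript_id
  for (i in 1:20) {
    tm2 <- tm
    row <- sample(nrow(tm2), 1)
    col <- sample(2:5, 1)
    tm2[row, col] <- tm2[row, col][[1]] + rexp(1, 0.2)
    kept2 <- filter_low_expression(tm2)$retained$transcript_id
    expect_true(all(kept %in% kept2))
  }
})

test_that("removed transcripts include every planted dropout", {
  sim <- simulate_expression(small_config(dropout_fraction = 0.2))
  tm <- aggregate_replicates(sim$expression, sim$samples)
  res <- filter_low_expression(tm)
  expect_true(all(sim$truth$dropout_ids %in% res$removed_ids))
})

test_that("expressed detection is inclusive, raw-scale, and pseudocount-invariant", {
  expr <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                         s1 = c(0.99, 1.0, 5.0), s2 = c(0, 0, 0))
  counts <- count_expressed(expr)
  expect_equal(counts$n_expressed[counts$sample_id == "s1"], 2)
  expect_equal(counts$n_expressed[counts$sample_id == "s2"], 0)
})

test_that("per-sample expressed counts match a brute-force recount", {
  sim <- simulate_expression(small_config())
  counts <- count_expressed(sim$expression)
  m <- as.matrix(sim$expression[-1])
  for (i in seq_len(ncol(m))) {
    expect_equal(counts$n_expressed[counts$sample_id == colnames(m)[i]],
                 sum(m[, i] >= 1))
  }
  annot <- classify_biotypes(sim$annotation)
  split_counts <- count_expressed(sim$expression, annot)
  tot <- tapply(split_counts$n_expressed, split_counts$sample_id, sum)
  expect_equal(as.vector(tot[counts$sample_id]), counts$n_expressed)
})

test_that("log transform applies log2(value + pseudocount)", {
  x <- tibble::tibble(transcript_id = "t1", s1 = 0, s2 = 0.9, s3 = 1.9)
  lt <- log_transform(x)
  expect_equal(unlist(lt[-1], use.names = FALSE),
               c(log2(0.1), 0, 1))
  expect_error(log_transform(x, pseudocount = 0), "pseudocount")
})

test_that("replicate concordance matches the exact Spearman formula", {
  samples <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "a",
                            site = c("1", "2"))
  expr <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                         s1 = c(1, 2, 3), s2 = c(1, 3, 2))
  # 1 - 6 * sum(d^2) / (n(n^2-1)) = 1 - 12/24 = 0.5
  expect_equal(replicate_concordance(expr, samples)$spearman, 0.5)
  # identical -> 1; reversed -> -1
  expr$s2 <- expr$s1
  expect_equal(replicate_concordance(expr, samples)$spearman, 1)
  expr$s2 <- rev(expr$s1)
  expect_equal(replicate_concordance(expr, samples)$spearman, -1)
})

test_that("a tissue with a single library reports missing concordance", {
  samples <- tibble::tibble(sample_id = "s1", tissue = "a", site = "1")
  expr <- tibble::tibble(transcript_id = c("t1", "t2"), s1 = c(1, 2))
  res <- replicate_concordance(expr, samples)
  expect_true(is.na(res$spearman))
  expect_equal(res$n_pairs, 0L)
})
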