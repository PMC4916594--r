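test_that("fold change is the best tissue over the max of the others", {
  # pseudocounted values (10, 4.9, 1, 1): FC = 10/4.9 >= 2 -> specific
  tm <- tibble::tibble(transcript_id = "t1",
                       a = 9.9, b = 4.8, c = 0.9, d = 0.9)
  call <- call_specific(tm)
  expect_equal(call$specific_tissue, "a")
  expect_equal(call$fold_change, 10 / 4.9)
})

test_that("the threshold is inclusive and ties at the maximum are never specific", {
  tm <- tibble::tibble(transcript_id = c("boundary", "flat", "tied"),
                       a = c(3.9, 1, 5), b = c(1.9, 1, 5), c = c(0.9, 1, 1))
  calls <- call_specific(tm)
  expect_equal(calls$specific_tissue[calls$transcript_id == "boundary"], "a")
  expect_equal(calls$fold_change[calls$transcript_id == "boundary"], 2)
  expect_true(is.na(calls$specific_tissue[calls$transcript_id == "flat"]))
  expect_true(is.na(calls$specific_tissue[calls$transcript_id == "tied"]))
})

test_that("single-tissue matrices and degenerate thresholds are rejected", {
  tm <- tibble::tibble(transcript_id = "t1", a = 5)
  expect_error(call_specific(tm), "2 tissues")
  expect_error(call_specific(tibble::tibble(transcript_id = "t1", a = 1, b = 2),
                             fold_threshold = 1), "fold_threshold")
})

test_that("each transcript is specific to at most one tissue and calls are labelled", {
  sim <- simulate_expression(small_config())
  annot <- classify_biotypes(sim$annotation)
  tm <- aggregate_replicates(sim$expression, sim$samples)
  calls <- call_specific(filter_low_expression(tm)$retained, annot)
  expect_equal(anyDuplicated(calls$transcript_id), 0)
  hits <- calls[!is.na(calls$specific_tissue), ]
  expect_true(all(hits$fold_change >= 2))
  expect_true(all(hits$class %in% c("TSCT", "TSNT")))
})

test_that("raising the fold threshold never adds a call", {
  set.seed(11)
  tm <- matrix_to_expr(matrix(rexp(300, 0.2), 60,
                              dimnames = list(sprintf("t%02d", 1:60), NULL)))
  names(tm)[-1] <- paste0("tis", 1:5)
  called_at <- function(th) {
    calls <- call_specific(tm, fold_threshold = th)
    calls$transcript_id[!is.na(calls$specific_tissue)]
  }
  prev <- called_at(1.5)
  for (th in c(2, 3, 5, 8)) {
    cur <- called_at(th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("planted specifics are recovered exactly at zero noise with closed-form FC", {
  cfg <- small_config(replicate_noise_sd = 0, module_size_per_tissue = 0,
                      dropout_fraction = 0)
  sim <- simulate_expression(cfg)
  tm <- aggregate_replicates(sim$expression, sim$samples)
  filt <- filter_low_expression(tm)
  calls <- call_specific(filt$retained, classify_biotypes(sim$annotation))
  hits <- calls[!is.na(calls$specific_tissue), ]
  truth <- sim$truth$specific_of
  retained_truth <- truth[truth$transcript_id %in% filt$retained$transcript_id, ]
  # every retained planted specific called, in its planted tissue
  expect_true(all(retained_truth$transcript_id %in% hits$transcript_id))
  m <- merge(hits, retained_truth, by = "transcript_id")
  expect_equal(m$specific_tissue, m$tissue)
  # no false positives: everything else is constant across tissues
  expect_true(all(hits$transcript_id %in% truth$transcript_id))
  # measured FC equals the pseudocount-attenuated closed form (f*B+0.1)/(B+0.1)
  tf <- sim$truth$tissue_fpkm
  for (k in sample(nrow(m), 10)) {
    row <- tf[tf$transcript_id == m$transcript_id[k], -1]
    B <- max(row[names(row) != m$tissue[k]])
    expect_equal(m$fold_change[k],
                 (max(row) + 0.1) / (B + 0.1), tolerance = 1e-10)
  }
  # pseudocount attenuation: measured FC never exceeds the planted fold
  expect_true(all(m$fold_change <= cfg$specific_fold + 1e-9))
})

test_that("per-tissue counts are sorted and partition the calls", {
  calls <- tibble::tibble(
    transcript_id = paste0("t", 1:5),
    specific_tissue = c("A", "A", "A", "B", NA),
    fold_change = c(3, 3, 3, 4, 1),
    class = c("TSCT", "TSCT", "TSNT", "TSCT", NA))
  counts <- count_specific(calls)
  expect_equal(counts$tissue, c("A", "B"))
  expect_equal(counts$TSCT, c(2, 1))
  expect_equal(counts$TSNT, c(1, 0))
  expect_equal(sum(counts$total), 4)
  empty <- count_specific(calls[5, ])
  expect_equal(nrow(empty), 0)
})

test_that("Z-scored rows have mean 0 and sd 1 in tissue-block order", {
  tm_log <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                           a = c(1, 5, 2), b = c(2, 1, 2), c = c(3, 1, 2))
  calls <- tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                          specific_tissue = c("c", "a", "a"),
                          fold_change = c(2, 4, 3),
                          class = c("TSCT", "TSCT", "TSNT"))
  expect_warning(z <- zscore_matrix(tm_log, calls), "zero-variance")
  # constant row t3 dropped; blocks ordered by call count: a (2 calls) first
  expect_equal(z$transcript_id, c("t2", "t1"))
  expect_equal(attr(z, "tissue_order"), c("a", "c"))
  expect_equal(unlist(z[z$transcript_id == "t1", c("a", "b", "c")],
                      use.names = FALSE), c(-1, 0, 1))
  m <- as.matrix(z[c("a", "b", "c")])
  expect_true(all(abs(rowMeans(m)) < 1e-12))
  expect_true(all(abs(apply(m, 1, sd) - 1) < 1e-12))
})
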