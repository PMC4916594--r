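test_that("soft-threshold adjacency is |cor|^beta with unit diagonal", {
  x <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 8,     # cor +1 with row 1
                4, 3, 2, 1,     # cor -1 with row 1
                1, 3, 2, 5), 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
  a <- adjacency_matrix(x, beta = 20)
  expect_equal(unname(diag(a)), rep(1, 4))
  expect_equal(a["t1", "t2"], 1)          # perfect correlation, any beta
  expect_equal(a["t1", "t3"], 1)          # unsigned: |-1|^beta
  r <- cor(x["t1", ], x["t4", ])
  expect_equal(a["t1", "t4"], abs(r)^20)
  expect_equal(a, t(a))
})

test_that("adjacency exponent 0.9^20 and monotone attenuation in beta", {
  expect_equal(0.9^20, 0.12157665, tolerance = 1e-7)
  set.seed(5)
  x <- matrix(rnorm(60), 10)
  rownames(x) <- paste0("t", 1:10)
  a5 <- adjacency_matrix(x, beta = 5)
  a6 <- adjacency_matrix(x, beta = 6)
  off <- upper.tri(a5)
  expect_true(all(a6[off] <= a5[off] + 1e-15))
})

test_that("adjacency rejects zero-variance rows and too few samples", {
  x <- rbind(t1 = c(1, 1, 1, 1), t2 = c(1, 2, 3, 4))
  expect_error(adjacency_matrix(x), "zero-variance.*t1")
  expect_error(adjacency_matrix(rbind(t1 = c(1, 2), t2 = c(2, 1))), "3 samples")
  expect_error(adjacency_matrix(rbind(t1 = 1:4, t2 = 4:1), beta = 2.5), "integer")
})

test_that("TOM has the stated closed forms on degenerate graphs", {
  # identity adjacency: no shared neighbours, no direct link
  a <- diag(4)
  dimnames(a) <- list(paste0("t", 1:4), paste0("t", 1:4))
  res <- topological_overlap(a)
  expect_equal(unname(res$tom[upper.tri(res$tom)]), rep(0, 6))
  expect_equal(unname(res$dissim[upper.tri(res$dissim)]), rep(1, 6))
  expect_equal(unname(diag(res$tom)), rep(1, 4))
  # complete graph: overlap is total for every pair
  b <- matrix(1, 5, 5)
  expect_true(all(abs(topological_overlap(b)$tom - 1) < 1e-12))
})

test_that("TOM matches the brute-force triple-loop oracle", {
  set.seed(42)
  a <- random_adjacency(6)
  res <- topological_overlap(a)
  expect_lt(max(abs(res$tom - tom_bruteforce(a))), 1e-12)
})

test_that("planted blocks with clean separation give perfect modules", {
  n <- 160
  d <- matrix(1, n, n)
  d[1:80, 1:80] <- 0.05
  d[81:160, 81:160] <- 0.05
  diag(d) <- 0
  rownames(d) <- colnames(d) <- sprintf("t%03d", 1:n)
  mod <- detect_modules(d, min_module_size = 60, cut_height = 0.995)
  asg <- mod$assignments
  expect_equal(max(asg$module), 2)
  expect_equal(length(unique(asg$module[1:80])), 1)
  expect_equal(length(unique(asg$module[81:160])), 1)
  expect_true(asg$module[1] != asg$module[81])
  expect_equal(sum(asg$module == 0), 0)
  # module 1 is the larger-or-equal module by convention
  expect_true(sum(asg$module == 1) >= sum(asg$module == 2))
})

test_that("fewer transcripts than the minimum module size leaves all gray", {
  d <- 1 - diag(50)
  rownames(d) <- colnames(d) <- paste0("t", 1:50)
  expect_warning(mod <- detect_modules(d, min_module_size = 60), "unassigned")
  expect_true(all(mod$assignments$module == 0L))
})

test_that("hub extraction ranks by intramodular connectivity", {
  # star: center connected at 0.9 to all, leaves mutually at 0.05
  n <- 6
  a <- matrix(0.05, n, n)
  a[1, ] <- a[, 1] <- 0.9
  diag(a) <- 1
  rownames(a) <- colnames(a) <- c("center", paste0("leaf", 1:5))
  modules <- structure(list(assignments = tibble::tibble(
    transcript_id = rownames(a), module = 1L)), class = "coexpression_modules")
  res <- extract_hubs(a, modules, n_hubs = 3)
  expect_equal(res$hubs$transcript_id[1], "center")
  expect_equal(res$hubs$hub_rank, 1:3)
  # small module returns all members with a warning
  expect_warning(all6 <- extract_hubs(a, modules, n_hubs = 30), "only 6")
  expect_equal(nrow(all6$hubs), 6)
  # brute-force top-k check on a random module
  set.seed(3)
  b <- random_adjacency(12)
  rownames(b) <- colnames(b) <- sprintf("n%02d", 1:12)
  mods2 <- structure(list(assignments = tibble::tibble(
    transcript_id = rownames(b), module = 1L)), class = "coexpression_modules")
  got <- extract_hubs(b, mods2, n_hubs = 4)$hubs$transcript_id
  k <- rowSums(b) - diag(b)
  expect_setequal(got, names(sort(k, decreasing = TRUE))[1:4])
})

test_that("hub edges are upper-triangle pairs with the requested weights", {
  a <- random_adjacency(5)
  rownames(a) <- colnames(a) <- paste0("t", 1:5)
  mods <- structure(list(assignments = tibble::tibble(
    transcript_id = rownames(a), module = 1L)), class = "coexpression_modules")
  res <- extract_hubs(a, mods, n_hubs = 3)
  expect_equal(nrow(res$edges), 3)
  expect_true(all(res$edges$method == "M1000"))
  expect_equal(res$edges$weight,
               a[cbind(res$edges$node1, res$edges$node2)], ignore_attr = TRUE)
  path <- withr::local_tempfile()
  write_visant_edges(res$edges, path)
  expect_equal(length(readLines(path)), 3)
})

test_that("module composition reports dominant tissue and class counts", {
  modules <- structure(list(assignments = tibble::tibble(
    transcript_id = paste0("t", 1:4), module = c(1L, 1L, 1L, 0L))),
    class = "coexpression_modules")
  calls <- tibble::tibble(transcript_id = paste0("t", 1:4),
                          specific_tissue = c("A", "A", "A", "B"),
                          fold_change = 3, class = c("TSCT", "TSNT", "TSCT", "TSCT"))
  comp <- module_class_composition(modules, calls)
  expect_equal(comp$dominant_tissue, "A")
  expect_equal(comp$purity, 1)
  expect_equal(comp$n_TSCT, 2)
  expect_equal(comp$n_TSNT, 1)
  empty <- structure(list(assignments = tibble::tibble(
    transcript_id = character(), module = integer())),
    class = "coexpression_modules")
  expect_equal(nrow(module_class_composition(empty, calls)), 0)
})

test_that("per-tissue call blocks form modules with the planted dominant tissue", {
  sim <- simulate_expression(small_config())
  annot <- classify_biotypes(sim$annotation)
  tm <- aggregate_replicates(sim$expression, sim$samples)
  calls <- call_specific(filter_low_expression(tm)$retained, annot)
  hits <- calls[!is.na(calls$specific_tissue), ]
  expr_log <- log_transform(
    sim$expression[sim$expression$transcript_id %in% hits$transcript_id, ])
  adj <- adjacency_matrix(expr_log, beta = 20)
  mod <- detect_modules(topological_overlap(adj)$dissim, min_module_size = 10)
  comp <- module_class_composition(mod, calls)
  truth <- sim$truth$specific_of
  expect_gte(nrow(comp), 3)
  for (i in seq_len(nrow(comp))) {
    members <- mod$assignments$transcript_id[mod$assignments$module == comp$module[i]]
    planted <- truth$tissue[match(members, truth$transcript_id)]
    expect_equal(comp$dominant_tissue[i], names(which.max(table(planted))))
  }
})
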