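# Shared fixtures: small simulation configs and independent oracles.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_tissues = 4, n_sites = 2, n_coding = 500, n_noncoding = 50,
         n_specific_per_tissue = 20, module_size_per_tissue = 40,
         specific_fold = 8, replicate_noise_sd = 0.1, seed = 1),
    list(...))
  do.call(sim_config, args)
}

tiny_expr <- function() {
  tibble::tibble(transcript_id = c("t1", "t2", "t3"),
                 s1 = c(0, 1, 5), s2 = c(0.5, 1, 4), s3 = c(10, 1, 3))
}

# Brute-force unsigned TOM over explicit (i, j, u) loops; independent of the
# matrix-algebra implementation.
tom_bruteforce <- function(adj) {
  n <- nrow(adj)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) {
      if (u != i && u != j) shared <- shared + adj[i, u] * adj[u, j]
    }
    ki <- sum(adj[i, -i])
    kj <- sum(adj[j, -j])
    out[i, j] <- (shared + adj[i, j]) / (min(ki, kj) + 1 - adj[i, j])
  }
  out
}

random_adjacency <- function(n) {
  r <- matrix(runif(n * n), n)
  a <- (r + t(r)) / 2
  diag(a) <- 1
  a
}

# Exhaustive hypergeometric upper tail: enumerate every possible query draw
# of size n from a universe of size N and count draws whose overlap with the
# K marked elements is >= x.
hyper_tail_enum <- function(x, K, N, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= x)
}
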