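#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (via
#' [stats::p.adjust()]), with input validation; the input order is
#' preserved.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the query (e.g. one tissue's
#' tissue-specific transcripts) overlaps the set more than expected by
#' chance when drawing `|query|` identifiers from the universe without
#' replacement. The p-value is the exact hypergeometric upper tail
#' `P(X >= overlap)`; adjusted p-values are Benjamini-Hochberg across all
#' sets. Sets are intersected with the universe before testing. This is a
#' reproducible, self-contained over-representation test in the spirit of
#' DAVID-style functional annotation, but using the exact hypergeometric
#' tail rather than the EASE-modified Fisher score.
#'
#' @param query Character vector of identifiers (must intersect the
#'   universe; identifiers outside the universe are dropped).
#' @param sets Gene-set tibble from [read_gmt()] /
#'   [simulate_gene_sets()], or a named list of character vectors.
#' @param universe Character vector: the background identifier set
#'   (typically all transcripts retained after low-expression filtering).
#' @return A tibble sorted by p-value: `name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `adjusted_p`.
#' @examples
#' hypergeometric_enrich(paste0("t", 1:10),
#'                       list(s = paste0("t", 1:5)),
#'                       paste0("t", 1:20))
#' @export
hypergeometric_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(intersect(query, universe))
  if (length(query) == 0) stop("empty query (after intersecting the universe)",
                               call. = FALSE)
  if (is.data.frame(sets)) {
    stopifnot(all(c("name", "genes") %in% names(sets)))
    set_list <- setNames(sets$genes, sets$name)
  } else {
    stopifnot(is.list(sets), !is.null(names(sets)))
    set_list <- sets
  }
  n_univ <- length(universe)
  n_query <- length(query)
  out <- purrr::imap_dfr(set_list, function(members, nm) {
    members <- unique(intersect(members, universe))
    k <- length(members)
    x <- length(intersect(members, query))
    tibble::tibble(
      name = nm, overlap = x, set_size = k,
      query_size = n_query, universe_size = n_univ,
      p_value = phyper(x - 1, k, n_univ - k, n_query, lower.tail = FALSE)
    )
  })
  out$adjusted_p <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$p_value, .data$name)
}
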