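#' Call tissue-specific transcripts by fold change
#'
#' A transcript is tissue-specific when its tissue-level expression in one
#' tissue is at least `fold_threshold` times higher than in any other
#' tissue. The ratio is computed on the pseudocounted FPKM scale
#' (`value + pseudocount`), equivalent to a difference of
#' `log2(fold_threshold)` on the log2 scale; the large pseudocount
#' deliberately compresses fold changes for weak expressors. The comparison
#' is inclusive ("at least"), and a transcript whose maximum is tied across
#' two or more tissues is never specific. Calls are labelled TSCT
#' (protein-coding) or TSNT (noncoding) when a classified annotation is
#' supplied.
#'
#' @param tm Tissue-level tibble (post low-expression filtering), one column
#'   per tissue; at least two tissues.
#' @param annot Optional classified annotation (see [classify_biotypes()]).
#' @param fold_threshold Minimum fold change (default 2; must be > 1).
#' @param pseudocount Pseudocount added before forming the ratio
#'   (default 0.1).
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `specific_tissue` (`NA` when not specific), `fold_change` (best tissue
#'   over the maximum of the others), and `class`
#'   (`"TSCT"`/`"TSNT"`/`NA`).
#' @examples
#' tm <- tibble::tibble(transcript_id = "t1", a = 9.9, b = 4.8, c = 0.9)
#' call_specific(tm)  # fold = 10/4.9 >= 2 -> specific to 'a'
#' @export
call_specific <- function(tm, annot = NULL, fold_threshold = 2,
                          pseudocount = 0.1) {
  validate_expression(tm, what = "tissue matrix")
  if (fold_threshold <= 1) stop("fold_threshold must be > 1", call. = FALSE)
  m <- expr_to_matrix(tm) + pseudocount
  if (ncol(m) < 2) stop("tissue specificity needs at least 2 tissues", call. = FALSE)
  top_idx <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), top_idx)]
  tied <- rowSums(m == top) > 1
  second <- m
  second[cbind(seq_len(nrow(m)), top_idx)] <- -Inf
  second <- second[cbind(seq_len(nrow(m)), max.col(second, ties.method = "first"))]
  fc <- top / second
  specific <- !tied & fc >= fold_threshold
  out <- tibble::tibble(
    transcript_id = rownames(m),
    specific_tissue = unname(ifelse(specific, colnames(m)[top_idx], NA_character_)),
    fold_change = unname(ifelse(tied, 1, fc))
  )
  if (!is.null(annot)) {
    stopifnot("merged_class" %in% names(annot))
    cls <- annot$merged_class[match(out$transcript_id, annot$transcript_id)]
    out$class <- dplyr::case_when(
      is.na(out$specific_tissue) ~ NA_character_,
      cls == "protein_coding" ~ "TSCT",
      !is.na(cls) ~ "TSNT",
      TRUE ~ NA_character_
    )
  } else {
    out$class <- NA_character_
  }
  stopifnot(sum(!is.na(out$specific_tissue)) ==
              dplyr::n_distinct(out$transcript_id[!is.na(out$specific_tissue)]))
  out
}

#' Count specific transcripts per tissue
#'
#' @param calls Call tibble from [call_specific()].
#' @return A tibble `tissue`, `TSCT`, `TSNT`, `unclassified`, `total`,
#'   sorted by descending total. Empty input gives an empty tibble.
#' @export
count_specific <- function(calls) {
  hits <- calls[!is.na(calls$specific_tissue), , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(tissue = character(), TSCT = integer(),
                          TSNT = integer(), unclassified = integer(),
                          total = integer()))
  }
  hits |>
    dplyr::mutate(class = ifelse(is.na(.data$class), "unclassified", .data$class)) |>
    dplyr::count(.data$specific_tissue, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L) |>
    dplyr::rename(tissue = "specific_tissue") |>
    (\(d) {
      for (col in c("TSCT", "TSNT", "unclassified"))
        if (!col %in% names(d)) d[[col]] <- 0L
      d
    })() |>
    dplyr::mutate(total = .data$TSCT + .data$TSNT + .data$unclassified) |>
    dplyr::arrange(dplyr::desc(.data$total)) |>
    dplyr::select("tissue", "TSCT", "TSNT", "unclassified", "total")
}

#' Z-score standardized matrix ordered for a specificity heatmap
#'
#' Restricts a log-scale tissue matrix to the called transcripts,
#' standardizes each row to mean 0 and sample standard deviation 1, and
#' orders rows in tissue blocks sorted by descending per-tissue call count
#' (the convention used for tissue-specificity heatmaps). Zero-variance
#' rows cannot be standardized and are dropped with a warning.
#'
#' @param tm_log Log-scale tissue tibble (see [log_transform()]).
#' @param calls Call tibble from [call_specific()]; only rows with a
#'   `specific_tissue` are used.
#' @return A tibble `transcript_id`, `specific_tissue`, `class`, then one
#'   standardized column per tissue; the block order is stored in
#'   `attr(, "tissue_order")`.
#' @export
zscore_matrix <- function(tm_log, calls) {
  hits <- calls[!is.na(calls$specific_tissue), , drop = FALSE]
  if (nrow(hits) == 0) stop("no specific calls to standardize", call. = FALSE)
  m <- expr_to_matrix(tm_log)
  m <- m[rownames(m) %in% hits$transcript_id, , drop = FALSE]
  rsd <- apply(m, 1, sd)
  if (any(rsd == 0)) {
    warning(sum(rsd == 0), " zero-variance row(s) dropped before Z-scoring")
    m <- m[rsd > 0, , drop = FALSE]
    rsd <- rsd[rsd > 0]
  }
  z <- (m - rowMeans(m)) / rsd
  tissue_order <- count_specific(hits)$tissue
  out <- matrix_to_expr(z) |>
    dplyr::left_join(hits[c("transcript_id", "specific_tissue", "class")],
                     by = "transcript_id") |>
    dplyr::mutate(specific_tissue = factor(.data$specific_tissue,
                                           levels = tissue_order)) |>
    dplyr::arrange(.data$specific_tissue) |>
    dplyr::mutate(specific_tissue = as.character(.data$specific_tissue)) |>
    dplyr::relocate("transcript_id", "specific_tissue", "class")
  attr(out, "tissue_order") <- tissue_order
  out
}
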