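#' Aggregate technical replicates into a tissue-level matrix
#'
#' Collapses each tissue's libraries to a single column. The default
#' aggregation is the geometric mean of `(FPKM + pseudocount)` across the
#' tissue's samples, minus the pseudocount and floored at zero; on the
#' `log2(FPKM + pseudocount)` scale used downstream this is exactly the
#' arithmetic mean of the replicate log values, so tissue-level log
#' statistics are replicate-average log values. A plain arithmetic mean of
#' FPKM is available as an alternative. With a single replicate either
#' method is the identity.
#'
#' @param expr Expression tibble (`transcript_id` + one column per sample).
#' @param samples Sample table mapping `sample_id` to `tissue`.
#' @param pseudocount Pseudocount used for the geometric method (default 0.1).
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return A tissue-level tibble: `transcript_id` + one column per tissue.
#' @examples
#' expr <- tibble::tibble(transcript_id = "t1", s1 = 0.3, s2 = 0.8)
#' samples <- tibble::tibble(sample_id = c("s1", "s2"),
#'                           tissue = "liver", site = c("A", "B"))
#' aggregate_replicates(expr, samples)  # sqrt(0.4 * 0.9) - 0.1 = 0.5
#' @export
aggregate_replicates <- function(expr, samples, pseudocount = 0.1,
                                 method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  validate_expression(expr)
  validate_sample_table(samples)
  samples <- samples[samples$sample_id %in% value_cols(expr), , drop = FALSE]
  tissues <- unique(samples$tissue)
  if (length(tissues) == 0) stop("no tissue has any sample column", call. = FALSE)
  m <- expr_to_matrix(expr)
  cols <- lapply(tissues, function(tis) {
    ids <- samples$sample_id[samples$tissue == tis]
    sub <- m[, ids, drop = FALSE]
    if (method == "geometric") {
      if (pseudocount <= 0) stop("geometric aggregation needs pseudocount > 0",
                                 call. = FALSE)
      pmax(2^rowMeans(log2(sub + pseudocount)) - pseudocount, 0)
    } else {
      rowMeans(sub)
    }
  })
  out <- matrix(unlist(cols), ncol = length(tissues),
                dimnames = list(rownames(m), tissues))
  matrix_to_expr(out)
}

#' Filter lowly expressed transcripts
#'
#' A transcript is retained iff the geometric mean of
#' `(value + pseudocount)` across tissues is at least `threshold`; the
#' comparison is inclusive, so a transcript sitting exactly at the boundary
#' is kept. Removed transcript ids are returned for audit.
#'
#' @param tm Tissue-level tibble from [aggregate_replicates()] (or any
#'   `transcript_id` + value-column tibble).
#' @param pseudocount Pseudocount (default 0.1).
#' @param threshold Geometric-mean threshold (default 1).
#' @return A list with elements `retained` (filtered tibble), `removed_ids`
#'   (character vector), and `geometric_mean` (named vector for all input
#'   transcripts).
#' @export
filter_low_expression <- function(tm, pseudocount = 0.1, threshold = 1) {
  validate_expression(tm, what = "tissue matrix")
  m <- expr_to_matrix(tm)
  gm <- 2^rowMeans(log2(m + pseudocount))
  keep <- gm >= threshold
  list(retained = tm[keep, , drop = FALSE],
       removed_ids = rownames(m)[!keep],
       geometric_mean = gm)
}

#' Count expressed transcripts per sample
#'
#' A transcript counts as expressed in a sample when its raw FPKM is at
#' least `threshold` (inclusive). Detection always uses raw FPKM values —
#' no pseudocount, no replicate aggregation, no prior filtering.
#'
#' @param expr Raw expression tibble.
#' @param annot Optional annotation with a `merged_class` column (see
#'   [classify_biotypes()]); when given, counts are split into coding vs
#'   noncoding.
#' @param threshold Minimum FPKM to call a transcript expressed (default 1).
#' @return A tibble with columns `sample_id`, `class`, `n_expressed`
#'   (`class` is `"all"` when no annotation is supplied).
#' @export
count_expressed <- function(expr, annot = NULL, threshold = 1) {
  validate_expression(expr)
  m <- expr_to_matrix(expr)
  groups <- if (is.null(annot)) {
    list(all = rownames(m))
  } else {
    stopifnot("merged_class" %in% names(annot))
    cls <- ifelse(annot$merged_class == "protein_coding", "coding", "noncoding")
    split(annot$transcript_id, cls)
  }
  purrr::imap_dfr(groups, function(ids, cls) {
    sub <- m[rownames(m) %in% ids, , drop = FALSE]
    tibble::tibble(sample_id = colnames(m), class = cls,
                   n_expressed = unname(colSums(sub >= threshold)))
  })
}

#' Log-transform expression values
#'
#' Applies `log2(value + pseudocount)` to every value column.
#'
#' @param x Expression or tissue-level tibble.
#' @param pseudocount Pseudocount; must be positive (default 0.1).
#' @return A tibble of the same shape on the log2 scale.
#' @export
log_transform <- function(x, pseudocount = 0.1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0 for a log transform",
                             call. = FALSE)
  dplyr::mutate(x, dplyr::across(dplyr::where(is.numeric),
                                 ~ log2(.x + pseudocount)))
}

#' Replicate concordance per tissue
#'
#' Spearman rank correlation between a tissue's technical replicates,
#' computed on raw FPKM values (ties get average ranks). With more than two
#' replicates all pairs are computed and averaged; a tissue with a single
#' replicate is reported as `NA`.
#'
#' @param expr Raw expression tibble.
#' @param samples Sample table.
#' @param annot Optional annotation with `merged_class`; when given the
#'   coefficient is computed separately for coding and noncoding transcripts.
#' @return A tibble with columns `tissue`, `class`, `spearman`, `n_pairs`.
#' @export
replicate_concordance <- function(expr, samples, annot = NULL) {
  validate_expression(expr)
  validate_sample_table(samples)
  samples <- samples[samples$sample_id %in% value_cols(expr), , drop = FALSE]
  m <- expr_to_matrix(expr)
  groups <- if (is.null(annot)) {
    list(all = rownames(m))
  } else {
    stopifnot("merged_class" %in% names(annot))
    cls <- ifelse(annot$merged_class == "protein_coding", "coding", "noncoding")
    split(annot$transcript_id, cls)
  }
  tidyr::expand_grid(tissue = unique(samples$tissue),
                     class = names(groups)) |>
    dplyr::rowwise() |>
    dplyr::mutate(res = list({
      ids <- samples$sample_id[samples$tissue == .data$tissue]
      sub <- m[rownames(m) %in% groups[[.data$class]], ids, drop = FALSE]
      if (length(ids) < 2) {
        tibble::tibble(spearman = NA_real_, n_pairs = 0L)
      } else {
        cc <- cor(sub, method = "spearman")
        tibble::tibble(spearman = mean(cc[upper.tri(cc)]),
                       n_pairs = as.integer(choose(length(ids), 2)))
      }
    })) |>
    dplyr::ungroup() |>
    tidyr::unnest("res")
}
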