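#' Default biotype merge rules
#'
#' Ordered rules consolidating Ensembl-style raw biotypes into merged
#' classes: any biotype containing `pseudogene` (including `IG_pseudogene`,
#' `miRNA_pseudogene`, ...) becomes `pseudogene`; any `TR_*` gene biotype
#' becomes `TR_gene`; any `IG_*` gene biotype becomes `IG_gene`;
#' `protein_coding` maps to itself; every other biotype maps to itself and
#' counts as its own noncoding class. The first matching rule wins, so the
#' pseudogene rule takes precedence over the IG/TR prefix rules.
#'
#' @return A tibble with columns `pattern`, `match_mode`
#'   (`exact`/`prefix`/`contains`), `merged_class`.
#' @export
default_merge_rules <- function() {
  tibble::tribble(
    ~pattern,         ~match_mode, ~merged_class,
    "pseudogene",     "contains",  "pseudogene",
    "TR_",            "prefix",    "TR_gene",
    "IG_",            "prefix",    "IG_gene",
    "protein_coding", "exact",     "protein_coding"
  )
}

#' Read or write biotype merge rules as TSV
#'
#' The rule table is data-driven so biotype vocabularies from other
#' annotation releases can be mapped without code changes.
#'
#' @param path Path to a TSV with columns `pattern`, `match_mode`,
#'   `merged_class`.
#' @return A rules tibble.
#' @export
read_merge_rules <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  req <- c("pattern", "match_mode", "merged_class")
  if (!all(req %in% names(x))) {
    stop("merge-rule file must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(x$match_mode), c("exact", "prefix", "contains"))
  if (length(bad) > 0) {
    stop("unknown match_mode: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x[req]
}

#' @rdname read_merge_rules
#' @param rules Rules tibble to write.
#' @export
write_merge_rules <- function(rules, path) {
  readr::write_tsv(rules, path)
  invisible(path)
}

#' Classify transcripts into merged biotype classes
#'
#' Applies the merge rules in order (first match wins) to populate a
#' `merged_class` column; raw biotypes matching no rule map to themselves,
#' so the classification is total and unknown biotypes simply become their
#' own noncoding class. Everything other than `protein_coding` is considered
#' noncoding.
#'
#' @param annot Annotation tibble with `raw_biotype`.
#' @param rules Rules tibble (default [default_merge_rules()]).
#' @return The annotation with `merged_class` (and logical `coding`) added.
#' @examples
#' classify_biotypes(tibble::tibble(transcript_id = c("t1", "t2", "t3"),
#'                                  raw_biotype = c("IG_pseudogene",
#'                                                  "protein_coding", "lincRNA")))
#' @export
classify_biotypes <- function(annot, rules = default_merge_rules()) {
  stopifnot("raw_biotype" %in% names(annot))
  raw <- annot$raw_biotype
  merged <- rep(NA_character_, length(raw))
  for (i in seq_len(nrow(rules))) {
    hit <- switch(rules$match_mode[i],
      exact    = raw == rules$pattern[i],
      prefix   = startsWith(raw, rules$pattern[i]),
      contains = grepl(rules$pattern[i], raw, fixed = TRUE),
      stop("unknown match_mode: ", rules$match_mode[i], call. = FALSE))
    merged[is.na(merged) & hit] <- rules$merged_class[i]
  }
  merged[is.na(merged)] <- raw[is.na(merged)]
  dplyr::mutate(annot, merged_class = merged,
                coding = merged == "protein_coding")
}

#' Tabulate merged biotype classes
#'
#' Counts transcripts per merged class and reports two percentage scales
#' matching common reporting conventions: the coding/noncoding split as a
#' percentage of all transcripts (one decimal), and each noncoding class as
#' a percentage of noncoding transcripts (nearest integer).
#'
#' @param annot Classified annotation (from [classify_biotypes()]).
#' @param restrict_to Optional character vector of transcript ids to
#'   tabulate (e.g. the retained set after filtering).
#' @return A tibble with columns `merged_class`, `n`, `pct_of_all`,
#'   `pct_of_noncoding` (`NA` for `protein_coding`), sorted by descending
#'   count.
#' @export
tabulate_classes <- function(annot, restrict_to = NULL) {
  stopifnot("merged_class" %in% names(annot))
  if (!is.null(restrict_to)) {
    annot <- annot[annot$transcript_id %in% restrict_to, , drop = FALSE]
  }
  if (nrow(annot) == 0) stop("no transcripts to tabulate", call. = FALSE)
  total <- nrow(annot)
  n_noncoding <- sum(annot$merged_class != "protein_coding")
  annot |>
    dplyr::count(.data$merged_class, name = "n") |>
    dplyr::mutate(
      pct_of_all = round(100 * .data$n / total, 1),
      pct_of_noncoding = ifelse(
        .data$merged_class == "protein_coding", NA_real_,
        round(100 * .data$n / n_noncoding))
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
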