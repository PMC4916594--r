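# Internal helpers shared across modules.

#' Convert between wide expression tibbles and numeric matrices
#'
#' The tidy representation used throughout the package is a wide tibble
#' with a `transcript_id` column plus one numeric column per sample or
#' tissue; the network functions operate on plain numeric matrices with
#' transcript ids as rownames. These helpers convert between the two.
#'
#' @param x Wide expression tibble.
#' @param m Numeric matrix (transcripts in rows); missing rownames are
#'   replaced by `t0001`, `t0002`, ...
#' @param id_col Name of the identifier column (default `transcript_id`).
#' @return A matrix (`expr_to_matrix`) or a tibble (`matrix_to_expr`).
#' @export
expr_to_matrix <- function(x, id_col = "transcript_id") {
  stopifnot(is.data.frame(x), id_col %in% names(x))
  value_cols <- setdiff(names(x), id_col)
  if (length(value_cols) == 0L) {
    stop("expression table has no value columns", call. = FALSE)
  }
  m <- as.matrix(x[value_cols])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(x[[id_col]])
  m
}

#' @rdname expr_to_matrix
#' @export
matrix_to_expr <- function(m, id_col = "transcript_id") {
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("t%04d", seq_len(nrow(m)))
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_col := ids), out)
}

# Columns of a wide expression tibble that hold values.
value_cols <- function(x, id_col = "transcript_id") setdiff(names(x), id_col)

validate_expression <- function(x, id_col = "transcript_id", what = "expression matrix") {
  if (!is.data.frame(x) || !id_col %in% names(x)) {
    stop(what, " must be a data frame with a '", id_col, "' column", call. = FALSE)
  }
  ids <- x[[id_col]]
  if (anyNA(ids) || any(ids == "")) {
    stop(what, ": missing transcript ids", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(what, ": duplicated transcript ids: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  vals <- x[value_cols(x, id_col)]
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad_col) > 0) {
    stop(what, ": non-numeric sample column(s): ", paste(bad_col, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(vals)) {
    na_cell <- which(is.na(as.matrix(vals)), arr.ind = TRUE)[1, ]
    stop(what, ": missing value at row ", na_cell[1], " (", ids[na_cell[1]],
         "), column '", names(vals)[na_cell[2]], "'", call. = FALSE)
  }
  if (any(as.matrix(vals) < 0)) {
    neg <- which(as.matrix(vals) < 0, arr.ind = TRUE)[1, ]
    stop(what, ": negative value at row ", neg[1], " (", ids[neg[1]],
         "), column '", names(vals)[neg[2]], "'", call. = FALSE)
  }
  invisible(x)
}

validate_sample_table <- function(samples) {
  req <- c("sample_id", "tissue", "site")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop("sample table must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("sample table: duplicated sample_id", call. = FALSE)
  }
  if (anyDuplicated(samples[c("tissue", "site")])) {
    stop("sample table: duplicated (tissue, site) pair", call. = FALSE)
  }
  invisible(samples)
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Write a tibble as TSV with '#'-prefixed provenance header lines.
write_table_with_provenance <- function(x, path, stage, params = list()) {
  hdr <- c(
    paste0("# tissuespec ", as.character(packageVersion("tissuespec")),
           "; stage=", stage),
    if (length(params) > 0)
      paste0("# params: ",
             paste(names(params), unlist(lapply(params, format)), sep = "=",
                   collapse = "; "))
  )
  writeLines(hdr, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
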