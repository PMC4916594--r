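#' Read a transcript-level expression matrix from TSV
#'
#' The canonical matrix format is tab-delimited with a header row; the first
#' column (`transcript_id`) holds unique transcript identifiers and every
#' other column holds non-negative FPKM values for one sample. Lines starting
#' with `#` are treated as comments (provenance headers written by this
#' package are skipped transparently).
#'
#' @param path Path to a TSV file.
#' @return A tibble with `transcript_id` plus one numeric column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("transcript_id\ts1\ts2", "t1\t1.5\t0", "t2\t3\t2"), tf)
#' read_expression_tsv(tf)
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      readr::col_character(),
                      .default = readr::col_double()
                    )))
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    stop("malformed cell in ", path, ": row ", prob$row[1], ", column ",
         prob$col[1], " (expected ", prob$expected[1], ", got '",
         prob$actual[1], "')", call. = FALSE)
  }
  names(x)[1] <- "transcript_id"
  validate_expression(x, what = paste0("expression matrix '", path, "'"))
  x
}

#' Write an expression matrix to TSV
#'
#' @param x Expression tibble (`transcript_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  validate_expression(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects tab-delimited columns `sample_id`, `tissue`, `site` (sequencing
#' site / technical replicate label).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `tissue`, `site`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  validate_sample_table(x)
  x
}

#' @rdname read_sample_table
#' @param x Sample table to write.
#' @export
write_sample_table <- function(x, path) {
  validate_sample_table(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a transcript biotype annotation
#'
#' Two formats are supported: a two-column TSV (`transcript_id`,
#' `raw_biotype`; a `biotype` header is accepted as an alias) and a GTF whose
#' transcript features carry `transcript_id` and a biotype attribute.
#' Ensembl GTF dialects name the biotype attribute differently across
#' releases, so the attribute key is configurable. Unknown biotype strings
#' are preserved verbatim.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gtf"`.
#' @param biotype_attribute GTF attribute holding the biotype
#'   (default `"transcript_biotype"`).
#' @return A tibble with columns `transcript_id`, `raw_biotype`.
#' @export
read_annotation <- function(path, format = c("tsv", "gtf"),
                            biotype_attribute = "transcript_biotype") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
    if ("biotype" %in% names(x) && !"raw_biotype" %in% names(x)) {
      names(x)[names(x) == "biotype"] <- "raw_biotype"
    }
    if (!all(c("transcript_id", "raw_biotype") %in% names(x))) {
      stop("annotation TSV must have columns transcript_id and raw_biotype/biotype",
           call. = FALSE)
    }
    x <- x[c("transcript_id", "raw_biotype")]
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GTF annotations requires the rtracklayer package", call. = FALSE)
    }
    g <- rtracklayer::import(path, format = "gtf")
    mc <- as.data.frame(g)
    if ("type" %in% names(mc)) {
      tr <- mc[as.character(mc$type) == "transcript", , drop = FALSE]
      if (nrow(tr) > 0) mc <- tr
    }
    if (!"transcript_id" %in% names(mc)) {
      stop("GTF has no transcript_id attribute", call. = FALSE)
    }
    if (!biotype_attribute %in% names(mc)) {
      stop("GTF has no '", biotype_attribute,
           "' attribute; set biotype_attribute to the key your annotation uses",
           call. = FALSE)
    }
    x <- tibble::tibble(transcript_id = as.character(mc$transcript_id),
                        raw_biotype = as.character(mc[[biotype_attribute]]))
    if (anyNA(x$raw_biotype)) {
      stop("GTF transcript(s) missing the '", biotype_attribute, "' attribute: ",
           paste(head(x$transcript_id[is.na(x$raw_biotype)], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  x <- dplyr::distinct(x)
  dup <- unique(x$transcript_id[duplicated(x$transcript_id)])
  if (length(dup) > 0) {
    stop("transcript(s) annotated with conflicting biotypes: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_annotation
#' @param x Annotation tibble to write (TSV only).
#' @export
write_annotation <- function(x, path) {
  stopifnot(all(c("transcript_id", "raw_biotype") %in% names(x)))
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write an annotation as a minimal GTF
#'
#' Emits one `transcript` feature per record with `transcript_id` and
#' `transcript_biotype` attributes, using placeholder coordinates. Mainly
#' useful for exercising GTF-based readers on synthetic data.
#'
#' @param x Annotation tibble (`transcript_id`, `raw_biotype`).
#' @param path Output path.
#' @export
write_annotation_gtf <- function(x, path) {
  stopifnot(all(c("transcript_id", "raw_biotype") %in% names(x)))
  n <- nrow(x)
  lines <- sprintf(
    "chr1\ttissuespec\ttranscript\t%d\t%d\t.\t+\t.\tgene_id \"G_%s\"; transcript_id \"%s\"; transcript_biotype \"%s\";",
    seq_len(n) * 1000L - 999L, seq_len(n) * 1000L,
    x$transcript_id, x$transcript_id, x$raw_biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Bind expression, sample metadata, and annotation into one dataset
#'
#' Restricts the expression matrix to samples present in the sample table and
#' (when an annotation is given) reconciles the transcript sets. Transcripts
#' without an annotation record are dropped (default) or kept with an
#' `"unannotated"` biotype; either way the count is reported.
#'
#' @param expr Expression tibble from [read_expression_tsv()].
#' @param samples Sample table from [read_sample_table()].
#' @param annot Optional annotation tibble from [read_annotation()].
#' @param unannotated `"drop"` or `"keep"`.
#' @return A list of class `tissue_dataset` with elements `expression`,
#'   `samples`, `annotation`.
#' @export
bind_dataset <- function(expr, samples, annot = NULL,
                         unannotated = c("drop", "keep")) {
  unannotated <- match.arg(unannotated)
  validate_expression(expr)
  validate_sample_table(samples)
  keep_samples <- intersect(value_cols(expr), samples$sample_id)
  if (length(keep_samples) == 0) {
    stop("no samples shared between expression matrix and sample table",
         call. = FALSE)
  }
  expr <- expr[c("transcript_id", keep_samples)]
  samples <- samples[samples$sample_id %in% keep_samples, , drop = FALSE]
  if (!is.null(annot)) {
    known <- expr$transcript_id %in% annot$transcript_id
    n_un <- sum(!known)
    if (n_un > 0) {
      message(n_un, " transcript(s) without annotation: ", unannotated, "ed")
      if (unannotated == "drop") {
        expr <- expr[known, , drop = FALSE]
      } else {
        annot <- dplyr::bind_rows(
          annot,
          tibble::tibble(transcript_id = expr$transcript_id[!known],
                         raw_biotype = "unannotated"))
      }
    }
    if (nrow(expr) == 0) {
      stop("no transcripts shared between expression matrix and annotation",
           call. = FALSE)
    }
    annot <- annot[match(expr$transcript_id, annot$transcript_id), , drop = FALSE]
  }
  structure(list(expression = expr, samples = samples, annotation = annot),
            class = "tissue_dataset")
}

#' @export
print.tissue_dataset <- function(x, ...) {
  cat("<tissue_dataset> ", nrow(x$expression), " transcripts x ",
      length(value_cols(x$expression)), " samples (",
      dplyr::n_distinct(x$samples$tissue), " tissues)\n", sep = "")
  if (!is.null(x$annotation)) {
    cat("  annotated biotypes: ", dplyr::n_distinct(x$annotation$raw_biotype),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read and write gene sets in GMT format
#'
#' GMT is tab-delimited: set name, description, then one member per field.
#'
#' @param path Path to a GMT file.
#' @return `read_gmt()`: a tibble with columns `name`, `description`, and a
#'   list-column `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    name = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(out$name)) stop("duplicated gene-set names in GMT", call. = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets Gene-set tibble (`name`, `description`, list-column `genes`).
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(c("name", "description", "genes") %in% names(sets)))
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$name[i], sets$description[i], sets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
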