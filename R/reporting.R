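#' Principal component analysis of samples
#'
#' PCA of the samples on transcript-centred log2 expression values
#' (no per-transcript scaling). Component signs are fixed by convention:
#' the largest-magnitude loading of each component is made positive, so
#' coordinates are fully deterministic.
#'
#' @param expr_log Log-scale expression tibble (`transcript_id` + sample
#'   columns); at least 2 samples.
#' @param samples Optional sample table; when given, tissue and site are
#'   attached to the scores.
#' @return An object of class `sample_pca`: list with `scores` (tibble
#'   `sample_id`, `PC1`, `PC2`, ...), `var_explained` (fractions), and
#'   `sdev`.
#' @export
pca_samples <- function(expr_log, samples = NULL) {
  m <- expr_to_matrix(expr_log)
  if (ncol(m) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  if (all(apply(m, 1, sd) == 0)) {
    stop("constant expression matrix: PCA undefined", call. = FALSE)
  }
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = colnames(m)),
                             tibble::as_tibble(pc$x))
  if (!is.null(samples)) {
    scores <- dplyr::left_join(scores, samples, by = "sample_id") |>
      dplyr::relocate("sample_id", "tissue", "site")
  }
  structure(list(scores = scores,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev),
            class = "sample_pca")
}

#' @export
print.sample_pca <- function(x, ...) {
  cat("<sample_pca> ", nrow(x$scores), " samples; PC1 ",
      round(100 * x$var_explained[1], 1), "%, PC2 ",
      round(100 * x$var_explained[2], 1), "% of variance\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Average-linkage clustering of samples on `1 - Pearson` correlation of
#' log2 expression profiles. Samples are ordered lexicographically before
#' clustering so ties in merge heights resolve deterministically.
#'
#' @param expr_log Log-scale expression tibble; at least 3 samples.
#' @param linkage Agglomeration method (default `"average"`).
#' @return An [stats::hclust] object over the samples.
#' @export
cluster_samples <- function(expr_log, linkage = "average") {
  m <- expr_to_matrix(expr_log)
  if (ncol(m) < 3) stop("sample clustering needs at least 3 samples", call. = FALSE)
  m <- m[, order(colnames(m)), drop = FALSE]
  d <- 1 - cor(m)
  hclust(as.dist(d), method = linkage)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on a bound dataset: replicate aggregation,
#' low-expression filtering, biotype classification, tissue-specificity
#' calling, Z-scored heatmap matrix, co-expression network with module
#' detection and hub extraction (on the union of the calls, over all
#' libraries), optional gene-set enrichment per tissue, and sample-level
#' reports (PCA, clustering, replicate concordance). All tables are
#' written to `out_dir` with provenance headers, together with a JSON run
#' manifest (parameters, package version, seed, file checksums) that
#' allows an exact rerun.
#'
#' @param dataset A `tissue_dataset` from [bind_dataset()] or a
#'   `tissue_simulation` (its expression/samples/annotation are used).
#' @param out_dir Output directory.
#' @param gene_sets Optional gene sets (tibble or named list) for
#'   enrichment of each tissue's calls.
#' @param pseudocount,filter_threshold,expressed_threshold,fold_threshold
#'   Transform and specificity parameters (defaults 0.1, 1, 1, 2).
#' @param beta,min_module_size,cut_height,n_hubs Network parameters
#'   (defaults 20, 60, 0.995, 30).
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisibly, a list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(dataset, out_dir, gene_sets = NULL,
                         pseudocount = 0.1, filter_threshold = 1,
                         expressed_threshold = 1, fold_threshold = 2,
                         beta = 20, min_module_size = 60, cut_height = 0.995,
                         n_hubs = 30, seed = NULL) {
  if (inherits(dataset, "tissue_simulation")) {
    dataset <- bind_dataset(dataset$expression, dataset$samples,
                            dataset$annotation)
  }
  stopifnot(inherits(dataset, "tissue_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(pseudocount = pseudocount, filter_threshold = filter_threshold,
                 expressed_threshold = expressed_threshold,
                 fold_threshold = fold_threshold, beta = beta,
                 min_module_size = min_module_size, cut_height = cut_height,
                 n_hubs = n_hubs)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()
  annot <- stage("classify", classify_biotypes(dataset$annotation))
  tm <- stage("aggregate", aggregate_replicates(dataset$expression,
                                                dataset$samples, pseudocount))
  filt <- stage("filter", filter_low_expression(tm, pseudocount, filter_threshold))
  res$expressed_counts <- stage("expressed",
    count_expressed(dataset$expression, annot, expressed_threshold))
  res$concordance <- stage("concordance",
    replicate_concordance(dataset$expression, dataset$samples, annot))
  res$class_table <- stage("classify",
    tabulate_classes(annot, restrict_to = filt$retained$transcript_id))
  res$calls <- stage("specific",
    call_specific(filt$retained, annot, fold_threshold, pseudocount))
  res$specific_counts <- count_specific(res$calls)
  tm_log <- log_transform(filt$retained, pseudocount)
  res$zscores <- stage("zscore", zscore_matrix(tm_log, res$calls))

  called_ids <- res$calls$transcript_id[!is.na(res$calls$specific_tissue)]
  expr_log <- log_transform(
    dataset$expression[dataset$expression$transcript_id %in% called_ids, ,
                       drop = FALSE], pseudocount)
  res$network <- stage("network", {
    adj <- adjacency_matrix(expr_log, beta)
    tom <- topological_overlap(adj)
    modules <- detect_modules(tom$dissim, min_module_size, cut_height)
    hubs <- if (any(modules$assignments$module > 0)) {
      extract_hubs(adj, modules, n_hubs, tom = tom$tom)
    }
    list(modules = modules, hubs = hubs,
         composition = module_class_composition(modules, res$calls))
  })
  if (!is.null(gene_sets)) {
    res$enrichment <- stage("enrich", {
      universe <- filt$retained$transcript_id
      hits <- res$calls[!is.na(res$calls$specific_tissue), , drop = FALSE]
      purrr::map_dfr(unique(hits$specific_tissue), function(tis) {
        dplyr::mutate(
          hypergeometric_enrich(hits$transcript_id[hits$specific_tissue == tis],
                                gene_sets, universe),
          tissue = tis, .before = 1)
      })
    })
  }
  res$pca <- stage("report", pca_samples(log_transform(dataset$expression,
                                                       pseudocount),
                                         dataset$samples))
  res$sample_tree <- stage("report",
    cluster_samples(log_transform(dataset$expression, pseudocount)))

  wt <- function(x, file, stg) write_table_with_provenance(
    x, file.path(out_dir, file), stg, params)
  wt(filt$retained, "tissue_matrix_filtered.tsv", "filter")
  writeLines(filt$removed_ids, file.path(out_dir, "removed_transcripts.txt"))
  wt(res$expressed_counts, "expressed_counts.tsv", "expressed")
  wt(res$concordance, "replicate_concordance.tsv", "concordance")
  wt(res$class_table, "biotype_classes.tsv", "classify")
  wt(res$calls[!is.na(res$calls$specific_tissue), ], "specificity_calls.tsv",
     "specific")
  wt(res$specific_counts, "specificity_counts.tsv", "specific")
  wt(res$zscores, "heatmap_zscores.tsv", "zscore")
  wt(res$network$modules$assignments, "module_assignments.tsv", "network")
  wt(res$network$composition, "module_composition.tsv", "network")
  if (!is.null(res$network$hubs)) {
    wt(res$network$hubs$hubs, "hub_transcripts.tsv", "network")
    write_visant_edges(res$network$hubs$edges,
                       file.path(out_dir, "hub_edges_visant.txt"))
  }
  if (!is.null(res$enrichment)) wt(res$enrichment, "enrichment.tsv", "enrich")
  wt(res$pca$scores, "pca_scores.tsv", "report")

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package = "tissuespec",
    version = as.character(packageVersion("tissuespec")),
    r_version = as.character(getRversion()),
    seed = seed, params = params,
    n_transcripts = nrow(dataset$expression),
    n_samples = nrow(dataset$samples),
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
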