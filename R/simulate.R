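#' Simulation configuration
#'
#' Defines the study design the generator emulates: `n_tissues` tissues
#' each sequenced as `n_sites` technical replicates, a log2-normal baseline
#' of FPKM values, a majority protein-coding / minority noncoding biotype
#' mix, planted tissue-specific transcripts at a controlled fold change,
#' per-tissue co-expressed transcript blocks driven by shared latent
#' factors, and a fraction of never-expressed transcripts. Defaults mirror
#' a 14-tissue, two-site design with 5,000 transcripts (93.7% coding), 40
#' planted specifics per tissue at fold 8, co-expression blocks of 80 per
#' tissue, and log2 replicate noise of 0.1.
#'
#' @param n_tissues,n_sites Number of tissues and technical replicates per
#'   tissue.
#' @param n_coding,n_noncoding Number of protein-coding / noncoding
#'   transcripts.
#' @param biotype_proportions Named fractions (summing to 1) of raw
#'   noncoding biotypes.
#' @param n_specific_per_tissue Planted tissue-specific transcripts per
#'   tissue.
#' @param specific_fold Multiplicative effect (FPKM scale, >= 1) of a
#'   planted specific transcript in its tissue.
#' @param module_size_per_tissue Planted co-expression block size per
#'   tissue (disjoint from the planted specifics).
#' @param module_factor_sd Standard deviation (log2 scale) of the
#'   per-tissue latent factor shared by a block's members.
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2-FPKM
#'   distribution.
#' @param replicate_noise_sd Log2-scale independent site noise.
#' @param dropout_fraction Fraction of unplanted transcripts forced to zero
#'   FPKM in every sample.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 14, n_sites = 2,
                       n_coding = 4685, n_noncoding = 315,
                       biotype_proportions = default_biotype_proportions(),
                       n_specific_per_tissue = 40, specific_fold = 8,
                       module_size_per_tissue = 80, module_factor_sd = 0.5,
                       baseline_log2_mean = 3, baseline_log2_sd = 1.5,
                       replicate_noise_sd = 0.1, dropout_fraction = 0.15,
                       seed = 42) {
  cfg <- list(n_tissues = n_tissues, n_sites = n_sites, n_coding = n_coding,
              n_noncoding = n_noncoding,
              biotype_proportions = biotype_proportions,
              n_specific_per_tissue = n_specific_per_tissue,
              specific_fold = specific_fold,
              module_size_per_tissue = module_size_per_tissue,
              module_factor_sd = module_factor_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              replicate_noise_sd = replicate_noise_sd,
              dropout_fraction = dropout_fraction, seed = as.integer(seed))
  counts <- c("n_tissues", "n_sites", "n_coding", "n_noncoding",
              "n_specific_per_tissue", "module_size_per_tissue")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || is.na(v) || v < 0 || v != round(v)) {
      stop("configuration error: ", nm, " must be a non-negative integer",
           call. = FALSE)
    }
  }
  if (cfg$n_tissues < 1 || cfg$n_sites < 1) {
    stop("configuration error: need at least one tissue and one site", call. = FALSE)
  }
  if (cfg$n_coding + cfg$n_noncoding < 1) {
    stop("configuration error: total transcript count must be positive",
         call. = FALSE)
  }
  if (cfg$specific_fold < 1) {
    stop("configuration error: specific_fold must be >= 1", call. = FALSE)
  }
  bp <- cfg$biotype_proportions
  if (cfg$n_noncoding > 0) {
    if (is.null(names(bp)) || any(bp < 0) || any(bp > 1) ||
        abs(sum(bp) - 1) > 1e-8) {
      stop("configuration error: biotype_proportions must be named fractions ",
           "in [0, 1] summing to 1", call. = FALSE)
    }
  }
  if (cfg$dropout_fraction < 0 || cfg$dropout_fraction > 1) {
    stop("configuration error: dropout_fraction must be in [0, 1]", call. = FALSE)
  }
  if (cfg$replicate_noise_sd < 0 || cfg$module_factor_sd < 0 ||
      cfg$baseline_log2_sd < 0) {
    stop("configuration error: standard deviations must be >= 0", call. = FALSE)
  }
  n_planted <- cfg$n_tissues * (cfg$n_specific_per_tissue + cfg$module_size_per_tissue)
  if (n_planted > cfg$n_coding + cfg$n_noncoding) {
    stop("configuration error: planted specifics + module members (", n_planted,
         ") exceed the transcript count", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default raw-biotype proportions for simulated noncoding transcripts
#'
#' Fractions of raw Ensembl-style biotypes among noncoding transcripts,
#' dominated by processed transcripts, lincRNAs, and pseudogene variants,
#' with a tail of rarer classes; pseudogene variants and IG/TR biotypes are
#' included so the merge rules are exercised.
#'
#' @return A named numeric vector summing to 1.
#' @export
default_biotype_proportions <- function() {
  c(processed_transcript = 0.56, lincRNA = 0.20,
    processed_pseudogene = 0.10, unprocessed_pseudogene = 0.04,
    miRNA_pseudogene = 0.02, IG_pseudogene = 0.01,
    misc_RNA = 0.02, snoRNA = 0.01, miRNA = 0.01, snRNA = 0.01,
    antisense = 0.01, IG_C_gene = 0.005, TR_V_gene = 0.005)
}

#' Simulate a multi-tissue FPKM matrix with planted ground truth
#'
#' Generates `n_tissues * n_sites` libraries over
#' `n_coding + n_noncoding` transcripts. On the log2 scale, a transcript's
#' value is its baseline (drawn once per transcript from
#' `N(baseline_log2_mean, baseline_log2_sd)`), plus `log2(specific_fold)`
#' in its planted tissue if it is a planted specific, plus its tissue
#' block's latent factor (a per-tissue level drawn from
#' `N(0, module_factor_sd)`, shared by a tissue's replicates) if it is a
#' planted block member, plus independent per-library Gaussian noise of sd
#' `replicate_noise_sd`. FPKM is `2^value`; a `dropout_fraction` of the
#' unplanted transcripts is then set to zero FPKM everywhere. Because the
#' latent factor is shared by a tissue's replicates, setting
#' `replicate_noise_sd = 0` makes a tissue's site columns identical.
#'
#' @param config A [sim_config()].
#' @return A list of class `tissue_simulation` with elements `expression`
#'   (FPKM tibble), `samples`, `annotation` (`transcript_id`,
#'   `raw_biotype`), and `truth` (see Details).
#' @details `truth` is a list with `specific_of` (tibble `transcript_id`,
#'   `tissue`), `module_of` (tibble `transcript_id`, `tissue`),
#'   `dropout_ids`, `tissue_fpkm` (the noise-free tissue-level FPKM
#'   tibble), and the `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_coding + cfg$n_noncoding
  ids <- sprintf("TX%05d", seq_len(n))
  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  samples <- tidyr::expand_grid(tissue = tissues,
                                site = sprintf("site%d", seq_len(cfg$n_sites))) |>
    dplyr::mutate(sample_id = paste(.data$tissue, .data$site, sep = "_")) |>
    dplyr::select("sample_id", "tissue", "site")

  with_rng_seed(cfg$seed, {
    raw_biotype <- c(rep("protein_coding", cfg$n_coding),
                     if (cfg$n_noncoding > 0)
                       sample(names(cfg$biotype_proportions), cfg$n_noncoding,
                              replace = TRUE, prob = cfg$biotype_proportions))
    baseline <- rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)

    per_tissue <- cfg$n_specific_per_tissue + cfg$module_size_per_tissue
    pool <- if (per_tissue > 0) sample.int(n, cfg$n_tissues * per_tissue) else integer()
    spec_idx <- vector("list", cfg$n_tissues)
    memb_idx <- vector("list", cfg$n_tissues)
    for (t in seq_len(cfg$n_tissues)) {
      block <- pool[((t - 1) * per_tissue + 1):(t * per_tissue)]
      spec_idx[[t]] <- head(block, cfg$n_specific_per_tissue)
      memb_idx[[t]] <- block[seq_len(cfg$module_size_per_tissue) +
                               cfg$n_specific_per_tissue]
    }

    # tissue-level log2 truth: baseline + spike + latent factor
    tl <- matrix(baseline, n, cfg$n_tissues, dimnames = list(ids, tissues))
    for (t in seq_len(cfg$n_tissues)) {
      tl[spec_idx[[t]], t] <- tl[spec_idx[[t]], t] + log2(cfg$specific_fold)
      if (length(memb_idx[[t]]) > 0 && cfg$module_factor_sd > 0) {
        factor_t <- rnorm(cfg$n_tissues, 0, cfg$module_factor_sd)
        # A block is co-expressed, not tissue-specific: cap the factor's
        # top-tissue excursion at 0.6 log2 above the runner-up so that no
        # member (loading <= 1.25) can reach a 2-fold tissue gap.
        if (cfg$n_tissues >= 2) {
          o <- order(factor_t, decreasing = TRUE)
          factor_t[o[1]] <- min(factor_t[o[1]], factor_t[o[2]] + 0.6)
        }
        loading <- runif(length(memb_idx[[t]]), 0.75, 1.25)
        tl[memb_idx[[t]], ] <- tl[memb_idx[[t]], ] + outer(loading, factor_t)
      }
    }

    # expand to libraries and add site noise
    e <- tl[, rep(seq_len(cfg$n_tissues), each = cfg$n_sites), drop = FALSE]
    colnames(e) <- samples$sample_id
    if (cfg$replicate_noise_sd > 0) {
      e <- e + matrix(rnorm(length(e), 0, cfg$replicate_noise_sd), nrow(e))
    }

    planted <- unique(unlist(c(spec_idx, memb_idx)))
    unplanted <- setdiff(seq_len(n), planted)
    n_drop <- round(cfg$dropout_fraction * length(unplanted))
    drop_idx <- if (n_drop > 0) sample(unplanted, n_drop) else integer()

    fpkm <- 2^e
    fpkm[drop_idx, ] <- 0
    tissue_fpkm <- 2^tl
    tissue_fpkm[drop_idx, ] <- 0

    truth <- list(
      specific_of = tibble::tibble(
        transcript_id = ids[unlist(spec_idx)],
        tissue = rep(tissues, vapply(spec_idx, length, integer(1)))),
      module_of = tibble::tibble(
        transcript_id = ids[unlist(memb_idx)],
        tissue = rep(tissues, vapply(memb_idx, length, integer(1)))),
      dropout_ids = ids[sort(drop_idx)],
      tissue_fpkm = matrix_to_expr(tissue_fpkm),
      config = cfg
    )

    structure(list(
      expression = matrix_to_expr(fpkm),
      samples = samples,
      annotation = tibble::tibble(transcript_id = ids, raw_biotype = raw_biotype),
      truth = truth
    ), class = "tissue_simulation")
  })
}

#' @export
print.tissue_simulation <- function(x, ...) {
  cfg <- x$truth$config
  cat("<tissue_simulation> ", nrow(x$expression), " transcripts x ",
      nrow(x$samples), " libraries (", cfg$n_tissues, " tissues x ",
      cfg$n_sites, " sites), seed ", cfg$seed, "\n",
      "  planted: ", nrow(x$truth$specific_of), " specific, ",
      nrow(x$truth$module_of), " module members, ",
      length(x$truth$dropout_ids), " dropouts\n", sep = "")
  invisible(x)
}

#' Simulate gene sets enriched in planted tissue-specific transcripts
#'
#' Builds `n_sets` GMT-compatible gene sets from a simulation's ground
#' truth. The first sets (one per tissue, up to `n_sets`) contain that
#' tissue's planted specific transcripts plus a handful of random decoys,
#' so each is strongly enriched in the corresponding tissue's calls; any
#' remaining sets are random draws from all transcripts.
#'
#' @param truth The `truth` element of a [simulate_expression()] result
#'   (or the whole `tissue_simulation`).
#' @param n_sets Number of sets (>= 1).
#' @param seed Integer seed.
#' @param n_decoys Random decoy members added to each tissue set
#'   (default 10).
#' @return A gene-set tibble (`name`, `description`, list-column `genes`)
#'   suitable for [write_gmt()] and [hypergeometric_enrich()].
#' @export
simulate_gene_sets <- function(truth, n_sets, seed = 1, n_decoys = 10) {
  if (inherits(truth, "tissue_simulation")) truth <- truth$truth
  if (n_sets < 1) stop("n_sets must be >= 1", call. = FALSE)
  if (nrow(truth$specific_of) == 0) {
    stop("truth has no planted specific transcripts", call. = FALSE)
  }
  all_ids <- truth$tissue_fpkm$transcript_id
  tissues <- unique(truth$specific_of$tissue)
  with_rng_seed(seed, {
    sets <- purrr::map(seq_len(n_sets), function(k) {
      if (k <= length(tissues)) {
        tis <- tissues[k]
        members <- truth$specific_of$transcript_id[truth$specific_of$tissue == tis]
        decoys <- sample(setdiff(all_ids, members), min(n_decoys,
                                                        length(all_ids) - length(members)))
        list(name = paste0(tis, "_markers"),
             description = paste0("planted specific transcripts of ", tis,
                                  " plus ", length(decoys), " decoys"),
             genes = c(members, decoys))
      } else {
        size <- sample(20:60, 1)
        list(name = sprintf("random_set_%02d", k - length(tissues)),
             description = "random background set",
             genes = sample(all_ids, min(size, length(all_ids))))
      }
    })
    out <- tibble::tibble(
      name = purrr::map_chr(sets, "name"),
      description = purrr::map_chr(sets, "description"),
      genes = purrr::map(sets, "genes")
    )
    stopifnot(all(lengths(out$genes) >= 2))
    out
  })
}

#' Write all simulation outputs to a directory
#'
#' Emits `expression.tsv`, `samples.tsv`, `annotation.tsv`,
#' `annotation.gtf`, and the ground-truth tables
#' (`truth_specific.tsv`, `truth_modules.tsv`, `truth_dropouts.tsv`).
#'
#' @param sim A `tissue_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tissue_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(sim$expression, file.path(dir, "expression.tsv"))
  write_sample_table(sim$samples, file.path(dir, "samples.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_annotation_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  readr::write_tsv(sim$truth$specific_of, file.path(dir, "truth_specific.tsv"))
  readr::write_tsv(sim$truth$module_of, file.path(dir, "truth_modules.tsv"))
  writeLines(sim$truth$dropout_ids, file.path(dir, "truth_dropouts.tsv"))
  invisible(dir)
}
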