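#' Soft-threshold adjacency matrix
#'
#' Connection strength between transcripts i and j is
#' `a_ij = |cor(x_i, x_j)|^beta`, the unsigned weighted-network adjacency
#' with Pearson correlation computed across all samples. Raising the
#' correlation to a large power `beta` suppresses weak correlations and
#' yields an approximately scale-free network.
#'
#' @param expr_log Log-scale expression tibble (`transcript_id` + sample
#'   columns) or a numeric matrix with transcripts as rows; at least 3
#'   samples. Zero-variance transcripts must be removed beforehand.
#' @param beta Soft-thresholding power (integer >= 1, default 20).
#' @return A symmetric numeric matrix in `[0, 1]` with unit diagonal and
#'   transcript ids as dimnames.
#' @export
adjacency_matrix <- function(expr_log, beta = 20) {
  if (beta < 1 || beta != round(beta)) {
    stop("beta must be an integer >= 1", call. = FALSE)
  }
  m <- if (is.matrix(expr_log)) expr_log else expr_to_matrix(expr_log)
  if (ncol(m) < 3) stop("adjacency needs at least 3 samples", call. = FALSE)
  rsd <- apply(m, 1, sd)
  if (any(rsd == 0)) {
    stop("zero-variance transcript(s) present (remove before building the ",
         "network): ", paste(head(rownames(m)[rsd == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  a <- abs(cor(t(m)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix and dissimilarity
#'
#' Unsigned topological overlap:
#' `TOM_ij = (sum_{u != i,j} a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k_i = sum_{u != i} a_iu`, and `TOM_ii = 1`. Two nodes
#' have high overlap when they are strongly connected to each other and
#' share the same neighbours; `1 - TOM` is the clustering dissimilarity.
#'
#' @param adj Adjacency matrix from [adjacency_matrix()].
#' @return A list with symmetric matrices `tom` and `dissim` (`1 - tom`),
#'   both in `[0, 1]`.
#' @export
topological_overlap <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (max(abs(adj - t(adj))) > 1e-10) stop("adjacency must be symmetric", call. = FALSE)
  if (min(adj) < 0 || max(adj) > 1 + 1e-12) {
    stop("adjacency values must lie in [0, 1]", call. = FALSE)
  }
  k <- rowSums(adj) - diag(adj)
  # shared-neighbour sum: sum_{u != i,j} a_iu a_uj = (A^2)_ij - a_ii a_ij - a_ij a_jj
  num <- adj %*% adj - 2 * adj + adj          # + a_ij back into the numerator
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- num / denom
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1) # symmetrize away float noise
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  list(tom = tom, dissim = 1 - tom)
}

#' Detect co-expression modules by average-linkage clustering of TOM
#' dissimilarity
#'
#' Builds an average-linkage dendrogram on the topological overlap
#' dissimilarity and cuts it at a fixed height: every branch below
#' `cut_height` with at least `min_module_size` leaves becomes a module;
#' all remaining transcripts are left unassigned (module 0, conventionally
#' drawn gray). Module labels are integers ordered by decreasing size.
#' This is the static-height tree cut; see the methods vignette for why the
#' dynamic-hybrid variant is not used.
#'
#' @param dissim Square symmetric dissimilarity matrix (`1 - TOM`).
#' @param min_module_size Minimum transcripts per module (default 60).
#' @param cut_height Dendrogram cut height in `(0, 1]` (default 0.995).
#' @return An object of class `coexpression_modules`: a list with
#'   `assignments` (tibble `transcript_id`, `module`), `tree` (the
#'   `hclust`), and `params`.
#' @export
detect_modules <- function(dissim, min_module_size = 60, cut_height = 0.995) {
  stopifnot(is.matrix(dissim), nrow(dissim) == ncol(dissim))
  if (min_module_size < 2) stop("min_module_size must be >= 2", call. = FALSE)
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]",
                                              call. = FALSE)
  ids <- rownames(dissim)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dissim)))
  if (nrow(dissim) < 2 || nrow(dissim) < min_module_size) {
    warning("fewer transcripts than min_module_size; all unassigned")
    return(structure(list(
      assignments = tibble::tibble(transcript_id = ids, module = 0L),
      tree = NULL,
      params = list(min_module_size = min_module_size, cut_height = cut_height)),
      class = "coexpression_modules"))
  }
  hc <- hclust(as.dist(dissim), method = "average")
  # average linkage is monotone; float noise can still leave neighbouring
  # merge heights out of order by ~1e-16, which cutree(h = ) refuses
  if (is.unsorted(hc$height)) {
    stopifnot(max(-diff(hc$height)) < 1e-8)
    hc$height <- cummax(hc$height)
  }
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # relabel kept clusters 1..K by decreasing size (ties: lower original label)
  big <- big[order(-sizes[big], as.integer(big))]
  module <- integer(length(cl))
  for (i in seq_along(big)) module[cl == big[i]] <- i
  structure(list(
    assignments = tibble::tibble(transcript_id = ids, module = module),
    tree = hc,
    params = list(min_module_size = min_module_size, cut_height = cut_height)),
    class = "coexpression_modules")
}

#' @export
print.coexpression_modules <- function(x, ...) {
  n_mod <- max(x$assignments$module)
  cat("<coexpression_modules> ", nrow(x$assignments), " transcripts, ",
      n_mod, " module(s), ", sum(x$assignments$module == 0L),
      " unassigned (gray)\n", sep = "")
  invisible(x)
}

#' Intramodular connectivity
#'
#' For each transcript assigned to a module, the sum of its adjacency to
#' the other members of the same module (`kWithin`). Unassigned (gray)
#' transcripts get `NA`.
#'
#' @param adj Adjacency matrix.
#' @param modules `coexpression_modules` object.
#' @return The assignment tibble with `k_within` added.
#' @export
module_connectivity <- function(adj, modules) {
  asg <- modules$assignments
  stopifnot(all(asg$transcript_id %in% rownames(adj)))
  k <- rep(NA_real_, nrow(asg))
  for (mod in setdiff(unique(asg$module), 0L)) {
    members <- asg$transcript_id[asg$module == mod]
    sub <- adj[members, members, drop = FALSE]
    k[asg$module == mod] <- rowSums(sub) - diag(sub)
  }
  dplyr::mutate(asg, k_within = k)
}

#' Extract hub transcripts and their edge list
#'
#' Hubs are each module's top transcripts by intramodular connectivity.
#' For every module the hub-hub edges are emitted in VisANT-style text
#' format (`node1`, `node2`, direction flag 0, method tag `M1000`, weight);
#' the edge weight is the topological overlap when `tom` is given,
#' otherwise the adjacency.
#'
#' @param adj Adjacency matrix.
#' @param modules `coexpression_modules` object.
#' @param n_hubs Hubs per module (default 30); smaller modules return all
#'   members with a warning.
#' @param tom Optional TOM matrix for edge weights.
#' @return A list with `hubs` (tibble `transcript_id`, `module`,
#'   `k_within`, `hub_rank`) and `edges` (tibble `node1`, `node2`,
#'   `direction`, `method`, `weight`, `module`).
#' @export
extract_hubs <- function(adj, modules, n_hubs = 30, tom = NULL) {
  conn <- module_connectivity(adj, modules)
  mods <- setdiff(sort(unique(conn$module)), 0L)
  if (length(mods) == 0) stop("no non-gray module to extract hubs from", call. = FALSE)
  w <- if (is.null(tom)) adj else tom
  res <- purrr::map(mods, function(mod) {
    mem <- conn[conn$module == mod, , drop = FALSE]
    mem <- mem[order(-mem$k_within, mem$transcript_id), , drop = FALSE]
    if (nrow(mem) < n_hubs) {
      warning("module ", mod, " has only ", nrow(mem), " member(s); returning all")
    }
    hubs <- head(mem, n_hubs)
    hubs$hub_rank <- seq_len(nrow(hubs))
    ids <- hubs$transcript_id
    edges <- if (length(ids) >= 2) {
      pairs <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
      tibble::tibble(node1 = ids[pairs[, 1]], node2 = ids[pairs[, 2]],
                     direction = 0L, method = "M1000",
                     weight = w[cbind(ids[pairs[, 1]], ids[pairs[, 2]])],
                     module = mod)
    } else {
      tibble::tibble(node1 = character(), node2 = character(),
                     direction = integer(), method = character(),
                     weight = double(), module = integer())
    }
    list(hubs = hubs, edges = edges)
  })
  list(hubs = purrr::list_rbind(purrr::map(res, "hubs")),
       edges = purrr::list_rbind(purrr::map(res, "edges")))
}

#' Write a VisANT-style edge list
#'
#' Tab-delimited, no header: node1, node2, direction flag, method tag,
#' weight.
#'
#' @param edges Edge tibble from [extract_hubs()].
#' @param path Output path.
#' @export
write_visant_edges <- function(edges, path) {
  readr::write_tsv(edges[c("node1", "node2", "direction", "method", "weight")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Module composition by specificity class and tissue
#'
#' Cross-tabulates module membership with specificity calls: per module,
#' the number of TSCTs and TSNTs and the dominant tissue (the modal
#' `specific_tissue` of its members, with its purity). Used to check that
#' transcripts specific to the same tissue land in the same module.
#'
#' @param modules `coexpression_modules` object.
#' @param calls Call tibble from [call_specific()].
#' @return A tibble `module`, `n`, `n_TSCT`, `n_TSNT`, `dominant_tissue`,
#'   `purity`.
#' @export
module_class_composition <- function(modules, calls) {
  asg <- modules$assignments
  joined <- dplyr::left_join(asg, calls, by = "transcript_id")
  mods <- setdiff(sort(unique(asg$module)), 0L)
  purrr::map_dfr(mods, function(mod) {
    sub <- joined[joined$module == mod, , drop = FALSE]
    tis <- sub$specific_tissue[!is.na(sub$specific_tissue)]
    tab <- sort(table(tis), decreasing = TRUE)
    tibble::tibble(
      module = mod, n = nrow(sub),
      n_TSCT = sum(sub$class == "TSCT", na.rm = TRUE),
      n_TSNT = sum(sub$class == "TSNT", na.rm = TRUE),
      dominant_tissue = if (length(tab) > 0) names(tab)[1] else NA_character_,
      purity = if (length(tab) > 0) as.numeric(tab[1]) / nrow(sub) else NA_real_
    )
  })
}
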