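# broom-style tidiers for the package's result objects.

#' Tidy a sample PCA
#'
#' @param x A `sample_pca` object.
#' @param ... Unused.
#' @return The per-sample score tibble.
#' @export
tidy.sample_pca <- function(x, ...) x$scores

#' @rdname tidy.sample_pca
#' @return `glance()`: one-row tibble with the number of samples and the
#'   variance fractions of the first two components.
#' @export
glance.sample_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 var_pc1 = x$var_explained[1],
                 var_pc2 = if (length(x$var_explained) > 1)
                   x$var_explained[2] else NA_real_,
                 var_top2 = sum(x$var_explained[seq_len(min(2, length(x$var_explained)))]))
}

#' Tidy a module assignment
#'
#' @param x A `coexpression_modules` object.
#' @param ... Unused.
#' @return The per-transcript assignment tibble (`module` 0 = unassigned).
#' @export
tidy.coexpression_modules <- function(x, ...) x$assignments

#' @rdname tidy.coexpression_modules
#' @return `glance()`: one-row tibble with transcript, module, and
#'   unassigned counts plus the cut parameters.
#' @export
glance.coexpression_modules <- function(x, ...) {
  tibble::tibble(n_transcripts = nrow(x$assignments),
                 n_modules = max(x$assignments$module),
                 n_unassigned = sum(x$assignments$module == 0L),
                 min_module_size = x$params$min_module_size,
                 cut_height = x$params$cut_height)
}
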