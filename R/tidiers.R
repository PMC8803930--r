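#' Tidy a PLS-DA ordination
#'
#' @param x A `regen_plsda` object.
#' @param ... Unused.
#' @return Scores as a tibble: `sample_id`, `group`, `comp1`, ...
#' @method tidy regen_plsda
#' @export
tidy.regen_plsda <- function(x, ...) {
  x$scores
}

#' One-row summary of a PLS-DA ordination
#'
#' @param x A `regen_plsda` object.
#' @param ... Unused.
#' @return A tibble with `n_components`, cumulative `r2x` and `r2y`.
#' @method glance regen_plsda
#' @export
glance.regen_plsda <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    r2x = sum(x$r2x),
    r2y = sum(x$r2y)
  )
}

#' Tidy a model-similarity tree
#'
#' @param x A `model_tree` object.
#' @param ... Unused.
#' @return Merge steps as a tibble: `step`, `height`, and negative
#'   (leaf) or positive (cluster) merge indices as in
#'   [stats::hclust()].
#' @method tidy model_tree
#' @export
tidy.model_tree <- function(x, ...) {
  h <- x$hclust
  tibble::tibble(
    step = seq_along(h$height),
    merge1 = h$merge[, 1L],
    merge2 = h$merge[, 2L],
    height = h$height
  )
}

#' One-row summary of a model-similarity tree
#'
#' @param x A `model_tree` object.
#' @param ... Unused.
#' @return A tibble with the number of models, metric and linkage.
#' @method glance model_tree
#' @export
glance.model_tree <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$hclust$labels),
    metric = x$metric,
    linkage = x$linkage,
    max_height = max(x$hclust$height)
  )
}

#' Tidy a permutation-correlation result
#'
#' @param x A `perm_cor` object.
#' @param ... Unused.
#' @return A long tibble of metabolite pairs (upper triangle):
#'   `feature_a`, `feature_b`, `observed_r`, `mean_perm_r`,
#'   `empirical_p`.
#' @method tidy perm_cor
#' @export
tidy.perm_cor <- function(x, ...) {
  idx <- which(upper.tri(x$observed), arr.ind = TRUE)
  tibble::tibble(
    feature_a = rownames(x$observed)[idx[, 1L]],
    feature_b = colnames(x$observed)[idx[, 2L]],
    observed_r = x$observed[idx],
    mean_perm_r = x$mean_cor[idx],
    empirical_p = x$p_value[idx]
  )
}
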