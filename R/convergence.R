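#' Cross-model direction matrix
#'
#' Recodes per-model contrast results into a metabolite-by-model table
#' of signed significance: +1 significant up, -1 significant down, 0
#' tested but not significant, `NA` untested in that model. Per-feature
#' support counts and the largest supporting |log2FC| per direction are
#' appended for candidate ranking.
#'
#' @param results Named list of contrast-result tibbles; names are
#'   model ids (must be unique).
#' @return A tibble of class `convergence_tbl`: `feature_id`, one
#'   integer column per model, `up_count`, `down_count`, `max_up_lfc`,
#'   `max_down_lfc`.
#' @export
build_direction_matrix <- function(results) {
  if (length(results) < 2L) {
    stop("need contrast results from at least 2 models", call. = FALSE)
  }
  if (is.null(names(results)) || anyDuplicated(names(results))) {
    stop("results must be uniquely named by model id", call. = FALSE)
  }
  long <- purrr::imap_dfr(results, function(tbl, model_id) {
    tibble::tibble(
      feature_id = tbl$feature_id,
      model_id = model_id,
      code = dplyr::case_when(
        tbl$significant & tbl$direction == "up" ~ 1L,
        tbl$significant & tbl$direction == "down" ~ -1L,
        .default = 0L
      ),
      log2fc = tbl$log2fc
    )
  })
  counts <- long |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      up_count = sum(.data$code == 1L),
      down_count = sum(.data$code == -1L),
      max_up_lfc = ifelse(any(.data$code == 1L),
                          max(abs(.data$log2fc[.data$code == 1L]),
                              na.rm = TRUE), NA_real_),
      max_down_lfc = ifelse(any(.data$code == -1L),
                            max(abs(.data$log2fc[.data$code == -1L]),
                                na.rm = TRUE), NA_real_),
      .groups = "drop"
    )
  wide <- long |>
    dplyr::select("feature_id", "model_id", "code") |>
    tidyr::pivot_wider(names_from = "model_id", values_from = "code")
  out <- dplyr::left_join(wide, counts, by = "feature_id")
  structure(out, models = names(results),
            class = c("convergence_tbl", class(out)))
}

#' Select convergent candidate metabolites
#'
#' Applies the headline selection rule: metabolites that are
#' significantly upregulated DPMPs in at least `min_models` models and
#' belong to an eligible super-pathway (by default Nucleotide, Amino
#' Acid and Lipid). Candidates are sorted by support count, ties broken
#' by the largest supporting |log2FC|, then by lower id for stability.
#'
#' @param tbl A `convergence_tbl` from [build_direction_matrix()].
#' @param annotation Metabolite annotation covering every feature in
#'   `tbl`.
#' @param min_models Minimum number of supporting models (default 4).
#' @param direction `"up"` (default) or `"down"`.
#' @param super_filter Eligible super-pathways; `NULL` disables the
#'   pathway restriction.
#' @return A tibble: `metabolite_id`, `super_pathway`, `sub_pathway`,
#'   `n_models`, `max_abs_log2fc`, sorted as described.
#' @export
select_candidates <- function(tbl, annotation, min_models = 4,
                              direction = c("up", "down"),
                              super_filter = c("Nucleotide", "Amino Acid",
                                               "Lipid")) {
  direction <- match.arg(direction)
  if (!is.null(super_filter)) {
    unknown <- setdiff(super_filter, super_pathways())
    if (length(unknown)) {
      stop("unknown super-pathway name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  missing_ann <- setdiff(tbl$feature_id, annotation$metabolite_id)
  if (length(missing_ann)) {
    stop("annotation missing for: ",
         paste(utils::head(missing_ann, 5L), collapse = ", "),
         call. = FALSE)
  }
  count_col <- if (direction == "up") "up_count" else "down_count"
  lfc_col <- if (direction == "up") "max_up_lfc" else "max_down_lfc"
  out <- tbl |>
    tibble::as_tibble() |>
    dplyr::filter(.data[[count_col]] >= min_models) |>
    dplyr::transmute(
      metabolite_id = .data$feature_id,
      n_models = .data[[count_col]],
      max_abs_log2fc = .data[[lfc_col]]
    ) |>
    dplyr::inner_join(
      dplyr::select(annotation, "metabolite_id", "super_pathway",
                    "sub_pathway"),
      by = "metabolite_id"
    )
  if (!is.null(super_filter)) {
    out <- dplyr::filter(out, .data$super_pathway %in% super_filter)
  }
  out |>
    dplyr::arrange(dplyr::desc(.data$n_models),
                   dplyr::desc(.data$max_abs_log2fc),
                   .data$metabolite_id) |>
    dplyr::select("metabolite_id", "super_pathway", "sub_pathway",
                  "n_models", "max_abs_log2fc")
}

#' The nine Metabolon-style super-pathways
#' @return Character vector of canonical super-pathway names.
#' @export
super_pathways <- function() {
  c("Amino Acid", "Carbohydrate", "Energy", "Lipid", "Nucleotide",
    "Peptide", "Cofactors and Vitamins", "Xenobiotics",
    "Partially Characterized Molecules")
}

#' Hierarchical clustering of model fold-change profiles
#'
#' Builds a model-similarity dendrogram from per-model log2-fold-change
#' profiles. Distances are computed pairwise on the features shared by
#' each model pair (models carry different metabolite panels):
#' correlation distance 1 - Pearson r, or the Euclidean norm.
#'
#' @param profiles Long tibble with columns `model_id`, `feature_id`,
#'   `log2fc`.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param shared `"pairwise"` (default) restricts each distance to the
#'   pair's shared features; `"complete"` uses only features present in
#'   every model.
#' @return An object of class `model_tree` wrapping the `hclust` fit
#'   with its metric and linkage tags; see [tidy.model_tree()] and
#'   [write_newick()].
#' @export
model_similarity <- function(profiles,
                             metric = c("correlation", "euclidean"),
                             linkage = "average",
                             shared = c("pairwise", "complete")) {
  metric <- match.arg(metric)
  shared <- match.arg(shared)
  models <- unique(profiles$model_id)
  if (length(models) < 2L) stop("need at least 2 models", call. = FALSE)
  wide <- profiles |>
    dplyr::select("model_id", "feature_id", "log2fc") |>
    tidyr::pivot_wider(names_from = "model_id", values_from = "log2fc")
  v <- as.matrix(wide[-1L])  # feature x model
  if (shared == "complete") {
    v <- v[stats::complete.cases(v), , drop = FALSE]
  }
  k <- length(models)
  d <- matrix(0, k, k, dimnames = list(models, models))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      ok <- !is.na(v[, i]) & !is.na(v[, j])
      if (sum(ok) < 2L) {
        stop("fewer than 2 shared features between models ", models[i],
             " and ", models[j], call. = FALSE)
      }
      d[i, j] <- d[j, i] <- if (metric == "correlation") {
        1 - cor(v[ok, i], v[ok, j])
      } else {
        sqrt(sum((v[ok, i] - v[ok, j])^2))
      }
    }
  }
  fit <- hclust(as.dist(d), method = linkage)
  structure(list(hclust = fit, metric = metric, linkage = linkage,
                 distance = d),
            class = "model_tree")
}

#' @export
print.model_tree <- function(x, ...) {
  cat("Model similarity tree (", x$metric, " distance, ", x$linkage,
      " linkage, ", length(x$hclust$labels), " models)\n", sep = "")
  invisible(x)
}

#' Export a model tree in Newick format
#'
#' @param tree A `model_tree` from [model_similarity()].
#' @param path File to write; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Replicate-permutation Pearson correlation among metabolites
#'
#' Assesses metabolite-metabolite correlations robust to replicate
#' pairing: each permutation independently shuffles every metabolite's
#' values across the replicates within each group, pairwise Pearson
#' correlations are recomputed, and the reported matrix is the mean
#' coefficient over permutations. Empirical significance for the
#' observed correlation uses the add-one convention
#' p = (1 + #\{permuted |r| >= observed |r|\}) / (n_perm + 1).
#'
#' @param m A complete abundance table (any stage past imputation).
#' @param design Design tibble with `sample_id` and `group` (replicates
#'   are shuffled within group); pass a single-group design to shuffle
#'   freely.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `perm_cor` with elements `observed`,
#'   `mean_cor`, `p_value` (metabolite x metabolite matrices), `n_perm`;
#'   see [tidy.perm_cor()].
#' @export
permutation_correlation <- function(m, design, n_perm = 100, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)
  v <- abund_values(m)
  if (anyNA(v)) stop("matrix must be complete (imputed)", call. = FALSE)
  if (nrow(v) < 3L) stop("need at least 3 replicates", call. = FALSE)
  design <- dplyr::filter(design, .data$sample_id %in% rownames(v))
  v <- v[design$sample_id, , drop = FALSE]
  groups <- split(seq_len(nrow(v)), design$group)
  observed <- cor(v)
  set.seed(seed)
  mean_cor <- matrix(0, ncol(v), ncol(v))
  exceed <- matrix(0L, ncol(v), ncol(v))
  for (b in seq_len(n_perm)) {
    vp <- v
    for (idx in groups) {
      if (length(idx) < 2L) next
      for (j in seq_len(ncol(v))) {
        vp[idx, j] <- v[sample(idx), j]
      }
    }
    r <- cor(vp)
    mean_cor <- mean_cor + r
    exceed <- exceed + (abs(r) >= abs(observed))
  }
  mean_cor <- mean_cor / n_perm
  p_value <- (1 + exceed) / (n_perm + 1)
  dimnames(mean_cor) <- dimnames(p_value) <- dimnames(observed)
  structure(list(observed = observed, mean_cor = mean_cor,
                 p_value = p_value, n_perm = n_perm),
            class = "perm_cor")
}

#' @export
print.perm_cor <- function(x, ...) {
  cat("Replicate-permutation correlation over", x$n_perm,
      "permutations of", nrow(x$observed), "metabolites\n")
  invisible(x)
}
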