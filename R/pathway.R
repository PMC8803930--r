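#' Pathway-level differential-abundance (DA) score
#'
#' For each super- or sub-pathway the DA score is
#' (number of increased metabolites - number of decreased metabolites) /
#' (number of identified metabolites in the pathway), ranging from -1
#' (every identified metabolite decreased) to +1 (every identified
#' metabolite increased). "Increased"/"decreased" count significant
#' DPMPs by direction; set `count_all = TRUE` to count every metabolite
#' by fold-change sign instead.
#'
#' @param dpmps A contrast-result tibble (one model), or a named list of
#'   them (names are model ids).
#' @param annotation Annotation tibble with `metabolite_id`,
#'   `super_pathway`, `sub_pathway` and optional `low_confidence`.
#' @param level `"super"` or `"sub"`.
#' @param model Model id recorded in the output when `dpmps` is a single
#'   table (default `"model_1"`).
#' @param count_all Count all tested metabolites by sign of `log2fc`
#'   rather than significant DPMPs only (default `FALSE`).
#' @param exclude_low_confidence Drop metabolites flagged as
#'   low-confidence identifications (the "*" mark) before scoring.
#' @return A tibble: `pathway_id`, `level`, `model_id`, `da_score`,
#'   `n_identified`, `n_up`, `n_down`.
#' @examples
#' dpmps <- tibble::tibble(
#'   feature_id = paste0("m", 1:4), log2fc = c(1, 1, -1, 0.2),
#'   p_value = c(0.01, 0.01, 0.01, 0.5), adjusted_p = NA_real_,
#'   direction = c("up", "up", "down", "none"),
#'   significant = c(TRUE, TRUE, TRUE, FALSE)
#' )
#' ann <- tibble::tibble(
#'   metabolite_id = paste0("m", 1:4),
#'   super_pathway = "Nucleotide", sub_pathway = "Pyrimidine Metabolism"
#' )
#' da_score(dpmps, ann, level = "super")  # (2 - 1) / 4
#' @export
da_score <- function(dpmps, annotation, level = c("super", "sub"),
                     model = "model_1", count_all = FALSE,
                     exclude_low_confidence = FALSE) {
  level <- match.arg(level)
  if (is.data.frame(dpmps)) {
    dpmps <- setNames(list(dpmps), model)
  }
  if (is.null(names(dpmps)) || any(!nzchar(names(dpmps)))) {
    stop("a list of contrast tables must be named by model id",
         call. = FALSE)
  }
  if (exclude_low_confidence && "low_confidence" %in% names(annotation)) {
    annotation <- dplyr::filter(annotation, !.data$low_confidence)
  }
  key <- if (level == "super") "super_pathway" else "sub_pathway"
  purrr::imap_dfr(dpmps, function(tbl, model_id) {
    unknown <- setdiff(tbl$feature_id, annotation$metabolite_id)
    if (length(unknown)) {
      stop("unannotated metabolite(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "),
           if (length(unknown) > 5L) ", ...", call. = FALSE)
    }
    joined <- dplyr::inner_join(
      tbl, annotation, by = c(feature_id = "metabolite_id")
    )
    if (count_all) {
      joined <- dplyr::mutate(
        joined,
        up = .data$log2fc > 0,
        down = .data$log2fc < 0
      )
    } else {
      joined <- dplyr::mutate(
        joined,
        up = .data$significant & .data$direction == "up",
        down = .data$significant & .data$direction == "down"
      )
    }
    joined |>
      dplyr::group_by(pathway_id = .data[[key]]) |>
      dplyr::summarise(
        n_identified = dplyr::n(),
        n_up = sum(.data$up, na.rm = TRUE),
        n_down = sum(.data$down, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        level = level,
        model_id = model_id,
        da_score = (.data$n_up - .data$n_down) / .data$n_identified
      ) |>
      dplyr::select("pathway_id", "level", "model_id", "da_score",
                    "n_identified", "n_up", "n_down")
  })
}

#' Flag pathways consistently shifted across models
#'
#' Reproduces the highlighting rule used for the sub-pathway heat map:
#' a pathway is flagged when its DA score is positive (or negative for
#' `direction = "down"`) in at least `min_models` models.
#'
#' @param scores A DA score table from [da_score()] over several models.
#' @param min_models Minimum number of supporting models (default 7).
#' @param direction `"up"` (DA score > 0) or `"down"` (< 0).
#' @return A tibble: `pathway_id`, `n_supporting`, `flagged`.
#' @export
flag_consistent_pathways <- function(scores, min_models = 7,
                                     direction = c("up", "down")) {
  direction <- match.arg(direction)
  scores |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      n_supporting = if (direction == "up") sum(.data$da_score > 0)
                     else sum(.data$da_score < 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n_supporting >= min_models)
}

#' Joint gene + metabolite pathway over-representation
#'
#' Simplified joint pathway analysis: differentially expressed genes and
#' differentially present metabolites are pooled into one hit list and
#' each pathway is tested for over-representation with a one-sided
#' hypergeometric tail on the pooled feature universe (no pathway
#' topology weighting).
#'
#' @param deg_ids Significant gene ids.
#' @param dpmp_ids Significant metabolite ids.
#' @param membership Tibble with columns `pathway_id` and `feature_id`
#'   (genes and metabolites mixed).
#' @param universe All tested feature ids (genes and metabolites).
#' @return A tibble: `pathway_id`, `n_pathway`, `n_hits`, `p_value`,
#'   `adjusted_p`, sorted by p-value.
#' @export
joint_pathway_enrichment <- function(deg_ids, dpmp_ids, membership,
                                     universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  hits <- unique(c(deg_ids, dpmp_ids))
  stray <- setdiff(hits, universe)
  if (length(stray)) {
    stop("hits outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  membership <- dplyr::filter(membership, .data$feature_id %in% universe)
  n_u <- length(universe)
  n_h <- length(hits)
  out <- membership |>
    dplyr::distinct(.data$pathway_id, .data$feature_id) |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      n_pathway = dplyr::n(),
      n_hits = sum(.data$feature_id %in% hits),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_value = phyper(.data$n_hits - 1L, .data$n_pathway,
                       n_u - .data$n_pathway, n_h, lower.tail = FALSE),
      adjusted_p = bh_adjust(.data$p_value)
    ) |>
    dplyr::arrange(.data$p_value)
  out
}
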