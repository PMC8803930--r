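#' Benjamini-Hochberg step-up adjustment
#'
#' The classical FDR step-up procedure: order the p-values, multiply
#' p(i) by m/i, take the cumulative minimum from the largest rank down,
#' cap at 1 and return in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1] with no missing values",
         call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(p_values[ord] * m / seq(m, 1L)))
  adj[order(ord)]
}

#' Call differentially expressed genes (DEGs)
#'
#' Two-group test on log-scale expression with the published cutoff:
#' significant when the (BH-adjusted or raw, per `adjust`) p-value is
#' strictly below `alpha` AND |log2 fold change| strictly exceeds
#' `lfc_threshold`. The log2 fold change is the difference of group
#' means on the log scale. The raw-p dialect (`adjust = "none"`) matches
#' the treatment of the non-human-primate tissue contrasts.
#'
#' @param e Expression tibble: `sample_id` column then numeric gene
#'   columns of log-scale expression.
#' @param design Design tibble with `sample_id` and `group`.
#' @param contrast `c(reference, alternative)`; log2fc is alt minus ref.
#' @param method `"welch"` (default) or `"wilcoxon"`.
#' @param adjust `"bh"` (default) or `"none"` — which p-value faces the
#'   `alpha` cutoff.
#' @param alpha Significance level (default 0.05, strict).
#' @param lfc_threshold Absolute log2-fold-change cutoff (default 0.25,
#'   strict).
#' @return A contrast-result tibble (see [test_dpmp()] for columns).
#' @export
test_deg <- function(e, design, contrast = NULL,
                     method = c("welch", "wilcoxon"),
                     adjust = c("bh", "none"),
                     alpha = 0.05, lfc_threshold = 0.25) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  e <- tibble::as_tibble(e)
  if (names(e)[1L] != "sample_id") {
    stop("expression table needs a leading `sample_id` column",
         call. = FALSE)
  }
  cc <- check_two_groups(design, contrast)
  v <- as.matrix(e[-1L])
  rownames(v) <- e$sample_id
  if (any(!is.finite(v[cc$design$sample_id, ]))) {
    stop("expression values must be finite", call. = FALSE)
  }
  x <- v[cc$design$sample_id[cc$design$group == cc$ref], , drop = FALSE]
  y <- v[cc$design$sample_id[cc$design$group == cc$alt], , drop = FALSE]
  res <- switch(method,
                welch = welch_t_cols(x, y),
                wilcoxon = wilcoxon_cols(x, y))
  log2fc <- res$mean_alt - res$mean_ref
  adjusted_p <- bh_adjust(res$p_value)
  p_used <- if (adjust == "bh") adjusted_p else res$p_value
  significant <- p_used < alpha & abs(log2fc) > lfc_threshold
  direction <- dplyr::case_when(
    significant & log2fc > 0 ~ "up",
    significant & log2fc < 0 ~ "down",
    .default = "none"
  )
  tibble::tibble(
    feature_id = colnames(v),
    log2fc = unname(log2fc),
    p_value = unname(res$p_value),
    adjusted_p = unname(adjusted_p),
    direction = direction,
    significant = unname(significant)
  )
}

#' Rescue DEGs: injury-induced changes reversed by treatment
#'
#' Intersects opposite-direction DEG calls from an injury contrast
#' (injured vs sham) and a treatment contrast (treated vs vehicle):
#' genes down upon injury and up upon treatment are
#' "rescue DEGs (upregulated)"; genes up upon injury and down upon
#' treatment are "rescue DEGs (downregulated)".
#'
#' @param injury Contrast-result tibble for injured-vs-sham.
#' @param treatment Contrast-result tibble for treated-vs-vehicle.
#' @return A tibble with columns `gene_id` and
#'   `set` (`"rescue_up"` / `"rescue_down"`).
#' @export
rescue_degs <- function(injury, treatment) {
  sig <- function(tbl, dir) tbl$feature_id[tbl$significant &
                                             tbl$direction == dir]
  rescue_up <- intersect(sig(injury, "down"), sig(treatment, "up"))
  rescue_down <- intersect(sig(injury, "up"), sig(treatment, "down"))
  tibble::tibble(
    gene_id = c(rescue_up, rescue_down),
    set = rep(c("rescue_up", "rescue_down"),
              c(length(rescue_up), length(rescue_down)))
  )
}

#' Differential-expression (DE) score of a gene set
#'
#' Fraction of a gene set's genes (restricted to the tested universe)
#' that are significant DEGs; ranges over \[0, 1\].
#'
#' @param degs Contrast-result tibble.
#' @param genes Character vector of gene-set members.
#' @param universe Tested gene ids; defaults to `degs$feature_id`.
#' @return A single number in \[0, 1\].
#' @export
de_score <- function(degs, genes, universe = degs$feature_id) {
  members <- intersect(genes, universe)
  if (!length(members)) {
    stop("gene set has no members in the tested universe", call. = FALSE)
  }
  hits <- degs$feature_id[degs$significant]
  length(intersect(hits, members)) / length(members)
}

#' Relative DE score (enrichment over background DEG rate)
#'
#' DE score of the set divided by the DE score of the whole universe.
#' Returns `NA` when no gene in the universe is differentially
#' expressed (zero background rate).
#'
#' @inheritParams de_score
#' @return A non-negative number, or `NA` when the background rate is 0.
#' @export
relative_de_score <- function(degs, genes, universe = degs$feature_id) {
  background <- de_score(degs, universe, universe)
  if (background == 0) return(NA_real_)
  de_score(degs, genes, universe) / background
}
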