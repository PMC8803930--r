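#' Call differentially present metabolic products (DPMPs)
#'
#' Runs a two-group location test per metabolite and flags DPMPs at raw
#' P < `alpha` (the published cutoff uses unadjusted p-values; BH
#' q-values are reported alongside but do not drive the flag). The
#' log2 fold change is the log2 ratio of group means and is therefore
#' computed on median-scaled (positive) values; the test statistic is
#' invariant to auto-scaling, so either stage may be tested.
#'
#' @param m An abundance table at stage `median_scaled` or `auto_scaled`.
#' @param design A design tibble with columns `sample_id` and `group`.
#' @param contrast Character vector `c(reference, high_regen)`; fold
#'   changes are alt over reference. Defaults to
#'   `c("control", "high_regen")` when both are present, otherwise the
#'   two groups in sorted order.
#' @param method `"welch"` (default), `"student"` or `"wilcoxon"`.
#' @param alpha Significance cutoff on the raw p-value (default 0.05).
#' @return A contrast-result tibble: `feature_id`, `log2fc`, `p_value`,
#'   `adjusted_p` (BH), `direction` (`up`/`down`/`none`), `significant`.
#' @examples
#' study <- gen_metabolome_study(synth_config(n_models = 1, n_metabolites = 20))
#' norm <- rescale_median(impute_minimum(study$abundance[[1]]))
#' test_dpmp(norm, study$design)
#' @export
test_dpmp <- function(m, design, contrast = NULL,
                      method = c("welch", "student", "wilcoxon"),
                      alpha = 0.05) {
  method <- match.arg(method)
  stage <- abundance_stage(m)
  if (!stage %in% c("median_scaled", "auto_scaled")) {
    stop("test_dpmp() expects a median_scaled or auto_scaled table; got ",
         stage, call. = FALSE)
  }
  if (is.null(contrast) &&
      all(c("control", "high_regen") %in% design$group)) {
    contrast <- c("control", "high_regen")
  }
  cc <- check_two_groups(design, contrast)
  v <- abund_values(m)
  missing_samples <- setdiff(cc$design$sample_id, rownames(v))
  if (length(missing_samples)) {
    stop("design samples absent from the matrix: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  x <- v[cc$design$sample_id[cc$design$group == cc$ref], , drop = FALSE]
  y <- v[cc$design$sample_id[cc$design$group == cc$alt], , drop = FALSE]
  res <- switch(method,
                welch = welch_t_cols(x, y),
                student = student_t_cols(x, y),
                wilcoxon = wilcoxon_cols(x, y))
  if (stage == "median_scaled") {
    ratio <- res$mean_alt / res$mean_ref
    log2fc <- ifelse(res$mean_ref > 0 & res$mean_alt > 0, log2(ratio),
                     NA_real_)
    if (anyNA(log2fc)) {
      warning("zero group mean for some metabolites; log2fc set NA there",
              call. = FALSE)
    }
  } else {
    # centered values carry no ratio information
    log2fc <- rep(NA_real_, ncol(v))
  }
  diff_sign <- sign(res$mean_alt - res$mean_ref)
  significant <- res$p_value < alpha & diff_sign != 0
  direction <- dplyr::case_when(
    significant & diff_sign > 0 ~ "up",
    significant & diff_sign < 0 ~ "down",
    .default = "none"
  )
  tibble::tibble(
    feature_id = colnames(v),
    log2fc = unname(log2fc),
    p_value = unname(res$p_value),
    adjusted_p = bh_adjust(unname(res$p_value)),
    direction = direction,
    significant = unname(significant)
  )
}
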