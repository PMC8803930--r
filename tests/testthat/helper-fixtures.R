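# small fixtures built in code, shared across test files

toy_abundance <- function(values, stage = "raw") {
  # values: named list of metabolite vectors, equal length
  n <- length(values[[1L]])
  abundance_matrix(
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%02d", seq_len(n))),
      tibble::as_tibble(values)
    ),
    stage = stage
  )
}

toy_design <- function(n_per_group, groups = c("control", "high_regen")) {
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n_per_group * length(groups))),
    group = rep(groups, each = n_per_group),
    replicate = rep(seq_len(n_per_group), length(groups))
  )
}

toy_contrast <- function(feature_id, direction, log2fc = NULL,
                         p_value = NULL) {
  significant <- direction != "none"
  if (is.null(log2fc)) {
    log2fc <- ifelse(direction == "up", 1, ifelse(direction == "down",
                                                  -1, 0.1))
  }
  if (is.null(p_value)) p_value <- ifelse(significant, 0.01, 0.5)
  tibble::tibble(
    feature_id = feature_id, log2fc = log2fc, p_value = p_value,
    adjusted_p = p_value, direction = direction, significant = significant
  )
}

# normalization front half of the pipeline
normalize_for_testing <- function(m) {
  rescale_median(impute_minimum(m))
}
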