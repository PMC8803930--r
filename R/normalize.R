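#' Minimum imputation of missing abundances
#'
#' Missing area counts in untargeted metabolomics are assumed to fall
#' below the limit of detection, so each missing cell is filled with the
#' observed minimum of its metabolite. Observed values are unchanged.
#'
#' @param m An abundance table at stage `raw` (see [abundance_matrix()]).
#' @return The table at stage `imputed`, same shape, no missing cells.
#' @examples
#' m <- abundance_matrix(tibble::tibble(
#'   sample_id = c("s1", "s2", "s3"),
#'   met_a = c(2, NA, 4)
#' ))
#' impute_minimum(m)
#' @export
impute_minimum <- function(m) {
  v <- abund_values(m)
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    stop("metabolite(s) with no observed values: ",
         paste(colnames(v)[all_missing], collapse = ", "), call. = FALSE)
  }
  mins <- apply(v, 2L, min, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mins[idx[, 2L]]
  abund_rebuild(v, m$sample_id, "imputed")
}

#' Median rescaling to 1
#'
#' Divides each metabolite by its own median so the per-metabolite
#' median of the normalized value equals 1.
#'
#' @param m An abundance table at stage `imputed` (complete, non-negative).
#' @return The table at stage `median_scaled`.
#' @examples
#' m <- abundance_matrix(tibble::tibble(
#'   sample_id = c("s1", "s2", "s3"), met_a = c(2, 4, 8)
#' ), stage = "imputed")
#' rescale_median(m)
#' @export
rescale_median <- function(m) {
  v <- abund_values(m)
  if (anyNA(v)) {
    stop("missing values present; run impute_minimum() first", call. = FALSE)
  }
  med <- apply(v, 2L, median)
  bad <- med <= 0
  if (any(bad)) {
    stop("zero or negative median for metabolite(s): ",
         paste(colnames(v)[bad], collapse = ", "), call. = FALSE)
  }
  abund_rebuild(sweep(v, 2L, med, "/"), m$sample_id, "median_scaled")
}

#' Auto-scaling (unit-variance scaling)
#'
#' Mean-centers each metabolite and divides by its sample standard
#' deviation (denominator n - 1), the scaling applied before two-group
#' testing and PLS-DA ordination. Zero-variance metabolites cannot be
#' scaled and are dropped with a warning.
#'
#' @param m An abundance table at stage `median_scaled`.
#' @return The table at stage `auto_scaled`; constant metabolites removed.
#' @examples
#' m <- abundance_matrix(tibble::tibble(
#'   sample_id = c("s1", "s2", "s3"), met_a = c(1, 2, 3)
#' ), stage = "median_scaled")
#' auto_scale(m)
#' @export
auto_scale <- function(m) {
  v <- abund_values(m)
  if (anyNA(v)) {
    stop("missing values present; run impute_minimum() first", call. = FALSE)
  }
  sds <- apply(v, 2L, sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("dropping zero-variance metabolite(s): ",
            paste(colnames(v)[constant], collapse = ", "), call. = FALSE)
    v <- v[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  if (!ncol(v)) stop("no metabolites left after dropping constants",
                     call. = FALSE)
  v <- sweep(sweep(v, 2L, colMeans(v)), 2L, sds, "/")
  abund_rebuild(v, m$sample_id, "auto_scaled")
}

#' Optional log2 transform
#'
#' Log2-transforms abundances (an optional pre-processing step before
#' auto-scaling, off by default in the pipeline). The stage tag is kept.
#'
#' @param m An abundance table with strictly positive values (or supply
#'   `offset`).
#' @param offset Constant added before taking logs (default 0).
#' @return The transformed table at the same stage.
#' @export
transform_log2 <- function(m, offset = 0) {
  v <- abund_values(m) + offset
  if (any(v <= 0, na.rm = TRUE)) {
    stop("non-positive values; supply a positive `offset`", call. = FALSE)
  }
  # log values may be negative, so bypass the non-negativity check
  out <- abund_rebuild(log2(v), m$sample_id, "auto_scaled")
  attr(out, "stage") <- abundance_stage(m)
  attr(out, "log2") <- TRUE
  out
}
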