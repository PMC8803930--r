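#' Metabolite abundance tables
#'
#' An abundance table is an ordinary tibble whose first column is
#' `sample_id` and whose remaining columns are numeric metabolite
#' abundances (raw area counts or normalized values). The normalization
#' stage is tracked in the `"stage"` attribute and moves through
#' `raw -> imputed -> median_scaled -> auto_scaled` as the table passes
#' through [impute_minimum()], [rescale_median()] and [auto_scale()].
#'
#' @param x A data frame with a `sample_id` column followed by numeric
#'   metabolite columns.
#' @param stage Normalization stage of the values.
#' @return A tibble of class `abundance_tbl` with a `stage` attribute.
#' @examples
#' m <- abundance_matrix(
#'   tibble::tibble(sample_id = c("s1", "s2"), met_a = c(1, 2), met_b = c(3, NA))
#' )
#' abundance_stage(m)
#' @export
abundance_matrix <- function(x, stage = c("raw", "imputed", "median_scaled",
                                          "auto_scaled")) {
  stage <- match.arg(stage)
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L || names(x)[1L] != "sample_id") {
    stop("an abundance table needs a leading `sample_id` column followed by ",
         "metabolite columns", call. = FALSE)
  }
  vals <- x[-1L]
  if (!all(vapply(vals, is.numeric, logical(1L)))) {
    stop("all metabolite columns must be numeric", call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id values", call. = FALSE)
  }
  if (stage != "auto_scaled" && any(unlist(vals) < 0, na.rm = TRUE)) {
    stop("negative abundances are not allowed before auto-scaling",
         call. = FALSE)
  }
  structure(x, stage = stage, class = c("abundance_tbl", class(x)))
}

#' @rdname abundance_matrix
#' @export
abundance_stage <- function(x) {
  attr(x, "stage") %||% "raw"
}

# sample x metabolite numeric matrix view (rownames = sample_id)
abund_values <- function(x) {
  v <- as.matrix(x[-1L])
  rownames(v) <- x$sample_id
  v
}

# rebuild an abundance tibble from a values matrix, keeping sample order
abund_rebuild <- function(values, sample_id, stage) {
  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id), out)
  abundance_matrix(out, stage = stage)
}

metabolite_ids <- function(x) names(x)[-1L]

#' @export
print.abundance_tbl <- function(x, ...) {
  cat("# Abundance table [stage: ", abundance_stage(x), "]\n", sep = "")
  NextMethod()
}

check_two_groups <- function(design, contrast) {
  groups <- unique(design$group)
  if (is.null(contrast)) {
    if (length(groups) != 2L) {
      stop("design must contain exactly two groups (got: ",
           paste(groups, collapse = ", "), "); pass `contrast` to subset",
           call. = FALSE)
    }
    contrast <- sort(groups)
  }
  if (length(contrast) != 2L || !all(contrast %in% groups)) {
    stop("`contrast` must name two groups present in the design",
         call. = FALSE)
  }
  design <- dplyr::filter(design, .data$group %in% contrast)
  counts <- table(design$group)
  if (any(counts < 2L)) {
    stop("each group needs at least 2 samples for testing", call. = FALSE)
  }
  list(design = design, ref = contrast[[1L]], alt = contrast[[2L]])
}
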