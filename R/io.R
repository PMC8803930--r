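#' Read and write pipeline tables
#'
#' Plain-text interfaces shared by every stage: TSV/CSV matrices whose
#' first column is `sample_id` and remaining columns are features
#' (UTF-8, "." decimal, empty cell = missing), annotation and design
#' TSVs, gene-set files with one id per line, and contrast-result TSVs
#' with the fixed header `feature_id, log2fc, p_value, adjusted_p,
#' direction, significant`.
#'
#' @param path File path. `read_abundance()` sniffs the delimiter from
#'   the extension (`.csv` vs anything else = tab).
#' @param stage Stage tag to attach to the abundance table.
#' @name pipeline-io
NULL

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' @rdname pipeline-io
#' @export
read_abundance <- function(path, stage = "raw") {
  x <- readr::read_delim(path, delim = delim_for(path),
                         show_col_types = FALSE, progress = FALSE)
  abundance_matrix(x, stage = stage)
}

#' @rdname pipeline-io
#' @param m Abundance table to write.
#' @export
write_abundance <- function(m, path) {
  readr::write_delim(tibble::as_tibble(m), path,
                     delim = delim_for(path), na = "")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("metabolite_id", "super_pathway", "sub_pathway")
  if (!all(need %in% names(x))) {
    stop("annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"low_confidence" %in% names(x)) x$low_confidence <- FALSE
  x
}

#' @rdname pipeline-io
#' @export
read_design <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(x))) {
    stop("design needs columns sample_id and group", call. = FALSE)
  }
  x
}

#' @rdname pipeline-io
#' @export
read_gene_set <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("empty gene-set file: ", path, call. = FALSE)
  unique(ids)
}

#' @rdname pipeline-io
#' @param result Contrast-result tibble to write.
#' @export
write_contrast <- function(result, path) {
  readr::write_tsv(result, path, na = "")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_contrast <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("feature_id", "log2fc", "p_value", "adjusted_p", "direction",
            "significant")
  if (!all(need %in% names(x))) {
    stop("contrast table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' @rdname pipeline-io
#' @export
read_screen_plate <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("metabolite", "concentration", "group", "confluence")
  if (!all(need %in% names(x))) {
    stop("screen plate needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Write a synthetic study to disk
#'
#' Serialises a [gen_metabolome_study()] result to the same TSV formats
#' the pipeline reads, with the planted ground truth as a JSON sidecar.
#'
#' @param study Output of [gen_metabolome_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (model in names(study$abundance)) {
    write_abundance(study$abundance[[model]],
                    file.path(dir, paste0("abundance_", model, ".tsv")))
  }
  readr::write_tsv(study$design, file.path(dir, "design.tsv"))
  readr::write_tsv(study$annotation, file.path(dir, "annotation.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
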