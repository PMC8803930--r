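#' Relative proliferation of a screen condition
#'
#' Mean confluence of the treated wells divided by the mean confluence
#' of the vehicle wells on the same plate (the 6-vs-6 normalization of
#' the live-imaging screen).
#'
#' @param plate Screen tibble with columns `metabolite`,
#'   `concentration`, `group`, `confluence` (and optionally `day`).
#' @param metabolite Metabolite to evaluate.
#' @param concentration Concentration to evaluate; `NULL` pools all
#'   concentrations of the metabolite.
#' @param day Day index to use (default: the latest day present).
#' @param min_wells Warn when a side has fewer wells than this
#'   (default 3).
#' @return The relative-proliferation ratio (a single number).
#' @export
relative_proliferation <- function(plate, metabolite,
                                   concentration = NULL, day = NULL,
                                   min_wells = 3) {
  if ("day" %in% names(plate)) {
    day <- day %||% max(plate$day)
    plate <- dplyr::filter(plate, .data$day == !!day)
  }
  vehicle <- dplyr::filter(plate, .data$group == "vehicle")
  treated <- dplyr::filter(plate, .data$group == "treated",
                           .data$metabolite == !!metabolite)
  if (!is.null(concentration)) {
    treated <- dplyr::filter(treated,
                             .data$concentration == !!concentration)
  }
  if (!nrow(treated) || !nrow(vehicle)) {
    stop("need at least one treated and one vehicle well", call. = FALSE)
  }
  if (nrow(treated) < min_wells || nrow(vehicle) < min_wells) {
    warning("fewer than ", min_wells, " wells on one side", call. = FALSE)
  }
  vm <- mean(vehicle$confluence)
  if (vm <= 0) stop("vehicle mean confluence is zero", call. = FALSE)
  mean(treated$confluence) / vm
}

#' Rank screened metabolites by proliferative effect
#'
#' Summarises each metabolite across its tested concentrations (by
#' default the maximum relative proliferation, i.e. its best
#' concentration) and ranks metabolites in descending order. Ties are
#' broken in favour of the lower concentration.
#'
#' @param plate Screen tibble (see [relative_proliferation()]).
#' @param summary `"max"` (default, best concentration) or `"mean"`
#'   across concentrations.
#' @param day Day index (default: latest day present).
#' @return A tibble: `rank`, `metabolite`, `concentration`,
#'   `relative_proliferation`, one row per metabolite.
#' @export
rank_screen <- function(plate, summary = c("max", "mean"), day = NULL) {
  summary <- match.arg(summary)
  if ("day" %in% names(plate)) {
    day <- day %||% max(plate$day)
    plate <- dplyr::filter(plate, .data$day == !!day)
  }
  conds <- plate |>
    dplyr::filter(.data$group == "treated") |>
    dplyr::distinct(.data$metabolite, .data$concentration)
  if (!nrow(conds)) stop("no treated conditions on the plate",
                         call. = FALSE)
  per_cond <- purrr::pmap_dfr(conds, function(metabolite, concentration) {
    tibble::tibble(
      metabolite = metabolite, concentration = concentration,
      relative_proliferation = relative_proliferation(
        plate, metabolite, concentration, day = day
      )
    )
  })
  best <- if (summary == "max") {
    per_cond |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::arrange(dplyr::desc(.data$relative_proliferation),
                     .data$concentration, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
  } else {
    per_cond |>
      dplyr::group_by(.data$metabolite) |>
      dplyr::summarise(
        concentration = NA_real_,
        relative_proliferation = mean(.data$relative_proliferation),
        .groups = "drop"
      )
  }
  best |>
    dplyr::arrange(dplyr::desc(.data$relative_proliferation),
                   .data$metabolite) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)
}
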