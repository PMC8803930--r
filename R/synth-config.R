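#' Configuration for the synthetic multi-model study generator
#'
#' Defines the stated world the generators emulate: a panel of paired
#' contrasts (higher- vs lower-regenerative-capacity samples) with
#' log-normal metabolite abundances, pathway-structured annotation and
#' planted convergent effects; negative-binomial-like log expression
#' with planted DEGs and rescue genes; and 96-well proliferation-screen
#' plates with planted multiplicative effects. Defaults mirror the
#' study design being emulated: 11 models (axolotl blastema, deer
#' antler stem cells, eight primate tissues, hMSCs), 9 super-pathways,
#' several hundred metabolites per panel.
#'
#' @param n_models Number of paired model contrasts (default 11).
#' @param n_samples_per_group Metabolome replicates per group (default 5).
#' @param n_metabolites Metabolites per panel (default 500, within the
#'   400-759 range typical of untargeted panels).
#' @param n_pathways_super Number of super-pathways used (2-9; default 9).
#' @param n_pathways_sub Number of sub-pathways nested in the supers
#'   (default 40).
#' @param planted_up_metabolites Tibble (or data frame) with columns
#'   `metabolite_id`, `models` (list-column of integer model indices)
#'   and `log2fc`: metabolites planted as increased in the high-regen
#'   group of those models.
#' @param missing_rate Fraction of cells missing completely at random,
#'   in \[0, 1) (default 0.10).
#' @param missingness `"mcar"` (default) or `"censor"` (left-censoring:
#'   the lowest cells of each metabolite go missing first).
#' @param abundance_log_sd Within-group SD of log2 abundance (default
#'   0.25).
#' @param n_genes Genes in the expression panel (default 2000).
#' @param n_samples_per_group_expr Expression replicates per group
#'   (default 6).
#' @param expression_log_sd Within-group SD of log2 expression (default
#'   0.4).
#' @param planted_degs Tibble with columns `gene_id`,
#'   `contrast` (`"injury"` or `"treatment"`) and `log2fc`.
#' @param planted_rescue_genes Gene ids planted down upon injury and up
#'   upon treatment (magnitude `rescue_effect`).
#' @param rescue_effect Absolute log2FC of planted rescue genes
#'   (default 2).
#' @param screen_effects Named numeric vector: multiplicative
#'   proliferation effect per screened metabolite (1 = null).
#' @param screen_concentrations Concentrations (uM) at which each
#'   screened metabolite is tested.
#' @param screen_baseline Mean vehicle confluence percent (default 40).
#' @param screen_sd Well-to-well confluence SD in percentage points
#'   (default 3).
#' @param seed Master seed; per-model substreams are spawned from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_models = 11,
                         n_samples_per_group = 5,
                         n_metabolites = 500,
                         n_pathways_super = 9,
                         n_pathways_sub = 40,
                         planted_up_metabolites = NULL,
                         missing_rate = 0.10,
                         missingness = c("mcar", "censor"),
                         abundance_log_sd = 0.25,
                         n_genes = 2000,
                         n_samples_per_group_expr = 6,
                         expression_log_sd = 0.4,
                         planted_degs = NULL,
                         planted_rescue_genes = character(0),
                         rescue_effect = 2,
                         screen_effects = NULL,
                         screen_concentrations = c(10, 50, 200, 1000),
                         screen_baseline = 40,
                         screen_sd = 3,
                         seed = 1L) {
  missingness <- match.arg(missingness)
  cfg <- list(
    n_models = n_models, n_samples_per_group = n_samples_per_group,
    n_metabolites = n_metabolites, n_pathways_super = n_pathways_super,
    n_pathways_sub = n_pathways_sub,
    planted_up_metabolites = planted_up_metabolites,
    missing_rate = missing_rate, missingness = missingness,
    abundance_log_sd = abundance_log_sd,
    n_genes = n_genes,
    n_samples_per_group_expr = n_samples_per_group_expr,
    expression_log_sd = expression_log_sd,
    planted_degs = planted_degs,
    planted_rescue_genes = planted_rescue_genes,
    rescue_effect = rescue_effect,
    screen_effects = screen_effects,
    screen_concentrations = screen_concentrations,
    screen_baseline = screen_baseline, screen_sd = screen_sd,
    seed = seed
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

cfg_stop <- function(field, msg) {
  stop("invalid synth_config field `", field, "`: ", msg, call. = FALSE)
}

validate_synth_config <- function(cfg) {
  count_fields <- c("n_models", "n_samples_per_group", "n_metabolites",
                    "n_pathways_super", "n_pathways_sub", "n_genes",
                    "n_samples_per_group_expr")
  for (f in count_fields) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]])) {
      cfg_stop(f, "must be a positive integer")
    }
  }
  if (cfg$n_samples_per_group < 2) {
    cfg_stop("n_samples_per_group", "need at least 2 replicates per group")
  }
  if (cfg$n_pathways_super > length(super_pathways())) {
    cfg_stop("n_pathways_super",
             "at most 9 canonical super-pathways exist")
  }
  if (cfg$n_pathways_sub < cfg$n_pathways_super) {
    cfg_stop("n_pathways_sub", "must be >= n_pathways_super")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    cfg_stop("missing_rate", "must lie in [0, 1)")
  }
  for (f in c("abundance_log_sd", "expression_log_sd", "screen_sd")) {
    if (cfg[[f]] <= 0) cfg_stop(f, "must be positive")
  }
  if (!is.null(cfg$planted_up_metabolites)) {
    p <- cfg$planted_up_metabolites
    need <- c("metabolite_id", "models", "log2fc")
    if (!all(need %in% names(p))) {
      cfg_stop("planted_up_metabolites",
               "needs columns metabolite_id, models, log2fc")
    }
    all_models <- unlist(p$models)
    if (length(all_models) &&
        (any(all_models < 1) || any(all_models > cfg$n_models))) {
      cfg_stop("planted_up_metabolites",
               "planted model ids must lie in 1..n_models")
    }
    if (!all(p$metabolite_id %in% met_ids(cfg))) {
      cfg_stop("planted_up_metabolites",
               "planted metabolite ids must exist in the panel")
    }
  }
  if (!is.null(cfg$planted_degs)) {
    p <- cfg$planted_degs
    if (!all(c("gene_id", "contrast", "log2fc") %in% names(p))) {
      cfg_stop("planted_degs", "needs columns gene_id, contrast, log2fc")
    }
    if (!all(p$contrast %in% c("injury", "treatment"))) {
      cfg_stop("planted_degs", "contrast must be 'injury' or 'treatment'")
    }
    if (!all(p$gene_id %in% gene_ids(cfg))) {
      cfg_stop("planted_degs", "planted gene ids must exist in the panel")
    }
  }
  if (length(cfg$planted_rescue_genes) &&
      !all(cfg$planted_rescue_genes %in% gene_ids(cfg))) {
    cfg_stop("planted_rescue_genes", "ids must exist in the gene panel")
  }
  if (!is.null(cfg$screen_effects)) {
    if (is.null(names(cfg$screen_effects)) ||
        any(!nzchar(names(cfg$screen_effects)))) {
      cfg_stop("screen_effects", "must be a named numeric vector")
    }
    if (any(cfg$screen_effects <= 0)) {
      cfg_stop("screen_effects", "effects are multiplicative, must be > 0")
    }
  }
  if (!length(cfg$screen_concentrations) ||
      any(cfg$screen_concentrations <= 0)) {
    cfg_stop("screen_concentrations", "need at least one positive value")
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed) ||
      cfg$seed != round(cfg$seed)) {
    cfg_stop("seed", "must be a single integer")
  }
  invisible(cfg)
}

met_ids <- function(cfg) {
  sprintf("met_%04d", seq_len(cfg$n_metabolites))
}

gene_ids <- function(cfg) {
  sprintf("gene_%05d", seq_len(cfg$n_genes))
}

model_ids <- function(cfg) {
  sprintf("model_%02d", seq_len(cfg$n_models))
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic study configuration:\n")
  cat("  ", x$n_models, " models x ", x$n_samples_per_group,
      "/group, ", x$n_metabolites, " metabolites, missing rate ",
      x$missing_rate, " (", x$missingness, ")\n", sep = "")
  cat("  ", x$n_genes, " genes x ", x$n_samples_per_group_expr,
      "/group, ", length(x$planted_rescue_genes),
      " planted rescue genes\n", sep = "")
  invisible(x)
}
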