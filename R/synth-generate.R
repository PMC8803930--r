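#' Generate a synthetic multi-model metabolome study
#'
#' Simulates one abundance matrix per model: per-metabolite baseline
#' log2 abundance drawn once (area-count scale, roughly 2^10..2^20),
#' within-group noise `abundance_log_sd` on the log2 scale (abundances
#' are therefore log-normal), planted metabolites shifted by their
#' `log2fc` in the high-regen group of their planted models only, and
#' cells removed at `missing_rate` (MCAR, or left-censored when
#' `missingness = "censor"`). A single annotation table assigns every
#' metabolite one super- and one nested sub-pathway. The master seed
#' spawns an independent substream per model.
#'
#' @param cfg A [synth_config()].
#' @return A list: `abundance` (named list of raw abundance tables, one
#'   per model), `design` (sample_id, model_id, group, replicate),
#'   `annotation`, `truth` (tibble metabolite_id, model_id, log2fc of
#'   planted effects).
#' @export
gen_metabolome_study <- function(cfg) {
  validate_synth_config(cfg)
  mets <- met_ids(cfg)
  models <- model_ids(cfg)
  annotation <- gen_annotation(cfg)
  seeds <- spawn_seeds(cfg$seed, cfg$n_models + 1L)
  set.seed(seeds[[1L]])
  baseline <- runif(cfg$n_metabolites, 10, 20)  # log2 area counts
  planted <- cfg$planted_up_metabolites
  truth <- if (is.null(planted)) {
    tibble::tibble(metabolite_id = character(0), model_id = character(0),
                   log2fc = numeric(0))
  } else {
    un <- tidyr::unnest_longer(tibble::as_tibble(planted), "models")
    tibble::tibble(metabolite_id = un$metabolite_id,
                   model_id = models[un$models],
                   log2fc = un$log2fc)
  }
  n <- cfg$n_samples_per_group
  abundance <- vector("list", cfg$n_models)
  names(abundance) <- models
  design_all <- vector("list", cfg$n_models)
  for (k in seq_len(cfg$n_models)) {
    set.seed(seeds[[k + 1L]])
    sample_id <- sprintf("%s_%s_r%d", models[[k]],
                         rep(c("ctrl", "hi"), each = n),
                         rep(seq_len(n), 2L))
    group <- rep(c("control", "high_regen"), each = n)
    mu <- matrix(baseline, nrow = 2L * n, ncol = cfg$n_metabolites,
                 byrow = TRUE)
    eff <- truth[truth$model_id == models[[k]], ]
    if (nrow(eff)) {
      cols <- match(eff$metabolite_id, mets)
      mu[group == "high_regen", cols] <-
        sweep(mu[group == "high_regen", cols, drop = FALSE], 2L,
              eff$log2fc, "+")
    }
    vals <- 2^(mu + matrix(rnorm(length(mu), sd = cfg$abundance_log_sd),
                           nrow = nrow(mu)))
    if (cfg$missing_rate > 0) {
      if (cfg$missingness == "mcar") {
        vals[runif(length(vals)) < cfg$missing_rate] <- NA_real_
      } else {
        # left-censoring: the lowest cells of each metabolite drop first
        for (j in seq_len(ncol(vals))) {
          n_miss <- rbinom(1L, nrow(vals), cfg$missing_rate)
          if (n_miss >= nrow(vals)) n_miss <- nrow(vals) - 1L
          if (n_miss > 0L) {
            vals[order(vals[, j])[seq_len(n_miss)], j] <- NA_real_
          }
        }
      }
      # the imputation contract needs >= 1 observed value per metabolite
      empty <- which(colSums(!is.na(vals)) == 0L)
      for (j in empty) vals[1L, j] <- 2^(baseline[[j]])
    }
    colnames(vals) <- mets
    abundance[[k]] <- abund_rebuild(vals, sample_id, "raw")
    design_all[[k]] <- tibble::tibble(
      sample_id = sample_id, model_id = models[[k]], group = group,
      replicate = rep(seq_len(n), 2L)
    )
  }
  list(abundance = abundance,
       design = dplyr::bind_rows(design_all),
       annotation = annotation,
       truth = truth)
}

gen_annotation <- function(cfg) {
  supers <- super_pathways()[seq_len(cfg$n_pathways_super)]
  # nest sub-pathways in supers (each super gets at least one)
  sub_super <- supers[1L + (seq_len(cfg$n_pathways_sub) - 1L) %%
                        cfg$n_pathways_super]
  subs <- sprintf("%s sub-pathway %d", sub_super,
                  stats::ave(seq_len(cfg$n_pathways_sub), sub_super,
                             FUN = seq_along))
  seeds <- spawn_seeds(cfg$seed + 104729L, 1L)
  set.seed(seeds[[1L]])
  sub_idx <- sample.int(cfg$n_pathways_sub, cfg$n_metabolites,
                        replace = TRUE)
  tibble::tibble(
    metabolite_id = met_ids(cfg),
    super_pathway = sub_super[sub_idx],
    sub_pathway = subs[sub_idx],
    low_confidence = runif(cfg$n_metabolites) < 0.05
  )
}

#' Generate a synthetic injury/treatment expression study
#'
#' Simulates log2-scale expression for three groups (`sham`,
#' `injury_vehicle`, `injury_treated`) supporting two contrasts:
#' injury (injured-vehicle vs sham) and treatment (treated vs vehicle).
#' Planted rescue genes are shifted down by `rescue_effect` in both
#' injured groups and restored (back up by `rescue_effect`) in the
#' treated group, so they are down in the injury contrast and up in the
#' treatment contrast; `planted_degs` add arbitrary effects to either
#' contrast; all other genes are null. Gene sets (regeneration,
#' mitochondrial, metabolic) are drawn as random panels enriched for
#' the planted genes.
#'
#' @param cfg A [synth_config()].
#' @return A list: `expression` (tibble, sample_id + gene columns),
#'   `design` (sample_id, group, replicate), `gene_sets` (named list of
#'   id vectors), `truth` (list with `degs` tibble and `rescue_genes`).
#' @export
gen_expression_study <- function(cfg) {
  validate_synth_config(cfg)
  genes <- gene_ids(cfg)
  n <- cfg$n_samples_per_group_expr
  groups <- c("sham", "injury_vehicle", "injury_treated")
  seeds <- spawn_seeds(cfg$seed + 15485863L, 2L)
  set.seed(seeds[[1L]])
  baseline <- rnorm(cfg$n_genes, mean = 6, sd = 2)
  sample_id <- sprintf("%s_r%d", rep(groups, each = n),
                       rep(seq_len(n), length(groups)))
  group <- rep(groups, each = n)
  mu <- matrix(baseline, nrow = length(sample_id), ncol = cfg$n_genes,
               byrow = TRUE)
  rescue <- cfg$planted_rescue_genes
  if (length(rescue)) {
    cols <- match(rescue, genes)
    mu[group != "sham", cols] <- mu[group != "sham", cols] -
      cfg$rescue_effect
    mu[group == "injury_treated", cols] <-
      mu[group == "injury_treated", cols] + cfg$rescue_effect
  }
  degs <- cfg$planted_degs
  if (!is.null(degs)) {
    for (i in seq_len(nrow(degs))) {
      j <- match(degs$gene_id[[i]], genes)
      rows <- if (degs$contrast[[i]] == "injury") {
        group %in% c("injury_vehicle", "injury_treated")
      } else {
        group == "injury_treated"
      }
      mu[rows, j] <- mu[rows, j] + degs$log2fc[[i]]
    }
  }
  set.seed(seeds[[2L]])
  vals <- mu + matrix(rnorm(length(mu), sd = cfg$expression_log_sd),
                      nrow = nrow(mu))
  colnames(vals) <- genes
  expression <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id),
    tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  )
  planted_ids <- unique(c(rescue, if (!is.null(degs)) degs$gene_id))
  gene_sets <- list(
    regeneration = draw_gene_set(genes, planted_ids, 150L),
    mitochondrial = draw_gene_set(genes, planted_ids, 120L),
    metabolic = draw_gene_set(genes, planted_ids, 200L)
  )
  truth_degs <- dplyr::bind_rows(
    if (!is.null(degs)) tibble::as_tibble(degs),
    if (length(rescue)) {
      dplyr::bind_rows(
        tibble::tibble(gene_id = rescue, contrast = "injury",
                       log2fc = -cfg$rescue_effect),
        tibble::tibble(gene_id = rescue, contrast = "treatment",
                       log2fc = cfg$rescue_effect)
      )
    }
  )
  list(expression = expression,
       design = tibble::tibble(sample_id = sample_id, group = group,
                               replicate = rep(seq_len(n),
                                               length(groups))),
       gene_sets = gene_sets,
       truth = list(degs = truth_degs, rescue_genes = rescue))
}

draw_gene_set <- function(genes, planted, size) {
  size <- min(size, length(genes))
  base <- sample(genes, size)
  unique(c(base, sample(planted, min(length(planted),
                                     ceiling(length(planted) / 2)))))
}

#' Generate a synthetic metabolite-screen plate
#'
#' Emulates a 96-well proliferation screen: 6 vehicle wells share a
#' baseline confluence, and each (metabolite, concentration) condition
#' gets 6 treated wells whose confluence is the baseline multiplied by
#' the metabolite's planted effect, plus well-to-well Gaussian noise.
#' Confluence is clamped to \[0, 100\] percent.
#'
#' @param cfg A [synth_config()]; `screen_effects` names the screened
#'   metabolites (default: three null metabolites if unset).
#' @return A tibble with columns `metabolite`, `concentration`, `unit`,
#'   `well`, `group`, `confluence`, `day`, plus the planted effects as
#'   the `truth` attribute.
#' @export
gen_screen_plate <- function(cfg) {
  validate_synth_config(cfg)
  effects <- cfg$screen_effects %||%
    setNames(rep(1, 3), paste0("screen_met_", 1:3))
  seeds <- spawn_seeds(cfg$seed + 32452843L, 1L)
  set.seed(seeds[[1L]])
  vehicle <- tibble::tibble(
    metabolite = NA_character_, concentration = NA_real_, unit = "uM",
    well = sprintf("V%02d", 1:6), group = "vehicle",
    confluence = pmin(100, pmax(0, rnorm(6, cfg$screen_baseline,
                                         cfg$screen_sd))),
    day = 6L
  )
  conds <- tidyr::expand_grid(
    metabolite = names(effects),
    concentration = cfg$screen_concentrations
  )
  treated <- purrr::pmap_dfr(conds, function(metabolite, concentration) {
    eff <- effects[[metabolite]]
    tibble::tibble(
      metabolite = metabolite, concentration = concentration, unit = "uM",
      well = sprintf("%s_%g_%d", metabolite, concentration, 1:6),
      group = "treated",
      confluence = pmin(100, pmax(0, rnorm(
        6, cfg$screen_baseline * eff, cfg$screen_sd
      ))),
      day = 6L
    )
  })
  out <- dplyr::bind_rows(vehicle, treated)
  attr(out, "truth") <- effects
  out
}
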