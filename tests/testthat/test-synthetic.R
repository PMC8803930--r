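test_that("generators are byte-identical under a fixed seed", {
  cfg <- synth_config(n_models = 3, n_metabolites = 40, n_genes = 50,
                      planted_rescue_genes = c("gene_00001", "gene_00002"),
                      screen_effects = c(uridine = 1.5, metA = 1.0),
                      seed = 42L)
  expect_identical(gen_metabolome_study(cfg), gen_metabolome_study(cfg))
  expect_identical(gen_expression_study(cfg), gen_expression_study(cfg))
  expect_identical(gen_screen_plate(cfg), gen_screen_plate(cfg))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(n_models = 0), "n_models")
  expect_error(synth_config(abundance_log_sd = -1), "abundance_log_sd")
  expect_error(
    synth_config(n_metabolites = 10, planted_up_metabolites = tibble::tibble(
      metabolite_id = "met_9999", models = list(1L), log2fc = 2
    )),
    "planted_up_metabolites"
  )
  expect_error(
    synth_config(n_models = 2, planted_up_metabolites = tibble::tibble(
      metabolite_id = "met_0001", models = list(5L), log2fc = 2
    )),
    "planted_up_metabolites"
  )
  expect_error(synth_config(planted_rescue_genes = "nope"),
               "planted_rescue_genes")
})

test_that("MCAR missingness hits the configured rate (3-sigma binomial bound)", {
  # 10 samples x 1000 metabolites = 10,000 cells at rate 0.1
  cfg <- synth_config(n_models = 1, n_samples_per_group = 5,
                      n_metabolites = 1000, missing_rate = 0.1, seed = 7L)
  m <- gen_metabolome_study(cfg)$abundance[[1L]]
  v <- as.matrix(m[-1L])
  rate <- mean(is.na(v))
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / length(v)) + 1e-3)
})

test_that("planted metabolite effects land on the configured log2FC", {
  planted <- tibble::tibble(metabolite_id = "met_0001",
                            models = list(1L), log2fc = 2)
  cfg <- synth_config(n_models = 2, n_samples_per_group = 30,
                      n_metabolites = 20, missing_rate = 0,
                      planted_up_metabolites = planted, seed = 11L)
  study <- gen_metabolome_study(cfg)
  ratio_in <- function(model) {
    m <- study$abundance[[model]]
    d <- dplyr::filter(study$design, model_id == model)
    hi <- m$met_0001[m$sample_id %in%
                       d$sample_id[d$group == "high_regen"]]
    lo <- m$met_0001[m$sample_id %in% d$sample_id[d$group == "control"]]
    log2(mean(hi) / mean(lo))
  }
  # 3 SE of the difference of two log-mean estimates at sd 0.25, n = 30
  se3 <- 3 * cfg$abundance_log_sd * sqrt(2 / 30)
  expect_lt(abs(ratio_in("model_01") - 2), se3 + 0.05)
  # effect planted in model 1 only
  expect_lt(abs(ratio_in("model_02")), se3 + 0.05)
})

test_that("annotation nests every sub-pathway in exactly one super-pathway", {
  cfg <- synth_config(n_models = 1, n_metabolites = 300,
                      n_pathways_super = 9, n_pathways_sub = 40, seed = 3L)
  ann <- gen_metabolome_study(cfg)$annotation
  expect_setequal(unique(ann$super_pathway),
                  intersect(super_pathways(), ann$super_pathway))
  nesting <- dplyr::distinct(ann, sub_pathway, super_pathway)
  expect_equal(anyDuplicated(nesting$sub_pathway), 0L)
})

test_that("planted rescue genes are recovered by the default pipeline", {
  # |effect| = 2, n = 6/group: >= 90% recall over repeated simulations
  rescue <- sprintf("gene_%05d", 1:5)
  n_sim <- 25L
  recalls <- vapply(seq_len(n_sim), function(s) {
    cfg <- synth_config(n_models = 1, n_genes = 400,
                        planted_rescue_genes = rescue, seed = 100L + s)
    study <- gen_expression_study(cfg)
    injury <- test_deg(study$expression, study$design,
                       contrast = c("sham", "injury_vehicle"))
    treatment <- test_deg(study$expression, study$design,
                          contrast = c("injury_vehicle", "injury_treated"))
    rs <- rescue_degs(injury, treatment)
    mean(rescue %in% rs$gene_id[rs$set == "rescue_up"])
  }, numeric(1L))
  expect_gte(mean(recalls), 0.9)
})

test_that("with nothing planted, rescue sets stay at the false-positive floor", {
  sizes <- vapply(1:15, function(s) {
    cfg <- synth_config(n_models = 1, n_genes = 300, seed = 500L + s)
    study <- gen_expression_study(cfg)
    injury <- test_deg(study$expression, study$design,
                       contrast = c("sham", "injury_vehicle"))
    treatment <- test_deg(study$expression, study$design,
                          contrast = c("injury_vehicle", "injury_treated"))
    nrow(rescue_degs(injury, treatment))
  }, numeric(1L))
  # joint BH+lfc false positives are rare; the null world stays near-empty
  expect_lte(mean(sizes > 0), 0.2)
})

test_that("screen plates carry 6 treated + 6 vehicle wells and planted effects rank correctly", {
  cfg <- synth_config(screen_effects = c(strong = 1.5, weak = 1.2,
                                         null = 1.0),
                      seed = 9L)
  plate <- gen_screen_plate(cfg)
  expect_equal(sum(plate$group == "vehicle"), 6L)
  counts <- plate |>
    dplyr::filter(group == "treated") |>
    dplyr::count(metabolite, concentration)
  expect_true(all(counts$n == 6L))

  # null effect: mean ratio ~ 1; 1.5 outranks 1.2 in >= 95% of seeds
  wins <- 0L
  nulls <- numeric(40L)
  for (s in 1:40) {
    plate_s <- gen_screen_plate(
      synth_config(screen_effects = c(strong = 1.5, weak = 1.2,
                                      null = 1.0), seed = 1000L + s)
    )
    ranked <- rank_screen(plate_s)
    wins <- wins + (ranked$metabolite[[1L]] == "strong")
    nulls[[s]] <- ranked$relative_proliferation[ranked$metabolite == "null"]
  }
  expect_gte(wins / 40, 0.95)
  expect_lt(abs(mean(nulls) - 1), 0.05)
})
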