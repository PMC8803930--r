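make_results <- function() {
  list(
    m1 = toy_contrast(c("a", "b", "c"), c("up", "down", "none")),
    m2 = toy_contrast(c("a", "b"), c("up", "none")),
    m3 = toy_contrast(c("a", "c"), c("none", "down"))
  )
}

test_that("direction matrix codes significance and absence correctly", {
  tbl <- build_direction_matrix(make_results())
  a <- tbl[tbl$feature_id == "a", ]
  expect_equal(c(a$m1, a$m2, a$m3), c(1L, 1L, 0L))
  expect_equal(a$up_count, 2L)
  b <- tbl[tbl$feature_id == "b", ]
  expect_equal(c(b$m1, b$m2), c(-1L, 0L))
  expect_true(is.na(b$m3))  # untested, never 0
  expect_equal(b$down_count, 1L)

  # permuting model order permutes columns only
  tbl2 <- build_direction_matrix(rev(make_results()))
  expect_equal(
    dplyr::arrange(tibble::as_tibble(tbl2), feature_id)[
      c("feature_id", "m1", "m2", "m3", "up_count", "down_count")],
    dplyr::arrange(tibble::as_tibble(tbl), feature_id)[
      c("feature_id", "m1", "m2", "m3", "up_count", "down_count")],
    ignore_attr = TRUE
  )

  expect_error(build_direction_matrix(make_results()[1]), "2 models")
  dup <- make_results()[c(1, 1, 2)]
  expect_error(build_direction_matrix(dup), "uniquely named")
})

test_that("candidate selection applies the >=k rule, pathway filter and ordering", {
  results <- list(
    m1 = toy_contrast(c("nuc4", "nuc3", "xeno5", "lip4"),
                      c("up", "up", "up", "up"),
                      log2fc = c(1, 1, 1, 3)),
    m2 = toy_contrast(c("nuc4", "nuc3", "xeno5", "lip4"),
                      c("up", "up", "up", "up"),
                      log2fc = c(2, 1, 1, 1)),
    m3 = toy_contrast(c("nuc4", "nuc3", "xeno5", "lip4"),
                      c("up", "up", "up", "up")),
    m4 = toy_contrast(c("nuc4", "nuc3", "xeno5", "lip4"),
                      c("up", "none", "up", "up")),
    m5 = toy_contrast(c("nuc4", "nuc3", "xeno5", "lip4"),
                      c("none", "none", "up", "none"))
  )
  ann <- tibble::tibble(
    metabolite_id = c("nuc4", "nuc3", "xeno5", "lip4"),
    super_pathway = c("Nucleotide", "Nucleotide", "Xenobiotics", "Lipid"),
    sub_pathway = "s", low_confidence = FALSE
  )
  tbl <- build_direction_matrix(results)
  cand <- select_candidates(tbl, ann, min_models = 4)
  # nuc3 only 3 models; xeno5 excluded by super-pathway filter
  expect_setequal(cand$metabolite_id, c("nuc4", "lip4"))
  # equal support (4): tie broken by larger supporting |log2FC| (lip4: 3)
  expect_equal(cand$metabolite_id, c("lip4", "nuc4"))

  # raising min_models never adds candidates (monotonicity)
  for (k in 1:5) {
    ck <- select_candidates(tbl, ann, min_models = k)$metabolite_id
    ck1 <- select_candidates(tbl, ann, min_models = k + 1)$metabolite_id
    expect_true(all(ck1 %in% ck))
  }

  expect_error(select_candidates(tbl, ann, super_filter = "Lipidz"),
               "super-pathway")
  expect_error(select_candidates(tbl, ann[-1L, ], min_models = 1),
               "annotation missing")
})

test_that("planted convergent metabolites are recovered with high precision/recall", {
  planted_ids <- sprintf("met_%04d", 1:10)
  n_seeds <- 20L
  stats <- vapply(seq_len(n_seeds), function(s) {
    planted <- tibble::tibble(
      metabolite_id = planted_ids,
      models = rep(list(1:4), 10),   # up in exactly 4 of 11 models
      log2fc = 2
    )
    cfg <- synth_config(n_models = 11, n_samples_per_group = 5,
                        n_metabolites = 120, abundance_log_sd = 0.25,
                        missing_rate = 0,
                        planted_up_metabolites = planted,
                        seed = 3000L + s)
    study <- gen_metabolome_study(cfg)
    results <- lapply(names(study$abundance), function(model) {
      d <- dplyr::filter(study$design, model_id == model)
      test_dpmp(normalize_for_testing(study$abundance[[model]]), d)
    })
    names(results) <- names(study$abundance)
    tbl <- build_direction_matrix(results)
    cand <- select_candidates(tbl, study$annotation, min_models = 4,
                              super_filter = NULL)
    tp <- sum(cand$metabolite_id %in% planted_ids)
    c(recall = tp / length(planted_ids),
      precision = if (nrow(cand)) tp / nrow(cand) else 1)
  }, numeric(2L))
  expect_gte(mean(stats["recall", ]), 0.9)
  expect_gte(mean(stats["precision", ]), 0.9)
})

test_that("model similarity recovers planted structure and invariances", {
  profiles <- tibble::tibble(
    model_id = rep(c("A", "B"), each = 3),
    feature_id = rep(c("f1", "f2", "f3"), 2),
    log2fc = c(1, 2, 3, 1, 2, 3)
  )
  tree <- model_similarity(profiles)
  expect_equal(unname(tree$distance["A", "B"]), 0, tolerance = 1e-12)

  anti <- profiles
  anti$log2fc[4:6] <- -anti$log2fc[4:6]
  tree2 <- model_similarity(anti)
  expect_equal(unname(tree2$distance["A", "B"]), 2, tolerance = 1e-12)

  # correlation distance invariant to per-model affine rescaling
  set.seed(60)
  prof3 <- tidyr::expand_grid(model_id = c("A", "B", "C"),
                              feature_id = sprintf("f%02d", 1:30)) |>
    dplyr::mutate(log2fc = rnorm(dplyr::n()))
  t_raw <- model_similarity(prof3)
  scaled <- prof3 |>
    dplyr::mutate(log2fc = dplyr::case_match(model_id,
                                             "A" ~ 3 * log2fc + 1,
                                             "B" ~ 0.5 * log2fc - 2,
                                             "C" ~ log2fc))
  t_scaled <- model_similarity(scaled)
  expect_equal(t_raw$distance, t_scaled$distance, tolerance = 1e-12)

  # planted shared effect: A and B join before C in nearly every seed
  joins_first <- vapply(1:40, function(s) {
    set.seed(7000 + s)
    shared <- rnorm(40, sd = 1)
    prof <- dplyr::bind_rows(
      tibble::tibble(model_id = "A", feature_id = sprintf("f%02d", 1:40),
                     log2fc = shared + rnorm(40, sd = 0.3)),
      tibble::tibble(model_id = "B", feature_id = sprintf("f%02d", 1:40),
                     log2fc = shared + rnorm(40, sd = 0.3)),
      tibble::tibble(model_id = "C", feature_id = sprintf("f%02d", 1:40),
                     log2fc = rnorm(40, sd = 1))
    )
    tr <- model_similarity(prof)$hclust
    all(tr$merge[1, ] < 0) &&
      setequal(tr$labels[-tr$merge[1, ]], c("A", "B"))
  }, logical(1L))
  expect_gte(mean(joins_first), 0.95)

  # Newick export round-trips through ape
  nwk <- write_newick(model_similarity(prof3))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))

  one <- dplyr::filter(profiles, model_id == "A")
  expect_error(model_similarity(one), "2 models")
})

test_that("PLS-DA separates planted groups and collapses under permuted labels", {
  sil1 <- function(scores, groups) {
    # 1-D silhouette on component 1, two groups
    s <- vapply(seq_along(scores), function(i) {
      own <- abs(scores[i] - scores[groups == groups[i]])
      other <- abs(scores[i] - scores[groups != groups[i]])
      a <- sum(own) / (length(own) - 1)
      b <- mean(other)
      (b - a) / max(a, b)
    }, numeric(1L))
    mean(s)
  }
  planted <- tibble::tibble(metabolite_id = sprintf("met_%04d", 1:10),
                            models = rep(list(1L), 10), log2fc = 2)
  cfg <- synth_config(n_models = 1, n_samples_per_group = 6,
                      n_metabolites = 50, missing_rate = 0,
                      planted_up_metabolites = planted, seed = 70L)
  study <- gen_metabolome_study(cfg)
  auto <- auto_scale(normalize_for_testing(study$abundance[[1L]]))
  fit <- plsda_ordination(auto, study$design)
  expect_equal(dim(as.matrix(fit$scores[c("comp1", "comp2")])),
               c(12L, 2L))
  expect_gt(sil1(fit$scores$comp1, fit$scores$group), 0)

  # permutation null: supervised ordination overfits when features
  # outnumber samples, so the null world uses n >> p; the permuted-label
  # silhouette then sits near 0 while the true labeling stays extreme
  planted2 <- tibble::tibble(metabolite_id = c("met_0001", "met_0002"),
                             models = rep(list(1L), 2), log2fc = 2)
  cfg2 <- synth_config(n_models = 1, n_samples_per_group = 30,
                       n_metabolites = 5, missing_rate = 0,
                       planted_up_metabolites = planted2, seed = 72L)
  study2 <- gen_metabolome_study(cfg2)
  auto2 <- auto_scale(normalize_for_testing(study2$abundance[[1L]]))
  obs_sil <- sil1(plsda_ordination(auto2, study2$design)$scores$comp1,
                  study2$design$group)
  set.seed(71)
  sils <- vapply(1:50, function(i) {
    d <- study2$design
    d$group <- sample(d$group)
    sil1(plsda_ordination(auto2, d)$scores$comp1, d$group)
  }, numeric(1L))
  expect_lt(abs(mean(sils)), 3 * stats::sd(sils) / sqrt(length(sils)) + 0.05)
  expect_true(all(sils < obs_sil))  # empirical p = 1/51

  single <- dplyr::mutate(study$design, group = "one")
  expect_error(plsda_ordination(auto, single), "2 classes")
})

test_that("permutation correlation is deterministic and obeys the add-one formula", {
  set.seed(80)
  base <- rnorm(9)
  m <- toy_abundance(list(a = base + 5, b = 2 * base + 10,
                          c = rnorm(9) + 5), stage = "median_scaled")
  d <- tibble::tibble(sample_id = m$sample_id,
                      group = rep(c("g1", "g2", "g3"), each = 3))
  r1 <- permutation_correlation(m, d, n_perm = 100, seed = 4L)
  r2 <- permutation_correlation(m, d, n_perm = 100, seed = 4L)
  expect_identical(r1, r2)

  # a and b are perfectly correlated; permutations break pairing, so no
  # permuted |r| reaches 1 and the empirical p is 1/101
  expect_equal(unname(r1$observed["a", "b"]), 1, tolerance = 1e-12)
  expect_equal(unname(r1$p_value["a", "b"]), 1 / 101)

  # independent metabolites: mean permuted |r| stays at the null scale
  set.seed(81)
  big <- toy_abundance(
    setNames(lapply(1:20, function(i) rnorm(30) + 10),
             sprintf("x%02d", 1:20)),
    stage = "median_scaled"
  )
  dd <- tibble::tibble(sample_id = big$sample_id, group = "all")
  rr <- permutation_correlation(big, dd, n_perm = 30, seed = 5L)
  off <- abs(rr$mean_cor[upper.tri(rr$mean_cor)])
  expect_lte(mean(off), 3 / sqrt(30))

  expect_error(permutation_correlation(m, d, n_perm = 0), "n_perm")
})
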