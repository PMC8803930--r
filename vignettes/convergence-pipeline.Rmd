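---
title: "Cross-species metabolomic convergence: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species metabolomic convergence: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(regenconverge)
library(dplyr)
```

## The scientific problem

Tissues and organisms differ enormously in how well they regenerate:
an axolotl regrows an amputated limb, deer regrow antlers annually,
young primate tissues repair better than aged ones, and wild-type human
mesenchymal stem cells (hMSCs) self-renew better than prematurely aged
(Werner-syndrome) ones. If a metabolite consistently rises with
regenerative capacity across such phylogenetically distant systems,
that convergence is itself evidence that the metabolite sits in a
conserved pro-regenerative program — and makes it a candidate for
supplementation experiments.

`regenconverge` implements the desk-side half of that argument as a
reusable, tested pipeline: per-model differential analysis of
untargeted metabolomics, pathway-level aggregation, cross-model
convergence counting, and the downstream checks (rescue differential
expression, joint pathway over-representation, proliferation-screen
ranking) that turn a convergent metabolite into a ranked, testable hit.

## The statistics, briefly

**Normalization.** Untargeted metabolomics area counts arrive with
missing cells, assumed below the detection limit. Each metabolite's
missing cells are imputed with its observed minimum, each metabolite is
rescaled so its median equals 1, and — for testing and ordination
only — auto-scaled (mean-centred, divided by the sample standard
deviation, denominator $n-1$). Fold changes are always computed on
median-scaled values, since ratios are meaningless after centring.

**DPMP calling.** A differentially present metabolic product is a
metabolite with two-sample test $P < 0.05$ (raw, not adjusted — BH
q-values are reported alongside but do not drive the flag). The default
engine is Welch's $t$; pooled-variance $t$ and Wilcoxon rank-sum (normal
approximation with tie and continuity correction) are selectable. The
Welch statistic is invariant under per-feature affine maps applied to
all samples, so p-values agree to numerical precision whether computed
on median-scaled or auto-scaled values — a property the test suite
asserts at $10^{-9}$.

**Pathway DA score.** For each super- or sub-pathway,

$$\mathrm{DA} = \frac{\#\,\text{increased} - \#\,\text{decreased}}
{\#\,\text{identified in pathway}} \in [-1, 1],$$

with $-1$ meaning every identified metabolite decreased and $+1$ every
one increased. "Increased/decreased" count significant DPMPs by
direction (a `count_all` switch counts every metabolite by fold-change
sign instead); the denominator is every *tested* metabolite of the
pathway, a deliberate choice where the original per-model QC panels are
unknowable. Swapping group labels flips every direction and negates
every score exactly — an antisymmetry the tests assert.

**DEG calling and rescue sets.** Genes are significant when the
BH-adjusted $P < 0.05$ **and** $|\log_2 \mathrm{FC}| > 0.25$, both
strict (the raw-$p$ dialect used for the primate tissue contrasts is a
switch). Rescue DEGs intersect opposite directions across two
contrasts: down upon injury $\cap$ up upon treatment ("rescue up"), and
the mirror. The DE score of a gene set is the fraction of its tested
members that are DEGs; the *relative* DE score divides by the
background DEG rate of the whole universe — that ratio definition is a
declared choice (the quantity is displayed but never defined in the
source analyses) and is reported as absent when the background rate
is zero.

**Convergence.** Per-model contrast results are recoded to a
metabolite-by-model matrix of $\{+1, -1, 0, \mathrm{NA}\}$ (significant
up / significant down / tested-null / untested). Candidates are
metabolites significantly up in at least `min_models = 4` models whose
super-pathway is Nucleotide, Amino Acid or Lipid; ties in support are
broken by the largest supporting $|\log_2\mathrm{FC}|$, then id, so the
ordering is total and reproducible.

**Joint pathway over-representation.** Significant genes and
metabolites are pooled into one hit list and each pathway is scored
with a one-sided hypergeometric tail on the pooled universe. This
deliberately drops the topology weighting of web-tool joint pathway
analysis — no pathway graphs ship with the package — and is labelled a
simplification. An exhaustive-enumeration oracle checks the tail
probabilities exactly for universes up to 25 features.

**Permutation correlation.** Metabolite-metabolite Pearson
correlations are assessed with 100 replicate permutations: each
permutation independently reshuffles every metabolite's values across
replicates *within* each group (shuffling rows identically would leave
correlations untouched), and the reported matrix is the mean
coefficient over permutations. Empirical significance uses the add-one
convention $p = (1 + \#\{|r_{perm}| \ge |r_{obs}|\})/(B + 1)$, so the
smallest attainable $p$ at $B = 100$ is $1/101$.

**PLS-DA.** Two-block partial least squares against a centred one-hot
class response, fitted by NIPALS with deterministic initialization
(first response column) — reproducible with no seed. See the
limitations below before reading anything into score separation.

**Screen ranking.** Each (metabolite, concentration) condition's mean
confluence over its 6 treated wells is divided by the mean of the 6
shared vehicle wells; each metabolite is summarised by its best
concentration (maximum ratio; mean-across-concentrations by flag), ties
broken toward the lower dose. Ratios are scale-invariant, and ranking
is a permutation of the tested metabolites.

## The synthetic stated world

Every input the pipeline consumes can be generated with planted ground
truth, so recovery is measurable without any external download. The
defaults were chosen once to mirror the emulated study design and are
not revisited:

| parameter | default | why |
|---|---|---|
| models | 11 | axolotl blastema, antler stem cells, 8 primate tissues, hMSCs |
| metabolites / panel | 500 | inside the 400–759 range of the emulated panels |
| samples / group (metabolome) | 5 | typical untargeted replication; configurable |
| abundance noise | SD 0.25 on log2 | modest biological+technical spread; abundances log-normal |
| missingness | 10% MCAR (censoring mode available) | realistic missing fraction for area counts |
| genes | 2000, SD 0.4 on log2, n = 6/group | desk-scale bulk expression panel |
| rescue effect | \|log2FC\| = 2 | the recovery world's stated effect |
| screen | baseline 40% confluence, well SD 3 points | day-6 live-imaging scale |

A master seed spawns independent per-model substreams, so adding a
model never perturbs earlier ones, and every generator is byte-identical
under a fixed seed.

What the generator does **not** emulate: correlated metabolite blocks,
batch effects, retention-time artifacts, heteroscedastic
mean-variance trends in expression, plate-edge effects. A green test
therefore establishes correctness of the statistical machinery on its
stated model, not robustness to those real-world pathologies.

## Numerical and design choices

- **Test choice for DPMPs.** The upstream description delegates to a
  web tool without naming the test; Welch's $t$ is the default because
  the standard two-group metabolomics workflow is $t$-based, with
  Wilcoxon as the robustness option.
- **Zero-variance metabolites** cannot be auto-scaled and are dropped
  with a warning before testing.
- **Zero group means** leave the fold change undefined (`NA`) with the
  p-value still reported; direction falls back to the sign of the mean
  difference.
- **BH adjustment** is the classical step-up (sort, $p_{(i)} m/i$,
  cumulative minimum from the largest rank, cap at 1), cross-checked
  against a brute-force implementation and `stats::p.adjust` to
  $10^{-12}$.
- **Dendrograms** default to correlation distance ($1 - r$) with
  average linkage, computed on pairwise-complete shared features since
  real panels differ between models; a strict all-model intersection
  mode exists. Both metric and linkage are tags on the returned object
  and exportable to Newick.
- **Low-confidence identifications** (the "*" mark) are included by
  default and excludable by flag.

## Minimum imputation and MCAR missingness: a real limitation

Minimum imputation assumes missingness means "below detection limit".
When missing cells are instead MCAR, a missing cell in the *high* group
of a strongly increased metabolite gets replaced by the global column
minimum — typically a control-group value several-fold lower — which
drags the high group's mean down and inflates its variance. Measured on
the planted recovery world (log2FC = 2, 4 of 11 models, noise SD 0.25),
candidate recall drops from ~1.0 on complete data to ~0.89 at 5% MCAR
and ~0.78 at 10% MCAR. The calibration and recovery test worlds
therefore use complete data, isolating the statistical machinery; the
generator's `missingness = "censor"` mode produces data that match the
imputation's own assumption. Analysts with substantial MCAR missingness
should expect attenuated sensitivity for their strongest hits.

## PLS-DA overfits when features outnumber samples

With $p \gg n$ the first latent component can separate *any* labelling
of the samples: at $n = 6$/group and $p = 50$ the mean silhouette of
component-1 scores under permuted labels is ~0.73 — visually
"separated", entirely spurious. The bias decays like $p/n$ (~0.04 at
$n = 30$/group, $p = 5$). Score plots alone are therefore never
evidence of class difference; the meaningful statement is
permutation-based (the true labelling beating all permuted ones), which
is how the test suite frames it.

## Thresholds near the convergence cutoff are unstable

A metabolite truly up in $k-1$ models needs only one false-positive
model (probability $\approx 1-(1-\alpha/2)^{m-k+1}$, ~18% at
$\alpha = 0.05$, 11 models, $k = 4$) to be promoted past the
$\ge k$ rule. Exact candidate counts are stable only for effects at
least two noise hits away from the threshold; interpret borderline
support counts accordingly.

## A worked example

```{r example}
planted <- tibble::tibble(
  metabolite_id = sprintf("met_%04d", 1:5),
  models = rep(list(1:5), 5),   # up in models 1-5
  log2fc = 2
)
cfg <- synth_config(n_models = 6, n_metabolites = 80,
                    planted_up_metabolites = planted, seed = 11L)
study <- gen_metabolome_study(cfg)

results <- lapply(names(study$abundance), function(model) {
  d <- filter(study$design, model_id == model)
  study$abundance[[model]] |>
    impute_minimum() |>
    rescale_median() |>
    test_dpmp(d)
})
names(results) <- names(study$abundance)

conv <- build_direction_matrix(results)
select_candidates(conv, study$annotation, min_models = 4,
                  super_filter = NULL)
```

```{r da}
da_score(results, study$annotation, level = "super") |>
  flag_consistent_pathways(min_models = 4)
```

## Known limitations

- The two-group engine is a desk-scale substitute for count-based
  differential expression; externally produced per-gene tables (e.g.
  from a negative-binomial model) can be ingested via
  `read_contrast()` and flow through `rescue_degs()` and the scores
  unchanged.
- Joint pathway analysis omits topology weighting.
- The screen ranks; it does not test (by design — ranking feeds a
  follow-up experiment, not an inference).
- Single-cell workflows (clustering, doublet removal) and enrichment of
  ranked lists are out of scope.
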