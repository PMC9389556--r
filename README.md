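# ifnnet

Stimulation-response co-expression networks, master regulators and
multi-omic risk prediction for paired stimulated/unstimulated immune
profiling cohorts.

## The scientific problem

Cord-blood mononuclear cells stimulated in vitro (LPS for bacterial
sensing; imiquimod and poly(I:C) for viral nucleic-acid sensing) alongside
matched unstimulated controls yield paired response profiles per subject.
A central question for infection-risk biology is whether susceptibility to
severe lower respiratory infection (sLRI) in infancy is visible in these
responses — and, in particular, whether it lives in network *wiring*
(how tightly interferon-response genes are co-regulated) rather than in
per-gene expression magnitude. `ifnnet` is for computational
immunologists and systems biologists who want that full analysis chain as
tested, reusable R functions.

## What the package computes

- **Paired differential expression** with an empirical-Bayes moderated t:
  per-gene contrasts with variances shrunk toward a gamma-moment prior,
  `t~ = b / (s~ sqrt(v))`, df = d + d0; BH FDR; strict DEG thresholds.
- **Weighted co-expression networks**: adjacency `|r|^beta` with the soft
  power chosen by signed scale-free fit; topological overlap
  `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`;
  module detection by average-linkage clustering with a static tree cut,
  stray-gene re-assignment and eigengene merging; module eigengenes
  (unit-variance PC1), intramodular connectivity kIM, scaled connectivity
  densities with a Monte-Carlo Lilliefors normality label, permutation
  preservation Z statistics, and cross-condition rank correlations of
  expression vs connectivity — the differential-wiring comparison.
- **Master-regulator inference**: mutual information by adaptive
  partitioning on copula ranks, permutation-screened edges, data-processing-
  inequality pruning, signed/weighted regulons, and two-tailed analytic
  rank-enrichment NES with an exact-moment normalizer (NES ~ N(0,1) under
  the null), plus promoter-window motif filtering of drivers.
- **Risk prediction**: OOB-tuned random forests on module genes, stratified
  repeated random re-splitting with AUC distributions (median, 95%
  percentile interval), per-resample permutation nulls, and transfer
  prediction to external cohorts on the shared gene set.
- **Multi-omic integration**: DIABLO-style multi-block sparse PLS-DA
  maximizing design-weighted covariance between block variates and the
  outcome indicator, 5-fold CV tuning, between-block correlation edge
  lists, bootstrap Spearman panels and Mann-Whitney/Hodges-Lehmann
  association estimates.
- **A synthetic-cohort generator** that plants co-expression modules,
  group-specific connectivity boosts, outcome shifts, driver TFs and
  matched external cohorts, so every stage above is testable end to end.

## Worked example

```r
library(ifnnet)

cfg <- sim_config(
  n_subjects = 40, prevalence = 0.45, n_genes = 600, stimuli = "LPS",
  modules = list(module_spec(80, "LPS", predictive = TRUE,
                             outcome_shift = 1, connectivity_boost = 1.5,
                             name = "IFN")),
  n_tfs = 2, targets_per_tf = 15, n_cytokines = 10, n_metabolites = 10,
  n_celltypes = 5, seed = 42)
cohort <- generate_cohort(cfg)

# differential expression of the LPS response
de <- fit_contrast(cohort$expr, cohort$samples, c("LPS", "CTRL"), paired = TRUE)
degs <- select_degs(de, lfc_min = 1, fdr_max = 0.01)
cat("up:", length(degs$up), " down:", length(degs$down), "\n")
#> up: 100  down: 8

# response network and modules
net <- build_adjacency(cohort$expr, power = 6, condition = "LPS")
tom <- compute_tom(net)
part <- detect_modules(tom$tom, cohort$expr, net = net)
part
#> module_partition: 600 genes
#> grey   M1
#>  495  105

# does the module eigengene stratify the outcome?
adj <- baseline_adjust(cohort$expr, cohort$samples, "LPS")
mod_genes <- names(part$labels)[part$labels == "M1"]
eg <- compute_eigengenes(adj[mod_genes, ], part$labels[mod_genes])$eigengenes[1, ]
mw <- eigengene_trait_test(eg, cohort$truth$outcome[colnames(adj)])
cat(sprintf("eigengene vs outcome: shift = %.2f, p = %.4f\n", mw$estimate, mw$p))
#> eigengene vs outcome: shift = 0.75, p = 0.0032

# resampled risk prediction from the module genes
fm <- build_feature_matrix(adj, mod_genes, cohort$truth$outcome)
params <- tune_forest(fm, seed = 1)
rd <- resample_evaluate(fm, n_resamples = 100, params = params, seed = 1)
rd
#> resample_distribution: 100 re-splits, median AUC 0.798 (95% CI 0.641-0.919)
```

Reading the output: the planted 80-gene module is recovered (105 genes
including a few correlated regulon targets; the rest stay grey); its
eigengene separates susceptible from resistant subjects (Hodges-Lehmann
shift 0.75 eigengene SD units, Mann-Whitney p = 0.0032); and a random
forest trained on the module genes predicts the outcome across 100
re-splits with a median validation AUC of 0.80.

A thin command-line wrapper over the same functions is included at
`inst/cli/ifnnet.R` (subcommands `simulate`, `de`, `network`, `predict`).

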