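---
title: "Stimulation-response networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulation-response networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnnet)
```

## The problem this package addresses

Innate immune responses measured at birth — mononuclear cells stimulated in
vitro with a bacterial ligand (LPS) or viral nucleic-acid mimics (imiquimod,
poly(I:C)) alongside matched unstimulated controls — can carry information
about a child's later risk of severe lower respiratory infection (sLRI).
Crucially, that information need not sit in expression *magnitude*: two
groups of subjects can show indistinguishable per-gene means while differing
in how tightly the response genes are *co-regulated*. `ifnnet` implements
the full analysis chain needed to ask that question: paired differential
expression, weighted co-expression networks and their differential wiring
between outcome strata, master-regulator inference, resampled risk
prediction, and supervised multi-omic integration — plus a synthetic-cohort
generator that plants every one of those signals so the chain is testable
end to end without any external data.

## The synthetic cohort generator

Each planted module is a one-factor model. For gene $g$ in module $m$,
subject $i$, condition $c$:

$$x_{gic} = \mu_g + \ell_g\,[\,m_c + \delta\,y_i\,\mathbb{1}(c = s_m)\,]
          + \ell_g\, b_i\, d_{ic} + \varepsilon_{gic},$$

where $m_c = E\,\mathbb{1}(c = s_m)$ is the stimulus mean effect
(`eigen_effect`, default 2 on the log2 scale), $\delta$ is the outcome shift
of the factor in susceptible subjects (`outcome_shift`), $d_{ic} = u_i +
r_i\,\mathbb{1}(c = s_m)$ is the stochastic factor (subject baseline $u_i$
plus response amplitude $r_i$, both standard normal), and $b_i$ equals
`connectivity_boost` for susceptible subjects and 1 otherwise. Loadings
$\ell_g$ are drawn from N(`loading_mean`, `loading_sd`) and noise from
N(0, `noise_sd`).

Two consequences of this construction are deliberate:

* the connectivity boost multiplies only the **stochastic** part of the
  factor, so susceptible subjects get stronger within-module correlation
  with *identical* marginal means — the dissociation between wiring and
  magnitude that the pipeline is designed to detect;
* the outcome shift multiplies the stimulated-sample factor mean, so it
  survives baseline adjustment (stimulated minus matched control) and is
  what the prediction harness must find.

TF genes respond to their assigned stimulus (`tf_effect`, default 2) and
drive their regulon targets with signed weights; negative modes occur with
probability `tf_mode_fraction_negative`. Cytokine and metabolite features
are noisy linear readouts of the module factors; cell proportions are
Dirichlet-like compositions independent of outcome.

Defaults mirror the emulated study design: 50 subjects, 46% outcome
prevalence (assignment is deterministic — the first
$\lceil 0.46 \cdot n\rceil$ shuffled subjects — so the count is exact for
every seed), three stimuli with matched controls, 17,363 transcripts,
39 cytokines, 47 metabolites, 8 cell types, and six interferon/
proinflammatory modules at their reported sizes. With `loading_mean = 1.5`
and `noise_sd = 1` the within-module correlation is about 0.65 — typical
for a strongly induced transcriptional program. Tests and the acceptance
script pass scaled-down gene counts (200–2,000 genes, module sizes 50–150)
so network stages stay fast; those sizes are the package's own choice of
test-problem scale.

What the generator does **not** emulate: library-size and GC artefacts of
real RNA-seq, batch effects, non-Gaussian marginal distributions,
overlapping module membership, and clinical covariates. Passing tests
therefore demonstrate that the algorithms recover the planted structure
under a clean factor model — not that any particular real cohort contains
such structure.

## Differential expression

`fit_contrast()` implements the empirical-Bayes moderated t: per-gene
linear contrasts (paired contrasts as one-sample tests on subject-wise
differences; unpaired with pooled variance), residual variances shrunk
toward a common prior estimated by the standard gamma-moment method
(log-variance moments matched to a scaled-F model, trigamma inverted by
Newton iteration), and

$$\tilde t_g = \frac{b_g}{\tilde s_g\sqrt{v}},\qquad
  \tilde s^2_g = \frac{d_0 s_0^2 + d\,s_g^2}{d_0 + d},\qquad
  \mathrm{df} = d + d_0 .$$

`prior_df` overrides $d_0$: 0 recovers the ordinary t-test exactly, `Inf`
fully pools variances. No observation-level precision weights are applied:
the generator emits approximately homoskedastic log-scale values, and the
weighting scheme used for counts-derived data is orthogonal to everything
tested here; `cpm_normalize()` provides the counts entry point
(`log2((count + prior)/(lib + 2 prior) * 10^6)`, prior 0.5).

DEG thresholds are strict inequalities; the default fold-change cutoff is
1.0 with FDR < 0.01, and the stricter 1.5 used for some reported gene
counts is available through `lfc_min`. `select_variable_genes()` ranks by
the paired-contrast p-value with ties broken by |log2FC| then gene id, so
selection is deterministic; a contrast-based ranking was chosen over an
F-test because the pipeline always works against a named stimulus.

## Co-expression networks

Adjacency is Pearson-based, `|r|^beta` (unsigned, the default) or the
signed-hybrid variant; the soft power is chosen as the smallest candidate
whose signed scale-free fit $R^2$ reaches the target (default 0.8), else
the maximizer, flagged. The topological overlap matrix follows

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
                           {\min(k_i,k_j) + 1 - a_{ij}} .$$

Module detection is a documented simplification of the dynamic hybrid tree
cut: average-linkage clustering of `1 - TOM`, a **static cut at an absolute
dissimilarity height** (default 0.99), dissolution of clusters below
`min_module_size` (30), re-assignment of stray genes to their nearest
module when their mean TOM to it reaches the module's 25th-percentile
intra-TOM, and iterative merging of modules whose eigengenes correlate
above `1 - merge_height` (0.25). A quantile-of-merge-heights cut was
rejected during development because, when most genes are unassigned noise,
nearly all merge heights crowd the top of the dendrogram and any high
quantile collapses the tree into one cluster; the absolute cut behaves like
the classic static tree cut and leaves noise in "grey". Module recovery is
judged by adjusted Rand index against planted membership, not label-exact
parity with any particular reference implementation.

Eigengenes are the first principal component of the standardized module
submatrix, unit-variance, sign-oriented so their correlation with the
module mean profile is positive. Intramodular connectivity `kIM` sums
adjacency within the module; profiles are scaled to `k/k_max`.

Two measurement conventions matter for the differential-wiring comparison:

* **stratified networks are built on baseline-adjusted responses.** The
  stimulus mean effect is shared by both outcome strata and, on pooled
  stimulated + control samples, pushes all module correlations toward their
  ceiling, masking a group-specific difference in co-regulation. Adjusting
  each subject's stimulated sample by its matched control removes that
  shared component and isolates response co-variation, which is where the
  wiring difference lives. Both strata reuse the whole-cohort soft power so
  the networks are comparable.
* the Lilliefors normality label on connectivity profiles uses a **seeded
  Monte-Carlo null** (default 2,000 draws, cached per sample size) rather
  than an approximation formula, so the test's calibration is itself a
  testable property.

Module preservation standardizes two observed statistics — mean
within-module adjacency in the test data, and the Spearman correlation of
intramodular connectivity between data sets — against permuted gene sets of
equal size (seeded, at least 20 permutations); the shared gene list is
sorted so results are invariant to input gene order.

## Regulon inference and TF activity

Mutual information uses adaptive partitioning on copula ranks: the unit
square is split into quadrants while a chi-square uniformity test rejects
(p < 0.05 on 3 df) and at least 8 points remain in the cell; cells
contribute $(n_c/n)\log\frac{n_c/n}{w_x w_y}$ nats. Edges are screened
against a pooled permutation null and pruned by the data-processing
inequality: in every fully connected triangle the strictly weakest edge is
removed when below `(1 - tolerance)` times the smaller of the other two,
with all removals decided on the original MI values (hence idempotent).
Regulon modes are Spearman correlations, likelihoods MI scaled to the
regulon maximum, and regulons below `min_targets` (10) are dropped.

TF activity is a two-tailed analytic rank-enrichment score. Signature
ranks map to normal quantiles $q$; a directional component weights $q$ by
mode × likelihood, a two-tail component weights the extremeness quantile by
(1 − |mode|) × likelihood; the components combine with the directional
sign (the two-tail part adds only when positive) and are divided by the
exact null standard deviation of the combined statistic,

$$\sqrt{w_1^2 + \tfrac{2}{\pi} w_1 w_2 + \tfrac{1}{2} w_2^2},$$

so NES is approximately standard normal under the null for *any*
mode/likelihood profile — the combined statistic is not Gaussian in shape,
so tail p-values are approximate in the same way they are in the original
two-tail enrichment formulation, but its first two moments are exact. The
score is exactly antisymmetric under mode negation. Contrast signatures
are the moderated-t vector; drivers are TFs with p < 0.05, optionally
filtered to those whose regulon targets carry the TF's promoter-window
binding motif (user-supplied table; no sequence scanning). Per-sample
activity matrices rank each baseline-adjusted column against the cohort.

## Risk prediction

The forest learner is pluggable (any bagged ensemble with class
probabilities and an OOB error report); the harness is the contribution.
Tuning is a seeded grid over `n_trees` in {250, 500, 1000, 2000} and
`m_try` in {√p/2, √p, 2√p, p/3}, minimum OOB error, ties toward the
smaller values. Splits are stratified (class proportions preserved; a
degenerate draw is redrawn and the redraw count kept) because at n = 25
per arm an unstratified split regularly produces single-class training
sets. Scores are class-1 vote fractions; AUC uses the tie-corrected rank
identity, with the swept ROC curve integrating to the same value exactly.

`resample_evaluate()` repeats the split `n_resamples` times from a derived
seed sequence with tuned parameters frozen, reporting the median and the
2.5/97.5 percentiles. Its permutation null (`permute_labels = TRUE`) draws
a **fresh label permutation for every re-split**: a single fixed
permutation retains its chance label–feature association across all
re-splits, so its resample median is biased away from 0.5 by that one
draw; re-permuting per split is the null that actually centres at chance.
Transfer prediction standardizes each gene within its own cohort before
training on the full internal cohort and scoring the external one — without
that, cross-cohort scale differences dominate the forest's splits.

At the default study conditions (n = 50, a 1-sd outcome shift on the module
factor), the realized strength of the planted signal varies considerably
between cohort draws; package checks therefore summarize the harness over
several consecutive generator seeds rather than trusting a single cohort.

## Multi-omic integration

`fit_diablo()` maximizes
$\sum_{j<k} c_{jk}\,\mathrm{cov}(X_j w_j, X_k w_k)$ over unit-norm,
cardinality-constrained loadings, with the outcome coded as a centered
dummy-indicator block and a full design (all off-diagonal weights 1) by
default. Each block update is the exact constrained maximizer (hard
thresholding to the `keep` largest absolute entries, then renormalization),
so the objective is non-decreasing — asserted per iteration in the tests —
and converges when the largest loading change drops below 1e-6 (500
iterations otherwise, with a warning and the partial model). Blocks are
deflated by regression on their own variates. With `keep` equal to the
block width and a two-block design this reduces to dense two-block PLS,
which the tests verify against a power-iteration SVD oracle. Tuning uses
stratified 5-fold cross-validation with nearest-centroid classification on
block-averaged variates, balanced error rate as the criterion, and ties
resolved toward fewer components then smaller `keep`.

Between-block edge lists come in two modes: the plotting convention
(feature–variate correlations multiplied across blocks) and raw pairwise
feature correlations; both honour the same absolute threshold (default
0.8). The bootstrap Spearman panel reports percentile intervals over
seeded resamples with BH adjustment across the panel; Mann-Whitney
associations report the Hodges-Lehmann shift of the comparison group
relative to the reference (positive = larger in the comparison group),
sharing the exact-for-small-n, tie-corrected-otherwise machinery used by
the eigengene trait test.

## Numerical and degenerate-input conventions

* All randomness flows through per-call seeds; library code saves and
  restores the caller's RNG state.
* Zero residual variances are floored at machine epsilon and flagged;
  zero-variance genes abort network construction with their names.
* Ties: mid-ranks throughout; hub and variable-gene orderings break ties
  lexicographically so outputs are deterministic.
* Mann-Whitney p-values are exact for combined n ≤ 20 without ties and
  use the tie-corrected normal approximation otherwise.
* Matrices are plain numeric matrices with gene/sample dimnames; TSV and
  GMT round-trips are provided in `io` helpers.

## Known limitations

* The tree cut is a deliberate simplification; cohorts whose modules sit
  on a connectivity continuum (no clean grey background) will be more
  sensitive to `cut_height` than the planted fixtures are.
* MI p-values pool a single permutation null across pairs, which is
  anti-conservative when marginal distributions differ strongly between
  genes; the generator's Gaussian marginals satisfy the pooling assumption.
* NES tail probabilities are moment-matched, not distribution-exact.
* Transfer prediction assumes the external cohort measures the same
  biological signal on a comparable (after per-gene standardization)
  scale; no batch or platform correction is attempted.
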