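---
title: "Methods: the dysbiosis index, beta diversity and the cohort simulator"
author: "dysbindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the dysbiosis index, beta diversity and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbindex)
```

# The problem

Type 2 diabetes (T2D) and acute ischemic stroke (AIS) both perturb the gut
microbiota, and comorbid patients show the largest community shift.
`dysbindex` implements the analysis pipeline such a study needs: a
disease-associated **dysbiosis index** fitted from genus-level 16S feature
tables, phylogeny-aware **beta diversity** (UniFrac, PCoA, distance to
controls, PERMANOVA), and **association screens** linking the index to
clinical stroke severity scores and linking taxa to outcomes in germfree
mice colonised by patient microbiota. Because per-sample data from such
studies are deposited only as raw reads, the package ships a
parameterised cohort simulator so every stage is testable end to end.

# The dysbiosis index

Fitting proceeds in three steps on whole-community relative abundances:

1. **Prevalence filter.** Genera detected (abundance > 0) in fewer than
   10% of samples are removed. The boundary is inclusive: a genus seen in
   exactly 10% of samples survives, because the filter is defined as
   discarding genera whose prevalence is *lower than* the threshold.
2. **Wilcoxon selection.** Each remaining genus is tested between the case
   group (T2D) and controls with the two-sample Wilcoxon rank-sum test.
   Genera with two-sided `p < alpha` (default 0.05, raw p) and a
   well-defined direction are selected. A genus is case-enriched when the
   mean pooled rank of the case samples exceeds the control mean rank.
3. **Weighted score.** For a sample with relative abundances $a_g$,

   $$\mathrm{index} = \sum_{g\,\in\,\text{case-enriched}} w_g\,a_g
     \;-\; \sum_{g\,\in\,\text{control-enriched}} w_g\,a_g,
     \qquad w_g = -\log_{10} p_g .$$

   Weights use $-\log_{10} p$, which is positive for $p < 1$, so that
   case-enriched genera *raise* the index and the index is higher in
   cases — the direction the study's group comparisons display. (A
   literal reading of the printed formula, with $\log_{10} p < 0$, would
   invert every comparison; we treat that as a sign typo and document the
   correction here.) p-values are floored at $10^{-300}$ before the log
   so weights stay finite.

The model is fitted **only** on the T2D-versus-control comparison and then
applied unchanged to all four groups, which is how the comorbid and
stroke-only groups are scored. Scores are raw weighted sums; no rescaling
is applied. Abundances are whole-community proportions: we do not
renormalise to the selected genera before scoring (the source analysis is
silent on this; whole-community proportions are the conservative reading,
and the choice is isolated in `computeIndexTable()` if a user wants
otherwise).

A practical consequence: a prevalence- or taxon-filtered proportion table
is a *subcomposition* — its rows sum to less than one while each retained
value keeps its whole-community scale. `FeatureTable` therefore accepts
proportion rows summing to anything in (0, 1]. This keeps "filter, then
test on whole-community proportions" representable without silent
renormalisation.

## Exact small-sample tests

Two rank tests are implemented as first-class primitives because the
pipeline leans on them at small n:

* `wilcoxonRankSum()` — statistic is the rank sum of the first sample
  (mid-ranks under ties). Exact mode enumerates all $\binom{n+m}{n}$
  assignments of the pooled ranks and reports
  $\min(1,\, 2\min(P(W \le w), P(W \ge w)))$; auto mode uses it for
  $n+m \le 12$ tie-free inputs and otherwise a tie-corrected normal
  approximation with continuity correction. A constant feature yields
  `p = 1` and direction `tied`; tied genera never enter the index model
  (the formula needs a side).
* `spearmanCorrelation()` — $\rho$ is the Pearson correlation of
  mid-ranks. Exact mode tabulates the full permutation distribution of
  the rank-difference statistic ($n! \le 9! = 362{,}880$, computed once
  per n and cached) and reports the fraction of permutations with
  $|\rho|$ at least the observed value; above $n = 9$, or under ties, a
  t approximation with $n-2$ degrees of freedom is used. The cut at
  $n \le 9$ matches the mouse study's n = 9 while staying sub-second.
  Constant inputs return an explicit degenerate record rather than NaN.

Both are verified in the test suite against independent enumeration
oracles and against the reference implementations in `stats`.

# Beta diversity

**UniFrac.** Both kernels consume a rooted `ape::phylo` with branch
lengths (the tree is an input, typically from an external placement or
*de novo* build). For each edge we precompute the descendant-leaf
incidence; a root edge, if present, is ignored — shared root length
carries no information about a pairwise difference, and conventions
differ between implementations. Unweighted UniFrac is the unique-branch
length over the union-branch length with presence defined as abundance
strictly greater than zero (no detection floor). Weighted UniFrac is
$\sum_e \ell_e\,|A_e - B_e|$ with $A_e$ the fraction of a sample
descending from edge $e$; the normalised form divides by
$\sum_e \ell_e\,(A_e + B_e)$, the leaf-depth normaliser, giving values in
[0, 1]. Distance matrices are computed over the *unfiltered* table:
prevalence filtering is an index-pipeline step, not a beta-diversity
step.

**PCoA.** Gower double-centring of $-\tfrac12 D^2$, symmetric
eigendecomposition, coordinates $v_k \sqrt{\lambda_k}$ for positive
eigenvalues. Negative eigenvalues (UniFrac matrices are generally
non-Euclidean) are reported as-is and their axes zeroed; we prefer that
transparency over a silent Cailliez or Lingoes correction. Proportion
explained is taken over the positive spectrum.

**Distance to controls.** For each non-reference sample, the mean of its
distances to every reference sample; for reference samples, the mean over
the *other* reference members. The alternative "distance to centroid"
reading would require an embedding; mean pairwise distance is computable
directly from any dissimilarity and is what we implement.

**PERMANOVA.** One-way pseudo-F from total versus within-group sums of
squared distances, $F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(n-a)}$, with the
p-value counting permuted statistics at least the observed one under the
$(c+1)/(B+1)$ convention, so p is never zero and is reproducible given
the seed. The statistic is cross-checked against `vegan::adonis2` in the
tests.

# Association screens

`scoreCorrelations()` correlates per-sample index scores with NIHSS, mRS
and Essen over all stroke samples (AIS and AIS_T2D) carrying the score,
always with mid-ranks — clinical integer scales are heavily tied.
`taxaOutcomeScreen()` runs every feature against every numeric outcome
column, pairwise-complete with per-record n (outcome columns may have
missing values, and small-n studies make n worth reporting per record);
`level = "family"` sums member abundances by the `f__` lineage component
first, which is how family-level rows such as Ruminococcaceae or S24-7
are produced. Significance is raw `p < alpha` by default with Bonferroni
available; at screen scale a raw-p display matches how such tables are
usually printed, and the per-record p values are reported at full
precision so any correction can be applied downstream.
`chiSquare2x2()` is Pearson's chi-square without continuity correction
(df = 1), with the Yates correction behind a flag. `relativeExpression()`
implements the comparative-Ct method, $2^{-\Delta\Delta C_t}$.

# The cohort simulator

`generateCohort()` emulates the processed genus table of a four-cohort
observational study — 55 controls, 90 AIS, 35 T2D and 60 comorbid
patients by default — not the sequencing that produced it.

* **Composition model.** Each group has an expected composition
  $\mathrm{softmax}(\log b + \log 2 \cdot \mathrm{lfc}_{\text{group}})$
  over a 39-genus panel with baseline proportions $b$; each sample draws
  a true composition from a Dirichlet with precision 100 around that
  expectation and counts from a multinomial with negative-binomial
  library size (mean 20,000, size 10). The Dirichlet-multinomial is a
  modelling stand-in — the emulated study publishes no abundance
  distributions — and is labelled as such in the `truth.json` the
  pipeline writes.
* **Planted effects.** The T2D effect vector places log2 fold changes of
  ±1.5 on eleven genera (enriched: Porphyromonas, Lactobacillus,
  Megasphaera, Catenibacterium, Cetobacterium and two placeholder
  Enterobacteriaceae genus buckets — the real two are unnamed at genus
  level; depleted: Blautia, Dorea, Lachnospira, Roseburia). The AIS
  vector enriches a Proteobacteria bloom (the Enterobacteriaceae buckets,
  Desulfovibrio, Bilophila, Haemophilus, Citrobacter, Klebsiella,
  Succinivibrio) and depletes Prevotella, Faecalibacterium, Lachnospira
  and Coprococcus. The comorbid group's effect vector is *definitionally*
  the sum of the two — the additive-dysbiosis hypothesis is built into
  the generator, and the additivity invariant is asserted exactly on the
  generator's internal expectations. ±1.5 gives clear but not trivial
  separation at these group sizes.
* **Where baselines sit matters.** Presence/absence distance responds to
  a shift from presence probability $q$ to $q'$ roughly as
  $(q'-q)(1-2q)$: depleting an always-present genus or enriching a
  half-prevalent one changes nothing. Planted depleted genera therefore
  start near 0.93 baseline presence (~0.5% relative abundance at the
  default depth) and planted enriched genera near 0.2 (~0.05%), so that
  disease moves them across the informative part of the presence curve.
  A tail of rarer genera sits below the 10% prevalence filter and
  exercises it.
* **Latent dysbiosis and scores.** Each sample's latent dysbiosis is the
  planted-enriched minus planted-depleted mass of its *true* (Dirichlet)
  composition — the generator's own ground truth, used for parameter-
  recovery tests rather than any fitted quantity. Clinical scores for
  stroke samples are linear in the standardised latent value plus
  Gaussian noise, rounded and clipped: NIHSS to 0–15 (the emulated
  admission criterion excludes NIHSS ≥ 16), mRS to 0–6, Essen to 0–9.
  Default slopes (3, 1.2, 1.5 score points per latent SD with noise SDs
  2, 1, 1.2) give the strong positive rank correlations the index-versus-
  severity analysis expects at n = 150 stroke samples.
* **Mouse study.** `generateMouseStudy()` (5 control-donor, 4
  diabetic-donor germfree mice by default) depletes five Ruminococcaceae
  and two Lachnospira features and enriches an S24-7 feature in the
  diabetic-donor group; a standardised latent injury value (S24-7 mass
  minus SCFA-producer mass) drives infarct ratio (clipped to [0, 1]),
  mNSS (integer 0–14), serum LBP and LPS positively, and tight-junction
  expression fold changes ($2^{-\Delta\Delta C_t}$ scale) negatively,
  with Cxcl chemokines positive. The `coupling` argument scales all
  slopes; 0 gives pure noise for null calibration.
* **Seeding.** One global seed feeds a named substream per stage
  (cohort draws, scores, tree, mouse, permutations), so changing one
  stage's draws cannot shift another's, and identical (config, seed)
  runs are bit-identical — `runPipeline()` writes a manifest of output
  checksums to make that checkable.

Random trees (`generateTree()`) are built by sequential random joins with
independent exponential(1) edge lengths and no root edge: an arbitrary
but reproducible phylogeny for UniFrac testing, not an evolutionary
model.

## What the simulator does and does not show

The generator reproduces the *statistical structure* the analysis
assumes: compositional count data with realistic overdispersion, planted
directional effects with additive comorbidity, severity scores monotone
in dysbiosis, and small-n animal outcomes coupled to community shifts.
It does not emulate real phylogenetic correlation between related genera
(the test tree is random), sequencing artifacts, batch effects,
enterotype-like mixture structure, or longitudinal sampling. Passing
tests therefore demonstrate that the pipeline recovers truth under its
own stated model, not that the model captures every property of real
16S data.

```{r quick-example, eval = TRUE}
coh <- generateCohort(syntheticConfig(seed = 1))
rel <- toRelativeAbundance(coh$table)
filt <- suppressMessages(prevalenceFilter(rel))
diffRes <- differentialGenera(filt, coh$metadata, "T2D", "control")
model <- fitIndexModel(diffRes, "T2D", "control")
model
scores <- suppressMessages(computeIndexTable(rel, model))
unlist(compareIndexGroups(scores, coh$metadata, "T2D", "control"))
```

# Numerical choices and degenerate inputs

* Unit inference on read: all-integral bodies are counts; rows summing to
  1 within 1e-6 are proportions (snapped back to exactly 1); anything
  else errors unless an explicit `unit` is passed, which always wins.
* Proportion validity tolerance is 1e-9 at construction; row sums in
  (0, 1] accommodate subcompositions; all-zero samples are always errors.
* Missing Newick branch lengths become 0 with a warning; negative or
  non-finite lengths are errors; duplicate leaf names are errors.
* Genus-absent lineages collapse into per-parent unclassified buckets
  keyed by their full lineage string, so unclassified members of
  different parents never merge.
* UniFrac floating-point negatives from the vectorised pairwise path are
  clipped at zero; the pairwise matrix is symmetrised exactly.
* Exact-test p-values are never zero (the observed arrangement counts);
  asymptotic p-values are floored at the smallest positive double.
* Wilcoxon variance of zero (fully tied input) short-circuits to p = 1.
* Rank ties everywhere use mid-ranks; duplicated pair sets leave Spearman
  rho unchanged.
* The test suite sizes its simulations to run in minutes on one CPU:
  null calibration uses 200 cohorts at 55 + 35 (differential), 500 small
  four-group cohorts of 40 samples with 199 permutations (PERMANOVA) and
  200 nine-mouse studies (screen); recovery and pattern checks use 100
  full-size cohorts each. Measured behaviour at the frozen defaults:
  comorbid distance ordering in 100/100 seeds, ≥9/11 planted genera with
  ≤2 false flags in ~88/100 seeds, mean index AUC ≈ 0.91, null rates
  0.040–0.053.

# Known limitations

* Exact Wilcoxon enumeration is practical only to n + m ≈ 20; auto mode
  switches to the (tie-corrected, continuity-corrected) normal
  approximation well before that, which is slightly conservative.
* No rarefaction step is provided: whether the emulated analysis rarefied
  genus tables before index computation is unstated, so the package takes
  tables as given and leaves depth normalisation to the caller.
* The family-aggregate screen keys on the `f__` lineage field and
  requires Greengenes-style lineages (semicolon-delimited, `k__`–`g__`
  prefixes).
* PERMANOVA is one-way only; no strata, covariates or sequential terms —
  use `vegan::adonis2` for those designs.
* LEfSe-style effect sizes, CLR/ALR compositional models, generalized
  UniFrac and ordination plotting are out of scope; coordinates and
  records are emitted as plain tables for downstream tooling.
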