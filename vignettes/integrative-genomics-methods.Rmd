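---
title: "Integrative genomic analysis of a resected PDAC trial cohort: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative genomic analysis of a resected PDAC trial cohort: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdacig)
```

# Overview

`pdacig` implements an integrative analysis of targeted-panel genomics for a
two-arm adjuvant trial cohort of resected pancreatic ductal adenocarcinoma
(PDAC): gemcitabine with or without the EGFR inhibitor erlotinib. The
pipeline has five analytical stages operating on four joined patient-level
tables (clinical, variants, copy-number calls, digital expression counts):

1. **Clonal architecture** — tumour purity and cancer cell fractions (CCF)
   from variant allele frequencies, clonal/subclonal classification, and a
   Bradley-Terry model of mutation acquisition order.
2. **Pairwise association** — Fisher tests of co-occurrence and mutual
   exclusivity over the binary alteration matrix, with Benjamini-Hochberg
   (BH) FDR control.
3. **Genetic subgroups** — non-negative matrix factorization (NMF) of the
   78-feature alteration matrix (67 SNV genes + 11 copy-number loci),
   subsampling stability, and Ward clustering of patients on their
   signature exposures.
4. **Expression biomarker** — housekeeping-normalized differential
   expression between SMAD4-altered and wild-type tumours, median
   dichotomization of MAPK9, and the four SMAD4 x MAPK9 groups.
5. **Survival** — Kaplan-Meier/log-rank machinery, univariable screening,
   multivariable Cox models with a treatment-by-biomarker interaction, and
   a random-split resampling validation of the subgroup treatment effect.

Because patient-level trial data of this kind are not public, the package
ships a first-class synthetic cohort generator whose defaults encode the
study conditions; every stage is tested against its planted ground truth.

# Clonality model

For a mutation in a copy-number-neutral region carried by a fraction CCF of
tumour cells in a sample of purity $\rho$, the expected variant allele
frequency is
$$\mathrm{VAF} = \frac{\mathrm{CCF}\,\rho\,m}{\rho\,n_t + (1-\rho)\,2}
  = \frac{\mathrm{CCF}\,\rho}{2} \quad (n_t = 2,\ m = 1).$$
The KRAS mutation is treated as the clonal heterozygous trunk event of
PDAC, giving the purity estimate $\hat\rho = \min(1,\ 2\,\mathrm{VAF}_{KRAS})$;
patients without a copy-number-neutral KRAS mutation are excluded from this
stage, mirroring the restriction of clonality analysis to CN-neutral
KRAS-mutant tumours. CCFs follow as $2\,\mathrm{VAF}/\hat\rho$, with a 95%
Clopper-Pearson interval on alt reads/depth mapped through the same linear
scaling. CCFs are capped at 1.5 and flagged above 1.2 (a violated
copy-number or purity assumption).

Classification uses the interval, not the point estimate: a mutation is
*clonal* when the upper CCF bound reaches 0.9 (`clonal_threshold`), so a
deep-coverage mutation at CCF 0.95 is clonal while a shallow one with a wide
interval is not called subclonal merely for noise. Both the threshold and
the ordering margin below are arguments, since no canonical values exist.

**Mutation ordering.** Within a patient carrying genes A and B, A "wins"
when $\mathrm{CCF}_A - \mathrm{CCF}_B > \delta$ with margin $\delta = 0.1$
(differences inside the margin are ties and contribute nothing; this
suppresses wins generated purely by read-count noise at depth ~200-600x).
The win matrix feeds a Bradley-Terry model,
$P(A \text{ before } B) = \pi_A/(\pi_A+\pi_B)$, fitted by
minorization-maximization ($\pi_i \leftarrow W_i / \sum_j n_{ij}/(\pi_i+\pi_j)$)
to convergence $\max|\Delta\log\pi| < 10^{-8}$; the log-likelihood is
asserted non-decreasing at every iteration. Genes with fewer than 5 total
comparisons are dropped ("sufficient overlap" is not otherwise
quantifiable), disconnected comparison graphs are fitted per component, and
a gene with all wins or all losses gets a 0.5 pseudo-count on its pairs to
keep the MLE finite — standard Bradley-Terry practice. Abilities are
normalized to sum 1 within a component and are only comparable within one.

# Pairwise association

Each unordered pair of retained features is tested on its 2x2 patient
table with the two-sided Fisher exact test (probability-mass convention:
the p-value sums all hypergeometric outcomes no more probable than the
observed table). The reported odds ratio is the sample $(ad)/(bc)$ — not
the conditional MLE — with a Haldane 0.5 correction applied, and flagged,
only when a zero cell occurs. SNV features enter when mutated in at least
4% of patients; the 11 curated copy-number loci always enter. BH adjustment
is applied across all tested pairs jointly, and pairs at FDR <= 5% are
labelled co-occurrence (OR > 1) or exclusivity (OR < 1).

# NMF subgroups

The binary matrix $V$ (78 features x patients with copy-number data;
patients lacking copy-number data are excluded, and this exclusion rule is
the package's explicit reading of a cohort in which a small subset has no
CNA assay) is factorized as $V \approx WH$ minimizing Frobenius error with
Lee-Seung multiplicative updates. Initialization is the deterministic
NNDSVD scheme (zeros replaced by a small positive constant), so a given
matrix always yields the same factors; an optional seeded multi-restart
mode keeps the best of R random initializations. Convergence is a relative
error change below $10^{-6}$ or 2000 iterations; the objective is asserted
non-increasing per update. W columns are L1-normalized with H rescaled so
$WH$ is unchanged (verified to $10^{-10}$).

Patients are clustered by Ward (ward.D2) agglomeration on Euclidean
distances between exposure profiles (H columns normalized to sum 1), with
the tree cut at 5 clusters. The analysis defaults are rank $k = 4$ and 5
clusters, following the study design; both are arguments. Stability is
assessed by step-wise subsampling: from the full cohort down to 50% in
steps of 5 patients, 20 random subsets per size, each re-factorized and
matched to the full-cohort signatures by the permutation maximizing total
cosine similarity (exhaustive over $k!$; $k \le 8$). Per-cluster feature
enrichment uses the same Fisher/BH machinery as the association stage.

# Expression and biomarker

Digital counts are normalized per sample by the geometric mean of the
housekeeping genes anchored to a fixed reference of 1000 housekeeping
units: $x = \log_2(\mathrm{count}/f + 1)$ with
$f = \mathrm{geomean}(\mathrm{hk})/1000$. A fixed reference (rather than
rescaling to a cohort average) keeps each sample's normalization
independent of the rest of the cohort and exactly invariant to rescaling
that sample's counts; a zero housekeeping count gets a 0.5 pseudo-count
with a warning.

Differential expression fits, per gene, an ordinary least-squares
regression of normalized log2 expression on the SMAD4 group indicator plus
optional covariates (one shared QR decomposition across genes), with a
two-sided t-test on the group coefficient and BH adjustment across genes.
Moderated (shrinkage) statistics are deliberately not used: the design
calls for a plain per-gene linear model.

MAPK9 is dichotomized at the cohort-wide median (value <= median is
"low") — the observed group sizes in the published cohort are consistent
with a split near the cohort median, and the cutpoint is an argument since
no explicit value exists. SMAD4-altered means at least one SMAD4 mutation
or SMAD4 copy-number deletion; amplifications are excluded by default
(nearly all SMAD4 copy-number events in this disease are deletions with
loss-of-function consequences) behind a flag. Crossing status with MAPK9
level yields the four biomarker groups (alt_low, alt_high, wt_low,
wt_high).

# Survival models

Kaplan-Meier curves, log-rank tests and Cox models are delegated to the
`survival` package with Efron handling of ties throughout (follow-up is
recorded in months, so ties are guaranteed). The headline model is
`biomarker + arm + biomarker:arm (+ adjusters)`; the interaction Wald p of
the product term is the test for a treatment-dependent biomarker effect.
Terms with monotone likelihood (complete separation) are flagged, dropped
and the model refitted. The univariable screen retains covariates at Wald
p < 0.05 by default and always emits the full screen table so the
selection can be overridden.

**Resampling validation.** The biomarker cohort (patients with both SMAD4
status and expression, 222 under default conditions) is halved at random
100 times; within each validation half the log-rank OS p between arms,
restricted to the biomarker-positive subgroup, is recorded. The summary is
the median and quartiles of the 100 p-values; the representative split (p
closest to the median) also reports its held-out test-half p. A repeat
whose subgroup has no events or only one arm is recorded as p = 1 and
flagged rather than silently skipped.

# Synthetic cohort generator

The generator is the package's test bed, not a fixture: it encodes the
study conditions and stores ground truth exactly as sampled.

* **Alterations.** Each patient draws a cluster from mixing weights
  proportional to the observed cluster sizes (11, 29, 121, 50, 69), then
  independent Bernoulli alterations from that cluster's 78-feature profile.
  Default profiles modulate the published marginal frequencies (KRAS 93%,
  TP53 74%, CDKN2A 27%, SMAD4 27%; SMAD4/CDKN2A/TP53 deletions 49/47/38%);
  KRAS is forced to its trunk frequency in every cluster. A separated
  block-profile variant (`separated_cluster_profiles()`) provides planted
  structure with inter-profile L1 distance >= 10 for recovery tests.
* **Reads.** True CCFs sit on gene tiers (clonal 1.0 by default; SMAD4 and
  ARID1A 0.6; TGFBR1 and KMT2C 0.3). Depth is 1 + Poisson(mean - 1) with
  mean 600 (the assay's mean coverage); alt reads are Binomial(depth,
  CCF * purity / 2); purity is Uniform(0.3, 0.9), a realistic FFPE range.
* **Expression.** Log2 expression is Normal(baseline + effect * SMAD4alt,
  0.5) over a 100-gene panel with 10 zero-effect housekeeping genes; the
  default planted effect is MAPK9 at -1 log2. Counts are exponentiated,
  scaled by log-normal(0, 0.2) library-size factors — so normalization does
  real work — and rounded.
* **Survival.** Exponential event times with log-linear hazard: baseline
  log(2)/26 per month (a realistic ~26-month median OS in the reference
  arm), biomarker main effect log(1.67), arm main effect 0, interaction
  log(0.32) — the planted counterpart of the published treatment-dependent
  biomarker effect — with administrative censoring at 60 months. DFS uses a
  competing faster process (baseline log(2)/14) truncated at OS so
  DFS <= OS holds by construction. Proportional hazards hold exactly, which
  is what the Cox stage assumes; a Weibull shape would be the natural
  config extension.

What the generator does *not* emulate: FFPE artifacts and sequencing error,
subclonal copy number, co-mutation correlation beyond cluster structure,
non-proportional hazards, informative censoring, and expression-genotype
coupling beyond the SMAD4 shifts. Passing recovery tests therefore
demonstrates correctness of the estimators under their own assumptions, not
robustness to violations of them.

# Numerical and design choices

* Two-sided Fisher p by probability mass; BH via the standard step-up;
  both verified against explicit enumeration oracles in the test suite.
* Clopper-Pearson (exact binomial) intervals for VAF, propagated linearly
  to CCF.
* NMF determinism is prioritized (NNDSVD init) over restart-based global
  search; the multi-restart mode exists but is off by default.
* Planted-cluster recovery tests factorize at rank 5 (one signature per
  planted block profile) while the analysis default stays at rank 4 with 5
  clusters as in the study design.
* Cox convergence |delta loglik| < 1e-9 (survival's Newton iterations);
  monotone-likelihood detection by |coef| > 15 or SE > 100.
* Monte Carlo problem sizes used by the tests and acceptance script:
  cluster recovery and stability at n = 300 (step 5, 20 repeats in tests;
  step 10, 10 repeats in the script), ordering recovery at n = 500 /
  depth 200, interaction recovery at n = 2000 with the estimate averaged
  over replicates to control Monte Carlo error at fixed cohort size, null
  calibrations at 500 replicates, resampling validation at n = 222 with
  100 splits.

# Known limitations

* Purity from a single trunk gene is biased downward when the KRAS VAF is
  binomially noisy and capped at 1; CCFs inherit this noise.
* The clonality stage has no mixture model over VAF clusters: it fulfils
  the CCF/classification contract the downstream analyses need, not a full
  subclonal reconstruction.
* Ordering counts treat each patient pair independently; shared purity
  error within a patient cancels in CCF differences only approximately.
* Permutation-based exclusivity nulls, consensus-NMF rank selection,
  proportional-hazards diagnostics and competing risks are out of scope.
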