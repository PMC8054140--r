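# pdacig — integrative genomics of resected pancreatic cancer cohorts

`pdacig` is an R package for the integrative analysis of targeted-panel
genomic data from two-arm adjuvant trial cohorts of resected pancreatic
ductal adenocarcinoma (PDAC): gemcitabine with or without the EGFR
inhibitor erlotinib. It is aimed at biostatisticians and translational
researchers who need a tested, reproducible path from patient-level tables
(clinical, variants, copy-number calls, digital expression counts) to

* **clonal architecture** — tumour purity from the KRAS trunk mutation
  (ρ = min(1, 2·VAF)), cancer cell fractions CCF = 2·VAF/ρ with exact
  binomial confidence intervals, clonal/subclonal classification, and a
  Bradley–Terry model of mutation acquisition order,
  P(A before B) = π_A/(π_A + π_B), fitted by minorization–maximization;
* **pairwise association** — Fisher co-occurrence/mutual-exclusivity tests
  over the 78-feature binary alteration matrix (67 SNV genes + 11
  copy-number loci) with Benjamini–Hochberg FDR control;
* **genetic subgroups** — deterministic non-negative matrix factorization
  (Frobenius multiplicative updates, NNDSVD initialization) of the
  alteration matrix, subsampling stability curves, and Ward clustering of
  patients on signature exposures;
* **expression biomarker** — housekeeping-geometric-mean normalization,
  per-gene covariate-adjusted differential expression (OLS + t-test + BH),
  median dichotomization of MAPK9, and the four SMAD4 × MAPK9 groups;
* **survival** — Kaplan–Meier/log-rank, univariable Cox screening, and
  multivariable Cox models with the treatment-by-biomarker interaction as
  the headline test, plus a 100-fold random-split resampling validation of
  the subgroup treatment effect.

Patient-level trial data of this kind are not public, so the package ships
a seed-deterministic synthetic cohort generator (`simulate_cohort()`) whose
defaults encode the study conditions (n = 293, KRAS 93%, TP53 74%,
five-cluster mixing, purity 0.3–0.9, depth ~600×, MAPK9 −1 log2 shift in
SMAD4-altered tumours, exponential survival with interaction hazard ratio
0.32) and stores ground truth for every recovery test.

## Worked example

```r
library(pdacig)

sim <- simulate_cohort(sim_config(n_patients = 293, seed = 7))
b <- sim$bundle

## clonality
pur <- estimate_purity(b$variants, b$cna)
ccf <- classify_clonality(compute_ccf(b$variants, pur))
head(subset(gene_clonality_summary(ccf), n >= 50), 4)
#>      gene   n fraction_clonal
#>    CDKN2A  54               1
#>      KRAS 226               1
#>      TP53 139               1
#>     SMAD4  73               0

## associations on the alteration matrix (patients with CNA data)
m <- build_alteration_matrix(b$variants, b$cna,
                             patients = b$patients[b$has_cna])
assoc <- pairwise_fisher(m); assoc$q <- bh_adjust(assoc$p)
top <- significant_pairs(assoc)[, c("feature_a", "feature_b",
                                    "odds_ratio", "q", "direction")]
head(top, 3)
#>  feature_a  feature_b odds_ratio           q     direction
#>  SMAD4_cna CDKN2A_cna   3.423077 0.001499451 co-occurrence
#>    RB1_cna  BRCA2_cna   6.771255 0.001629295 co-occurrence
#>       TP53  SMAD4_cna   3.100413 0.001940120 co-occurrence

## biomarker groups and the interaction model
ne <- normalize_expression(b$expression)
bg <- define_biomarker_groups(b$variants, b$cna,
                              dichotomize_gene(ne, "MAPK9"))
d <- b$clinical
d$arm01 <- as.integer(d$arm == "GemErlo")
d$biomarker <- as.integer(bg$group[d$patient_id] == "alt_low")
interaction_model(d, "os_time", "os_event", "biomarker", "arm01")
#> Cox model: n = 293 , events = 216
#>             term   coef    hr hr_lo hr_hi      z        p
#>        biomarker  0.652 1.920 1.331 2.769  3.489 4.85e-04
#>            arm01  0.178 1.195 0.824 1.732  0.940 3.47e-01
#>  biomarker:arm01 -1.180 0.307 0.178 0.531 -4.222 2.42e-05

## random-split self-validation of the subgroup effect
d$subgroup <- d$biomarker
resample_validation(d, "os_time", "os_event", n_repeats = 100, seed = 11)
#> resampling validation over 100 random splits
#>  median p = 0.000216 [Q1 1.7e-05 , Q3 0.00137 ]
#>  representative split 70 : validation p = 0.000223 , test p = 8.23e-05
```

Reading the output: the truly clonal drivers (KRAS, TP53, CDKN2A) are
called fully clonal while SMAD4, simulated on a subclonal CCF tier of 0.6,
is not; the strongest associations are the planted co-deletions; the
biomarker main effect (HR 1.92) marks SMAD4-altered/MAPK9-low patients as
a poor-prognosis group under gemcitabine alone, and the interaction term
(HR 0.307, close to the planted 0.32) shows that adding erlotinib reverses
this — exactly the structure the generator plants. The resampling medians
are small because the planted effect is strong relative to the simulated
event rate.

A thin command-line front end mirrors the stages
(`exec/pdacig simulate|clonality|assoc|nmf|express|survive|validate-split`).

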