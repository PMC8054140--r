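ccf_row <- function(patient, gene, ccf, lo = ccf - 0.1, hi = ccf + 0.1) {
  data.frame(patient_id = patient, gene = gene, ccf = ccf, ccf_lo = lo,
             ccf_hi = hi, flagged = FALSE, stringsAsFactors = FALSE)
}

test_that("purity is twice the trunk VAF, capped at 1", {
  v <- data.frame(patient_id = c("P1", "P2", "P3"),
                  gene = c("KRAS", "KRAS", "TP53"),
                  vaf = c(0.25, 0.6, 0.4), stringsAsFactors = FALSE)
  pur <- estimate_purity(v)
  expect_equal(pur$rho[pur$patient_id == "P1"], 0.5)
  expect_equal(pur$rho[pur$patient_id == "P2"], 1)      # capped
  expect_false("P3" %in% pur$patient_id)                # no KRAS variant
})

test_that("patients with non-neutral KRAS copy number are excluded", {
  v <- data.frame(patient_id = "P1", gene = "KRAS", vaf = 0.3,
                  stringsAsFactors = FALSE)
  cna <- data.frame(patient_id = "P1", locus = "KRAS",
                    call = "amplification", stringsAsFactors = FALSE)
  expect_equal(nrow(estimate_purity(v, cna)), 0)
  cna$call <- "neutral"
  expect_equal(nrow(estimate_purity(v, cna)), 1)
})

test_that("CCF equals 2 VAF / rho with Clopper-Pearson bounds scaled alike", {
  v <- data.frame(patient_id = c("P1", "P1"), gene = c("KRAS", "TP53"),
                  alt_reads = c(50, 20), depth = c(200, 200),
                  vaf = c(0.25, 0.10), stringsAsFactors = FALSE)
  pur <- data.frame(patient_id = "P1", rho = 0.5, source_gene = "KRAS",
                    stringsAsFactors = FALSE)
  ccf <- compute_ccf(v, pur)
  expect_equal(ccf$ccf, c(1.0, 0.4))
  # interval oracle: exact binomial interval mapped through the same 2/rho
  cp <- stats::binom.test(50, 200)$conf.int
  expect_equal(ccf$ccf_lo[1], cp[1] * 4)
  expect_equal(ccf$ccf_hi[1], cp[2] * 4)
  # scale consistency: doubling rho halves the CCF
  pur2 <- pur; pur2$rho <- 1
  expect_equal(compute_ccf(v, pur2)$ccf, c(0.5, 0.2))
  expect_error(compute_ccf(v, pur[0, ]), "no purity")
})

test_that("clonality labels follow the upper-CI rule", {
  r <- classify_clonality(rbind(ccf_row("P1", "A", 1.0, 0.85, 1.15),
                                ccf_row("P1", "B", 0.3, 0.2, 0.42)))
  expect_equal(r$label, c("clonal", "subclonal"))
})

test_that("deep sequencing of truly clonal mutations is labelled clonal", {
  cfg <- sim_config(n_patients = 300, seed = 12, depth_mean = 200,
                    ccf_levels = numeric(0), kras_trunk_freq = 1,
                    purity_range = c(0.6, 0.6), cna_missing_rate = 1)
  sim <- simulate_cohort(cfg)
  b <- sim$bundle
  pur <- estimate_purity(b$variants)
  ccf <- classify_clonality(compute_ccf(b$variants, pur))
  ccf <- ccf[ccf$gene != "KRAS", ]   # KRAS anchors the purity itself
  expect_gt(mean(ccf$label == "clonal"), 0.95)
})

test_that("gene clonality summary reports per-gene clonal fractions", {
  r <- classify_clonality(rbind(ccf_row("P1", "A", 1.0, 0.95, 1.1),
                                ccf_row("P2", "A", 1.0, 0.95, 1.1),
                                ccf_row("P1", "B", 0.2, 0.1, 0.35)))
  s <- gene_clonality_summary(r)
  expect_equal(s$fraction_clonal[s$gene == "A"], 1.0)
  expect_equal(s$fraction_clonal[s$gene == "B"], 0.0)
  expect_false("C" %in% s$gene)
  expect_error(gene_clonality_summary(r[0, ]), "no CCF")
})

test_that("ordering counts respect the tie margin and symmetry", {
  r <- rbind(ccf_row("P1", "A", 1.0), ccf_row("P1", "B", 0.4))
  w <- count_pairwise_orderings(r, margin = 0.1)
  expect_equal(w["A", "B"], 1L)
  expect_equal(w["B", "A"], 0L)

  # difference inside the margin contributes nothing
  r2 <- rbind(ccf_row("P1", "A", 0.5), ccf_row("P1", "B", 0.45))
  w2 <- count_pairwise_orderings(r2, margin = 0.1)
  expect_true(all(w2 == 0))

  # mirrored cohort gives symmetric counts
  r3 <- rbind(ccf_row("P1", "A", 1.0), ccf_row("P1", "B", 0.4),
              ccf_row("P2", "A", 0.4), ccf_row("P2", "B", 1.0))
  w3 <- count_pairwise_orderings(r3, margin = 0.1)
  expect_equal(w3["A", "B"], w3["B", "A"])
})

test_that("Bradley-Terry MLE matches the 2-item closed form", {
  w <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  bt <- fit_bradley_terry(w, min_comparisons = 1)
  expect_equal(bt_prob(bt, "A", "B"), 0.75, tolerance = 1e-7)
  expect_equal(sum(bt$ability), 1)
  # predicted pairwise probability reproduces the empirical win fraction
  expect_equal(bt_prob(bt, "A", "B"), 3 / 4, tolerance = 1e-7)
})

test_that("balanced counts give equal abilities", {
  w <- matrix(2L, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(w) <- 0L
  bt <- fit_bradley_terry(w, min_comparisons = 1)
  expect_equal(unname(bt$ability), rep(1 / 3, 3), tolerance = 1e-7)
})

test_that("degenerate all-win genes are flagged and kept finite", {
  w <- matrix(c(0, 5, 5, 0, 0, 3, 0, 2, 0), 3, 3, byrow = TRUE,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  bt <- fit_bradley_terry(w, min_comparisons = 1)
  expect_equal(bt$flagged, "A")
  expect_true(all(is.finite(bt$ability) & bt$ability > 0))
  expect_equal(bt$ranking[1], "A")
})

test_that("genes below min_comparisons are dropped; components fit separately", {
  w <- matrix(0L, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  w["A", "B"] <- 6L; w["B", "A"] <- 2L
  w["C", "D"] <- 4L; w["D", "C"] <- 4L
  w["E", "A"] <- 1L   # only 1 comparison -> dropped
  bt <- fit_bradley_terry(w, min_comparisons = 3)
  expect_false("E" %in% names(bt$ability))
  expect_equal(length(unique(bt$component)), 2)
  expect_error(bt_prob(bt, "A", "C"), "different comparison components")
})

test_that("a planted CCF tier hierarchy is recovered in the BT ranking", {
  prof <- matrix(c(1, 0.95, 0.9, 0.9), ncol = 1,
                 dimnames = list(c("KRAS", "TP53", "SMAD4", "TGFBR1"), "c1"))
  attr(prof, "weights") <- 1
  cfg <- sim_config(n_patients = 400, seed = 13, cluster_profiles = prof,
                    kras_trunk_freq = 1, depth_mean = 200,
                    ccf_levels = c(SMAD4 = 0.6, TGFBR1 = 0.3),
                    cna_missing_rate = 1)
  sim <- simulate_cohort(cfg)
  pur <- estimate_purity(sim$bundle$variants)
  ccf <- classify_clonality(compute_ccf(sim$bundle$variants, pur))
  wins <- count_pairwise_orderings(ccf[ccf$gene != "KRAS", ], margin = 0.1)
  bt <- fit_bradley_terry(wins)
  expect_equal(bt$ranking, c("TP53", "SMAD4", "TGFBR1"))
})
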