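# Fixtures built in code: a 3-patient cohort exercising all four tables,
# plus independent oracles used against the implementation.

tiny_clinical <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    age = c(61, 70, 55),
    sex = c("male", "female", "male"),
    arm = c("Gem", "GemErlo", "Gem"),
    karnofsky = c(90, 80, 100),
    grading = c("G2", "G3", "unknown"),
    t_stage = c("T3", "T3", "T2"),
    n_stage = c("N1", "N0", "N1"),
    ca19_9_postop = c(12.5, NA, 240),
    dfs_time = c(10, 5.5, 30),
    dfs_event = c(1, 1, 0),
    os_time = c(18, 8, 30),
    os_event = c(1, 1, 0),
    stringsAsFactors = FALSE)
}

tiny_variants <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2", "P3"),
    gene = c("KRAS", "TP53", "KRAS", "SMAD4"),
    variant_class = c("missense", "missense", "missense", "truncating"),
    alt_reads = c(50, 40, 30, 25),
    depth = c(200, 200, 150, 100),
    vaf = c(0.25, 0.2, 0.2, 0.25),
    stringsAsFactors = FALSE)
}

tiny_cna <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2"),
    locus = c("SMAD4", "CDKN2A", "SMAD4"),
    call = c("deletion", "deletion", "neutral"),
    stringsAsFactors = FALSE)
}

tiny_expression <- function() {
  counts <- matrix(c(100, 210, 160,
                     820, 790, 805,
                     400, 410, 395), nrow = 3, byrow = TRUE,
                   dimnames = list(c("MAPK9", "HK01", "HK02"),
                                   c("P1", "P2", "P3")))
  list(counts = counts,
       housekeeping = c(MAPK9 = FALSE, HK01 = TRUE, HK02 = TRUE),
       stage = "raw")
}

write_tiny_cohort <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  bundle <- list(clinical = tiny_clinical(), variants = tiny_variants(),
                 cna = tiny_cna(), expression = tiny_expression(),
                 patients = c("P1", "P2", "P3"))
  class(bundle) <- "cohort_bundle"
  write_cohort(bundle, dir)
  dir
}

# independent step-up oracle for the BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- which(p[o] >= p[o][i])
    q[o[i]] <- min(1, min(m * p[o][js] / js))
  }
  q
}

# independent two-sided Fisher p by explicit hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # margin of feature A
  n <- c + d
  k <- a + c          # margin of feature B
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
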