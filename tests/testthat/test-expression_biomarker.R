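test_that("normalization is invariant to per-sample scaling", {
  expr <- tiny_expression()
  doubled <- expr
  doubled$counts[, "P2"] <- doubled$counts[, "P2"] * 2
  n1 <- normalize_expression(expr)
  n2 <- normalize_expression(doubled)
  # doubling every count of one sample is absorbed by its scale factor
  expect_equal(n1$counts, n2$counts, tolerance = 1e-9)
  expect_equal(n2$scale_factor[["P2"]] / n1$scale_factor[["P2"]], 2,
               tolerance = 1e-9)
})

test_that("an all-equal matrix maps to a constant on the log scale", {
  expr <- list(counts = matrix(64, 3, 4,
                               dimnames = list(c("A", "HK1", "HK2"),
                                               paste0("P", 1:4))),
               housekeeping = c(A = FALSE, HK1 = TRUE, HK2 = TRUE),
               stage = "raw")
  n <- normalize_expression(expr)
  expect_true(all(abs(n$counts - log2(1001)) < 1e-9))
  expect_equal(unname(n$scale_factor), rep(64 / 1000, 4))
})

test_that("zero housekeeping counts get a pseudo-count with a warning", {
  expr <- tiny_expression()
  expr$counts["HK01", "P1"] <- 0
  expect_warning(n <- normalize_expression(expr), "pseudo-count")
  expect_true(all(is.finite(n$counts)))
})

test_that("planted library-size factors are removed by normalization", {
  # noise-free housekeeping: the factor recovery must be exact
  ids <- paste0("P", 1:8)
  planted <- exp(seq(-0.4, 0.4, length.out = 8))
  base <- rbind(G1 = 2^7.3, G2 = 2^9.1, HK1 = 2^10, HK2 = 2^8)
  counts <- base[, rep(1, 8)] %*% diag(planted)
  dimnames(counts) <- list(rownames(base), ids)
  expr <- list(counts = counts,
               housekeeping = c(G1 = FALSE, G2 = FALSE, HK1 = TRUE,
                                HK2 = TRUE), stage = "raw")
  n <- normalize_expression(expr)
  ratio <- n$scale_factor / planted
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-9)
  # normalized values carry no library-size trace
  expect_lt(max(apply(n$counts, 1, stats::sd)), 1e-9)

  # realistic generator noise: estimated factors track the planted ones
  cfg <- sim_config(n_patients = 200, seed = 51)
  set.seed(51)
  status <- stats::setNames(rbinom(200, 1, 0.5) == 1, sprintf("P%04d", 1:200))
  sim_expr <- simulate_expression(cfg, status)
  ns <- normalize_expression(sim_expr)
  expect_gt(stats::cor(log(ns$scale_factor),
                       log(attr(sim_expr, "lib_factor"))), 0.7)
})

test_that("DE estimates are invariant to gene-wise location shifts", {
  cfg <- sim_config(n_patients = 100, seed = 52)
  set.seed(52)
  status <- stats::setNames(rep(c(TRUE, FALSE), 50), sprintf("P%04d", 1:100))
  expr <- simulate_expression(cfg, status)
  n <- normalize_expression(expr)
  g <- stats::setNames(as.integer(status), names(status))
  de1 <- differential_expression(n, g)
  n2 <- n
  n2$counts <- n$counts + 7   # absorbed by the intercept
  de2 <- differential_expression(n2, g)
  expect_equal(de1$coef, de2$coef, tolerance = 1e-9)
  expect_equal(de1$p, de2$p, tolerance = 1e-9)
})

test_that("covariate adjustment removes a planted confounded shift", {
  set.seed(53)
  n <- 200
  ids <- sprintf("P%04d", 1:n)
  batch <- rep(c(0, 1), each = n / 2)
  group <- stats::setNames(as.integer(batch == 1), ids)  # fully confounded? no:
  group[] <- as.integer(runif(n) < 0.2 + 0.6 * batch)    # group tracks batch
  y <- matrix(rnorm(3 * n, sd = 0.3), 3, n,
              dimnames = list(c("G1", "HK1", "HK2"), ids))
  y["G1", ] <- y["G1", ] + 2 * batch                     # batch effect only
  expr <- list(counts = y, housekeeping = c(G1 = FALSE, HK1 = TRUE,
                                            HK2 = TRUE),
               stage = "normalized_log2")
  unadj <- differential_expression(expr, group)
  adj <- differential_expression(expr, group,
                                 covariates = data.frame(batch = batch,
                                                         row.names = ids))
  expect_lt(unadj$p[unadj$gene == "G1"], 0.01)   # spurious without adjustment
  expect_gt(adj$p[adj$gene == "G1"], 0.05)       # gone once batch is in model
})

test_that("zero-variance genes are flagged with p = 1", {
  ids <- paste0("P", 1:10)
  y <- rbind(FLAT = rep(3, 10), OK = rnorm(10))
  colnames(y) <- ids
  expr <- list(counts = y, housekeeping = c(FLAT = FALSE, OK = FALSE),
               stage = "normalized_log2")
  g <- stats::setNames(rep(0:1, 5), ids)
  de <- differential_expression(expr, g)
  expect_true(de$flagged[de$gene == "FLAT"])
  expect_equal(de$p[de$gene == "FLAT"], 1)
})

test_that("median dichotomization splits the cohort in half", {
  expr <- list(counts = matrix(c(1, 2, 3, 4), 1, 4,
                               dimnames = list("MAPK9", paste0("P", 1:4))),
               housekeeping = c(MAPK9 = FALSE), stage = "normalized_log2")
  lev <- dichotomize_gene(expr, "MAPK9")
  expect_equal(unname(lev), c("low", "low", "high", "high"))
  expect_error(dichotomize_gene(expr, "ABSENT"), "not in matrix")
  allsame <- expr
  allsame$counts[] <- 5
  expect_warning(lev2 <- dichotomize_gene(allsame, "MAPK9"), "all values")
  expect_true(all(lev2 == "low"))
})

test_that("biomarker groups cross SMAD4 status with expression level", {
  lev <- c(P1 = "low", P2 = "high", P3 = "low", P4 = "high")
  variants <- data.frame(patient_id = "P1", gene = "SMAD4",
                         stringsAsFactors = FALSE)
  cnas <- data.frame(patient_id = c("P2", "P3"),
                     locus = c("SMAD4", "SMAD4"),
                     call = c("deletion", "amplification"),
                     stringsAsFactors = FALSE)
  bg <- define_biomarker_groups(variants, cnas, lev)
  expect_equal(as.character(bg$group[c("P1", "P2", "P3", "P4")]),
               c("alt_low", "alt_high", "wt_low", "wt_high"))
  # amplification counted only on request
  bg2 <- define_biomarker_groups(variants, cnas, lev,
                                 count_amplifications = TRUE)
  expect_equal(as.character(bg2$group[["P3"]]), "alt_low")
  expect_equal(sum(bg$counts), 4)
})

test_that("simulated SMAD4-altered fraction matches the generator truth", {
  sim <- simulate_cohort(sim_config(n_patients = 400, seed = 54))
  b <- sim$bundle
  ne <- normalize_expression(b$expression)
  lev <- dichotomize_gene(ne, "MAPK9")
  bg <- define_biomarker_groups(b$variants, b$cna, lev)
  alt_frac <- mean(startsWith(as.character(bg$group), "alt"))
  expect_equal(alt_frac, mean(sim$truth$patients$smad4_alt),
               tolerance = 1e-9)
})
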