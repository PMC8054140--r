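# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes for a
# resected-PDAC trial cohort: cluster-structured binary alteration profiles
# with KRAS as a near-ubiquitous trunk event, clonal/subclonal CCF tiers
# observed through binomial read counts at a given purity and depth,
# SMAD4-dependent expression shifts (including MAPK9 down-regulation) with
# per-sample library-size factors, and exponential survival with a
# treatment-by-biomarker interaction on the log hazard. Ground truth is
# stored exactly as sampled so parameter recovery can be tested.

#' Simulation configuration
#'
#' Defaults encode the study conditions of a two-arm adjuvant PDAC trial
#' cohort: 293 patients, five genetic clusters mixed with the observed
#' cluster sizes, per-gene alteration frequencies anchored at the published
#' marginals (KRAS 93%, TP53 74%, CDKN2A 27%, SMAD4 27% for SNVs; SMAD4 49%,
#' CDKN2A 47%, TP53 38% for deletions), tumour purity uniform on 0.3-0.9,
#' mean sequencing depth 600x, a -1 log2 MAPK9 shift in SMAD4-altered
#' tumours, and overall survival with baseline hazard log(2)/26 per month,
#' biomarker main-effect hazard ratio 1.67 and treatment-by-biomarker
#' interaction hazard ratio 0.32, censored administratively at 60 months.
#'
#' @param n_patients cohort size.
#' @param seed integer seed used by [simulate_cohort()].
#' @param cluster_profiles features x clusters matrix of Bernoulli
#'   probabilities with a `weights` attribute (mixing proportions, sum 1).
#' @param kras_trunk_freq frequency at which the KRAS trunk mutation is
#'   forced, overriding cluster profiles.
#' @param purity_range tumour purity range (uniform draw), in (0, 1].
#' @param depth_mean mean sequencing depth (shifted Poisson, minimum 1).
#' @param ccf_levels named vector of true cancer cell fractions per gene
#'   tier; genes not named are clonal (CCF 1).
#' @param expr_n_genes,expr_n_housekeeping expression panel size and number
#'   of housekeeping genes (zero-effect by construction).
#' @param expr_effects named log2 shifts applied to SMAD4-altered patients.
#' @param expr_sigma residual SD of log2 expression.
#' @param libsize_sdlog SD of log library-size factors (log-normal, mean 0).
#' @param cna_missing_rate fraction of patients without any CNA data.
#' @param survival list: `lambda` baseline hazard per month, `beta_biomarker`,
#'   `beta_arm`, `beta_interaction` log hazard ratios, `lambda_dfs` baseline
#'   hazard for the relapse process, `censor_time` months.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(n_patients = 293,
                       seed = 1L,
                       cluster_profiles = pdac_cluster_profiles(),
                       kras_trunk_freq = 0.93,
                       purity_range = c(0.3, 0.9),
                       depth_mean = 600,
                       ccf_levels = c(SMAD4 = 0.6, ARID1A = 0.6,
                                      TGFBR1 = 0.3, KMT2C = 0.3),
                       expr_n_genes = 100,
                       expr_n_housekeeping = 10,
                       expr_effects = c(MAPK9 = -1.0),
                       expr_sigma = 0.5,
                       libsize_sdlog = 0.2,
                       cna_missing_rate = 10 / 293,
                       survival = list(lambda = log(2) / 26,
                                       lambda_dfs = log(2) / 14,
                                       beta_biomarker = log(1.67),
                                       beta_arm = 0,
                                       beta_interaction = log(0.32),
                                       censor_time = 60)) {
  w <- attr(cluster_profiles, "weights")
  stop_if(is.null(w), "cluster_profiles needs a 'weights' attribute")
  stop_if(abs(sum(w) - 1) > 1e-8, "mixing weights must sum to 1")
  stop_if(any(cluster_profiles < 0 | cluster_profiles > 1),
          "profile probabilities must lie in [0,1]")
  stop_if(survival$lambda <= 0, "baseline hazard must be positive")
  stop_if(purity_range[1] <= 0 || purity_range[2] > 1,
          "purity_range must lie in (0,1]")
  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              cluster_profiles = cluster_profiles,
              kras_trunk_freq = kras_trunk_freq,
              purity_range = purity_range, depth_mean = depth_mean,
              ccf_levels = ccf_levels, expr_n_genes = expr_n_genes,
              expr_n_housekeeping = expr_n_housekeeping,
              expr_effects = expr_effects, expr_sigma = expr_sigma,
              libsize_sdlog = libsize_sdlog,
              cna_missing_rate = cna_missing_rate, survival = survival)
  class(cfg) <- "sim_config"
  cfg
}

#' PDAC-like cluster alteration profiles
#'
#' Five cluster profiles over the default 78 features, built by modulating
#' the published marginal frequencies: an ERBB-pathway-mutated high-burden
#' cluster, a tumour-suppressor-deletion cluster (RB1/BRCA2/PTEN), a
#' CNA-heavy cluster, a SMAD4-mutation-enriched cluster lacking CDKN2A
#' deletions, and a low-burden cluster. Mixing weights follow the observed
#' cluster sizes (11, 29, 121, 50, 69).
#'
#' @return features x 5 probability matrix with a `weights` attribute.
#' @export
pdac_cluster_profiles <- function() {
  snv <- default_snv_panel()
  cna <- cna_feature_labels(default_cna_panel())
  base <- stats::setNames(rep(0.03, length(snv)), snv)
  base[c("KRAS", "TP53", "CDKN2A", "SMAD4")] <- c(0.93, 0.74, 0.27, 0.27)
  base[c("ARID1A", "KMT2C", "KMT2D", "RNF43", "TGFBR2", "GNAS", "ATM",
         "TGFBR1", "BRCA2", "RBM10", "SF3B1")] <-
    c(0.10, 0.08, 0.08, 0.07, 0.05, 0.05, 0.05, 0.05, 0.04, 0.04, 0.04)
  cna_base <- stats::setNames(
    c(0.49, 0.47, 0.38, 0.15, 0.12, 0.12, 0.10, 0.10, 0.08, 0.35, 0.35),
    cna)
  p <- c(base, cna_base)
  k <- 5
  profiles <- matrix(rep(p, k), ncol = k,
                     dimnames = list(names(p), paste0("cluster", 1:k)))
  clip <- function(x) pmin(pmax(x, 0), 0.98)
  erbb <- c("PLCG2", "MAP2K7", "ERBB4", "CAMK2B", "ERBB2", "GNAS", "KMT2D")
  profiles[erbb, 1] <- clip(pmax(p[erbb] * 4, 0.45))
  profiles[snv, 1] <- clip(pmax(profiles[snv, 1], p[snv] * 2))
  ts_del <- cna_feature_labels(c("RB1", "BRCA2", "PTEN"))
  profiles[ts_del, 2] <- 0.7
  profiles[cna, 3] <- clip(p[cna] * 1.6)
  profiles["SMAD4", 4] <- 0.6
  profiles["CDKN2A_cna", 4] <- 0.05
  profiles[, 5] <- clip(p * 0.4)
  profiles["KRAS", ] <- 0.93
  attr(profiles, "weights") <- c(11, 29, 121, 50, 69) / 280
  profiles
}

#' Well-separated block cluster profiles
#'
#' Each cluster switches on its own block of features with high probability
#' (`p_on`) against a low background (`p_off`); inter-profile L1 distance is
#' `2 * block_size * (p_on - p_off)`. Used to test cluster recovery under a
#' planted, clearly separated structure.
#'
#' @param k number of clusters.
#' @param block_size features per cluster-specific block.
#' @param p_on,p_off within-block and background probabilities.
#' @param weights mixing proportions (default equal).
#' @return features x k probability matrix with a `weights` attribute.
#' @export
separated_cluster_profiles <- function(k = 5, block_size = 10, p_on = 0.8,
                                       p_off = 0.05, weights = rep(1 / k, k)) {
  features <- c(default_snv_panel(), cna_feature_labels(default_cna_panel()))
  stop_if(k * block_size > length(features), "too many block features")
  profiles <- matrix(p_off, nrow = length(features), ncol = k,
                     dimnames = list(features, paste0("cluster", seq_len(k))))
  for (j in seq_len(k))
    profiles[seq_len(block_size) + (j - 1) * block_size, j] <- p_on
  profiles["KRAS", ] <- pmax(profiles["KRAS", ], 0.9)
  attr(profiles, "weights") <- weights / sum(weights)
  profiles
}

sim_patient_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Simulate alteration tables and ground truth
#'
#' Draws each patient's cluster from the mixing weights, then independent
#' Bernoulli alterations from that cluster's profile (KRAS forced to the
#' configured trunk frequency). SNV features become variant rows (read
#' counts added by [simulate_reads()]); CNA features become non-neutral
#' calls, with neutral rows emitted for every other locus of patients that
#' have CNA data at all.
#'
#' @param config a [sim_config()].
#' @return list with `variants`, `cna`, and `truth` (per-patient cluster,
#'   purity; per-mutation true CCF).
#' @export
simulate_alterations <- function(config) {
  n <- config$n_patients
  ids <- sim_patient_ids(n)
  profiles <- config$cluster_profiles
  k <- ncol(profiles)
  features <- rownames(profiles)
  cluster <- sample.int(k, n, replace = TRUE, prob = attr(profiles, "weights"))
  prob <- profiles[, cluster, drop = FALSE]
  if ("KRAS" %in% features) prob["KRAS", ] <- config$kras_trunk_freq
  altered <- matrix(stats::rbinom(length(prob), 1L, prob),
                    nrow = nrow(prob), dimnames = list(features, ids))
  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])

  is_cna <- grepl("_cna$", features)
  snv_genes <- features[!is_cna]
  cna_loci <- sub("_cna$", "", features[is_cna])

  idx <- which(altered[!is_cna, , drop = FALSE] == 1L, arr.ind = TRUE)
  genes <- snv_genes[idx[, 1]]
  variants <- data.frame(
    patient_id = ids[idx[, 2]],
    gene = genes,
    variant_class = ifelse(
      genes == "SMAD4",
      sample(VARIANT_CLASSES, length(genes), TRUE,
             prob = c(0.2, 0.65, 0.05, 0.05, 0.05)),
      sample(VARIANT_CLASSES, length(genes), TRUE,
             prob = c(0.60, 0.25, 0.05, 0.05, 0.05))),
    stringsAsFactors = FALSE)
  ccf <- rep(1, nrow(variants))
  named <- variants$gene %in% names(config$ccf_levels)
  ccf[named] <- config$ccf_levels[variants$gene[named]]
  variants$true_ccf <- ccf
  ord <- order(variants$patient_id, variants$gene)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  has_cna <- stats::rbinom(n, 1L, 1 - config$cna_missing_rate) == 1L
  cna <- NULL
  if (any(is_cna) && any(has_cna)) {
    amp_loci <- c("KRAS", "GATA6", "MYC")
    pat <- rep(ids[has_cna], each = length(cna_loci))
    loc <- rep(cna_loci, sum(has_cna))
    alt <- altered[is_cna, has_cna, drop = FALSE][cbind(
      rep(seq_along(cna_loci), sum(has_cna)),
      rep(seq_len(sum(has_cna)), each = length(cna_loci)))]
    call <- rep("neutral", length(pat))
    amp_p <- ifelse(loc %in% amp_loci, 0.9, 0.1)
    hit <- alt == 1L
    call[hit] <- ifelse(stats::runif(sum(hit)) < amp_p[hit],
                        "amplification", "deletion")
    cna <- data.frame(patient_id = pat, locus = loc, call = call,
                      stringsAsFactors = FALSE)
  }

  truth <- list(
    patients = data.frame(patient_id = ids, cluster = cluster,
                          purity = purity, has_cna = has_cna,
                          stringsAsFactors = FALSE),
    mutations = variants[, c("patient_id", "gene", "true_ccf")]
  )
  variants$true_ccf <- NULL
  list(variants = variants, cna = cna, truth = truth)
}

#' Add binomial read counts to simulated variants
#'
#' Under the copy-number-neutral assumption (total copy number 2, single
#' mutated copy), the expected variant allele frequency of a mutation with
#' cancer cell fraction CCF in a sample of purity rho is
#' `CCF * rho / 2`. Depth is drawn as 1 + Poisson(depth_mean - 1) and
#' alt reads as Binomial(depth, expected VAF).
#'
#' @param variants variant table from [simulate_alterations()].
#' @param truth matching ground truth (purity, true CCF).
#' @param config a [sim_config()].
#' @return variant table with `alt_reads`, `depth`, `vaf` columns.
#' @export
simulate_reads <- function(variants, truth, config) {
  purity <- stats::setNames(truth$patients$purity, truth$patients$patient_id)
  rho <- purity[variants$patient_id]
  ccf <- truth$mutations$true_ccf
  stopifnot(length(ccf) == nrow(variants))
  evaf <- ccf * rho / 2
  stop_if(any(evaf > 1), "expected VAF exceeds 1; invalid configuration")
  depth <- 1L + stats::rpois(nrow(variants), max(config$depth_mean - 1, 0))
  alt <- stats::rbinom(nrow(variants), depth, evaf)
  variants$alt_reads <- alt
  variants$depth <- depth
  variants$vaf <- alt / depth
  variants
}

#' Simulate an nCounter-style expression count matrix
#'
#' Log2 expression is Normal(baseline + effect * SMAD4alt, sigma) per gene;
#' counts are exponentiated, scaled by a log-normal per-sample library-size
#' factor, and rounded. Housekeeping genes carry no group effect.
#'
#' @param config a [sim_config()].
#' @param smad4_status named logical: is the patient SMAD4-altered.
#' @return list as from [read_expression()], with attributes `lib_factor`
#'   and `latent_log2` (pre-library-size log2 values).
#' @export
simulate_expression <- function(config, smad4_status) {
  ids <- names(smad4_status)
  stop_if(is.null(ids), "smad4_status must be a named logical vector")
  n_hk <- config$expr_n_housekeeping
  n_target <- config$expr_n_genes - n_hk
  stop_if(n_target < length(config$expr_effects) + 1,
          "expr_n_genes too small for the configured effects")
  target_genes <- unique(c(names(config$expr_effects),
                           sprintf("TG%03d", seq_len(n_target))))[seq_len(n_target)]
  genes <- c(target_genes, sprintf("HK%02d", seq_len(n_hk)))
  hk <- stats::setNames(c(rep(FALSE, n_target), rep(TRUE, n_hk)), genes)
  baseline <- stats::setNames(stats::runif(length(genes), 6, 12), genes)
  baseline[hk] <- stats::runif(n_hk, 9, 11)
  effect <- stats::setNames(rep(0, length(genes)), genes)
  effect[names(config$expr_effects)] <- config$expr_effects

  log2e <- matrix(stats::rnorm(length(genes) * length(ids),
                               mean = baseline +
                                 outer(effect, as.numeric(smad4_status)),
                               sd = config$expr_sigma),
                  nrow = length(genes), dimnames = list(genes, ids))
  lib <- stats::setNames(exp(stats::rnorm(length(ids), 0, config$libsize_sdlog)), ids)
  counts <- round(2^log2e * rep(lib, each = length(genes)))
  out <- list(counts = counts, housekeeping = hk, stage = "raw")
  attr(out, "lib_factor") <- lib
  attr(out, "latent_log2") <- log2e
  out
}

#' Simulate exponential survival with a treatment-by-biomarker interaction
#'
#' Event times are Exponential with rate `lambda * exp(lp)` where the linear
#' predictor is `beta_biomarker * biomarker + beta_arm * arm +
#' beta_interaction * biomarker * arm` (plus optional extra terms), censored
#' administratively at `censor_time`.
#'
#' @param arm,biomarker 0/1 vectors.
#' @param config a [sim_config()] (its `survival` element is used).
#' @param lambda baseline hazard; defaults to the config value.
#' @param extra_lp optional additional linear-predictor contribution.
#' @return data.frame with `time`, `event`, `lp`.
#' @export
simulate_survival <- function(arm, biomarker, config,
                              lambda = config$survival$lambda,
                              extra_lp = 0) {
  sv <- config$survival
  lp <- sv$beta_biomarker * biomarker + sv$beta_arm * arm +
    sv$beta_interaction * biomarker * arm + extra_lp
  t_event <- stats::rexp(length(lp), rate = lambda * exp(lp))
  time <- pmin(t_event, sv$censor_time)
  data.frame(time = time, event = as.integer(t_event <= sv$censor_time),
             lp = lp)
}

#' Simulate a complete cohort bundle with ground truth
#'
#' Runs the whole generator under `config$seed`: alterations, read counts,
#' expression (with the SMAD4-dependent shifts), biomarker grouping
#' (SMAD4-altered and latent MAPK9 at or below the cohort median), clinical
#' covariates, and DFS/OS with the planted interaction.
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (a `cohort_bundle`) and `truth` (patients
#'   table with cluster, purity, SMAD4 status, biomarker group, linear
#'   predictor; mutation-level true CCFs).
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  alt <- simulate_alterations(config)
  variants <- simulate_reads(alt$variants, alt$truth, config)
  n <- config$n_patients
  ids <- alt$truth$patients$patient_id

  smad4_snv <- ids %in% variants$patient_id[variants$gene == "SMAD4"]
  smad4_del <- if (!is.null(alt$cna))
    ids %in% alt$cna$patient_id[alt$cna$locus == "SMAD4" &
                                alt$cna$call == "deletion"] else rep(FALSE, n)
  smad4_alt <- stats::setNames(smad4_snv | smad4_del, ids)

  expression <- simulate_expression(config, smad4_alt)
  latent <- attr(expression, "latent_log2")
  mapk9_gene <- names(config$expr_effects)[1] %||% "MAPK9"
  mapk9_low <- if (mapk9_gene %in% rownames(latent))
    latent[mapk9_gene, ] <= stats::median(latent[mapk9_gene, ])
  else rep(FALSE, n)
  biomarker <- as.integer(smad4_alt & mapk9_low)

  arm01 <- stats::rbinom(n, 1L, 0.5)
  os <- simulate_survival(arm01, biomarker, config)
  dfs_extra <- simulate_survival(arm01, biomarker, config,
                                 lambda = config$survival$lambda_dfs)
  dfs_time <- pmin(os$time, dfs_extra$time)
  dfs_event <- as.integer(ifelse(dfs_extra$time < os$time,
                                 dfs_extra$event, os$event))

  karnofsky <- sample(c(60, 70, 80, 90, 100), n, TRUE,
                      prob = c(1, 10, 75, 112, 95))
  grading <- sample(c("G1", "G2", "G3", "unknown"), n, TRUE,
                    prob = c(7, 180, 96, 10))
  ca19 <- round(exp(stats::rnorm(n, log(20), 1.4)), 1)
  ca19[stats::runif(n) < 0.1] <- NA
  clinical <- data.frame(
    patient_id = ids,
    age = pmin(pmax(round(stats::rnorm(n, 64, 9)), 24), 82),
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.56, 0.44)),
    arm = c("Gem", "GemErlo")[arm01 + 1L],
    karnofsky = karnofsky,
    grading = grading,
    t_stage = sample(paste0("T", 1:4), n, TRUE, prob = c(9, 30, 251, 3)),
    n_stage = sample(c("N0", "N1"), n, TRUE, prob = c(0.36, 0.64)),
    ca19_9_postop = ca19,
    dfs_time = round(dfs_time, 2),
    dfs_event = dfs_event,
    os_time = round(os$time, 2),
    os_event = os$event,
    stringsAsFactors = FALSE)
  # rounding must preserve dfs <= os
  clinical$dfs_time <- pmin(clinical$dfs_time, clinical$os_time)

  bundle <- list(clinical = clinical, variants = variants, cna = alt$cna,
                 expression = expression, patients = ids,
                 has_cna = stats::setNames(alt$truth$patients$has_cna, ids),
                 has_expr = stats::setNames(rep(TRUE, n), ids))
  class(bundle) <- "cohort_bundle"

  truth_pat <- alt$truth$patients
  truth_pat$smad4_alt <- as.logical(smad4_alt)
  truth_pat$mapk9_low <- as.logical(mapk9_low)
  truth_pat$biomarker <- biomarker
  truth_pat$arm01 <- arm01
  truth_pat$lp <- os$lp
  list(bundle = bundle,
       truth = list(patients = truth_pat, mutations = alt$truth$mutations))
}
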