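# Expression normalization, per-gene covariate-adjusted differential
# expression, and the SMAD4 x MAPK9 biomarker grouping.

#' Housekeeping-based normalization of digital counts
#'
#' Per-sample scale factor = geometric mean of the housekeeping-gene
#' counts divided by a fixed reference level (`reference`, default 1000),
#' so normalized values are log2 counts per 1000 housekeeping units:
#' `log2(count / factor + 1)`. Anchoring to a fixed reference rather than a
#' cohort average makes each sample's normalization independent of the
#' others and exactly invariant to rescaling that sample's counts. A
#' housekeeping gene with a zero count in a sample gets a 0.5 pseudo-count
#' (with a warning).
#'
#' @param expr list as from [read_expression()] (counts, housekeeping,
#'   stage "raw").
#' @param reference housekeeping level that maps counts onto themselves.
#' @return same list with `counts` replaced by the normalized log2 matrix,
#'   `stage = "normalized_log2"` and a `scale_factor` element.
#' @export
normalize_expression <- function(expr, reference = 1000) {
  stop_if(expr$stage != "raw", "expression is already normalized")
  hk <- names(expr$housekeeping)[expr$housekeeping]
  stop_if(length(hk) == 0, "no housekeeping genes flagged")
  counts <- expr$counts
  hk_counts <- counts[hk, , drop = FALSE]
  if (any(hk_counts == 0)) {
    warning("zero housekeeping count(s); applying 0.5 pseudo-count")
    hk_counts[hk_counts == 0] <- 0.5
  }
  f <- apply(hk_counts, 2, geometric_mean) / reference
  norm <- log2(sweep(counts, 2, f, "/") + 1)
  list(counts = norm, housekeeping = expr$housekeeping,
       stage = "normalized_log2", scale_factor = f)
}

#' Per-gene covariate-adjusted differential expression
#'
#' For each gene, ordinary least squares of normalized log2 expression on
#' a binary group indicator plus optional covariates (shared design,
#' computed via one QR decomposition); two-sided t-test on the group
#' coefficient; BH adjustment across genes. Zero-variance genes get p = 1
#' and are flagged.
#'
#' @param expr normalized expression list (stage "normalized_log2").
#' @param group named 0/1 (or logical) vector over samples.
#' @param covariates optional data.frame of per-sample covariates
#'   (rownames = sample IDs).
#' @return data.frame (gene, coef, se, t, p, q, flagged), `coef` being the
#'   log2 difference group 1 vs group 0.
#' @export
differential_expression <- function(expr, group, covariates = NULL) {
  stop_if(expr$stage != "normalized_log2",
          "run normalize_expression() first")
  samples <- intersect(colnames(expr$counts), names(group))
  stop_if(length(samples) < 3, "too few samples with group labels")
  Y <- t(expr$counts[, samples, drop = FALSE])   # samples x genes
  g <- as.numeric(group[samples])
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    cv <- covariates[samples, , drop = FALSE]
    mm <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  qrX <- qr(X)
  stop_if(qrX$rank < ncol(X), "design matrix is rank deficient")
  coefs <- qr.coef(qrX, Y)
  resid <- qr.resid(qrX, Y)
  df <- nrow(X) - ncol(X)
  stop_if(df < 1, "no residual degrees of freedom")
  sigma2 <- colSums(resid^2) / df
  xtxi_gg <- chol2inv(qr.R(qrX))[2, 2]
  se <- sqrt(sigma2 * xtxi_gg)
  beta <- coefs["group", ]
  zero_var <- apply(Y, 2, stats::var) == 0 | se == 0
  tstat <- ifelse(zero_var, 0, beta / se)
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), df))
  data.frame(gene = colnames(Y), coef = unname(beta), se = unname(se),
             t = unname(tstat), p = unname(p), q = bh_adjust(unname(p)),
             flagged = unname(zero_var), stringsAsFactors = FALSE)
}

#' Median dichotomization of one gene's expression
#'
#' Cohort-wide median split: value <= median is "low", above is "high".
#' With distinct values the two halves differ in size by at most one; if
#' all values are equal everyone is "low" (warning).
#'
#' @param expr normalized expression list.
#' @param gene gene symbol.
#' @return named character vector ("low"/"high") over samples.
#' @export
dichotomize_gene <- function(expr, gene) {
  stop_if(!gene %in% rownames(expr$counts), "gene not in matrix: ", gene)
  v <- expr$counts[gene, ]
  if (length(unique(v)) == 1) warning("all values equal; everyone 'low'")
  stats::setNames(ifelse(v <= stats::median(v), "low", "high"), names(v))
}

#' Define SMAD4 x expression biomarker groups
#'
#' A patient is SMAD4-altered when carrying at least one SMAD4 mutation or
#' a SMAD4 copy-number deletion (amplifications are not counted as loss of
#' function unless `count_amplifications`). Crossing with the low/high
#' expression level yields four groups: alt_low, alt_high, wt_low, wt_high.
#' Only patients with both data types are grouped.
#'
#' @param variants variant table.
#' @param cnas CNA table (may be `NULL`).
#' @param expression_level named "low"/"high" vector, e.g. from
#'   [dichotomize_gene()] on MAPK9.
#' @param patients patients with SMAD4 status (default: all in
#'   `expression_level`).
#' @param count_amplifications count SMAD4 amplifications as altered.
#' @return list (group: named factor over patients; counts: table).
#' @export
define_biomarker_groups <- function(variants, cnas, expression_level,
                                    patients = names(expression_level),
                                    count_amplifications = FALSE) {
  patients <- intersect(patients, names(expression_level))
  mut <- patients %in% variants$patient_id[variants$gene == "SMAD4"]
  cna_calls <- if (count_amplifications) c("deletion", "amplification")
               else "deletion"
  del <- if (!is.null(cnas))
    patients %in% cnas$patient_id[cnas$locus == "SMAD4" &
                                  cnas$call %in% cna_calls]
  else rep(FALSE, length(patients))
  alt <- mut | del
  lev <- expression_level[patients]
  grp <- factor(paste0(ifelse(alt, "alt", "wt"), "_", lev),
                levels = c("alt_low", "alt_high", "wt_low", "wt_high"))
  names(grp) <- patients
  list(group = grp, counts = table(grp))
}
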