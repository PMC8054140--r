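# Clonal architecture inference.
#
# Restricted to copy-number-neutral loci: tumour purity is estimated from
# the VAF of the KRAS trunk mutation (rho = 2 * VAF, capped at 1, valid for
# a clonal heterozygous mutation in a diploid region), cancer cell fractions
# follow as CCF = 2 * VAF / rho with an exact-binomial confidence interval
# propagated through the same linear map, and per-patient CCF orderings feed
# a Bradley-Terry model of mutation acquisition order.

#' Estimate tumour purity from the KRAS trunk mutation
#'
#' For a patient whose KRAS mutation lies in a copy-number-neutral region,
#' a clonal heterozygous trunk mutation has expected VAF = rho / 2, so
#' `rho = min(1, 2 * VAF)`. Patients without an eligible KRAS variant (or
#' with a KRAS copy-number aberration, when a CNA table is supplied) are
#' excluded with a message rather than an error.
#'
#' @param variants variant table (patient_id, gene, vaf).
#' @param cnas optional CNA table used to drop patients with non-neutral
#'   KRAS.
#' @return data.frame (patient_id, rho, source_gene), one row per eligible
#'   patient.
#' @export
estimate_purity <- function(variants, cnas = NULL) {
  kras <- variants[variants$gene == "KRAS", , drop = FALSE]
  if (!is.null(cnas)) {
    bad <- unique(cnas$patient_id[cnas$locus == "KRAS" & cnas$call != "neutral"])
    kras <- kras[!kras$patient_id %in% bad, , drop = FALSE]
  }
  if (nrow(kras) == 0)
    return(data.frame(patient_id = character(), rho = numeric(),
                      source_gene = character(), stringsAsFactors = FALSE))
  # one purity per patient: use the highest-VAF KRAS call
  kras <- kras[order(kras$patient_id, -kras$vaf), , drop = FALSE]
  kras <- kras[!duplicated(kras$patient_id), , drop = FALSE]
  data.frame(patient_id = kras$patient_id,
             rho = pmin(1, 2 * kras$vaf),
             source_gene = "KRAS", stringsAsFactors = FALSE)
}

#' Cancer cell fractions with exact-binomial confidence intervals
#'
#' For copy-number-neutral loci, `CCF = VAF * (2 rho + 2 (1 - rho)) /
#' (rho * 1) = 2 * VAF / rho`. The 95% interval is the Clopper-Pearson
#' interval on alt_reads/depth mapped through the same scaling. CCFs are
#' capped at 1.5; estimates above 1.2 are flagged (they indicate a violated
#' copy-number or purity assumption).
#'
#' @param variants variant table with alt_reads, depth.
#' @param purity data.frame from [estimate_purity()].
#' @param conf confidence level for the interval.
#' @return data.frame (patient_id, gene, ccf, ccf_lo, ccf_hi, flagged);
#'   patients without a purity estimate are dropped.
#' @export
compute_ccf <- function(variants, purity, conf = 0.95) {
  stop_if(nrow(purity) == 0, "no purity estimates supplied")
  rho <- stats::setNames(purity$rho, purity$patient_id)
  v <- variants[variants$patient_id %in% names(rho), , drop = FALSE]
  r <- rho[v$patient_id]
  scale <- 2 / r
  ci <- t(vapply(seq_len(nrow(v)), function(i) {
    as.numeric(stats::binom.test(v$alt_reads[i], v$depth[i],
                                 conf.level = conf)$conf.int)
  }, numeric(2)))
  ccf <- pmin(v$vaf * scale, 1.5)
  data.frame(patient_id = v$patient_id, gene = v$gene,
             ccf = ccf,
             ccf_lo = pmin(ci[, 1] * scale, 1.5),
             ccf_hi = pmin(ci[, 2] * scale, 1.5),
             flagged = v$vaf * scale > 1.2,
             stringsAsFactors = FALSE)
}

#' Classify mutations as clonal or subclonal
#'
#' A mutation is called clonal when the upper confidence bound of its CCF
#' reaches `clonal_threshold` (default 0.9): a mutation compatible with
#' presence in (essentially) all tumour cells. Otherwise subclonal.
#'
#' @param ccf data.frame from [compute_ccf()].
#' @param clonal_threshold CCF upper-bound cutoff.
#' @return same data.frame with a `label` column.
#' @export
classify_clonality <- function(ccf, clonal_threshold = 0.9) {
  stop_if(is.null(ccf$ccf_hi), "confidence bounds missing; run compute_ccf first")
  ccf$label <- ifelse(ccf$ccf_hi >= clonal_threshold, "clonal", "subclonal")
  ccf
}

#' Per-gene clonality summary
#'
#' @param ccf labelled CCF table from [classify_clonality()].
#' @return data.frame (gene, n, fraction_clonal), genes with no records
#'   omitted, sorted by decreasing clonal fraction.
#' @export
gene_clonality_summary <- function(ccf) {
  stop_if(nrow(ccf) == 0, "no CCF records")
  n <- table(ccf$gene)
  cl <- tapply(ccf$label == "clonal", ccf$gene, mean)
  out <- data.frame(gene = names(n), n = as.integer(n),
                    fraction_clonal = as.numeric(cl[names(n)]),
                    stringsAsFactors = FALSE)
  out[order(-out$fraction_clonal, out$gene), , drop = FALSE]
}

#' Count pairwise mutation orderings across patients
#'
#' Within each patient carrying mutations in both gene A and gene B,
#' `wins[A, B]` is incremented when `ccf_A - ccf_B > margin`; differences
#' within the margin contribute nothing (tie region against read-count
#' noise).
#'
#' @param ccf CCF table (one row per patient-gene; if a patient has several
#'   mutations in a gene, the maximum CCF is used).
#' @param margin minimum CCF difference to count a win.
#' @return square integer matrix `wins` over the genes present.
#' @export
count_pairwise_orderings <- function(ccf, margin = 0.1) {
  stop_if(margin < 0, "margin must be >= 0")
  genes <- sort(unique(ccf$gene))
  wins <- matrix(0L, length(genes), length(genes),
                 dimnames = list(genes, genes))
  agg <- stats::aggregate(ccf ~ patient_id + gene, data = ccf, FUN = max)
  for (pid in unique(agg$patient_id)) {
    p <- agg[agg$patient_id == pid, , drop = FALSE]
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      for (j in (i + 1):nrow(p)) {
        d <- p$ccf[i] - p$ccf[j]
        if (d > margin)
          wins[p$gene[i], p$gene[j]] <- wins[p$gene[i], p$gene[j]] + 1L
        else if (-d > margin)
          wins[p$gene[j], p$gene[i]] <- wins[p$gene[j], p$gene[i]] + 1L
      }
    }
  }
  wins
}

bt_components <- function(wins) {
  # connected components of the comparison graph (undirected)
  n <- nrow(wins)
  adj <- (wins + t(wins)) > 0
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Fit a Bradley-Terry model of mutation order
#'
#' Maximum-likelihood worth parameters pi (P(A precedes B) =
#' pi_A / (pi_A + pi_B)) by minorization-maximization, iterating
#' `pi_i <- W_i / sum_j n_ij / (pi_i + pi_j)` until
#' `max |delta log pi| < tol`. Genes with fewer than `min_comparisons`
#' total comparisons are dropped; if the comparison graph is disconnected
#' the model is fitted per connected component (worths are only comparable
#' within a component). Genes with all wins or all losses get a 0.5
#' pseudo-count on every cell of their pairs (flagged) to keep the MLE
#' finite. The log-likelihood is checked to be non-decreasing at every
#' iteration.
#'
#' @param wins square win-count matrix from [count_pairwise_orderings()].
#' @param min_comparisons minimum total comparisons for a gene to enter.
#' @param tol convergence tolerance on `max |delta log pi|`.
#' @param max_iter iteration cap.
#' @return list of class `bt_model`: `ability` (named, sums to 1 within
#'   each component), `ranking` (genes by decreasing ability), `component`,
#'   `flagged`, `n_iter`, `logLik`.
#' @export
fit_bradley_terry <- function(wins, min_comparisons = 5, tol = 1e-8,
                              max_iter = 10000) {
  stopifnot(nrow(wins) == ncol(wins))
  total <- rowSums(wins) + colSums(wins)
  keep <- total >= min_comparisons
  stop_if(sum(keep) < 2, "fewer than two genes with sufficient comparisons")
  w <- wins[keep, keep, drop = FALSE]
  mode(w) <- "double"

  degenerate <- (rowSums(w) == 0 | colSums(w) == 0) & (rowSums(w) + colSums(w) > 0)
  flagged <- rownames(w)[degenerate]
  if (length(flagged) > 0) {
    pairmask <- outer(degenerate, rep(TRUE, ncol(w))) |
      outer(rep(TRUE, nrow(w)), degenerate)
    played <- (w + t(w)) > 0
    add <- pairmask & played
    w[add] <- w[add] + 0.5
    diag(w) <- 0
  }

  comp <- bt_components(w)
  g <- ncol(w)
  pi_hat <- rep(NA_real_, g)
  names(pi_hat) <- colnames(w)
  n_iter <- 0L
  ll_total <- 0

  bt_loglik <- function(wc, p) {
    s <- outer(p, p, "+")
    val <- wc * (matrix(log(p), nrow(wc), ncol(wc)) - log(s))
    diag(val) <- 0
    sum(val)
  }

  for (cc in unique(comp)) {
    sel <- comp == cc
    if (sum(sel) == 1) { pi_hat[sel] <- 1; next }
    wc <- w[sel, sel, drop = FALSE]
    nij <- wc + t(wc)
    Wi <- rowSums(wc)
    p <- rep(1 / sum(sel), sum(sel))
    ll_old <- bt_loglik(wc, p)
    for (it in seq_len(max_iter)) {
      denom <- rowSums(nij / outer(p, p, "+") * (nij > 0))
      p_new <- ifelse(denom > 0, Wi / denom, p)
      p_new <- p_new / sum(p_new)
      ll_new <- bt_loglik(wc, p_new)
      stop_if(ll_new < ll_old - 1e-9,
              "Bradley-Terry likelihood decreased; MM update invalid")
      delta <- max(abs(log(p_new) - log(p)))
      p <- p_new
      ll_old <- ll_new
      if (delta < tol) break
    }
    n_iter <- max(n_iter, it)
    pi_hat[sel] <- p
    ll_total <- ll_total + ll_old
  }

  out <- list(ability = pi_hat,
              ranking = names(sort(pi_hat, decreasing = TRUE)),
              component = stats::setNames(comp, colnames(w)),
              flagged = flagged, n_iter = n_iter, logLik = ll_total)
  class(out) <- "bt_model"
  out
}

#' @export
print.bt_model <- function(x, ...) {
  cat("Bradley-Terry model:", length(x$ability), "genes,",
      length(unique(x$component)), "component(s)\n")
  print(round(sort(x$ability, decreasing = TRUE), 4))
  invisible(x)
}

#' Predicted probability that gene A precedes gene B
#' @param model a `bt_model`.
#' @param a,b gene names.
#' @return probability `pi_a / (pi_a + pi_b)`.
#' @export
bt_prob <- function(model, a, b) {
  stop_if(!a %in% names(model$ability) || !b %in% names(model$ability),
          "gene not in model")
  stop_if(model$component[a] != model$component[b],
          "genes lie in different comparison components")
  model$ability[[a]] / (model$ability[[a]] + model$ability[[b]])
}
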