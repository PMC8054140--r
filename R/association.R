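# Pairwise co-occurrence / mutual-exclusivity testing over the binary
# alteration matrix, with Benjamini-Hochberg FDR control.

#' Two-sided Fisher test on a 2x2 alteration table
#'
#' p-value from the conditional hypergeometric distribution (probability-
#' mass method, as in [stats::fisher.test()]); odds ratio is the sample
#' (ad)/(bc), with a Haldane 0.5 correction applied to every cell only when
#' a zero cell occurs (flagged).
#'
#' @param a_and_b,a_only,b_only,neither 2x2 cell counts.
#' @return list (p, odds_ratio, haldane).
#' @export
fisher_2x2 <- function(a_and_b, a_only, b_only, neither) {
  tab <- matrix(c(a_and_b, b_only, a_only, neither), 2, 2)
  p <- stats::fisher.test(tab)$p.value
  haldane <- any(tab == 0)
  cells <- c(a_and_b, a_only, b_only, neither) + if (haldane) 0.5 else 0
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(p = min(p, 1), odds_ratio = or, haldane = haldane)
}

#' Pairwise Fisher tests across alteration features
#'
#' Tests every unordered pair of retained features for co-occurrence or
#' mutual exclusivity. SNV features must reach `min_frequency` across
#' patients to enter; CNA features ("_cna" suffix) always enter, matching a
#' design where the copy-number panel is small and curated. Zero-variance
#' features are skipped with a message.
#'
#' @param matrix binary alteration matrix (features x patients).
#' @param min_frequency minimum mutated fraction for SNV features.
#' @return data.frame (feature_a, feature_b, 2x2 counts, odds_ratio,
#'   haldane, p), one row per tested pair; `q` left unset.
#' @export
pairwise_fisher <- function(matrix, min_frequency = 0.04) {
  stop_if(min_frequency < 0 || min_frequency > 1,
          "min_frequency must lie in [0,1]")
  stop_if(!all(matrix %in% c(0, 1)), "matrix must be binary")
  n <- ncol(matrix)
  freq <- rowMeans(matrix)
  is_cna <- grepl("_cna$", rownames(matrix))
  keep <- (freq >= min_frequency | is_cna)
  zerovar <- freq %in% c(0, 1)
  if (any(keep & zerovar))
    message("skipping zero-variance feature(s): ",
            paste(rownames(matrix)[keep & zerovar], collapse = ", "))
  keep <- keep & !zerovar
  feats <- rownames(matrix)[keep]
  stop_if(length(feats) < 2, "fewer than two testable features")
  m <- matrix[feats, , drop = FALSE]
  pairs <- utils::combn(feats, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    fa <- pairs[1, i]; fb <- pairs[2, i]
    both <- sum(m[fa, ] == 1 & m[fb, ] == 1)
    a_only <- sum(m[fa, ] == 1 & m[fb, ] == 0)
    b_only <- sum(m[fa, ] == 0 & m[fb, ] == 1)
    neither <- n - both - a_only - b_only
    ft <- fisher_2x2(both, a_only, b_only, neither)
    data.frame(feature_a = fa, feature_b = fb, a_and_b = both,
               a_only = a_only, b_only = b_only, neither = neither,
               odds_ratio = ft$odds_ratio, haldane = ft$haldane, p = ft$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]): the adjusted value of
#' the i-th order statistic is `min_j>=i (m * p_(j) / j)`, capped at 1.
#'
#' @param p numeric p-values in [0,1].
#' @return q-values in original order.
#' @export
bh_adjust <- function(p) {
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter and label significant pairwise associations
#'
#' @param associations data.frame from [pairwise_fisher()]; a `q` column is
#'   added (BH across all tested pairs) if not present.
#' @param q_threshold FDR threshold.
#' @return rows with `q <= q_threshold`, labelled `co-occurrence`
#'   (OR > 1) or `exclusivity` (OR < 1), sorted by q.
#' @export
significant_pairs <- function(associations, q_threshold = 0.05) {
  if (nrow(associations) == 0) {
    associations$q <- numeric(0)
    associations$direction <- character(0)
    return(associations)
  }
  if (is.null(associations$q)) associations$q <- bh_adjust(associations$p)
  out <- associations[associations$q <= q_threshold, , drop = FALSE]
  if (nrow(out) == 0) {
    out$direction <- character(0)
    return(out)
  }
  out$direction <- ifelse(out$odds_ratio > 1, "co-occurrence",
                          ifelse(out$odds_ratio < 1, "exclusivity", "none"))
  out[order(out$q, out$p), , drop = FALSE]
}
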