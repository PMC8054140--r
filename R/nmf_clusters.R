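# Genetic signature extraction by non-negative matrix factorization.
#
# V (features x patients, binary) is factorized as W H with Frobenius
# multiplicative updates from a deterministic NNDSVD initialization, so a
# given matrix always yields the same factors. Signature stability is
# assessed by step-wise patient subsampling; patients are grouped by Ward
# clustering of their normalized exposures.

nndsvd_init <- function(V, k) {
  # Boutsidis & Gallopoulos non-negative double SVD; zeros replaced by a
  # small positive value so multiplicative updates can move every entry.
  sv <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k)
  H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
      }
    }
  }
  eps <- mean(V) * 1e-2 + 1e-9
  W[W <= 0] <- eps
  H[H <= 0] <- eps
  list(W = W, H = H)
}

#' Extract non-negative signatures from an alteration matrix
#'
#' Minimizes the Frobenius reconstruction error `||V - W H||` by
#' multiplicative updates (Lee-Seung) from the deterministic NNDSVD
#' initialization; the objective is asserted non-increasing at every
#' iteration. Stops when the relative error change falls below `tol` or at
#' `max_iter` iterations. W columns are then L1-normalized with H rescaled
#' so the product is unchanged. Optionally the best of `n_restarts`
#' additional seeded random initializations is kept (lowest error).
#'
#' @param V non-negative matrix, features x patients.
#' @param k number of signatures (>= 1, < min(dim(V))).
#' @param n_restarts extra random restarts (0 = deterministic NNDSVD only).
#' @param seed seed for the random restarts.
#' @param tol relative-error convergence tolerance.
#' @param max_iter maximum multiplicative updates.
#' @return object of class `signature_set`: `W` (features x k, columns sum
#'   to 1), `H` (k x patients), `k`, `reconstruction_error`, `n_iter`.
#' @export
extract_signatures <- function(V, k, n_restarts = 0, seed = 1,
                               tol = 1e-6, max_iter = 2000) {
  stop_if(any(V < 0), "matrix must be non-negative")
  stop_if(sum(V) == 0, "all-zero matrix cannot be factorized")
  stop_if(k < 1 || k >= min(dim(V)), "k must satisfy 1 <= k < min(dim)")
  run <- function(W, H) {
    err_old <- sqrt(sum((V - W %*% H)^2))
    eps <- .Machine$double.eps
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- sqrt(sum((V - W %*% H)^2))
      stop_if(err > err_old + 1e-8 * max(err_old, 1),
              "NMF objective increased; update invalid")
      if (abs(err_old - err) <= tol * max(err_old, eps)) {
        err_old <- err
        break
      }
      err_old <- err
    }
    list(W = W, H = H, err = err_old, n_iter = it)
  }
  init <- nndsvd_init(V, k)
  best <- run(init$W, init$H)
  if (n_restarts > 0) {
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      W0 <- matrix(stats::runif(nrow(V) * k, 0.01, 1), nrow(V), k)
      H0 <- matrix(stats::runif(k * ncol(V), 0.01, 1), k, ncol(V))
      cand <- run(W0, H0)
      if (cand$err < best$err) best <- cand
    }
  }
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- sweep(best$H, 1, scale, "*")
  dimnames(W) <- list(rownames(V), paste0("S", seq_len(k)))
  dimnames(H) <- list(paste0("S", seq_len(k)), colnames(V))
  out <- list(W = W, H = H, k = k,
              reconstruction_error = best$err, n_iter = best$n_iter)
  class(out) <- "signature_set"
  out
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set: k =", x$k, "over", nrow(x$W), "features,",
      ncol(x$H), "patients; reconstruction error",
      signif(x$reconstruction_error, 4), "\n")
  invisible(x)
}

#' Match two signature sets
#'
#' Finds the one-to-one pairing of columns maximizing total cosine
#' similarity (exhaustive over the k! permutations; k <= 8) and reports the
#' mean similarity over matched pairs.
#'
#' @param set_a,set_b `signature_set`s (or plain W matrices) on the same
#'   feature space with equal k.
#' @return list (pairing: column of `set_b` matched to each column of
#'   `set_a`; mean_cosine; cosines per pair).
#' @export
match_signatures <- function(set_a, set_b) {
  Wa <- if (inherits(set_a, "signature_set")) set_a$W else set_a
  Wb <- if (inherits(set_b, "signature_set")) set_b$W else set_b
  stop_if(ncol(Wa) != ncol(Wb), "signature counts differ")
  stop_if(nrow(Wa) != nrow(Wb), "feature spaces differ")
  k <- ncol(Wa)
  stop_if(k > 8, "permutation matching supports k <= 8")
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    sim[i, j] <- cosine_similarity(Wa[, i], Wb[, j])
  perms <- permutations_of(k)
  totals <- vapply(perms, function(p) sum(sim[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(totals)]]
  cosines <- sim[cbind(seq_len(k), best)]
  list(pairing = best, mean_cosine = mean(cosines), cosines = cosines)
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[idx]] <- append(p, k, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

#' Signature stability under step-wise patient subsampling
#'
#' Starting from the full cohort, removes `step` patients at a time down to
#' half the cohort; at each size draws `n_repeats` random patient subsets,
#' re-extracts signatures and records the mean matched cosine similarity to
#' the full-cohort signatures.
#'
#' @param V alteration matrix (features x patients).
#' @param k signature count.
#' @param step patients removed per step.
#' @param n_repeats random subsets per size.
#' @param seed RNG seed.
#' @param ... passed to [extract_signatures()].
#' @return data.frame (n_patients, mean_cosine, sd_cosine).
#' @export
subsample_stability <- function(V, k, step = 5, n_repeats = 20, seed = 1,
                                ...) {
  stop_if(step < 1, "step must be >= 1")
  full <- extract_signatures(V, k, ...)
  n <- ncol(V)
  sizes <- seq(n, ceiling(n / 2), by = -step)
  set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    sims <- vapply(seq_len(n_repeats), function(r) {
      sub <- V[, sample.int(n, sz), drop = FALSE]
      match_signatures(full, extract_signatures(sub, k, ...))$mean_cosine
    }, numeric(1))
    data.frame(n_patients = sz, mean_cosine = mean(sims),
               sd_cosine = stats::sd(sims))
  })
  do.call(rbind, rows)
}

#' Cluster patients on their signature exposures
#'
#' Exposure profiles (columns of H) are normalized to sum 1, then clustered
#' by agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances) and the tree cut at `n_clusters`.
#'
#' @param signature_set from [extract_signatures()].
#' @param n_clusters number of patient clusters (>= 2).
#' @return named integer vector of cluster labels, plus attributes
#'   `linkage` and `n_clusters`.
#' @export
assign_clusters <- function(signature_set, n_clusters = 5) {
  H <- signature_set$H
  stop_if(n_clusters < 2, "n_clusters must be >= 2")
  stop_if(n_clusters > ncol(H), "more clusters than patients")
  cs <- colSums(H)
  cs[cs == 0] <- 1
  E <- t(sweep(H, 2, cs, "/"))
  hc <- stats::hclust(stats::dist(E), method = "ward.D2")
  labels <- stats::cutree(hc, k = n_clusters)
  names(labels) <- colnames(H)
  attr(labels, "linkage") <- "ward.D2"
  attr(labels, "n_clusters") <- n_clusters
  labels
}

#' Per-cluster feature enrichment
#'
#' Fisher test of each feature in each cluster against the rest of the
#' cohort, BH-adjusted across all (cluster, feature) tests.
#'
#' @param assignment labels from [assign_clusters()].
#' @param matrix binary alteration matrix over the same patients.
#' @return data.frame (cluster, feature, odds_ratio, p, q, direction).
#' @export
cluster_feature_enrichment <- function(assignment, matrix) {
  stop_if(length(unique(assignment)) < 2, "need >= 2 clusters")
  patients <- names(assignment)
  m <- matrix[, patients, drop = FALSE]
  rows <- list()
  for (cl in sort(unique(assignment))) {
    inside <- assignment == cl
    for (f in rownames(m)) {
      x <- m[f, ] == 1
      ft <- fisher_2x2(sum(x & inside), sum(!x & inside),
                       sum(x & !inside), sum(!x & !inside))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, feature = f, odds_ratio = ft$odds_ratio,
        haldane = ft$haldane, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$direction <- ifelse(out$odds_ratio > 1, "enriched", "depleted")
  out
}

#' Mean alteration burden per cluster
#'
#' @param assignment labels from [assign_clusters()].
#' @param matrix binary alteration matrix over the same patients.
#' @return data.frame (cluster, n_patients, mean_alterations).
#' @export
cluster_burden <- function(assignment, matrix) {
  patients <- names(assignment)
  burden <- colSums(matrix[, patients, drop = FALSE])
  agg <- tapply(burden, assignment, mean)
  data.frame(cluster = as.integer(names(agg)),
             n_patients = as.integer(table(assignment)[names(agg)]),
             mean_alterations = as.numeric(agg))
}
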