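# Survival machinery: Kaplan-Meier curves, log-rank tests, univariable
# screening, multivariable Cox models with a treatment-by-biomarker
# interaction, and random-split resampling validation of a subgroup
# treatment effect. Model fitting is delegated to the survival package
# (Efron handling of tied event times throughout).

#' Kaplan-Meier survival curve
#'
#' @param time,event follow-up times (months) and 0/1 event indicators.
#' @return data.frame (time, n_risk, n_event, surv): the product-limit
#'   estimate, starting at 1, non-increasing.
#' @export
km_curve <- function(time, event) {
  stop_if(any(time < 0), "negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test between groups
#'
#' Standard observed-minus-expected statistic, chi-square with g-1 degrees
#' of freedom. With no events the test is undefined; p = 1 is returned with
#' a warning.
#'
#' @param time,event survival outcome.
#' @param group group labels (>= 2 distinct values).
#' @return list (chisq, df, p).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  stop_if(nlevels(droplevels(group)) < 2, "need >= 2 groups")
  if (sum(event) == 0) {
    warning("no events; log-rank undefined, returning p = 1")
    return(list(chisq = 0, df = nlevels(droplevels(group)) - 1, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

term_wald <- function(fit, term) {
  # overall Wald test of all coefficients belonging to one model term
  idx <- grep(paste0("^", term), names(stats::coef(fit)))
  beta <- stats::coef(fit)[idx]
  ok <- !is.na(beta)
  beta <- beta[ok]; idx <- idx[ok]
  if (length(beta) == 0) return(NA_real_)
  V <- stats::vcov(fit)[idx, idx, drop = FALSE]
  stat <- drop(t(beta) %*% solve(V) %*% beta)
  stats::pchisq(stat, length(beta), lower.tail = FALSE)
}

#' Univariable Cox screen
#'
#' Fits one Cox model per covariate and retains those with overall Wald
#' p below `threshold` for the multivariable model. The full screen table
#' is always returned so the selection can be overridden.
#'
#' @param data data.frame holding outcome and covariates.
#' @param time_col,event_col column names of the outcome.
#' @param covariates character vector of covariate columns.
#' @param threshold selection p-value cutoff.
#' @return list (table: covariate/p/selected, selected: character vector).
#' @export
univariable_screen <- function(data, time_col, event_col, covariates,
                               threshold = 0.05) {
  stop_if(length(covariates) == 0, "no covariates supplied")
  surv <- survival::Surv(data[[time_col]], data[[event_col]])
  p <- vapply(covariates, function(cv) {
    fit <- tryCatch(
      survival::coxph(stats::as.formula(paste("surv ~", cv)), data = data,
                      ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        f <- suppressWarnings(
          survival::coxph(stats::as.formula(paste("surv ~", cv)),
                          data = data, ties = "efron"))
        if (any(abs(stats::coef(f)) > 15, na.rm = TRUE)) NULL else f
      })
    if (is.null(fit)) return(NA_real_)
    term_wald(fit, cv)
  }, numeric(1))
  tab <- data.frame(covariate = covariates, p = p,
                    selected = !is.na(p) & p < threshold,
                    stringsAsFactors = FALSE)
  if (any(is.na(p)))
    warning("covariate(s) excluded (non-converging): ",
            paste(covariates[is.na(p)], collapse = ", "))
  list(table = tab, selected = covariates[tab$selected])
}

#' Multivariable Cox model
#'
#' Partial-likelihood fit (Efron ties, Newton-Raphson to |delta loglik| <
#' 1e-9) with per-term hazard ratios, Wald z and p. Terms showing monotone-
#' likelihood behaviour (effectively infinite coefficients) are flagged and
#' dropped, and the model refitted.
#'
#' @param data data.frame with outcome and covariates.
#' @param time_col,event_col outcome columns.
#' @param terms model terms (column names or interaction expressions like
#'   `"biomarker * arm"`).
#' @return object of class `cox_result`: `table` (term, coef, HR, CI, z,
#'   p), `n`, `n_events`, `dropped`, and the underlying `fit`.
#' @export
cox_fit <- function(data, time_col, event_col, terms) {
  stop_if(length(terms) == 0, "no model terms")
  build <- function(tms) {
    f <- stats::as.formula(paste(
      "survival::Surv(", time_col, ",", event_col, ") ~",
      paste(tms, collapse = " + ")))
    survival::coxph(f, data = data, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50))
  }
  dropped <- character()
  tms <- terms
  repeat {
    fit <- withCallingHandlers(
      build(tms),
      warning = function(w) invokeRestart("muffleWarning"))
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    infinite <- is.na(beta) | abs(beta) > 15 | se > 100
    if (!any(infinite)) break
    bad_coefs <- names(beta)[infinite]
    bad_terms <- unique(unlist(lapply(tms, function(t) {
      vars <- all.vars(stats::as.formula(paste("~", t)))
      if (any(vapply(vars, function(v) any(startsWith(bad_coefs, v)),
                     logical(1)))) t else NULL
    })))
    stop_if(length(bad_terms) == length(tms),
            "all terms show monotone likelihood; model cannot be fitted")
    dropped <- c(dropped, bad_terms)
    tms <- setdiff(tms, bad_terms)
  }
  if (length(dropped) > 0)
    warning("dropped term(s) with monotone likelihood: ",
            paste(dropped, collapse = ", "))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(term = names(beta), coef = unname(beta),
                    hr = exp(unname(beta)),
                    hr_lo = exp(unname(beta - 1.96 * se)),
                    hr_hi = exp(unname(beta + 1.96 * se)),
                    z = unname(z),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE)
  out <- list(table = tab, n = fit$n, n_events = fit$nevent,
              dropped = dropped, fit = fit)
  class(out) <- "cox_result"
  out
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox model: n =", x$n, ", events =", x$n_events, "\n")
  tab <- x$table
  tab[, c("coef", "hr", "hr_lo", "hr_hi", "z")] <-
    round(tab[, c("coef", "hr", "hr_lo", "hr_hi", "z")], 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (length(x$dropped)) cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Treatment-by-biomarker interaction Cox model
#'
#' Fits `biomarker + arm + biomarker:arm (+ adjusters)` and reports the
#' interaction hazard ratio and Wald p as the headline result, together
#' with per-stratum Kaplan-Meier curves.
#'
#' @param data data.frame with outcome, `biomarker` and `arm` columns
#'   (both binary 0/1) and any adjusters.
#' @param time_col,event_col outcome columns.
#' @param biomarker_col,arm_col names of the binary biomarker and arm
#'   columns.
#' @param adjusters additional covariate columns.
#' @return `cox_result` with extra elements `interaction` (term, hr, p) and
#'   `km_strata` (per biomarker x arm stratum KM curve).
#' @export
interaction_model <- function(data, time_col, event_col,
                              biomarker_col = "biomarker", arm_col = "arm",
                              adjusters = character()) {
  b <- data[[biomarker_col]]; a <- data[[arm_col]]
  stop_if(!all(b %in% 0:1) || !all(a %in% 0:1),
          "biomarker and arm must be binary 0/1")
  strata <- table(b, a)
  stop_if(any(strata == 0) || length(strata) < 4,
          "empty biomarker x arm stratum: ",
          paste(sprintf("b=%s,a=%s", rep(rownames(strata), 2),
                        rep(colnames(strata), each = 2))[strata == 0],
                collapse = "; "))
  stop_if(length(unique(b)) < 2, "biomarker is constant")
  terms <- c(biomarker_col, arm_col,
             paste0(biomarker_col, ":", arm_col), adjusters)
  res <- cox_fit(data, time_col, event_col, terms)
  int_row <- grep(":", res$table$term)
  stop_if(length(int_row) != 1, "interaction term missing from fit")
  res$interaction <- res$table[int_row, , drop = FALSE]
  res$km_strata <- lapply(split(seq_len(nrow(data)), list(b = b, a = a)),
                          function(i) km_curve(data[[time_col]][i],
                                               data[[event_col]][i]))
  res
}

#' Random-split resampling validation of a subgroup treatment effect
#'
#' Repeatedly halves the cohort at random; within the validation half,
#' computes the log-rank p between treatment arms restricted to the
#' biomarker-positive subgroup. Summarized by the median and quartiles of
#' the `n_repeats` p-values; the representative split is the one whose p is
#' closest to the median, and its held-out (test-half) subgroup p is also
#' reported. Repeats whose subgroup has no events in one half are recorded
#' as p = 1 and flagged.
#'
#' @param data data.frame with outcome, `arm` (0/1 or two levels) and a
#'   logical/0-1 `subgroup` column.
#' @param time_col,event_col outcome columns.
#' @param subgroup_col,arm_col column names.
#' @param n_repeats number of random splits.
#' @param seed RNG seed.
#' @return object of class `resampling_summary`: `p_values`, `median`,
#'   `lower_quartile`, `upper_quartile`, `representative` (split id,
#'   validation and test p), `n_flagged`, `seed`.
#' @export
resample_validation <- function(data, time_col, event_col,
                                subgroup_col = "subgroup", arm_col = "arm",
                                n_repeats = 100, seed = 1) {
  n <- nrow(data)
  stop_if(n < 4, "cohort too small to split")
  sub <- as.logical(data[[subgroup_col]])
  arm <- data[[arm_col]]
  set.seed(seed)
  half <- floor(n / 2)
  split_p <- function(idx) {
    d <- data[idx, , drop = FALSE]
    s <- sub[idx]
    if (sum(s) < 2 || length(unique(arm[idx][s])) < 2 ||
        sum(d[[event_col]][s]) == 0)
      return(NA_real_)
    suppressWarnings(
      logrank_test(d[[time_col]][s], d[[event_col]][s], arm[idx][s])$p)
  }
  p_val <- numeric(n_repeats)
  p_test <- numeric(n_repeats)
  flagged <- logical(n_repeats)
  for (r in seq_len(n_repeats)) {
    val_idx <- sample.int(n, half)
    test_idx <- setdiff(seq_len(n), val_idx)
    pv <- split_p(val_idx)
    pt <- split_p(test_idx)
    flagged[r] <- is.na(pv)
    p_val[r] <- if (is.na(pv)) 1 else pv
    p_test[r] <- if (is.na(pt)) 1 else pt
  }
  med <- stats::median(p_val)
  rep_id <- which.min(abs(p_val - med))
  out <- list(p_values = p_val, median = med,
              lower_quartile = unname(stats::quantile(p_val, 0.25)),
              upper_quartile = unname(stats::quantile(p_val, 0.75)),
              representative = list(split_id = rep_id,
                                    validation_p = p_val[rep_id],
                                    test_p = p_test[rep_id]),
              n_flagged = sum(flagged), seed = seed)
  class(out) <- "resampling_summary"
  out
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat("resampling validation over", length(x$p_values), "random splits\n",
      "median p =", signif(x$median, 3),
      "[Q1", signif(x$lower_quartile, 3), ", Q3",
      signif(x$upper_quartile, 3), "]\n",
      "representative split", x$representative$split_id,
      ": validation p =", signif(x$representative$validation_p, 3),
      ", test p =", signif(x$representative$test_p, 3), "\n")
  invisible(x)
}
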