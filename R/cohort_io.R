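# Typed readers/writers for the four cohort tables and the binary
# alteration matrix feeding the association and NMF stages.
#
# Dialect: clinical table is CSV; variant, CNA and expression tables are
# UTF-8 TSV with "." for missing numerics (see write_table).

CLINICAL_NUMERIC <- c("age", "karnofsky", "ca19_9_postop",
                      "dfs_time", "dfs_event", "os_time", "os_event")
VARIANT_CLASSES <- c("missense", "truncating", "splice", "inframe", "other")
CNA_CALLS <- c("deletion", "neutral", "amplification")

#' Read and validate a clinical table
#'
#' Expects a CSV with columns patient_id, age, sex, arm, karnofsky, grading,
#' t_stage, n_stage, ca19_9_postop, dfs_time, dfs_event, os_time, os_event.
#' Missing CA19-9 is "." (kept as NA, categorised as "unknown" downstream);
#' missing grading is the explicit level "unknown".
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                       colClasses = "character", na.strings = NULL)
  required <- c("patient_id", CLINICAL_NUMERIC, "sex", "arm", "grading",
                "t_stage", "n_stage")
  missing_cols <- setdiff(required, names(x))
  stop_if(length(missing_cols) > 0,
          "clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  for (nm in CLINICAL_NUMERIC) {
    v <- x[[nm]]
    v[v == "."] <- NA
    x[[nm]] <- as.numeric(v)
  }
  dup <- unique(x$patient_id[duplicated(x$patient_id)])
  stop_if(length(dup) > 0,
          "duplicate patient_id in clinical table: ", paste(dup, collapse = ", "))
  stop_if(any(!x$sex %in% c("male", "female")), "sex must be male/female")
  stop_if(any(!x$arm %in% c("Gem", "GemErlo")), "arm must be Gem/GemErlo")
  stop_if(any(!x$grading %in% c("G1", "G2", "G3", "unknown")),
          "grading must be G1..G3 or unknown")
  bad_time <- which(x$dfs_time < 0 | x$os_time < 0 | x$dfs_time > x$os_time)
  stop_if(length(bad_time) > 0,
          "invalid survival times (negative or DFS > OS) for: ",
          paste(x$patient_id[bad_time], collapse = ", "))
  stop_if(any(!x$dfs_event %in% 0:1) || any(!x$os_event %in% 0:1),
          "event indicators must be 0/1")
  x
}

#' Read and validate a MAF-like variant table
#'
#' TSV with columns patient_id, gene, variant_class, alt_reads, depth and
#' optionally vaf (recomputed as alt_reads/depth when absent; validated
#' against it when present).
#'
#' @param path TSV file path.
#' @return validated data.frame with a numeric `vaf` column.
#' @export
read_variants <- function(path) {
  x <- read_table(path, numeric_cols = c("alt_reads", "depth", "vaf"))
  required <- c("patient_id", "gene", "variant_class", "alt_reads", "depth")
  missing_cols <- setdiff(required, names(x))
  stop_if(length(missing_cols) > 0,
          "variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  stop_if(any(!x$variant_class %in% VARIANT_CLASSES),
          "variant_class must be one of ", paste(VARIANT_CLASSES, collapse = "/"))
  stop_if(any(x$depth < 1), "depth must be >= 1")
  stop_if(any(x$alt_reads < 0 | x$alt_reads > x$depth),
          "alt_reads must lie in [0, depth]")
  if (is.null(x$vaf)) {
    x$vaf <- x$alt_reads / x$depth
  } else {
    bad <- which(x$vaf < 0 | x$vaf > 1)
    stop_if(length(bad) > 0, "VAF outside [0,1] at row(s): ",
            paste(bad, collapse = ", "))
    # allow rounding of a printed VAF to ~2 decimals
    off <- which(abs(x$vaf - x$alt_reads / x$depth) > 0.005 + 0.5 / x$depth)
    stop_if(length(off) > 0, "VAF inconsistent with alt_reads/depth at row(s): ",
            paste(off, collapse = ", "))
  }
  x
}

#' Read and validate a copy-number call table
#'
#' TSV with columns patient_id, locus, call (deletion/neutral/amplification);
#' at most one call per (patient, locus).
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_cna <- function(path) {
  x <- read_table(path)
  required <- c("patient_id", "locus", "call")
  missing_cols <- setdiff(required, names(x))
  stop_if(length(missing_cols) > 0,
          "CNA table lacks columns: ", paste(missing_cols, collapse = ", "))
  stop_if(any(!x$call %in% CNA_CALLS),
          "call must be one of ", paste(CNA_CALLS, collapse = "/"))
  key <- paste(x$patient_id, x$locus)
  dup <- unique(key[duplicated(key)])
  stop_if(length(dup) > 0, "multiple CNA calls for (patient, locus): ",
          paste(dup, collapse = "; "))
  x
}

#' Read an expression count table
#'
#' TSV with columns gene, housekeeping (TRUE/FALSE) followed by one numeric
#' column per patient (raw digital counts).
#'
#' @param path TSV file path.
#' @return list with `counts` (genes x patients matrix, gene rownames),
#'   `housekeeping` (named logical) and `stage` ("raw").
#' @export
read_expression <- function(path) {
  x <- read_table(path)
  stop_if(!all(c("gene", "housekeeping") %in% names(x)),
          "expression table needs gene and housekeeping columns")
  patients <- setdiff(names(x), c("gene", "housekeeping"))
  stop_if(length(patients) == 0, "expression table has no patient columns")
  counts <- as.matrix(vapply(x[patients], as.numeric, numeric(nrow(x))))
  if (nrow(x) == 1L) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, patients))
  rownames(counts) <- x$gene
  stop_if(any(counts < 0, na.rm = TRUE), "expression counts must be >= 0")
  hk <- x$housekeeping %in% c("TRUE", "true", "1")
  names(hk) <- x$gene
  list(counts = counts, housekeeping = hk, stage = "raw")
}

#' Load a cohort bundle
#'
#' Reads the four tables and joins them on patient_id. Patients present in
#' the clinical table but absent from the CNA or expression table are kept,
#' with that slot flagged absent (`has_cna` / `has_expr`), mirroring real
#' panels where a data type fails QC for a subset of patients.
#'
#' @param clinical_path,variant_path,cna_path,expression_path file paths;
#'   `cna_path` and `expression_path` may be `NULL`.
#' @return object of class `cohort_bundle`: list with elements `clinical`,
#'   `variants`, `cna`, `expression`, and per-patient availability flags.
#' @export
load_cohort <- function(clinical_path, variant_path, cna_path = NULL,
                        expression_path = NULL) {
  clinical <- read_clinical(clinical_path)
  variants <- read_variants(variant_path)
  cna <- if (!is.null(cna_path)) read_cna(cna_path) else NULL
  expression <- if (!is.null(expression_path)) read_expression(expression_path) else NULL

  patients <- clinical$patient_id
  orphan <- setdiff(variants$patient_id, patients)
  stop_if(length(orphan) > 0, "variant rows for unknown patients: ",
          paste(unique(orphan), collapse = ", "))

  bundle <- list(
    clinical = clinical,
    variants = variants,
    cna = cna,
    expression = expression,
    patients = patients,
    has_cna = stats::setNames(patients %in% (cna$patient_id %||% character()), patients),
    has_expr = stats::setNames(patients %in% (colnames(expression$counts) %||% character()),
                               patients)
  )
  class(bundle) <- "cohort_bundle"
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", length(x$patients), "patients;",
      nrow(x$variants), "variants;",
      if (is.null(x$cna)) "no CNA table;" else paste(sum(x$has_cna), "with CNA;"),
      if (is.null(x$expression)) "no expression table" else
        paste(sum(x$has_expr), "with expression"), "\n")
  invisible(x)
}

#' Write a cohort bundle to a directory
#'
#' Inverse of [load_cohort()]: writes clinical.csv, variants.tsv, cna.tsv and
#' expression.tsv in the package dialect.
#'
#' @param bundle cohort_bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- bundle$clinical
  for (j in seq_along(cl)) {
    if (is.numeric(cl[[j]])) {
      v <- as.character(cl[[j]]); v[is.na(v)] <- "."
      cl[[j]] <- v
    }
  }
  utils::write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE,
                   quote = FALSE)
  write_table(bundle$variants, file.path(dir, "variants.tsv"))
  if (!is.null(bundle$cna))
    write_table(bundle$cna, file.path(dir, "cna.tsv"))
  if (!is.null(bundle$expression)) {
    expr <- bundle$expression
    df <- data.frame(gene = rownames(expr$counts),
                     housekeeping = unname(expr$housekeeping[rownames(expr$counts)]),
                     expr$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_table(df, file.path(dir, "expression.tsv"))
  }
  invisible(dir)
}

#' Load a cohort bundle from a directory written by [write_cohort()]
#' @param dir directory path.
#' @return cohort_bundle.
#' @export
load_cohort_dir <- function(dir) {
  cna <- file.path(dir, "cna.tsv")
  expr <- file.path(dir, "expression.tsv")
  load_cohort(file.path(dir, "clinical.csv"),
              file.path(dir, "variants.tsv"),
              if (file.exists(cna)) cna else NULL,
              if (file.exists(expr)) expr else NULL)
}

#' Build the binary alteration matrix
#'
#' One row per feature (SNV genes, then CNA loci suffixed "_cna"), one
#' column per patient. An SNV feature is 1 when the patient carries at least
#' one mutation in the gene; a CNA feature is 1 for any non-neutral call at
#' the locus. With the default panels this yields 78 features (67 + 11).
#'
#' @param variants variant data.frame (patient_id, gene, ...).
#' @param cnas CNA data.frame (patient_id, locus, call) or `NULL`.
#' @param snv_genes,cna_loci feature panels.
#' @param patients patient IDs defining the columns; defaults to all patients
#'   seen in either table.
#' @return binary matrix, features x patients.
#' @export
build_alteration_matrix <- function(variants, cnas = NULL,
                                    snv_genes = default_snv_panel(),
                                    cna_loci = default_cna_panel(),
                                    patients = NULL) {
  stop_if(length(snv_genes) == 0, "snv_genes must be non-empty")
  if (is.null(patients))
    patients <- sort(unique(c(variants$patient_id, cnas$patient_id)))
  features <- c(snv_genes, cna_feature_labels(cna_loci))
  m <- matrix(0L, nrow = length(features), ncol = length(patients),
              dimnames = list(features, patients))
  v <- variants[variants$gene %in% snv_genes &
                variants$patient_id %in% patients, , drop = FALSE]
  if (nrow(v) > 0)
    m[cbind(match(v$gene, features), match(v$patient_id, patients))] <- 1L
  if (!is.null(cnas) && length(cna_loci) > 0) {
    cc <- cnas[cnas$locus %in% cna_loci & cnas$call != "neutral" &
               cnas$patient_id %in% patients, , drop = FALSE]
    if (nrow(cc) > 0)
      m[cbind(match(cna_feature_labels(cc$locus), features),
              match(cc$patient_id, patients))] <- 1L
  }
  m
}
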