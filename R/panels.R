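# Default alteration panels.
#
# The default SNV panel holds 67 genes recurrently mutated and/or clinically
# actionable in pancreatic ductal adenocarcinoma (core drivers KRAS/TP53/
# CDKN2A/SMAD4, TGF-beta and chromatin-remodelling genes, DNA-damage response
# and receptor-kinase pathway members). The default copy-number panel holds
# the 11 loci assayed by the MLPA backup assay. SNV and CNA events at the
# same gene are distinct features; CNA features carry a "_cna" suffix.

#' Default 67-gene SNV panel
#' @return character vector of 67 gene symbols.
#' @export
default_snv_panel <- function() {
  c("KRAS", "TP53", "CDKN2A", "SMAD4", "ARID1A", "KMT2C", "KMT2D",
    "TGFBR1", "TGFBR2", "RNF43", "GNAS", "ATM", "BRCA1", "BRCA2", "PALB2",
    "ERBB4", "ERBB2", "EGFR", "PLCG2", "MAP2K7", "CAMK2B", "PTEN", "RB1",
    "MYC", "GATA6", "ACVR1B", "ACVR2A", "SF3B1", "U2AF1", "RBM10", "SPTA1",
    "MAP2K4", "STK11", "AKT2", "PIK3CA", "PIK3R1", "MTOR", "BRAF", "NRAS",
    "CTNNB1", "APC", "FBXW7", "NOTCH1", "NOTCH2", "ARID2", "PBRM1",
    "SMARCA4", "SETD2", "KDM6A", "CREBBP", "EP300", "TET2", "DNMT3A",
    "IDH1", "CDK6", "CCND1", "FGFR1", "MET", "ALK", "ROS1", "CHEK2",
    "MSH2", "MSH6", "MLH1", "POLE", "GLI3", "TLE4")
}

#' Default 11-locus copy-number (MLPA) panel
#' @return character vector of 11 gene symbols.
#' @export
default_cna_panel <- function() {
  c("SMAD4", "CDKN2A", "TP53", "KRAS", "MYC", "GATA6", "PTEN", "RB1",
    "BRCA2", "JAK2", "CD274")
}

cna_feature_labels <- function(loci) paste0(loci, "_cna")
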