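# Small hand-built tables shared across unit tests.

clinical_fixture <- function() {
  data.frame(
    barcode = sprintf("T-%02d", 1:8),
    cancer_type = "BRCA",
    histology = c(rep("Primary Tumor", 7L), "Metastatic"),
    low_quality = c(FALSE, TRUE, rep(FALSE, 6L)),
    cancer_dna_fraction = c(0.8, 0.8, 0.49, 0.5, 0.8, NA, 0.8, 0.8),
    subclonal_fraction = c(0.1, 0.1, 0.1, 0.5, 0.51, 0.1, 0.1, 0.1),
    sex = "female",
    age = 55L,
    stage = "II",
    has_sna = c(rep(TRUE, 6L), FALSE, TRUE),
    has_cna = TRUE,
    has_aneuploidy = TRUE,
    stringsAsFactors = FALSE
  )
}

# one gene (7157) with SNAs, one amplification-only gene (4609)
sna_fixture <- function() {
  data.frame(
    barcode = c("T-01", "T-01", "T-04", "T-04", "T-08"),
    entrez = c(7157L, 7157L, 7157L, 4609L, 7157L),
    symbol = c("TP53", "TP53", "TP53", "MYC", "TP53"),
    transcript = sprintf("ENST%08d", c(7157L, 7157L, 7157L, 4609L, 7157L)),
    variant_class = c("Missense_Mutation", "Nonsense_Mutation",
                      "Missense_Mutation", "Silent", "Missense_Mutation"),
    substitution = c("c.215C>G", "c.637C>T", "c.215C>G", "c.100A>A",
                     "c.215C>G"),
    cancer_type = "BRCA",
    stringsAsFactors = FALSE
  )
}

status_matrix <- function(values, genes, patients) {
  matrix(values, length(genes), length(patients), byrow = TRUE,
         dimnames = list(genes, patients))
}
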