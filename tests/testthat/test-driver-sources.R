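test_that("source ingestion applies the strict q-value filter", {
  tab <- data.frame(entrez = 1:4, cancer_type = "BRCA",
                    q_value = c(0.06, 0.05, NA, 0.01),
                    stringsAsFactors = FALSE)
  src <- driver_source("alg1", tab, kind = "gene")
  # q = 0.06 dropped; q = 0.05 kept (boundary); missing q kept (curated)
  expect_setequal(src$table$entrez, c(2L, 3L, 4L))

  expect_error(driver_source("alg1", tab[, "entrez", drop = FALSE],
                             kind = "gene"), "cancer_type")
  bad <- tab; bad$q_value[1] <- 1.5
  expect_error(driver_source("alg1", bad, kind = "gene"), "q-value")
})

pair_setup <- function() {
  patients <- data.frame(
    barcode = c("B1", "B2", "L1"),
    cancer_type = c("BRCA", "BRCA", "LUSC"),
    stringsAsFactors = FALSE
  )
  snas <- data.frame(
    barcode = c("B1", "L1"),
    entrez = c(7157L, 7157L),
    transcript = "ENST00000269305",
    variant_class = "Missense_Mutation",
    substitution = "c.215C>G",
    cancer_type = c("BRCA", "LUSC"),
    stringsAsFactors = FALSE
  )
  cna <- matrix(c(0L, 1L, 0L), 1, 3,
                dimnames = list("7157", c("B1", "B2", "L1")))
  list(patients = patients, snas = snas, cna = cna)
}

test_that("gene-level entries convert to patient-gene pairs by Entrez + cancer type", {
  s <- pair_setup()
  src <- driver_source("alg1",
                       data.frame(entrez = 7157L, cancer_type = "BRCA",
                                  stringsAsFactors = FALSE),
                       kind = "gene")
  pairs <- to_patient_level(src, s$snas, s$cna, s$patients)
  # B1 via the SNA route, B2 via the validated-CNA route;
  # L1 carries the SNA but is LUSC, not BRCA -> no pair
  expect_setequal(pairs$barcode, c("B1", "B2"))
  expect_true(all(pairs$entrez == 7157L))
})

test_that("mutation-level entries match transcript + substitution + cancer type", {
  s <- pair_setup()
  src <- driver_source("chasm",
                       data.frame(entrez = 7157L,
                                  transcript = "ENST00000269305",
                                  substitution = "c.215C>G",
                                  cancer_type = "LUSC",
                                  stringsAsFactors = FALSE),
                       kind = "mutation")
  pairs <- to_patient_level(src, s$snas, s$cna, s$patients)
  # only L1 matches on the SNA route; the CNA route finds nothing in LUSC
  expect_equal(pairs$barcode, "L1")

  # a substitution string matching no patient yields no pair
  src2 <- driver_source("chasm",
                        data.frame(entrez = 7157L,
                                   transcript = "ENST00000269305",
                                   substitution = "c.999G>T",
                                   cancer_type = "LUSC",
                                   stringsAsFactors = FALSE),
                        kind = "mutation")
  expect_equal(nrow(to_patient_level(src2, s$snas, s$cna, s$patients)), 0L)
})

test_that("pairs are never emitted for patients outside the QC population", {
  s <- pair_setup()
  src <- driver_source("alg1",
                       data.frame(entrez = 7157L, cancer_type = "BRCA",
                                  stringsAsFactors = FALSE),
                       kind = "gene")
  no_b2 <- s$patients[s$patients$barcode != "B2", , drop = FALSE]
  pairs <- to_patient_level(src, s$snas, s$cna, no_b2)
  expect_false("B2" %in% pairs$barcode)
})

test_that("consensus keeps pairs supported by at least two distinct sources", {
  p1 <- data.frame(barcode = c("B1", "B2"), entrez = 7157L,
                   source = "alg1", stringsAsFactors = FALSE)
  p2 <- data.frame(barcode = "B1", entrez = 7157L,
                   source = "alg2", stringsAsFactors = FALSE)
  out <- consensus_filter(list(p1, p2))
  expect_equal(out$barcode, "B1")
  expect_equal(out$n_sources, 2L)
  expect_equal(out$sources, "alg1|alg2")

  # single-source pairs are removed; empty input gives empty output
  expect_equal(nrow(consensus_filter(list(p1))), 0L)
  expect_equal(nrow(consensus_filter(list(p1[0, ]))), 0L)

  # monotone: adding a source never removes a surviving pair
  p3 <- data.frame(barcode = "B2", entrez = 7157L,
                   source = "alg3", stringsAsFactors = FALSE)
  with2 <- consensus_filter(list(p1, p2))
  with3 <- consensus_filter(list(p1, p2, p3))
  expect_true(all(paste(with2$barcode, with2$entrez) %in%
                    paste(with3$barcode, with3$entrez)))
  # duplicate support from the same file counts once
  expect_equal(nrow(consensus_filter(list(p1, p1))), 0L)
})
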