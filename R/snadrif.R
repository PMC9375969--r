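#' Default MAF variant-classification vocabulary
#'
#' Maps MAF-style `Variant_Classification` labels onto the four functional
#' categories used by the SNA classifier: frameshift indels, nonsense,
#' nonstop and translation start site mutations are potentially
#' inactivating; in-frame indels, in-frame de novo starts and missense
#' mutations potentially hyperactivating; out-of-frame de novo starts and
#' silent mutations passengers. Labels absent from the table are "unclear".
#' The table is an ordinary data.frame and can be edited or replaced to
#' accommodate other file dialects.
#'
#' @return data.frame with columns `variant_class` and `category`.
#' @export
default_variant_categories <- function() {
  data.frame(
    variant_class = c("Frame_Shift_Del", "Frame_Shift_Ins",
                      "Nonsense_Mutation", "Nonstop_Mutation",
                      "Translation_Start_Site",
                      "In_Frame_Del", "In_Frame_Ins",
                      "De_novo_Start_InFrame", "Missense_Mutation",
                      "De_novo_Start_OutOfFrame", "Silent"),
    category = c(rep("inactivating", 5L),
                 rep("hyperactivating", 4L),
                 rep("passenger", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Classify variant labels into functional SNA categories
#'
#' @param variant_class character vector of variant classification labels.
#' @param vocabulary mapping table as produced by
#'   [default_variant_categories()].
#' @return character vector over `{"hyperactivating", "inactivating",
#'   "passenger", "unclear"}`; any label not in the vocabulary is
#'   "unclear", so the function is total.
#' @export
classify_sna <- function(variant_class,
                         vocabulary = default_variant_categories()) {
  idx <- match(variant_class, vocabulary$variant_class)
  out <- vocabulary$category[idx]
  out[is.na(out)] <- "unclear"
  out
}

#' Hyperactivating-to-Inactivating SNA Ratio
#'
#' Gene-level polarity score: `(n_hyper + 1) / (n_inact + 1)`. Values above
#' 5 mark oncogene-like genes, values at or below 5 suppressor-like genes.
#' The pseudocounts keep the ratio finite and defined for genes with few
#' mutations of either kind.
#'
#' @param n_hyper,n_inact non-negative mutation counts (vectorized).
#' @return positive numeric ratio.
#' @export
hisr <- function(n_hyper, n_inact) {
  if (any(n_hyper < 0) || any(n_inact < 0)) {
    stop("hisr: counts must be non-negative", call. = FALSE)
  }
  (n_hyper + 1) / (n_inact + 1)
}

#' Gene-level SNA summary with HISR (SNADRIF)
#'
#' Tallies the functional categories of every SNA record per gene across
#' all patients, removes genes whose SNAs are all of unclear role (likely
#' non-coding) and genes with fewer than 10 classified (hyperactivating +
#' inactivating + passenger) SNAs, and computes HISR for the survivors.
#' Input records must already be restricted to the QC-passing population.
#'
#' @param snas data.frame with columns `barcode`, `entrez`, `variant_class`
#'   (optionally `symbol`, others are carried through untouched elsewhere).
#' @param min_classified minimum number of classified SNAs for a gene to
#'   be retained (default 10; the boundary itself is kept).
#' @param vocabulary variant-class mapping, see [classify_sna()].
#' @return data.frame with one row per retained gene: `entrez`, `symbol`
#'   (if supplied), `n_hyper`, `n_inact`, `n_passenger`, `n_unclear`,
#'   `hisr`, ordered by Entrez ID.
#' @export
snadrif_summary <- function(snas, min_classified = 10L,
                            vocabulary = default_variant_categories()) {
  empty <- data.frame(entrez = integer(), symbol = character(),
                      n_hyper = integer(), n_inact = integer(),
                      n_passenger = integer(), n_unclear = integer(),
                      hisr = numeric(), stringsAsFactors = FALSE)
  if (nrow(snas) == 0L) return(empty)

  cat_ <- classify_sna(snas$variant_class, vocabulary)
  tab <- table(factor(snas$entrez), factor(cat_, levels = c(
    "hyperactivating", "inactivating", "passenger", "unclear")))
  counts <- as.data.frame.matrix(tab)
  entrez <- as.integer(rownames(counts))
  out <- data.frame(
    entrez = entrez,
    n_hyper = counts$hyperactivating,
    n_inact = counts$inactivating,
    n_passenger = counts$passenger,
    n_unclear = counts$unclear,
    stringsAsFactors = FALSE
  )
  if ("symbol" %in% names(snas)) {
    out$symbol <- snas$symbol[match(out$entrez, snas$entrez)]
    out <- out[, c("entrez", "symbol", "n_hyper", "n_inact",
                   "n_passenger", "n_unclear")]
  }
  n_classified <- out$n_hyper + out$n_inact + out$n_passenger
  out <- out[n_classified > 0L & n_classified >= min_classified, , drop = FALSE]
  out$hisr <- hisr(out$n_hyper, out$n_inact)
  out <- out[order(out$entrez), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per patient-gene SNA counts
#'
#' Patient-level tallies of hyperactivating and inactivating SNAs, the
#' inputs to driver-event classification. Passenger and unclear records
#' contribute nothing here (they only enter the gene-level summary).
#'
#' @inheritParams snadrif_summary
#' @return data.frame with columns `barcode`, `entrez`, `n_hyper`,
#'   `n_inact` (one row per pair with at least one functional SNA).
#' @export
patient_gene_sna_counts <- function(snas,
                                    vocabulary = default_variant_categories()) {
  empty <- data.frame(barcode = character(), entrez = integer(),
                      n_hyper = integer(), n_inact = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(snas) == 0L) return(empty)
  cat_ <- classify_sna(snas$variant_class, vocabulary)
  keep <- cat_ %in% c("hyperactivating", "inactivating")
  if (!any(keep)) return(empty)
  sub <- snas[keep, , drop = FALSE]
  cat_ <- cat_[keep]
  key <- paste(sub$barcode, sub$entrez, sep = "\r")
  hy <- tapply(cat_ == "hyperactivating", key, sum)
  ia <- tapply(cat_ == "inactivating", key, sum)
  parts <- strsplit(names(hy), "\r", fixed = TRUE)
  out <- data.frame(
    barcode = vapply(parts, `[`, "", 1L),
    entrez = as.integer(vapply(parts, `[`, "", 2L)),
    n_hyper = as.integer(hy),
    n_inact = as.integer(ia),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$barcode, out$entrez), , drop = FALSE]
  rownames(out) <- NULL
  out
}
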