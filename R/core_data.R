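#' Quality filter defining the analysis population
#'
#' Restricts a per-patient clinical/QC table to the samples on which all
#' downstream driver calling operates: primary malignant histology, not
#' flagged low quality, cancer DNA fraction of at least 50%, subclonal
#' genome fraction of at most 50%, and simultaneous availability of SNA,
#' CNA and aneuploidy data. Records with a missing purity or subclonality
#' fraction are removed, because the corresponding criterion cannot be
#' certified for them.
#'
#' @param patients data.frame with columns `barcode`, `cancer_type`,
#'   `histology`, `low_quality` (logical), `cancer_dna_fraction`,
#'   `subclonal_fraction`, `has_sna`, `has_cna`, `has_aneuploidy`;
#'   optional `sex`, `age`, `stage`.
#' @param accepted_histology character vector of histology labels counted
#'   as primary malignant. The default absorbs the common file dialects.
#' @param verbose emit one log line per criterion with its removal count.
#'
#' @return The retained rows, in input order, with an attribute
#'   `"filter_report"`: a named integer vector of per-criterion removal
#'   counts (each record is attributed to every criterion it violates).
#' @export
filter_samples <- function(patients,
                           accepted_histology = c("Primary Tumor",
                                                  "primary malignant neoplasm"),
                           verbose = FALSE) {
  required <- c("barcode", "cancer_type", "histology", "low_quality",
                "cancer_dna_fraction", "subclonal_fraction",
                "has_sna", "has_cna", "has_aneuploidy")
  missing_cols <- setdiff(required, names(patients))
  if (length(missing_cols) > 0L) {
    stop("filter_samples: clinical table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(patients) == 0L) {
    stop("filter_samples: clinical table is empty", call. = FALSE)
  }
  if (anyDuplicated(patients$barcode)) {
    stop("filter_samples: duplicated patient barcodes", call. = FALSE)
  }

  frac_ok <- function(x, lo_ok) !is.na(x) & x >= 0 & x <= 1
  bad_rng <- (!is.na(patients$cancer_dna_fraction) &
                (patients$cancer_dna_fraction < 0 | patients$cancer_dna_fraction > 1)) |
             (!is.na(patients$subclonal_fraction) &
                (patients$subclonal_fraction < 0 | patients$subclonal_fraction > 1))
  if (any(bad_rng)) {
    stop("filter_samples: fraction outside [0,1] for barcode(s): ",
         paste(utils::head(patients$barcode[bad_rng], 5L), collapse = ", "),
         call. = FALSE)
  }

  crit <- cbind(
    histology      = patients$histology %in% accepted_histology,
    low_quality    = !patients$low_quality,
    # boundary kept: exactly 0.5 passes both fraction criteria
    purity         = !is.na(patients$cancer_dna_fraction) &
                     patients$cancer_dna_fraction >= 0.5,
    subclonality   = !is.na(patients$subclonal_fraction) &
                     patients$subclonal_fraction <= 0.5,
    data_complete  = patients$has_sna & patients$has_cna & patients$has_aneuploidy
  )
  missing_fraction <- is.na(patients$cancer_dna_fraction) |
                      is.na(patients$subclonal_fraction)

  keep <- rowSums(!crit) == 0L
  report <- c(colSums(!crit), missing_fraction = sum(missing_fraction))

  if (verbose) {
    for (nm in names(report)) {
      message(sprintf("filter_samples: %-16s removed %d", nm, report[[nm]]))
    }
    message(sprintf("filter_samples: retained %d of %d patients",
                    sum(keep), nrow(patients)))
  }

  out <- patients[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}
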