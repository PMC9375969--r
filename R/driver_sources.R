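#' Construct a cohort-level driver source
#'
#' Wraps one driver-prediction source (e.g. the output of a cohort-level
#' algorithm, a multi-algorithm consensus list, or a curated census) in a
#' common structure and applies the q-value filter: entries with
#' `q_value > q_max` are dropped, entries without a q-value (curated lists)
#' are retained.
#'
#' @param name source identifier used in consensus accounting.
#' @param table data.frame. Gene-level sources need columns `entrez` and
#'   `cancer_type`; mutation-level sources need `transcript`,
#'   `substitution` and `cancer_type`. An optional `q_value` column is
#'   filtered on.
#' @param kind `"gene"` or `"mutation"`.
#' @param q_max q-value cutoff (default 0.05, strict: q equal to the
#'   cutoff is retained).
#' @return object of class `"driver_source"`: list with `name`, `kind`,
#'   `table` (filtered).
#' @export
driver_source <- function(name, table, kind = c("gene", "mutation"),
                          q_max = 0.05) {
  kind <- match.arg(kind)
  needed <- if (kind == "gene") c("entrez", "cancer_type")
            else c("transcript", "substitution", "cancer_type")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L) {
    stop("driver_source '", name, "': missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("q_value" %in% names(table)) {
    bad <- !is.na(table$q_value) & (table$q_value < 0 | table$q_value > 1)
    if (any(bad)) {
      stop("driver_source '", name, "': q-value outside [0, 1] at row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
    }
    table <- table[is.na(table$q_value) | table$q_value <= q_max, ,
                   drop = FALSE]
  }
  rownames(table) <- NULL
  structure(list(name = name, kind = kind, table = table),
            class = "driver_source")
}

#' Read a driver source from a TSV file
#'
#' @param path TSV file with a header matching the columns described in
#'   [driver_source()].
#' @inheritParams driver_source
#' @return a `"driver_source"` object.
#' @export
read_driver_source <- function(path, name, kind = c("gene", "mutation"),
                               q_max = 0.05) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  driver_source(name = name, table = tab, kind = match.arg(kind),
                q_max = q_max)
}

#' Convert one cohort-level source to patient-gene pairs
#'
#' Gene-level entries match every QC-passing patient of the entry's cancer
#' type that carries at least one SNA in the gene (by Entrez ID) or a
#' nonzero validated CNA there. Mutation-level entries match patients via
#' Ensembl transcript ID plus the exact substitution string plus cancer
#' type on the SNA route, and via Entrez ID plus cancer type on the CNA
#' route. SNA- and CNA-derived pairs are unioned and de-duplicated.
#'
#' @param source a `"driver_source"` object.
#' @param snas SNA table restricted to QC-passing patients, with columns
#'   `barcode`, `entrez`, `transcript`, `substitution`, `cancer_type`.
#' @param cna validated CNA matrix (genes x patients, Entrez rownames).
#' @param patients QC-filtered clinical table (`barcode`, `cancer_type`).
#' @return data.frame of unique pairs: `barcode`, `entrez`, `source`.
#' @export
to_patient_level <- function(source, snas, cna, patients) {
  stopifnot(inherits(source, "driver_source"))
  empty <- data.frame(barcode = character(), entrez = integer(),
                      source = character(), stringsAsFactors = FALSE)
  tab <- source$table
  if (nrow(tab) == 0L) return(empty)

  snas <- snas[snas$barcode %in% patients$barcode, , drop = FALSE]
  patient_ct <- patients$cancer_type[match(snas$barcode, patients$barcode)]

  cna_pairs_for <- function(entrez_ids, cancer_types) {
    genes <- intersect(unique(as.character(entrez_ids)), rownames(cna))
    if (length(genes) == 0L) return(empty[, 1:2])
    keep_pat <- intersect(colnames(cna), patients$barcode)
    sub <- cna[genes, keep_pat, drop = FALSE]
    hits <- which(!is.na(sub) & sub != 0, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(empty[, 1:2])
    cand <- data.frame(
      barcode = colnames(sub)[hits[, "col"]],
      entrez = as.integer(rownames(sub)[hits[, "row"]]),
      stringsAsFactors = FALSE
    )
    cand_ct <- patients$cancer_type[match(cand$barcode, patients$barcode)]
    want <- paste(cand$entrez, cand_ct) %in%
      paste(as.integer(entrez_ids), cancer_types)
    cand[want, , drop = FALSE]
  }

  if (source$kind == "gene") {
    sna_hit <- paste(snas$entrez, patient_ct) %in%
      paste(as.integer(tab$entrez), tab$cancer_type)
    sna_pairs <- data.frame(barcode = snas$barcode[sna_hit],
                            entrez = as.integer(snas$entrez[sna_hit]),
                            stringsAsFactors = FALSE)
    cna_pairs <- cna_pairs_for(tab$entrez, tab$cancer_type)
  } else {
    sna_hit <- paste(snas$transcript, snas$substitution, patient_ct) %in%
      paste(tab$transcript, tab$substitution, tab$cancer_type)
    sna_pairs <- data.frame(barcode = snas$barcode[sna_hit],
                            entrez = as.integer(snas$entrez[sna_hit]),
                            stringsAsFactors = FALSE)
    if (!"entrez" %in% names(tab)) {
      stop("to_patient_level: mutation-level source '", source$name,
           "' needs an 'entrez' column for the CNA route", call. = FALSE)
    }
    cna_pairs <- cna_pairs_for(tab$entrez, tab$cancer_type)
  }

  out <- rbind(sna_pairs, cna_pairs)
  if (nrow(out) == 0L) return(empty)
  out <- out[!duplicated(paste(out$barcode, out$entrez)), , drop = FALSE]
  out$source <- source$name
  out <- out[order(out$barcode, out$entrez), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus filter over patient-gene pairs from all sources
#'
#' Keeps exactly the patient-gene pairs supported by at least
#' `min_sources` distinct source lists.
#'
#' @param pair_tables list of pair tables from [to_patient_level()] (or
#'   one row-bound table with a `source` column).
#' @param min_sources minimum number of distinct supporting sources
#'   (default 2).
#' @return data.frame: `barcode`, `entrez`, `sources` (pipe-joined),
#'   `n_sources`.
#' @export
consensus_filter <- function(pair_tables, min_sources = 2L) {
  if (is.data.frame(pair_tables)) pair_tables <- list(pair_tables)
  all_pairs <- do.call(rbind, pair_tables)
  empty <- data.frame(barcode = character(), entrez = integer(),
                      sources = character(), n_sources = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(all_pairs) || nrow(all_pairs) == 0L) return(empty)
  key <- paste(all_pairs$barcode, all_pairs$entrez, sep = "\r")
  src <- tapply(all_pairs$source, key, function(s) sort(unique(s)))
  n_src <- vapply(src, length, 0L)
  keep <- n_src >= min_sources
  if (!any(keep)) return(empty)
  parts <- strsplit(names(src)[keep], "\r", fixed = TRUE)
  out <- data.frame(
    barcode = vapply(parts, `[`, "", 1L),
    entrez = as.integer(vapply(parts, `[`, "", 2L)),
    sources = vapply(src[keep], paste, "", collapse = "|"),
    n_sources = as.integer(n_src[keep]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$barcode, out$entrez), , drop = FALSE]
  rownames(out) <- NULL
  out
}
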