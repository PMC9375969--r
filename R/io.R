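#' Write a cohort bundle to a directory of TSV files
#'
#' Persists the six inputs in plain tab-separated form: `clinical.tsv`,
#' `sna.tsv`, `cna.tsv`, `expression.tsv`, `arms.tsv`,
#' `chromosomes.tsv`, one `source_<name>.tsv` per driver source and a
#' `sources.tsv` registry (name, file, kind).
#'
#' @param bundle a bundle list (see [driver_strength()]).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file, rn = FALSE) {
    utils::write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  wt(bundle$clinical, "clinical.tsv")
  wt(bundle$sna, "sna.tsv")
  wt(as.data.frame(bundle$cna), "cna.tsv", rn = TRUE)
  wt(as.data.frame(bundle$expression), "expression.tsv", rn = TRUE)
  wt(as.data.frame(bundle$arms), "arms.tsv", rn = TRUE)
  if (!is.null(bundle$chromosomes)) {
    wt(as.data.frame(bundle$chromosomes), "chromosomes.tsv", rn = TRUE)
  }
  reg <- data.frame(name = character(), file = character(),
                    kind = character(), stringsAsFactors = FALSE)
  for (src in bundle$sources) {
    f <- paste0("source_", src$name, ".tsv")
    wt(src$table, f)
    reg <- rbind(reg, data.frame(name = src$name, file = f, kind = src$kind,
                                 stringsAsFactors = FALSE))
  }
  wt(reg, "sources.tsv")
  invisible(dir)
}

#' Read a cohort bundle from a directory of TSV files
#'
#' Counterpart of [write_bundle()].
#'
#' @param dir directory containing the bundle files.
#' @return a bundle list.
#' @export
read_bundle <- function(dir) {
  rd <- function(file) {
    utils::read.delim(file.path(dir, file), stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  rm_ <- function(file) {
    d <- utils::read.delim(file.path(dir, file), row.names = 1L,
                           check.names = FALSE)
    as.matrix(d)
  }
  need <- function(file) {
    p <- file.path(dir, file)
    if (!file.exists(p)) {
      stop("read_bundle: missing input file '", file, "'", call. = FALSE)
    }
    p
  }
  for (f in c("clinical.tsv", "sna.tsv", "cna.tsv", "expression.tsv",
              "arms.tsv", "sources.tsv")) need(f)
  reg <- rd("sources.tsv")
  sources <- lapply(seq_len(nrow(reg)), function(i) {
    driver_source(reg$name[i], rd(reg$file[i]), kind = reg$kind[i])
  })
  chrom_path <- file.path(dir, "chromosomes.tsv")
  list(
    clinical = rd("clinical.tsv"),
    sna = rd("sna.tsv"),
    cna = rm_("cna.tsv"),
    expression = rm_("expression.tsv"),
    arms = rm_("arms.tsv"),
    chromosomes = if (file.exists(chrom_path)) rm_("chromosomes.tsv"),
    sources = sources
  )
}

#' Validate a cohort bundle
#'
#' Schema and value-range checks before fitting: status levels of the CNA
#' matrix (-2..2) and aneuploidy tables (-1..1), non-negative expression,
#' required clinical columns, and identifier join coverage across files.
#' Hard violations raise errors; partial coverage (patients or genes
#' present in some files only, which the fit tolerates by exclusion)
#' yields warnings collected in the report.
#'
#' @param bundle a bundle list.
#' @return character vector of warnings (empty when fully consistent),
#'   invisibly; errors are thrown for hard violations.
#' @export
validate_bundle <- function(bundle) {
  warnings_ <- character()
  req_clin <- c("barcode", "cancer_type", "histology", "low_quality",
                "cancer_dna_fraction", "subclonal_fraction",
                "has_sna", "has_cna", "has_aneuploidy")
  miss <- setdiff(req_clin, names(bundle$clinical))
  if (length(miss) > 0L) {
    stop("validate_bundle: clinical table lacks ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  req_sna <- c("barcode", "entrez", "variant_class", "cancer_type")
  miss <- setdiff(req_sna, names(bundle$sna))
  if (length(miss) > 0L) {
    stop("validate_bundle: SNA table lacks ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  .check_status_levels(bundle$cna, -2:2, "validate_bundle: CNA")
  .check_status_levels(bundle$arms, -1:1, "validate_bundle: arm")
  if (!is.null(bundle$chromosomes)) {
    .check_status_levels(bundle$chromosomes, -1:1, "validate_bundle: chromosome")
  }
  if (any(bundle$expression < 0, na.rm = TRUE)) {
    stop("validate_bundle: negative expression values", call. = FALSE)
  }

  clin_bc <- bundle$clinical$barcode
  orphan_sna <- setdiff(unique(bundle$sna$barcode), clin_bc)
  if (length(orphan_sna) > 0L) {
    warnings_ <- c(warnings_, sprintf(
      "%d SNA patient(s) absent from the clinical table (excluded)",
      length(orphan_sna)))
  }
  orphan_cna <- setdiff(colnames(bundle$cna), clin_bc)
  if (length(orphan_cna) > 0L) {
    warnings_ <- c(warnings_, sprintf(
      "%d CNA patient(s) absent from the clinical table (excluded)",
      length(orphan_cna)))
  }
  no_expr <- setdiff(rownames(bundle$cna), rownames(bundle$expression))
  if (length(no_expr) > 0L) {
    warnings_ <- c(warnings_, sprintf(
      "%d CNA gene(s) without expression (calls pass through unvalidated)",
      length(no_expr)))
  }
  for (w in warnings_) warning(w, call. = FALSE)
  invisible(warnings_)
}

#' Write fit results to a directory
#'
#' Persists the per entity-class index table (with the stratum profile as
#' a JSON column), the ranked DSI and NDSI lists, the cohort-level
#' aneuploidy calls, per-patient totals, and a JSON manifest recording
#' the thresholds, seed and per-stage record counts.
#'
#' @param fit a `"driver_strength"` object.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "driver_strength"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file) {
    utils::write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  idx <- fit$index
  if (nrow(idx) > 0L && "p_A" %in% names(idx)) {
    idx$p_A <- vapply(idx$p_A, function(v) {
      as.character(jsonlite::toJSON(as.list(v), auto_unbox = TRUE))
    }, "")
  }
  wt(idx, "index.tsv")
  wt(fit$top_dsi, "top_dsi.tsv")
  wt(fit$top_ndsi, "top_ndsi.tsv")
  wt(fit$arm_calls, "arm_calls.tsv")
  if (!is.null(fit$chrom_calls)) wt(fit$chrom_calls, "chromosome_calls.tsv")
  wt(fit$events, "events.tsv")
  wt(fit$totals$per_patient, "patient_totals.tsv")
  manifest <- list(
    package = "driverstrength",
    version = as.character(utils::packageVersion("driverstrength")),
    seed = fit$seed,
    thresholds = fit$thresholds,
    counts = list(
      patients = nrow(fit$patients),
      consensus_pairs = nrow(fit$pairs),
      events = nrow(fit$events),
      index_records = nrow(fit$index)
    ),
    filter_report = as.list(fit$filter_report)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
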