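#' Fit the patient-level driver strength model to a cohort bundle
#'
#' Runs the full integration in dependency order: sample QC filtering;
#' expression-based validation of copy-number calls; gene-level SNA
#' classification and HISR; bootstrap aneuploidy driver calling with
#' Benjamini-Hochberg control and patient-level instantiation; conversion
#' of every cohort-level driver source to patient-gene pairs and the
#' two-source consensus; classification of each pair into a driver event
#' class; and the per-entity Driver Strength Index and its normalized
#' form over the patient strata of total driver event counts.
#'
#' @param bundle list with elements `clinical`, `sna`, `cna`,
#'   `expression`, `arms`, `chromosomes` (optional), `sources` (list of
#'   [driver_source()] objects), as produced by [generate_cohort()],
#'   [worked_example()] or [read_bundle()].
#' @param B bootstrap replicates for aneuploidy calling (default 10000).
#' @param fdr false discovery rate for aneuploidy calls (default 0.05).
#' @param hisr_cutoff oncogene/suppressor HISR boundary (default 5).
#' @param min_classified minimum classified SNAs per gene (default 10).
#' @param min_sources consensus requirement on supporting source lists
#'   (default 2).
#' @param i_max largest per-patient driver event total considered
#'   (default 100).
#' @param min_patients reporting filter for ranked lists (default 10).
#' @param ndsi_floor minimum NDSI in NDSI-ranked lists (default 0.05).
#' @param top_n length of the ranked lists (default 50).
#' @param seed seed for the bootstrap stage; the whole fit is
#'   reproducible from it.
#' @param verbose log per-stage record counts.
#' @return object of class `"driver_strength"`; see Details.
#'
#' @details The returned object is a list with the filtered `patients`,
#'   the validated CNA matrix (`validated_cna`), the gene-level SNA
#'   summary (`gene_summary`), cohort-level aneuploidy calls
#'   (`arm_calls`, `chrom_calls`) and their patient-level events
#'   (`aneuploidy`), the consensus `pairs`, classified patient-gene
#'   `states`, the combined unit `events`, the strata (`totals`), the per
#'   entity-class `index` table, and ranked `top_dsi`/`top_ndsi` lists.
#'   `coef()` returns the index table, `plot()` draws a top-list
#'   barchart.
#' @export
driver_strength <- function(bundle,
                            B = 10000L, fdr = 0.05,
                            hisr_cutoff = 5, min_classified = 10L,
                            min_sources = 2L, i_max = 100L,
                            min_patients = 10L, ndsi_floor = 0.05,
                            top_n = 50L,
                            seed = 1L, verbose = FALSE) {
  needed <- c("clinical", "sna", "cna", "expression", "arms", "sources")
  miss <- setdiff(needed, names(bundle))
  if (length(miss) > 0L) {
    stop("driver_strength: bundle lacks input(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  log_ <- function(...) if (verbose) message(sprintf(...))

  patients <- filter_samples(bundle$clinical, verbose = verbose)
  barcodes <- patients$barcode
  log_("QC: %d of %d patients retained", length(barcodes),
       nrow(bundle$clinical))

  sna <- bundle$sna[bundle$sna$barcode %in% barcodes, , drop = FALSE]
  expr <- bundle$expression[, intersect(colnames(bundle$expression), barcodes),
                            drop = FALSE]
  cna <- bundle$cna[, intersect(colnames(bundle$cna), barcodes), drop = FALSE]

  expr_status <- expression_status_matrix(expr)
  vcna <- validate_cna(cna, expr_status)
  log_("GECNAV: %d of %d nonzero CNA calls confirmed",
       sum(vcna != 0, na.rm = TRUE), sum(cna != 0, na.rm = TRUE))

  gene_summary <- snadrif_summary(sna, min_classified = min_classified)
  sna_counts <- patient_gene_sna_counts(sna)
  log_("SNADRIF: %d genes retained", nrow(gene_summary))

  arms <- bundle$arms[intersect(rownames(bundle$arms), barcodes), ,
                      drop = FALSE]
  chroms <- if (!is.null(bundle$chromosomes)) {
    bundle$chromosomes[intersect(rownames(bundle$chromosomes), barcodes), ,
                       drop = FALSE]
  }
  aneu <- with_seed(seed, {
    arm_calls <- andrif_calls(arms, patients, "arm", B = B, fdr = fdr)
    chrom_calls <- if (!is.null(chroms)) {
      andrif_calls(chroms, patients, "chromosome", B = B, fdr = fdr)
    }
    list(arm_calls = arm_calls, chrom_calls = chrom_calls)
  })
  aneu_events <- aneuploidy_events(arms, aneu$arm_calls, patients,
                                   chrom_table = chroms,
                                   chrom_calls = aneu$chrom_calls)
  log_("ANDRIF: %d cohort calls, %d patient events",
       sum(!is.na(aneu$arm_calls$label)) +
         sum(!is.na(aneu$chrom_calls$label)),
       nrow(aneu_events))

  pair_tables <- lapply(bundle$sources, to_patient_level,
                        snas = sna, cna = vcna, patients = patients)
  pairs <- consensus_filter(pair_tables, min_sources = min_sources)
  log_("Sources: %d consensus patient-gene pairs", nrow(pairs))

  states <- classify_events(
    patient_gene_states(pairs, sna_counts, gene_summary, vcna),
    hisr_cutoff = hisr_cutoff
  )
  events <- rbind(gene_events(states),
                  aneu_events[, c("barcode", "entity", "event_class")])
  totals <- total_events(events, i_max = i_max)
  index <- compute_indices(events, totals)
  log_("PALDRIC: %d unit events, %d entity-class records",
       nrow(events), nrow(index))

  fit <- list(
    call = match.call(),
    patients = patients,
    filter_report = attr(patients, "filter_report"),
    validated_cna = vcna,
    gene_summary = gene_summary,
    sna_counts = sna_counts,
    arm_calls = aneu$arm_calls,
    chrom_calls = aneu$chrom_calls,
    aneuploidy = aneu_events,
    pairs = pairs,
    states = states,
    events = events,
    totals = totals,
    index = index,
    top_dsi = rank_and_filter(index, "dsi", min_patients = min_patients,
                              top_n = top_n),
    top_ndsi = rank_and_filter(index, "ndsi", min_patients = min_patients,
                               ndsi_floor = ndsi_floor, top_n = top_n),
    thresholds = list(B = B, fdr = fdr, hisr_cutoff = hisr_cutoff,
                      min_classified = min_classified,
                      min_sources = min_sources, i_max = i_max,
                      min_patients = min_patients, ndsi_floor = ndsi_floor,
                      top_n = top_n),
    seed = seed
  )
  class(fit) <- "driver_strength"
  fit
}

#' @export
print.driver_strength <- function(x, ...) {
  cat("Patient-level driver strength fit\n")
  cat(sprintf("  patients: %d (QC-passed), cohorts: %d\n",
              nrow(x$patients), length(unique(x$patients$cancer_type))))
  cat(sprintf("  driver events: %d across %d patients\n",
              nrow(x$events), sum(x$totals$per_patient$included)))
  cat(sprintf("  entity-class records: %d; aneuploidy calls: %d\n",
              nrow(x$index),
              sum(!is.na(x$arm_calls$label)) +
                if (!is.null(x$chrom_calls))
                  sum(!is.na(x$chrom_calls$label)) else 0L))
  if (nrow(x$top_ndsi) > 0L) {
    cat("  top NDSI entities:",
        paste(utils::head(x$top_ndsi$entity, 5L), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.driver_strength <- function(object, n = 10L, ...) {
  s <- list(
    n_patients = nrow(object$patients),
    filter_report = object$filter_report,
    p_i = object$totals$p_i,
    mean_events = with(object$totals$per_patient,
                       mean(total[included])),
    top_dsi = utils::head(object$top_dsi, n),
    top_ndsi = utils::head(object$top_ndsi, n),
    thresholds = object$thresholds
  )
  class(s) <- "summary.driver_strength"
  s
}

#' @export
print.summary.driver_strength <- function(x, ...) {
  cat("Driver strength summary\n")
  cat(sprintf("  QC-passed patients: %d; mean driver events per evaluable patient: %.2f\n",
              x$n_patients, x$mean_events))
  nz <- which(x$p_i > 0)
  if (length(nz) > 0L) {
    cat("  stratum sizes p_i (nonzero): ",
        paste(sprintf("p_%d=%d", nz, x$p_i[nz]), collapse = ", "), "\n")
  }
  cat("  Top by DSI:\n")
  print(x$top_dsi, row.names = FALSE)
  cat("  Top by NDSI:\n")
  print(x$top_ndsi, row.names = FALSE)
  invisible(x)
}

#' Extract the driver index table from a fit
#'
#' @param object a `"driver_strength"` fit.
#' @param ranked return the merged, filtered ranking instead of the raw
#'   per entity-class table.
#' @param index which index to rank by when `ranked = TRUE`.
#' @param ... passed to [rank_and_filter()] when `ranked = TRUE`.
#' @return data.frame of index records or a ranked list.
#' @export
coef.driver_strength <- function(object, ranked = FALSE,
                                 index = c("ndsi", "dsi", "count"), ...) {
  if (!ranked) return(object$index)
  rank_and_filter(object$index, match.arg(index), ...)
}

#' Barchart of the top-ranked driver entities
#'
#' @param x a `"driver_strength"` fit.
#' @param index `"ndsi"`, `"dsi"` or `"count"`.
#' @param n bars to draw.
#' @param min_patients reporting filter (defaults to the fit's own).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.driver_strength <- function(x, index = c("ndsi", "dsi", "count"),
                                 n = 10L, min_patients = NULL, ...) {
  index <- match.arg(index)
  if (is.null(min_patients)) min_patients <- x$thresholds$min_patients
  ranked <- rank_and_filter(x$index, index, min_patients = min_patients,
                            ndsi_floor = x$thresholds$ndsi_floor,
                            top_n = n)
  if (nrow(ranked) == 0L) {
    stop("plot.driver_strength: nothing passes the reporting filters",
         call. = FALSE)
  }
  graphics::barplot(rev(ranked$value), names.arg = rev(ranked$entity),
                    horiz = TRUE, las = 1,
                    xlab = toupper(index),
                    main = sprintf("Top %d driver entities by %s",
                                   nrow(ranked), toupper(index)), ...)
  invisible(ranked)
}

#' Derive chromosome statuses from arm statuses
#'
#' Optional helper for inputs without a chromosome-level table: a
#' chromosome is assigned the shared sign of its arms when all of them
#' are nonzero with equal sign, and 0 otherwise.
#'
#' @param arms patient x arm status matrix.
#' @param arm_map arm-to-chromosome map, see [default_arm_map()].
#' @return patient x chromosome status matrix.
#' @export
derive_chromosome_status <- function(arms, arm_map = default_arm_map()) {
  chroms <- unique(arm_map$chromosome)
  out <- matrix(0L, nrow(arms), length(chroms),
                dimnames = list(rownames(arms), chroms))
  for (ch in chroms) {
    members <- arm_map$arm[arm_map$chromosome == ch]
    members <- intersect(members, colnames(arms))
    if (length(members) == 0L) next
    sub <- arms[, members, drop = FALSE]
    sgn <- sign(sub)
    same <- apply(sgn, 1L, function(v) {
      if (any(is.na(v)) || any(v == 0)) 0L else if (all(v == v[1L])) v[1L] else 0L
    })
    out[, ch] <- as.integer(same)
  }
  out
}
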