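# Independent brute-force oracles. These deliberately avoid the package's
# grouped-count code paths: everything is computed by direct per-patient
# iteration over the event table, straight from the index definitions.

# Per entity-class DSI/NDSI by explicit loops over patients and strata.
oracle_indices <- function(events, i_max = 100L) {
  patients <- unique(events$barcode)
  totals <- vapply(patients, function(b) sum(events$barcode == b), 0L)
  included <- patients[totals >= 1L & totals <= i_max]

  p_i <- vapply(seq_len(i_max), function(i) {
    sum(vapply(included, function(b) totals[[b]] == i, TRUE))
  }, 0L)

  keys <- unique(paste(events$entity, events$event_class, sep = "\r"))
  rows <- lapply(keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    carriers <- events$barcode[events$entity == parts[1L] &
                                 events$event_class == parts[2L]]
    carriers <- intersect(carriers, included)
    dsi_sum <- 0; occ_sum <- 0; n <- 0L
    for (i in seq_len(i_max)) {
      p_Ai <- sum(vapply(carriers, function(b) totals[[b]] == i, TRUE))
      n <- n + p_Ai
      if (p_i[i] > 0L) {
        dsi_sum <- dsi_sum + p_Ai / (i * p_i[i])
        occ_sum <- occ_sum + p_Ai / p_i[i]
      }
    }
    data.frame(entity = parts[1L], event_class = parts[2L],
               n_patients = n, dsi = dsi_sum,
               ndsi = if (occ_sum > 0) dsi_sum / occ_sum else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$entity, out$event_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Benjamini-Hochberg by checking every candidate k explicitly.
oracle_bh <- function(pvalues, fdr = 0.05) {
  if (is.null(names(pvalues))) names(pvalues) <- as.character(seq_along(pvalues))
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0L) return(character())
  m <- length(p)
  ps <- sort(p)
  best_k <- 0L
  for (k in seq_len(m)) {
    if (ps[[k]] <= k * fdr / m) best_k <- k
  }
  if (best_k == 0L) return(character())
  names(ps)[seq_len(best_k)]
}

# Random unit-event cohort for oracle-equivalence and invariance checks:
# every patient draws a number of events over a small entity universe.
random_event_table <- function(n_patients, n_entities = 8L,
                               max_events = 6L) {
  classes <- c("SNA_oncogene", "SNA_suppressor", "CNA_oncogene", "DAG")
  entities <- c(as.character(1000L + seq_len(n_entities - 1L)), "8q")
  ent_class <- setNames(sample(classes, n_entities, replace = TRUE), entities)
  rows <- list()
  for (p in seq_len(n_patients)) {
    k <- sample.int(max_events, 1L)
    ents <- sample(entities, min(k, n_entities))
    rows[[p]] <- data.frame(
      barcode = sprintf("PT%03d", p),
      entity = ents,
      event_class = unname(ent_class[ents]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
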