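#' Assemble per patient-gene alteration states
#'
#' Joins the consensus patient-gene pairs with the patient-level SNA
#' counts, the gene-level HISR, and the validated CNA status. Pairs with
#' no SNA match get zero counts; genes absent from the gene-level summary
#' get a missing HISR; pairs with no CNA match get status 0.
#'
#' @param pairs consensus pairs (`barcode`, `entrez`), see
#'   [consensus_filter()].
#' @param sna_counts per patient-gene counts from
#'   [patient_gene_sna_counts()].
#' @param gene_summary gene-level table from [snadrif_summary()]
#'   (`entrez`, `hisr`).
#' @param cna validated CNA matrix (genes x patients).
#' @return data.frame: `barcode`, `entrez`, `n_hyper`, `n_inact`,
#'   `n_nonsyn`, `hisr`, `cna`.
#' @export
patient_gene_states <- function(pairs, sna_counts, gene_summary, cna) {
  idx <- match(paste(pairs$barcode, pairs$entrez),
               paste(sna_counts$barcode, sna_counts$entrez))
  n_hyper <- ifelse(is.na(idx), 0L, sna_counts$n_hyper[idx])
  n_inact <- ifelse(is.na(idx), 0L, sna_counts$n_inact[idx])
  hisr_v <- gene_summary$hisr[match(pairs$entrez, gene_summary$entrez)]
  cna_v <- rep(0L, nrow(pairs))
  gi <- match(as.character(pairs$entrez), rownames(cna))
  pi_ <- match(pairs$barcode, colnames(cna))
  ok <- !is.na(gi) & !is.na(pi_)
  cna_v[ok] <- cna[cbind(gi[ok], pi_[ok])]
  cna_v[is.na(cna_v)] <- 0L
  data.frame(
    barcode = pairs$barcode,
    entrez = as.integer(pairs$entrez),
    n_hyper = as.integer(n_hyper),
    n_inact = as.integer(n_inact),
    n_nonsyn = as.integer(n_hyper + n_inact),
    hisr = as.numeric(hisr_v),
    cna = as.integer(cna_v),
    stringsAsFactors = FALSE
  )
}

#' Classify patient-gene states into driver event classes
#'
#' Applies the rule table that assigns each patient-gene alteration state
#' to one of six driver classes (each counted as one unit event), to
#' "passenger" (no alteration at all) or to "low_probability" (every
#' remaining combination, counted as zero). The number of nonsynonymous
#' SNAs is the sum of the hyperactivating and inactivating counts; a gene
#' with HISR above 5 is treated as oncogene-like, at or below 5 as
#' suppressor-like. A missing HISR with any nonzero evidence yields
#' "low_probability"; with no evidence at all, "passenger".
#'
#' @param states data.frame from [patient_gene_states()] (columns
#'   `n_nonsyn`, `n_inact`, `hisr`, `cna`; other columns carried through).
#' @param hisr_cutoff oncogene/suppressor boundary on HISR (default 5).
#' @return `states` with columns `event_class` and `count` (0/1) added.
#' @export
classify_events <- function(states, hisr_cutoff = 5) {
  n_nonsyn <- states$n_nonsyn
  n_inact <- states$n_inact
  h <- states$hisr
  cna <- states$cna
  amp <- cna %in% c(1L, 2L)
  del <- cna %in% c(-1L, -2L)
  onc <- !is.na(h) & h > hisr_cutoff
  sup <- !is.na(h) & h <= hisr_cutoff

  cls <- rep("low_probability", nrow(states))
  cls[n_nonsyn >= 1 & n_inact == 0 & onc & cna == 0] <- "SNA_oncogene"
  cls[n_nonsyn == 0 & onc & amp]                     <- "CNA_oncogene"
  cls[n_nonsyn >= 1 & n_inact == 0 & onc & amp]      <- "mixed_oncogene"
  cls[n_nonsyn >= 1 & sup & cna == 0]                <- "SNA_suppressor"
  cls[n_nonsyn == 0 & sup & del]                     <- "CNA_suppressor"
  cls[n_nonsyn >= 1 & sup & del]                     <- "mixed_suppressor"
  cls[n_nonsyn == 0 & cna == 0]                      <- "passenger"

  states$event_class <- cls
  states$count <- as.integer(!cls %in% c("passenger", "low_probability"))
  states
}

#' Gene-level driver events from classified states
#'
#' @param classified output of [classify_events()].
#' @return data.frame of unit events: `barcode`, `entity` (Entrez ID as
#'   character), `event_class`.
#' @export
gene_events <- function(classified) {
  keep <- classified$count == 1L
  data.frame(
    barcode = classified$barcode[keep],
    entity = as.character(classified$entrez[keep]),
    event_class = classified$event_class[keep],
    stringsAsFactors = FALSE
  )
}

#' Per-patient driver event totals and the cohort stratum counts
#'
#' Sums each patient's unit events across genes, chromosome arms and
#' whole chromosomes, and tabulates `p_i`, the number of patients with
#' exactly `i` driver events, for `i` from 1 to `i_max`. Patients with no
#' events, or with more than `i_max`, are excluded from the strata (and
#' from all index calculations).
#'
#' @param events data.frame of unit events (`barcode`, `entity`,
#'   `event_class`) combining gene and aneuploidy events; rows must be
#'   unique per (patient, entity).
#' @param i_max largest total considered (default 100).
#' @return list with `per_patient` (data.frame `barcode`, `total`,
#'   `included`) and `p_i` (integer vector of length `i_max`, index = i).
#' @export
total_events <- function(events, i_max = 100L) {
  if (nrow(events) > 0L &&
      anyDuplicated(paste(events$barcode, events$entity))) {
    stop("total_events: duplicated (patient, entity) events", call. = FALSE)
  }
  totals <- table(events$barcode)
  per_patient <- data.frame(
    barcode = names(totals),
    total = as.integer(totals),
    stringsAsFactors = FALSE
  )
  per_patient$included <- per_patient$total >= 1L & per_patient$total <= i_max
  p_i <- integer(i_max)
  inc <- per_patient[per_patient$included, , drop = FALSE]
  tab <- table(factor(inc$total, levels = seq_len(i_max)))
  p_i[] <- as.integer(tab)
  list(per_patient = per_patient, p_i = p_i)
}

#' Driver Strength Index
#'
#' `DSI_A = sum_i p_Ai / (i * p_i)`, where `p_Ai` counts the patients
#' carrying event A among the patients with `i` driver events in total and
#' `p_i` counts all patients with `i` driver events. Occurrences in
#' driver-sparse patients are weighted up by the factor `1/i`.
#'
#' @param p_A numeric vector of `p_Ai` counts, index position = i (padded
#'   with zeros up to the length of `p_i`).
#' @param p_i numeric vector of stratum sizes, index position = i.
#' @return the index value (0 for an all-zero `p_A`).
#' @export
dsi <- function(p_A, p_i) {
  p_A <- .pad_counts(p_A, length(p_i))
  if (any(p_A > p_i)) {
    stop("dsi: p_Ai exceeds p_i in stratum ",
         paste(which(p_A > p_i), collapse = ", "), call. = FALSE)
  }
  i <- seq_along(p_i)
  keep <- p_i > 0
  sum(p_A[keep] / (i[keep] * p_i[keep]))
}

#' Normalized Driver Strength Index
#'
#' `NDSI_A = [sum_i p_Ai / (i * p_i)] / [sum_i p_Ai / p_i]`: the DSI
#' divided by the unweighted occupancy sum, which cancels the gene's
#' overall alteration frequency. Lies in `[1/i_max, 1]` whenever defined;
#' equal to `1/k` when all of A's events fall in the stratum `i = k`.
#'
#' @inheritParams dsi
#' @return the normalized index, or `NA` when `p_A` is all zero (the
#'   entity then carries no events and is excluded from ranking).
#' @export
ndsi <- function(p_A, p_i) {
  p_A <- .pad_counts(p_A, length(p_i))
  if (sum(p_A) == 0) return(NA_real_)
  keep <- p_i > 0
  denom <- sum(p_A[keep] / p_i[keep])
  dsi(p_A, p_i) / denom
}

.pad_counts <- function(p_A, n) {
  if (!is.null(names(p_A))) {
    full <- numeric(n)
    idx <- as.integer(names(p_A))
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > n)) {
      stop("stratum names must be integers in 1..", n, call. = FALSE)
    }
    full[idx] <- p_A
    return(full)
  }
  length(p_A) <- n
  p_A[is.na(p_A)] <- 0
  p_A
}

#' Per entity-class index records
#'
#' Computes, for every (entity, event class) combination present in the
#' events, its stratum profile `p_Ai`, patient count, DSI and NDSI,
#' against the cohort strata from [total_events()]. Patients outside the
#' 1..`i_max` range contribute to neither `p_i` nor any `p_Ai`.
#'
#' @param events combined unit-event table (`barcode`, `entity`,
#'   `event_class`).
#' @param totals result of [total_events()] on the same events.
#' @return data.frame: `entity`, `event_class`, `n_patients`, `dsi`,
#'   `ndsi`, `p_A` (list column of named stratum counts).
#' @export
compute_indices <- function(events, totals) {
  i_max <- length(totals$p_i)
  pp <- totals$per_patient
  tot_of <- pp$total[match(events$barcode, pp$barcode)]
  inc <- pp$included[match(events$barcode, pp$barcode)]
  ev <- events[inc, , drop = FALSE]
  tot_of <- tot_of[inc]
  if (nrow(ev) == 0L) {
    return(data.frame(entity = character(), event_class = character(),
                      n_patients = integer(), dsi = numeric(),
                      ndsi = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(ev$entity, ev$event_class, sep = "\r")
  groups <- split(tot_of, key)
  rec <- lapply(names(groups), function(k) {
    is <- groups[[k]]
    p_A <- integer(i_max)
    tab <- table(factor(is, levels = seq_len(i_max)))
    p_A[] <- as.integer(tab)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(entity = parts[1L], event_class = parts[2L],
               n_patients = sum(p_A),
               dsi = dsi(p_A, totals$p_i),
               ndsi = ndsi(p_A, totals$p_i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  p_As <- lapply(names(groups), function(k) {
    is <- groups[[k]]
    tab <- table(factor(is, levels = seq_len(i_max)))
    v <- as.integer(tab)
    names(v) <- seq_len(i_max)
    v[v > 0L]
  })
  out$p_A <- p_As
  out <- out[order(out$entity, out$event_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank driver entities and apply the reporting filters
#'
#' Drops entity-class records seen in fewer than `min_patients` patients,
#' merges entities appearing in several classes by keeping the class with
#' the higher index (ties broken by higher patient count, then by entity
#' identifier), additionally drops NDSI values below `ndsi_floor` when
#' ranking by NDSI, sorts descending and returns the head of the list.
#'
#' @param index_table output of [compute_indices()].
#' @param index `"ndsi"`, `"dsi"` or `"count"` (patient count).
#' @param min_patients minimum patients per entity-class record
#'   (default 10).
#' @param ndsi_floor minimum NDSI retained in NDSI rankings
#'   (default 0.05).
#' @param top_n list length (default 50).
#' @param genes_only drop chromosome arms and whole chromosomes (applied
#'   after merging, for handover to gene-only downstream tools).
#' @return ranked data.frame with a `rank` column and the index in
#'   `value`.
#' @export
rank_and_filter <- function(index_table, index = c("ndsi", "dsi", "count"),
                            min_patients = 10L, ndsi_floor = 0.05,
                            top_n = 50L, genes_only = FALSE) {
  index <- match.arg(index)
  tab <- index_table[index_table$n_patients >= min_patients, , drop = FALSE]
  if (nrow(tab) == 0L) {
    return(data.frame(rank = integer(), entity = character(),
                      event_class = character(), n_patients = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  tab$value <- switch(index,
    ndsi = tab$ndsi,
    dsi = tab$dsi,
    count = as.numeric(tab$n_patients)
  )
  tab <- tab[!is.na(tab$value), , drop = FALSE]

  # deterministic order before de-duplication: best value, then larger
  # patient count, then entity id ascending
  suppressWarnings(ent_num <- as.numeric(tab$entity))
  ent_key <- ifelse(is.na(ent_num), Inf, ent_num)
  ord <- order(-tab$value, -tab$n_patients, ent_key, tab$entity)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$entity), , drop = FALSE]

  if (index == "ndsi") {
    tab <- tab[tab$value >= ndsi_floor, , drop = FALSE]
  }
  if (genes_only) {
    tab <- tab[grepl("^[0-9]+$", tab$entity), , drop = FALSE]
  }
  tab <- utils::head(tab, top_n)
  out <- data.frame(rank = seq_len(nrow(tab)),
                    entity = tab$entity,
                    event_class = tab$event_class,
                    n_patients = tab$n_patients,
                    value = tab$value,
                    stringsAsFactors = FALSE)
  out
}

#' Stratified driver event counts
#'
#' Counts unit events per event class and entity within patient groups
#' defined by a clinical variable: cancer type, stage, age group (by
#' decade), sex, or the patient's total driver event count.
#'
#' @param events combined unit-event table.
#' @param patients clinical table with `barcode`, `cancer_type` and the
#'   optional `stage`, `age`, `sex` columns.
#' @param grouping one of `"cancer_type"`, `"stage"`, `"age_group"`,
#'   `"sex"`, `"total_events"`.
#' @param totals result of [total_events()]; required for
#'   `grouping = "total_events"`.
#' @param age_breaks decade bins by default.
#' @return data.frame: `group`, `event_class`, `entity`, `n_patients`.
#' @export
stratified_counts <- function(events, patients,
                              grouping = c("cancer_type", "stage",
                                           "age_group", "sex",
                                           "total_events"),
                              totals = NULL,
                              age_breaks = seq(0, 120, by = 10)) {
  grouping <- match.arg(grouping)
  grp <- switch(grouping,
    cancer_type = patients$cancer_type[match(events$barcode, patients$barcode)],
    stage = patients$stage[match(events$barcode, patients$barcode)],
    sex = patients$sex[match(events$barcode, patients$barcode)],
    age_group = {
      if (!"age" %in% names(patients)) {
        stop("stratified_counts: clinical table has no 'age' column",
             call. = FALSE)
      }
      age <- patients$age[match(events$barcode, patients$barcode)]
      as.character(cut(age, breaks = age_breaks, right = FALSE))
    },
    total_events = {
      if (is.null(totals)) {
        stop("stratified_counts: totals required for grouping by total events",
             call. = FALSE)
      }
      pp <- totals$per_patient
      as.character(pp$total[match(events$barcode, pp$barcode)])
    }
  )
  if (grouping %in% c("stage", "sex") && !grouping %in% names(patients)) {
    stop("stratified_counts: clinical table has no '", grouping, "' column",
         call. = FALSE)
  }
  keep <- !is.na(grp)
  ev <- events[keep, , drop = FALSE]
  grp <- grp[keep]
  if (nrow(ev) == 0L) {
    return(data.frame(group = character(), event_class = character(),
                      entity = character(), n_patients = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(grp, ev$event_class, ev$entity, sep = "\r")
  n <- table(key)
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  out <- data.frame(
    group = vapply(parts, `[`, "", 1L),
    event_class = vapply(parts, `[`, "", 2L),
    entity = vapply(parts, `[`, "", 3L),
    n_patients = as.integer(n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$group, out$event_class, -out$n_patients, out$entity), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top events per class within stratified counts
#'
#' @param counts output of [stratified_counts()].
#' @param n list length per (group, class), and per group overall
#'   (default 10).
#' @return data.frame in the shape of `counts` plus a `scope` column
#'   (`"class"` rows are per event class, `"overall"` rows pool classes).
#' @export
top_events <- function(counts, n = 10L) {
  if (nrow(counts) == 0L) {
    out <- counts
    out$scope <- character(0)
    return(out)
  }
  per_class <- do.call(rbind, lapply(
    split(counts, paste(counts$group, counts$event_class, sep = "\r")),
    function(d) utils::head(d[order(-d$n_patients, d$entity), , drop = FALSE], n)
  ))
  per_class$scope <- "class"
  overall <- do.call(rbind, lapply(split(counts, counts$group), function(d) {
    agg <- stats::aggregate(n_patients ~ group + entity, data = d, sum)
    agg$event_class <- "all"
    utils::head(agg[order(-agg$n_patients, agg$entity),
                    c("group", "event_class", "entity", "n_patients")], n)
  }))
  overall$scope <- "overall"
  out <- rbind(per_class, overall)
  rownames(out) <- NULL
  out
}
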