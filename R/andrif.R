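#' Bootstrap null distribution of mean alteration status
#'
#' Draws `length(statuses)` values with replacement from `statuses`,
#' records their mean, and repeats `B` times. For cohort-level aneuploidy
#' calling the supplied statuses are the pooled arm (or chromosome)
#' statuses of one cancer type, so the resulting distribution of means is
#' the exchangeable null against which each individual arm's observed mean
#' is compared.
#'
#' @param statuses integer vector with values in \{-1, 0, 1\} (missing
#'   entries must be dropped by the caller).
#' @param B number of bootstrap replicates (default 10000).
#' @param n number of statuses drawn per replicate; defaults to
#'   `length(statuses)`. Cohort calling sets this to the number of
#'   patients so the null mean has the sampling variance of one arm.
#' @return list with `replicate_means` (length `B`), `median_mean`, `B`
#'   and `n`.
#' @export
bootstrap_null <- function(statuses, B = 10000L, n = length(statuses)) {
  statuses <- statuses[!is.na(statuses)]
  if (length(statuses) == 0L) {
    stop("bootstrap_null: empty status vector", call. = FALSE)
  }
  if (!all(statuses %in% c(-1L, 0L, 1L))) {
    stop("bootstrap_null: statuses must be in {-1, 0, 1}", call. = FALSE)
  }
  if (B < 1L) stop("bootstrap_null: B must be >= 1", call. = FALSE)
  draws <- matrix(sample(statuses, n * B, replace = TRUE), nrow = B)
  means <- rowMeans(draws)
  list(replicate_means = means,
       median_mean = stats::median(means),
       B = as.integer(B),
       n = as.integer(n))
}

#' One-sided bootstrap p-value for an observed mean status
#'
#' An arm (or chromosome) qualifies for testing only when its observed
#' mean is nonzero and lies beyond the median of the bootstrap means on
#' the same side. The exceedance count is divided by `B/2`, as the calling
#' convention prescribes, and capped at 1.
#'
#' @param observed_mean observed mean alteration status of the entity.
#' @param null a list from [bootstrap_null()].
#' @return p-value in `[0, 1]`, or `NA` when the entity does not qualify.
#' @export
status_pvalue <- function(observed_mean, null) {
  if (is.na(observed_mean)) return(NA_real_)
  reps <- null$replicate_means
  if (observed_mean > 0 && observed_mean > null$median_mean) {
    p <- sum(reps > observed_mean) / (null$B / 2)
  } else if (observed_mean < 0 && observed_mean < null$median_mean) {
    p <- sum(reps < observed_mean) / (null$B / 2)
  } else {
    return(NA_real_)
  }
  min(p, 1)
}

#' Benjamini-Hochberg step-up selection
#'
#' Standard BH: sort the p-values ascending, find the largest k with
#' `p_(k) <= k * fdr / m`, and select everything up to and including k.
#' Entries with `NA` p-values are never selected and do not count towards
#' m (they were never tested).
#'
#' @param pvalues named numeric vector of p-values in `[0, 1]`.
#' @param fdr target false discovery rate (default 0.05).
#' @return character vector of selected names (possibly empty).
#' @export
bh_select <- function(pvalues, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  if (is.null(names(pvalues))) {
    names(pvalues) <- as.character(seq_along(pvalues))
  }
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0L) return(character())
  if (any(p < 0 | p > 1)) stop("bh_select: p-values outside [0, 1]", call. = FALSE)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  passing <- which(ps <= seq_len(m) * fdr / m)
  if (length(passing) == 0L) return(character())
  k <- max(passing)
  names(ps)[seq_len(k)]
}

#' Default chromosome-arm to chromosome map
#'
#' The 39 autosomal arms scored in TCGA-style aneuploidy tables: both arms
#' of chromosomes 1-12 and 16-20, and only the q arm of the acrocentric
#' chromosomes 13, 14, 15, 21 and 22.
#'
#' @return data.frame with columns `arm` and `chromosome`.
#' @export
default_arm_map <- function() {
  acro <- c(13L, 14L, 15L, 21L, 22L)
  chroms <- 1:22
  arms <- unlist(lapply(chroms, function(ch) {
    if (ch %in% acro) paste0(ch, "q") else paste0(ch, c("p", "q"))
  }))
  data.frame(arm = arms,
             chromosome = as.character(sub("[pq]$", "", arms)),
             stringsAsFactors = FALSE)
}

#' Cohort-level aneuploidy driver calls (ANDRIF)
#'
#' For each cancer type, pools all non-missing statuses of the table into
#' one bootstrap null (means of resamples of patient-count size), computes
#' each entity's observed mean status and its one-sided bootstrap p-value,
#' and applies Benjamini-Hochberg selection at the given FDR within the
#' cancer type. Selected entities are labelled by the sign of their mean:
#' gains and losses at the arm level ("DAG"/"DAL") or the chromosome level
#' ("DCG"/"DCL").
#'
#' @param status_table integer patients x entities matrix with entries in
#'   \{-1, 0, 1\} or `NA` (rownames barcodes, colnames arm or chromosome
#'   labels).
#' @param patients data.frame giving `barcode` and `cancer_type` for the
#'   rows of `status_table`; rows of the matrix without a match are
#'   ignored.
#' @param level `"arm"` or `"chromosome"`, which only controls the label
#'   vocabulary.
#' @param B bootstrap replicates (default 10000).
#' @param fdr Benjamini-Hochberg FDR (default 0.05).
#' @return data.frame with one row per entity x cancer type: `entity`,
#'   `cancer_type`, `mean_status`, `p_value`, `label` (`NA` when not
#'   called).
#' @export
andrif_calls <- function(status_table, patients, level = c("arm", "chromosome"),
                         B = 10000L, fdr = 0.05) {
  level <- match.arg(level)
  labels <- if (level == "arm") c(gain = "DAG", loss = "DAL")
            else c(gain = "DCG", loss = "DCL")
  ct <- patients$cancer_type[match(rownames(status_table), patients$barcode)]
  keep <- !is.na(ct)
  status_table <- status_table[keep, , drop = FALSE]
  ct <- ct[keep]

  res <- list()
  for (type in sort(unique(ct))) {
    sub <- status_table[ct == type, , drop = FALSE]
    pooled <- as.integer(sub[!is.na(sub)])
    if (length(pooled) == 0L) {
      stop("andrif_calls: no ", level, " statuses for cancer type ", type,
           call. = FALSE)
    }
    null <- bootstrap_null(pooled, B = B, n = nrow(sub))
    means <- colMeans(sub, na.rm = TRUE)
    pv <- vapply(means, status_pvalue, numeric(1), null = null)
    selected <- bh_select(pv, fdr = fdr)
    lab <- rep(NA_character_, length(means))
    names(lab) <- names(means)
    lab[selected] <- ifelse(means[selected] > 0, labels[["gain"]],
                            labels[["loss"]])
    res[[type]] <- data.frame(
      entity = names(means),
      cancer_type = type,
      mean_status = as.numeric(means),
      p_value = as.numeric(pv),
      label = lab,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Patient-level aneuploidy driver events
#'
#' Instantiates cohort-level calls in individual patients: a patient gains
#' a DAL event on an arm when their own status there is -1 and the arm is
#' cohort-labelled DAL for their cancer type (and symmetrically for gains
#' and for chromosomes). A driver chromosome call overrides its arms: a
#' patient with a DCG or DCL event on a chromosome contributes no arm
#' events on that chromosome, preventing the same aneuploidy from being
#' counted up to three times.
#'
#' @param arm_table,chrom_table patient x entity status matrices (the
#'   chromosome table may be `NULL`).
#' @param arm_calls,chrom_calls call tables from [andrif_calls()].
#' @param patients data.frame with `barcode` and `cancer_type`.
#' @param arm_map arm-to-chromosome map, see [default_arm_map()].
#' @return data.frame of unit events: `barcode`, `entity`, `event_class`
#'   (one of DAG/DAL/DCG/DCL).
#' @export
aneuploidy_events <- function(arm_table, arm_calls, patients,
                              chrom_table = NULL, chrom_calls = NULL,
                              arm_map = default_arm_map()) {
  unknown <- setdiff(colnames(arm_table), arm_map$arm)
  if (length(unknown) > 0L) {
    stop("aneuploidy_events: arm(s) missing from arm map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  match_events <- function(tab, calls, gain_lab, loss_lab) {
    if (is.null(tab) || is.null(calls)) {
      return(data.frame(barcode = character(), entity = character(),
                        event_class = character(), stringsAsFactors = FALSE))
    }
    ct <- patients$cancer_type[match(rownames(tab), patients$barcode)]
    rows <- list()
    called <- calls[!is.na(calls$label), , drop = FALSE]
    for (i in seq_len(nrow(called))) {
      ent <- called$entity[i]
      if (!ent %in% colnames(tab)) next
      want <- if (called$label[i] %in% c(gain_lab)) 1L else -1L
      hit <- which(!is.na(tab[, ent]) & tab[, ent] == want &
                     !is.na(ct) & ct == called$cancer_type[i])
      if (length(hit) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          barcode = rownames(tab)[hit],
          entity = ent,
          event_class = called$label[i],
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(barcode = character(), entity = character(),
                        event_class = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, rows)
  }

  chrom_events <- match_events(chrom_table, chrom_calls, "DCG", "DCL")
  arm_events <- match_events(arm_table, arm_calls, "DAG", "DAL")

  if (nrow(chrom_events) > 0L && nrow(arm_events) > 0L) {
    arm_chrom <- arm_map$chromosome[match(arm_events$entity, arm_map$arm)]
    overridden <- paste(arm_events$barcode, arm_chrom) %in%
      paste(chrom_events$barcode, chrom_events$entity)
    arm_events <- arm_events[!overridden, , drop = FALSE]
  }

  out <- rbind(chrom_events, arm_events)
  out <- out[order(out$barcode, out$entity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
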