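#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

.sim_classes <- c("SNA_oncogene", "CNA_oncogene", "mixed_oncogene",
                  "SNA_suppressor", "CNA_suppressor", "mixed_suppressor")

#' Synthetic TCGA-like cohort with plantable driver-strength structure
#'
#' Emits a complete input bundle (clinical/QC table, MAF-like SNA table,
#' CNA and expression matrices, arm and chromosome status tables, and two
#' mock gene-level driver-source lists) in which every driver event is
#' placed by construction: each patient receives a target total driver
#' event count, planted genes receive events only in patients whose target
#' total lies inside the gene's configured stratum, and the remaining
#' slots are filled with filler driver genes. A separate small reference
#' cohort (code `"NREF"`, never present in the source lists) hosts the
#' mutations that define each driver gene's hyperactivating-to-
#' inactivating ratio and satisfy the 10-SNA precision filter without
#' creating driver events. Both mock source lists contain every planted
#' and filler gene, so all placed events survive the two-source consensus.
#'
#' Event realisation per class: SNA-based oncogene events are one missense
#' mutation; SNA-based suppressor events one nonsense mutation; CNA-based
#' events a +/-2 raw copy-number call whose expression is shifted
#' multiplicatively (x1.5 gains, x0.5 losses) so expression validation
#' confirms them; mixed events combine the two. An optional planted arm
#' gains status +1 (or -1 for losses) exactly in its designated carriers,
#' which makes the cohort-level call decisive at any bootstrap size.
#'
#' @param n_patients number of patients in the main cohort.
#' @param cancer_type cohort code of the main cohort.
#' @param total_range candidate target totals per patient (sampled
#'   uniformly).
#' @param planted optional data.frame with columns `entrez`, `symbol`,
#'   `class` (one of the six driver classes), `n_carriers`, `stratum_min`,
#'   `stratum_max`: each gene's events are placed only in patients whose
#'   target total lies in `[stratum_min, stratum_max]`.
#' @param arm_plant optional list `list(arm =, direction = +1 or -1,
#'   n_carriers =)`; carriers spend one of their event slots on the arm.
#' @param arm_noise when `TRUE`, non-planted arm and chromosome statuses
#'   are drawn i.i.d. uniform on \{-1, 0, 1\} (the calibration null);
#'   when `FALSE` (default) they are 0 so realised totals are exact.
#' @param n_donors patients in the HISR reference cohort.
#' @param n_background non-driver genes carrying background passenger
#'   mutations.
#' @param background_rate per patient-gene probability of a background
#'   silent mutation.
#' @param expr_noise_sd standard deviation of the log-normal expression
#'   noise (0 gives noiseless expression).
#' @param n_qc_fail extra patients violating one QC criterion each
#'   (exercise for the sample filter; they carry no planted structure).
#' @param max_gene_frac cap on the fraction of patients carrying any one
#'   filler gene (keeps planted CNAs from moving the expression median).
#' @param seed integer seed; the bundle is a pure function of the
#'   arguments and this seed.
#' @return list with the input tables (`clinical`, `sna`, `cna`,
#'   `expression`, `arms`, `chromosomes`, `sources`) and `truth`
#'   (intended per-patient totals, per-gene classes and carriers, the arm
#'   plant).
#' @export
generate_cohort <- function(n_patients = 60L,
                            cancer_type = "SIMA",
                            total_range = 1:6,
                            planted = NULL,
                            arm_plant = NULL,
                            arm_noise = FALSE,
                            n_donors = 6L,
                            n_background = 5L,
                            background_rate = 0.05,
                            expr_noise_sd = 0.05,
                            n_qc_fail = 2L,
                            max_gene_frac = 0.4,
                            seed = 1L) {
  if (!is.null(planted)) {
    stopifnot(all(planted$class %in% .sim_classes),
              all(planted$n_carriers >= 1L))
  }
  with_seed(seed, {
    barcodes <- sprintf("%s-%04d", cancer_type, seq_len(n_patients))
    donors <- sprintf("NREF-%04d", seq_len(n_donors))

    target <- sample(rep_len(total_range, n_patients))
    names(target) <- barcodes
    remaining <- target

    # event ledger: one row per intended unit event
    ev_barcode <- character(); ev_gene <- integer(); ev_class <- character()
    place <- function(gene, class, carriers) {
      ev_barcode <<- c(ev_barcode, carriers)
      ev_gene <<- c(ev_gene, rep(gene, length(carriers)))
      ev_class <<- c(ev_class, rep(class, length(carriers)))
      remaining[carriers] <<- remaining[carriers] - 1L
    }

    arm_carriers <- character()
    if (!is.null(arm_plant)) {
      eligible <- names(remaining)[remaining > 0L]
      if (length(eligible) < arm_plant$n_carriers) {
        stop("generate_cohort: not enough free event slots for the arm plant",
             call. = FALSE)
      }
      arm_carriers <- sample(eligible, arm_plant$n_carriers)
      remaining[arm_carriers] <- remaining[arm_carriers] - 1L
    }

    gene_class <- character()  # named by entrez
    gene_symbol <- character()
    if (!is.null(planted)) {
      for (k in seq_len(nrow(planted))) {
        g <- planted$entrez[k]
        eligible <- names(target)[target >= planted$stratum_min[k] &
                                  target <= planted$stratum_max[k] &
                                  remaining > 0L]
        if (length(eligible) < planted$n_carriers[k]) {
          stop("generate_cohort: stratum [", planted$stratum_min[k], ",",
               planted$stratum_max[k], "] cannot host ",
               planted$n_carriers[k], " carriers of gene ", g,
               call. = FALSE)
        }
        place(g, planted$class[k], sample(eligible, planted$n_carriers[k]))
        gene_class[as.character(g)] <- planted$class[k]
        gene_symbol[as.character(g)] <- planted$symbol[k]
      }
    }

    # filler driver genes soak up the remaining slots
    filler_cap <- max(1L, floor(max_gene_frac * (n_patients + n_donors)))
    next_gene <- 900000L
    cls_cycle <- 0L
    while (any(remaining > 0L)) {
      open <- names(remaining)[remaining > 0L]
      carriers <- sample(open, min(filler_cap, length(open)))
      g <- next_gene; next_gene <- next_gene + 1L
      cls_cycle <- cls_cycle + 1L
      cls <- .sim_classes[1L + (cls_cycle - 1L) %% length(.sim_classes)]
      place(g, cls, carriers)
      gene_class[as.character(g)] <- cls
      gene_symbol[as.character(g)] <- paste0("FILL", g - 900000L + 1L)
    }

    driver_genes <- as.integer(names(gene_class))
    onc_like <- gene_class %in% c("SNA_oncogene", "CNA_oncogene",
                                  "mixed_oncogene")
    names(onc_like) <- names(gene_class)

    # --- SNA records -----------------------------------------------------
    sna_rows <- list()
    add_sna <- function(barcode, entrez, vclass, ct) {
      sna_rows[[length(sna_rows) + 1L]] <<- data.frame(
        barcode = barcode, entrez = entrez,
        symbol = gene_symbol[as.character(entrez)],
        transcript = sprintf("ENST%08d", entrez),
        variant_class = vclass,
        substitution = sprintf("c.%d%s", 100L + entrez %% 1000L,
                               ifelse(vclass == "Missense_Mutation",
                                      "A>G", "C>T")),
        cancer_type = ct, stringsAsFactors = FALSE)
    }

    # donor cohort fixes each driver gene's HISR and the 10-SNA filter
    for (g in driver_genes) {
      gc <- as.character(g)
      if (onc_like[gc]) {
        for (j in 1:12) add_sna(donors[1L + (j - 1L) %% n_donors], g,
                                "Missense_Mutation", "NREF")
      } else {
        for (j in 1:6) add_sna(donors[1L + (j - 1L) %% n_donors], g,
                               "Missense_Mutation", "NREF")
        for (j in 1:6) add_sna(donors[1L + (j - 1L) %% n_donors], g,
                               "Nonsense_Mutation", "NREF")
      }
    }

    # patient-level event realisation
    sna_classes <- c(SNA_oncogene = "Missense_Mutation",
                     mixed_oncogene = "Missense_Mutation",
                     SNA_suppressor = "Nonsense_Mutation",
                     mixed_suppressor = "Nonsense_Mutation")
    cna_value <- c(CNA_oncogene = 2L, mixed_oncogene = 2L,
                   CNA_suppressor = -2L, mixed_suppressor = -2L)
    expr_mult <- c(CNA_oncogene = 1.5, mixed_oncogene = 1.5,
                   CNA_suppressor = 0.5, mixed_suppressor = 0.5)

    all_genes <- c(driver_genes,
                   if (n_background > 0L) 800000L + seq_len(n_background))
    for (bg in setdiff(all_genes, driver_genes)) {
      gene_symbol[as.character(bg)] <- paste0("BG", bg - 800000L)
      gene_class[as.character(bg)] <- "background"
    }
    all_patients <- c(barcodes, donors)

    cna <- matrix(0L, length(all_genes), length(all_patients),
                  dimnames = list(as.character(all_genes), all_patients))
    shift <- matrix(1, length(all_genes), length(all_patients),
                    dimnames = dimnames(cna))

    for (r in seq_along(ev_barcode)) {
      cls <- ev_class[r]; g <- as.character(ev_gene[r]); b <- ev_barcode[r]
      if (cls %in% names(sna_classes)) {
        add_sna(b, ev_gene[r], sna_classes[[cls]], cancer_type)
      }
      if (cls %in% names(cna_value)) {
        cna[g, b] <- cna_value[[cls]]
        shift[g, b] <- expr_mult[[cls]]
      }
    }

    # background passenger mutations on non-driver genes
    for (bg in setdiff(all_genes, driver_genes)) {
      hit <- barcodes[stats::runif(n_patients) < background_rate]
      for (b in hit) add_sna(b, bg, "Silent", cancer_type)
      # keep background genes past the 10-SNA filter irrelevant: they are
      # in no source list, so they can never form pairs
    }

    sna <- do.call(rbind, sna_rows)
    rownames(sna) <- NULL

    # --- expression ------------------------------------------------------
    base_median <- stats::runif(length(all_genes), 100, 5000)
    noise <- if (expr_noise_sd > 0) {
      matrix(exp(stats::rnorm(length(all_genes) * length(all_patients),
                              0, expr_noise_sd)),
             length(all_genes), length(all_patients))
    } else {
      matrix(1, length(all_genes), length(all_patients))
    }
    expression <- base_median * noise * shift
    dimnames(expression) <- dimnames(cna)

    # --- aneuploidy tables ----------------------------------------------
    arm_map <- default_arm_map()
    arms <- matrix(0L, length(all_patients), nrow(arm_map),
                   dimnames = list(all_patients, arm_map$arm))
    chroms <- matrix(0L, length(all_patients), 22L,
                     dimnames = list(all_patients, as.character(1:22)))
    if (arm_noise) {
      arms[seq_len(n_patients), ] <-
        sample(c(-1L, 0L, 1L), n_patients * ncol(arms), replace = TRUE)
      chroms[seq_len(n_patients), ] <-
        sample(c(-1L, 0L, 1L), n_patients * ncol(chroms), replace = TRUE)
    }
    if (!is.null(arm_plant)) {
      arms[, arm_plant$arm] <- 0L
      arms[arm_carriers, arm_plant$arm] <- as.integer(arm_plant$direction)
    }

    # --- clinical --------------------------------------------------------
    clin <- data.frame(
      barcode = all_patients,
      cancer_type = c(rep(cancer_type, n_patients), rep("NREF", n_donors)),
      histology = "Primary Tumor",
      low_quality = FALSE,
      cancer_dna_fraction = round(stats::runif(length(all_patients), 0.6, 1), 3),
      subclonal_fraction = round(stats::runif(length(all_patients), 0, 0.4), 3),
      sex = sample(c("male", "female"), length(all_patients), replace = TRUE),
      age = sample(30:85, length(all_patients), replace = TRUE),
      stage = sample(c("I", "II", "III", "IV"), length(all_patients),
                     replace = TRUE),
      has_sna = TRUE, has_cna = TRUE, has_aneuploidy = TRUE,
      stringsAsFactors = FALSE
    )
    if (n_qc_fail > 0L) {
      fail <- data.frame(
        barcode = sprintf("%s-F%03d", cancer_type, seq_len(n_qc_fail)),
        cancer_type = cancer_type,
        histology = "Primary Tumor",
        low_quality = FALSE,
        cancer_dna_fraction = 0.9,
        subclonal_fraction = 0.1,
        sex = "female", age = 60L, stage = "II",
        has_sna = TRUE, has_cna = TRUE, has_aneuploidy = TRUE,
        stringsAsFactors = FALSE
      )
      flaw <- rep_len(c("purity", "subclonal", "quality"), n_qc_fail)
      fail$cancer_dna_fraction[flaw == "purity"] <- 0.3
      fail$subclonal_fraction[flaw == "subclonal"] <- 0.7
      fail$low_quality[flaw == "quality"] <- TRUE
      clin <- rbind(clin, fail)
    }

    # --- mock driver sources --------------------------------------------
    src_tab <- if (length(driver_genes) > 0L) {
      data.frame(entrez = driver_genes,
                 symbol = gene_symbol[as.character(driver_genes)],
                 cancer_type = cancer_type,
                 q_value = 0.01,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(entrez = integer(), symbol = character(),
                 cancer_type = character(), q_value = numeric(),
                 stringsAsFactors = FALSE)
    }
    sources <- list(
      driver_source("mockA", src_tab, kind = "gene"),
      driver_source("mockB", src_tab, kind = "gene")
    )

    truth <- list(
      target_totals = target,
      events = data.frame(barcode = ev_barcode, entrez = ev_gene,
                          event_class = ev_class, stringsAsFactors = FALSE),
      gene_class = gene_class[as.character(driver_genes)],
      arm_plant = arm_plant,
      arm_carriers = arm_carriers,
      cancer_type = cancer_type
    )

    list(clinical = clin, sna = sna, cna = cna, expression = expression,
         arms = arms, chromosomes = chroms, sources = sources, truth = truth)
  })
}

#' Null cohort for aneuploidy calibration
#'
#' A bundle with no planted driver structure at all: arm and chromosome
#' statuses i.i.d. uniform on \{-1, 0, 1\}, no planted genes, empty source
#' lists (so the consensus table and the index table are empty by
#' construction).
#'
#' @inheritParams generate_cohort
#' @return bundle as in [generate_cohort()].
#' @export
null_cohort <- function(n_patients = 30L, cancer_type = "NULLC", seed = 1L,
                        n_background = 3L) {
  bundle <- generate_cohort(
    n_patients = n_patients, cancer_type = cancer_type,
    total_range = 0L, planted = NULL, arm_plant = NULL, arm_noise = TRUE,
    n_background = n_background, n_qc_fail = 0L, seed = seed
  )
  empty <- data.frame(entrez = integer(), symbol = character(),
                      cancer_type = character(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  bundle$sources <- list(driver_source("mockA", empty, kind = "gene"),
                         driver_source("mockB", empty, kind = "gene"))
  bundle
}

#' Simulated patient x arm status table for aneuploidy calibration
#'
#' Draws every arm status i.i.d. uniform on \{-1, 0, 1\} and optionally
#' biases one arm so that its mean status equals `effect`: the gain and
#' loss probabilities become `1/3 + effect/2` and `1/3 - effect/2`
#' (negative effects bias towards losses). Used for false-call and power
#' calibration of the bootstrap aneuploidy caller.
#'
#' @param n_patients cohort size.
#' @param cancer_type cohort code.
#' @param bias_arm arm label to bias, or `NULL` for a pure null table.
#' @param effect target mean status of the biased arm, in `[-2/3, 2/3]`.
#' @param seed integer seed.
#' @return list with `arms` (matrix) and `patients` (clinical stub with
#'   `barcode`, `cancer_type`).
#' @export
simulate_arm_table <- function(n_patients = 30L, cancer_type = "SIM1",
                               bias_arm = NULL, effect = 0, seed = 1L) {
  stopifnot(abs(effect) <= 2 / 3)
  with_seed(seed, {
    arm_map <- default_arm_map()
    barcodes <- sprintf("%s-%04d", cancer_type, seq_len(n_patients))
    arms <- matrix(sample(c(-1L, 0L, 1L), n_patients * nrow(arm_map),
                          replace = TRUE),
                   n_patients, nrow(arm_map),
                   dimnames = list(barcodes, arm_map$arm))
    if (!is.null(bias_arm)) {
      p_gain <- 1 / 3 + effect / 2
      p_loss <- 1 / 3 - effect / 2
      arms[, bias_arm] <- sample(c(1L, -1L, 0L), n_patients, replace = TRUE,
                                 prob = c(p_gain, p_loss, 1 - p_gain - p_loss))
    }
    list(arms = arms,
         patients = data.frame(barcode = barcodes,
                               cancer_type = cancer_type,
                               stringsAsFactors = FALSE))
  })
}

#' Deterministic 18-patient worked example
#'
#' A fixed miniature bundle: one cohort of 12 evaluable patients plus a
#' 4-patient HISR reference cohort and 2 QC-failing patients; six genes
#' covering all six driver event classes and one planted 8q arm gain.
#' Expression is noiseless, so copy-number validation and the bootstrap
#' call are exact at any replicate count. The returned `expected` table
#' carries the DSI/NDSI values for every entity, derived by direct
#' per-patient summation of the index definitions.
#'
#' @return list: the bundle fields of [generate_cohort()] plus
#'   `expected` (entity, event_class, n_patients, dsi, ndsi).
#' @export
worked_example <- function() {
  ct <- "SIMA"
  main <- sprintf("P%02d", 1:12)
  donors <- sprintf("D%02d", 1:4)
  barcodes <- c(paste0(ct, "-", main), paste0("NREF-", donors))

  genes <- data.frame(
    entrez = c(101L, 102L, 103L, 104L, 105L, 106L),
    symbol = c("ONC1", "ONC2", "SUP1", "SUP2", "BG1", "MIXO1"),
    stringsAsFactors = FALSE
  )

  # patient x gene event plan (class determined by the gene)
  plan <- list(
    ONC1  = c("P01", "P02", "P03", "P06", "P09", "P11", "P12"),  # SNA_oncogene
    ONC2  = c("P05", "P08", "P09", "P11"),                       # CNA_oncogene
    SUP1  = c("P04", "P05", "P06", "P08", "P10", "P11", "P12"),  # SNA_suppressor
    SUP2  = c("P07", "P08", "P09", "P10", "P11"),                # mixed_suppressor
    MIXO1 = c("P07", "P09", "P10", "P11")                        # mixed_oncogene
  )
  arm_carriers <- c("P03", "P04", "P06", "P07", "P08", "P10")    # 8q gain

  full <- function(p) paste0(ct, "-", p)
  dfull <- function(p) paste0("NREF-", p)

  sna <- list()
  add <- function(barcode, entrez, symbol, vclass, ctype) {
    sna[[length(sna) + 1L]] <<- data.frame(
      barcode = barcode, entrez = entrez, symbol = symbol,
      transcript = sprintf("ENST%08d", entrez),
      variant_class = vclass,
      substitution = sprintf("c.%d%s", 100L + entrez,
                             ifelse(vclass == "Missense_Mutation", "A>G", "C>T")),
      cancer_type = ctype, stringsAsFactors = FALSE)
  }

  # donor SNAs: ONC1/ONC2/MIXO1 oncogene-like, SUP1/SUP2 suppressor-like
  for (g in c(101L, 102L, 106L)) {
    sym <- genes$symbol[genes$entrez == g]
    for (j in 1:10) add(dfull(donors[1L + (j - 1L) %% 4L]), g, sym,
                        "Missense_Mutation", "NREF")
  }
  for (g in c(103L, 104L)) {
    sym <- genes$symbol[genes$entrez == g]
    for (j in 1:5) add(dfull(donors[1L + (j - 1L) %% 4L]), g, sym,
                       "Missense_Mutation", "NREF")
    for (j in 1:5) add(dfull(donors[1L + (j - 1L) %% 4L]), g, sym,
                       "Nonsense_Mutation", "NREF")
  }
  # background gene BG1: 10 silent donor SNAs + one patient missense
  for (j in 1:10) add(dfull(donors[1L + (j - 1L) %% 4L]), 105L, "BG1",
                      "Silent", "NREF")
  add(full("P01"), 105L, "BG1", "Missense_Mutation", ct)

  # patient events
  for (p in plan$ONC1) add(full(p), 101L, "ONC1", "Missense_Mutation", ct)
  for (p in plan$SUP1) add(full(p), 103L, "SUP1", "Missense_Mutation", ct)
  for (p in plan$SUP2) add(full(p), 104L, "SUP2", "Nonsense_Mutation", ct)
  for (p in plan$MIXO1) add(full(p), 106L, "MIXO1", "Missense_Mutation", ct)
  sna <- do.call(rbind, sna)

  cna <- matrix(0L, 6L, length(barcodes),
                dimnames = list(as.character(genes$entrez), barcodes))
  shift <- matrix(1, 6L, length(barcodes), dimnames = dimnames(cna))
  for (p in plan$ONC2) { cna["102", full(p)] <- 2L; shift["102", full(p)] <- 1.5 }
  for (p in plan$MIXO1) { cna["106", full(p)] <- 1L; shift["106", full(p)] <- 1.5 }
  for (p in plan$SUP2) { cna["104", full(p)] <- -2L; shift["104", full(p)] <- 0.5 }
  # discordant call: raw amplification with flat expression must be zeroed
  cna["102", full("P02")] <- 1L

  base_median <- c(1000, 800, 1200, 600, 1500, 900)
  expression <- base_median * shift
  dimnames(expression) <- dimnames(cna)

  arm_map <- default_arm_map()
  arms <- matrix(0L, length(barcodes), nrow(arm_map),
                 dimnames = list(barcodes, arm_map$arm))
  arms[full(arm_carriers), "8q"] <- 1L
  chroms <- matrix(0L, length(barcodes), 22L,
                   dimnames = list(barcodes, as.character(1:22)))

  clin <- data.frame(
    barcode = c(barcodes, paste0(ct, "-Q01"), paste0(ct, "-Q02")),
    cancer_type = c(rep(ct, 12L), rep("NREF", 4L), ct, ct),
    histology = "Primary Tumor",
    low_quality = FALSE,
    cancer_dna_fraction = c(rep(0.8, 16L), 0.3, 0.9),
    subclonal_fraction = c(rep(0.1, 16L), 0.1, 0.7),
    sex = rep(c("male", "female"), 9L),
    age = rep(c(45L, 62L, 58L), 6L),
    stage = rep(c("I", "II", "III"), 6L),
    has_sna = TRUE, has_cna = TRUE, has_aneuploidy = TRUE,
    stringsAsFactors = FALSE
  )

  src_tab <- data.frame(
    entrez = c(101L, 102L, 103L, 104L, 106L),
    symbol = c("ONC1", "ONC2", "SUP1", "SUP2", "MIXO1"),
    cancer_type = ct, q_value = 0.01, stringsAsFactors = FALSE
  )
  sources <- list(driver_source("mockA", src_tab, kind = "gene"),
                  driver_source("mockB", src_tab, kind = "gene"))

  # strata: p_1 = 2 (P01 P02), p_2 = 4 (P03 P04 P05 P12), p_3 = 2 (P06 P07),
  # p_4 = 3 (P08 P09 P10), p_5 = 1 (P11); indices by direct summation
  expected <- data.frame(
    entity = c("101", "102", "103", "104", "106", "8q"),
    event_class = c("SNA_oncogene", "CNA_oncogene", "SNA_suppressor",
                    "mixed_suppressor", "mixed_oncogene", "DAG"),
    n_patients = c(7L, 4L, 7L, 5L, 4L, 6L),
    dsi = c(17 / 10, 59 / 120, 109 / 120, 37 / 60, 8 / 15, 3 / 4),
    ndsi = c(51 / 100, 59 / 230, 109 / 350, 37 / 150, 16 / 65, 9 / 26),
    stringsAsFactors = FALSE
  )

  truth <- list(
    target_totals = c(P01 = 1L, P02 = 1L, P03 = 2L, P04 = 2L, P05 = 2L,
                      P06 = 3L, P07 = 3L, P08 = 4L, P09 = 4L, P10 = 4L,
                      P11 = 5L, P12 = 2L),
    plan = plan, arm_carriers = arm_carriers, cancer_type = ct
  )
  names(truth$target_totals) <- full(names(truth$target_totals))

  list(clinical = clin, sna = sna, cna = cna, expression = expression,
       arms = arms, chromosomes = chroms, sources = sources,
       truth = truth, expected = expected)
}
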