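state_row <- function(n_hyper, n_inact, hisr, cna, barcode = "P1",
                      entrez = 1L) {
  data.frame(barcode = barcode, entrez = entrez,
             n_hyper = n_hyper, n_inact = n_inact,
             n_nonsyn = n_hyper + n_inact,
             hisr = hisr, cna = cna, stringsAsFactors = FALSE)
}

test_that("event classification follows the rule table", {
  cases <- list(
    list(state_row(2, 0, 7, 0),  "SNA_oncogene", 1L),
    list(state_row(0, 0, 7, 2),  "CNA_oncogene", 1L),
    list(state_row(1, 0, 7, 1),  "mixed_oncogene", 1L),
    list(state_row(1, 0, 3, 0),  "SNA_suppressor", 1L),
    list(state_row(1, 1, 3, 0),  "SNA_suppressor", 1L),  # inactivating allowed
    list(state_row(0, 0, 3, -2), "CNA_suppressor", 1L),
    list(state_row(1, 1, 3, -1), "mixed_suppressor", 1L),
    list(state_row(0, 0, 9, 0),  "passenger", 0L),
    list(state_row(0, 0, NA, 0), "passenger", 0L),
    # oncogene-like gene with a deletion: no rule row fits
    list(state_row(1, 0, 7, -1), "low_probability", 0L),
    # inactivating SNA in an oncogene-like gene
    list(state_row(1, 1, 7, 0),  "low_probability", 0L),
    # evidence but no HISR (gene failed the SNA filters)
    list(state_row(1, 0, NA, 0), "low_probability", 0L),
    list(state_row(0, 0, NA, 2), "low_probability", 0L),
    # HISR exactly 5 is suppressor-like
    list(state_row(1, 0, 5, 0),  "SNA_suppressor", 1L)
  )
  for (cs in cases) {
    out <- classify_events(cs[[1]])
    expect_equal(out$event_class, cs[[2]])
    expect_equal(out$count, cs[[3]])
  }
})

test_that("classification partitions the state space deterministically", {
  set.seed(31)
  states <- data.frame(
    barcode = "P1", entrez = 1L,
    n_hyper = sample(0:3, 500, TRUE),
    n_inact = sample(0:3, 500, TRUE),
    hisr = sample(c(NA, 0.4, 1, 5, 5.01, 12), 500, TRUE),
    cna = sample(-2:2, 500, TRUE),
    stringsAsFactors = FALSE
  )
  states$n_nonsyn <- states$n_hyper + states$n_inact
  out <- classify_events(states)
  valid <- c("SNA_oncogene", "CNA_oncogene", "mixed_oncogene",
             "SNA_suppressor", "CNA_suppressor", "mixed_suppressor",
             "passenger", "low_probability")
  expect_true(all(out$event_class %in% valid))
  expect_identical(out$count,
                   as.integer(!out$event_class %in%
                                c("passenger", "low_probability")))
  # pure function of the state: re-running yields the same classes
  expect_identical(classify_events(states)$event_class, out$event_class)
})

test_that("per-patient totals count unit events and respect the 1..100 range", {
  events <- rbind(
    data.frame(barcode = "A", entity = c("1", "2", "8q", "7"),
               event_class = c("SNA_oncogene", "CNA_suppressor", "DAL",
                               "DCG"), stringsAsFactors = FALSE),
    data.frame(barcode = "B", entity = as.character(1:101),
               event_class = "SNA_oncogene", stringsAsFactors = FALSE),
    data.frame(barcode = "C", entity = "1",
               event_class = "SNA_oncogene", stringsAsFactors = FALSE)
  )
  tot <- total_events(events)
  expect_equal(tot$per_patient$total[tot$per_patient$barcode == "A"], 4L)
  # B has 101 events: excluded from every stratum
  expect_false(tot$per_patient$included[tot$per_patient$barcode == "B"])
  expect_equal(tot$p_i[4], 1L)
  expect_equal(tot$p_i[1], 1L)
  expect_equal(sum(tot$p_i), 2L)

  expect_error(total_events(rbind(events, events[1, ])), "duplicated")
})

test_that("index formulas reproduce hand-computed values", {
  p <- c(10, 20, rep(0, 98))

  expect_equal(dsi(c("1" = 3, "2" = 2), p), 3 / 10 + 2 / 40)  # 0.35
  expect_equal(dsi(c("1" = 10), c(10, rep(0, 99))), 1.0)
  expect_equal(dsi(numeric(0), p), 0)

  expect_equal(ndsi(c("1" = 3, "2" = 2), p), 0.35 / 0.4)      # 0.875
  expect_true(is.na(ndsi(c("1" = 0), p)))

  # a gene confined to stratum i = 4 scores exactly 1/4
  p4 <- c(5, 5, 5, 8, rep(0, 96))
  expect_equal(ndsi(c("4" = 3), p4), 0.25)

  expect_error(dsi(c("1" = 11), c(10, rep(0, 99))), "exceeds")
})

test_that("grouped indices equal direct per-patient summation (oracle)", {
  set.seed(12)
  for (rep in 1:25) {
    events <- random_event_table(n_patients = sample(5:20, 1))
    got <- compute_indices(events, total_events(events))
    want <- oracle_indices(events)
    expect_equal(got$entity, want$entity)
    expect_equal(got$n_patients, want$n_patients)
    expect_equal(got$dsi, want$dsi, tolerance = 1e-14)
    expect_equal(got$ndsi, want$ndsi, tolerance = 1e-14)
  }
})

test_that("NDSI is frequency-invariant while DSI scales with frequency", {
  p <- c(10, 12, 6, 5, rep(0, 96))
  p_A <- c("1" = 2, "3" = 1, "4" = 1)
  base_dsi <- dsi(p_A, p)
  base_ndsi <- ndsi(p_A, p)
  for (c_ in c(2, 3, 5)) {
    expect_equal(dsi(p_A * c_, p * c_) , base_dsi)   # uniform replication
    expect_equal(ndsi(p_A * c_, p * c_), base_ndsi, tolerance = 1e-13)
    # c-fold carrier frequency within unchanged strata
    expect_equal(dsi(p_A * c_, p), c_ * base_dsi, tolerance = 1e-13)
    expect_equal(ndsi(p_A * c_, p), base_ndsi, tolerance = 1e-13)
  }
})

test_that("ranking filters, merges duplicates and breaks ties deterministically", {
  idx <- data.frame(
    entity = c("10", "10", "20", "30", "8q"),
    event_class = c("SNA_oncogene", "mixed_oncogene", "SNA_suppressor",
                    "CNA_oncogene", "DAG"),
    n_patients = c(15L, 12L, 9L, 30L, 25L),
    dsi = c(0.9, 0.8, 0.7, 0.2, 0.5),
    ndsi = c(0.3, 0.2, 0.6, 0.04, 0.25),
    stringsAsFactors = FALSE
  )
  ranked <- rank_and_filter(idx, "ndsi", min_patients = 10)
  # entity 20 dropped (9 patients); entity 10 keeps its higher-NDSI class;
  # entity 30 falls below the 0.05 NDSI floor
  expect_equal(ranked$entity, c("10", "8q"))
  expect_equal(ranked$event_class[1], "SNA_oncogene")
  expect_equal(ranked$value[1], 0.3)

  # DSI ranking has no floor: entity 30 reappears
  ranked_dsi <- rank_and_filter(idx, "dsi", min_patients = 10)
  expect_equal(ranked_dsi$entity, c("10", "8q", "30"))

  # arms/chromosomes removed when handing over to gene-only tools
  genes <- rank_and_filter(idx, "dsi", min_patients = 10, genes_only = TRUE)
  expect_false("8q" %in% genes$entity)

  # count ranking and index ranking can disagree: high-count entity 30
  # tops by count but is last by DSI
  by_count <- rank_and_filter(idx, "count", min_patients = 10)
  expect_equal(by_count$entity[1], "30")
  expect_equal(ranked_dsi$entity[3], "30")
})

test_that("stratified counts partition by group", {
  patients <- data.frame(
    barcode = c("A", "B", "C"),
    cancer_type = c("BRCA", "BRCA", "LUAD"),
    sex = c("female", "male", "female"),
    age = c(45L, 62L, 58L),
    stage = c("I", "II", "II"),
    stringsAsFactors = FALSE
  )
  events <- data.frame(
    barcode = c("A", "A", "B", "C"),
    entity = c("1", "8q", "1", "1"),
    event_class = c("SNA_oncogene", "DAG", "SNA_oncogene", "SNA_oncogene"),
    stringsAsFactors = FALSE
  )
  by_ct <- stratified_counts(events, patients, "cancer_type")
  g1 <- by_ct[by_ct$entity == "1" & by_ct$event_class == "SNA_oncogene", ]
  expect_equal(sum(g1$n_patients), 3L)
  expect_equal(g1$n_patients[g1$group == "BRCA"], 2L)

  # sex partition: male + female totals equal the overall total
  by_sex <- stratified_counts(events, patients, "sex")
  expect_equal(sum(by_sex$n_patients), nrow(events))

  by_age <- stratified_counts(events, patients, "age_group")
  expect_true(all(grepl("^\\[", by_age$group)))

  tot <- total_events(events)
  by_tot <- stratified_counts(events, patients, "total_events", totals = tot)
  expect_setequal(unique(by_tot$group), c("1", "2"))

  top <- top_events(by_ct, n = 1)
  expect_true(all(c("class", "overall") %in% top$scope))

  expect_error(stratified_counts(events, patients[, c("barcode", "cancer_type")],
                                 "age_group"), "age")
})
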