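planted_spec <- function() {
  data.frame(
    entrez = c(1001L, 1002L),
    symbol = c("STR1", "WEAK1"),
    class = c("SNA_oncogene", "SNA_suppressor"),
    n_carriers = c(6L, 6L),
    stratum_min = c(1L, 4L),
    stratum_max = c(2L, 6L),
    stringsAsFactors = FALSE
  )
}

test_that("the generator is deterministic given the seed", {
  b1 <- generate_cohort(n_patients = 30, planted = planted_spec(), seed = 4)
  b2 <- generate_cohort(n_patients = 30, planted = planted_spec(), seed = 4)
  expect_identical(b1, b2)
  b3 <- generate_cohort(n_patients = 30, planted = planted_spec(), seed = 5)
  expect_false(identical(b1$sna, b3$sna))
})

test_that("generated bundles pass validation and realize the intended totals", {
  b <- generate_cohort(n_patients = 40, total_range = 1:5,
                       planted = planted_spec(),
                       arm_plant = list(arm = "5q", direction = -1L,
                                        n_carriers = 9L),
                       seed = 8)
  expect_silent(validate_bundle(b))

  fit <- driver_strength(b, B = 1000, seed = 2)
  pp <- fit$totals$per_patient
  realized <- pp$total[match(names(b$truth$target_totals), pp$barcode)]
  realized[is.na(realized)] <- 0L
  expect_true(all(abs(realized - b$truth$target_totals) <= 1L))

  # the planted arm is called as a loss and lands in its carriers
  expect_equal(fit$arm_calls$label[fit$arm_calls$entity == "5q" &
                                     fit$arm_calls$cancer_type == "SIMA"],
               "DAL")
  dal <- fit$aneuploidy[fit$aneuploidy$entity == "5q", ]
  expect_setequal(dal$barcode, b$truth$arm_carriers)
})

test_that("strong-stratum planting bounds the NDSI from below", {
  b <- generate_cohort(n_patients = 40, total_range = 1:6,
                       planted = data.frame(
                         entrez = 1001L, symbol = "STR1",
                         class = "SNA_oncogene", n_carriers = 8L,
                         stratum_min = 1L, stratum_max = 3L,
                         stringsAsFactors = FALSE),
                       seed = 21)
  fit <- driver_strength(b, B = 500, seed = 3)
  strong <- fit$index[fit$index$entity == "1001", ]
  expect_equal(strong$n_patients, 8L)
  # every index term has i <= 3, so NDSI >= 1/3
  expect_gte(strong$ndsi, 1 / 3)
})

test_that("the generator refuses impossible plants", {
  expect_error(
    generate_cohort(n_patients = 10, total_range = 1L,
                    planted = data.frame(entrez = 1L, symbol = "X",
                                         class = "SNA_oncogene",
                                         n_carriers = 50L,
                                         stratum_min = 1L, stratum_max = 1L,
                                         stringsAsFactors = FALSE),
                    seed = 1),
    "stratum")
})

test_that("null cohorts carry no consensus structure and validate cleanly", {
  b <- null_cohort(n_patients = 20, seed = 17)
  expect_silent(validate_bundle(b))
  fit <- driver_strength(b, B = 500, seed = 9)
  expect_equal(nrow(fit$pairs), 0L)
  expect_equal(nrow(fit$index[grepl("^[0-9]+$", fit$index$entity), ]), 0L)
})

test_that("the worked example is internally consistent with the oracle", {
  wx <- worked_example()
  expect_silent(validate_bundle(wx))
  # recompute the expected table from the fixture's own event plan with the
  # independent per-patient oracle
  plan <- wx$truth$plan
  gene_of <- c(ONC1 = "101", ONC2 = "102", SUP1 = "103", SUP2 = "104",
               MIXO1 = "106")
  class_of <- c(ONC1 = "SNA_oncogene", ONC2 = "CNA_oncogene",
                SUP1 = "SNA_suppressor", SUP2 = "mixed_suppressor",
                MIXO1 = "mixed_oncogene")
  rows <- lapply(names(plan), function(g) {
    data.frame(barcode = paste0("SIMA-", plan[[g]]),
               entity = gene_of[[g]], event_class = class_of[[g]],
               stringsAsFactors = FALSE)
  })
  rows[[length(rows) + 1L]] <- data.frame(
    barcode = paste0("SIMA-", wx$truth$arm_carriers),
    entity = "8q", event_class = "DAG", stringsAsFactors = FALSE)
  events <- do.call(rbind, rows)
  want <- oracle_indices(events)
  got <- merge(wx$expected, want, by = c("entity", "event_class"))
  expect_equal(nrow(got), nrow(wx$expected))
  expect_equal(got$dsi.x, got$dsi.y, tolerance = 1e-14)
  expect_equal(got$ndsi.x, got$ndsi.y, tolerance = 1e-14)
})
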