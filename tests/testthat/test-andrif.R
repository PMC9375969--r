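test_that("bootstrap null handles degenerate and small inputs correctly", {
  set.seed(1)
  all0 <- bootstrap_null(rep(0L, 10), B = 50)
  expect_true(all(all0$replicate_means == 0))
  expect_equal(all0$median_mean, 0)

  all1 <- bootstrap_null(rep(1L, 10), B = 50)
  expect_true(all(all1$replicate_means == 1))
  expect_equal(all1$median_mean, 1)

  expect_error(bootstrap_null(integer()), "empty")
  expect_error(bootstrap_null(c(0L, 2L)), "-1, 0, 1")
})

test_that("bootstrap replicate means match exhaustive enumeration for n = 3", {
  # all 27 equiprobable draws from {1, 0, -1}: the mean takes values
  # k/3 for k in -3..3 with multinomial weights
  draws <- expand.grid(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(-1, 0, 1))
  exact <- table(factor(rowMeans(draws), levels = seq(-1, 1, by = 1 / 3))) / 27

  set.seed(99)
  null <- bootstrap_null(c(1L, 0L, -1L), B = 30000)
  got <- table(factor(round(null$replicate_means, 10),
                      levels = round(seq(-1, 1, by = 1 / 3), 10))) / null$B
  expect_lt(max(abs(as.numeric(got) - as.numeric(exact))), 0.01)
})

test_that("status p-values follow the exceedance-over-half-B rule", {
  # constructed nulls: 10,000 replicate means with median 0 and a known
  # number of exceedances beyond the observed mean
  reps <- c(rep(0, 9880), rep(0.7, 120))
  null <- list(replicate_means = reps, median_mean = 0, B = 10000L)
  expect_equal(status_pvalue(0.6, null), 120 / 5000)  # = 0.024

  reps2 <- c(rep(-0.6, 40), rep(0, 9960))
  null2 <- list(replicate_means = reps2, median_mean = 0, B = 10000L)
  expect_equal(status_pvalue(-0.5, null2), 40 / 5000)  # = 0.008

  # observed mean not beyond the median on its side -> no test
  degen <- list(replicate_means = rep(1, 100), median_mean = 1, B = 100L)
  expect_true(is.na(status_pvalue(1, degen)))
  expect_true(is.na(status_pvalue(0, null)))

  # cap at 1
  lop <- list(replicate_means = rep(0.5, 100), median_mean = 0, B = 100L)
  expect_equal(status_pvalue(0.4, lop), 1)
})

test_that("BH selection matches hand-worked cases", {
  p <- c(a = 0.001, b = 0.02, c = 0.04, d = 0.9)
  expect_setequal(bh_select(p, 0.05), c("a", "b"))
  expect_equal(bh_select(c(x = 1, y = 1, z = 1), 0.05), character())
  expect_equal(bh_select(c(only = 0.04), 0.05), "only")
})

test_that("BH selection agrees with brute force and p.adjust on random vectors", {
  set.seed(7)
  for (rep in 1:1000) {
    m <- sample.int(25, 1L)
    p <- round(runif(m), 3)
    names(p) <- paste0("e", seq_len(m))
    fdr <- sample(c(0.01, 0.05, 0.1), 1L)
    got <- sort(bh_select(p, fdr))
    expect_identical(got, sort(oracle_bh(p, fdr)))
    # independent cross-check through the standard adjusted-p route
    adj <- sort(names(p)[stats::p.adjust(p, "BH") <= fdr])
    expect_identical(got, adj)
  }
})

test_that("cohort calls are deterministic given the seed and label by sign", {
  sim <- simulate_arm_table(60, bias_arm = "8q", effect = 0.5, seed = 5)
  set.seed(11)
  calls1 <- andrif_calls(sim$arms, sim$patients, "arm", B = 1000)
  set.seed(11)
  calls2 <- andrif_calls(sim$arms, sim$patients, "arm", B = 1000)
  expect_identical(calls1, calls2)
  expect_equal(calls1$label[calls1$entity == "8q"], "DAG")
  # labels only where called, and match the sign of the mean
  called <- calls1[!is.na(calls1$label), ]
  expect_true(all((called$label == "DAG") == (called$mean_status > 0)))
})

test_that("patient events require matching sign and obey chromosome override", {
  patients <- data.frame(barcode = c("P1", "P2", "P3"),
                         cancer_type = "LUAD", stringsAsFactors = FALSE)
  arms <- matrix(c(-1L, 1L, -1L,   # 8p
                   0L, 0L, 1L,     # 7p
                   0L, 0L, 1L),    # 7q
                 nrow = 3,
                 dimnames = list(c("P1", "P2", "P3"), c("8p", "7p", "7q")))
  chroms <- matrix(c(0L, 0L, 1L), nrow = 3,
                   dimnames = list(c("P1", "P2", "P3"), "7"))
  arm_calls <- data.frame(entity = c("8p", "7p", "7q"), cancer_type = "LUAD",
                          mean_status = c(-0.6, 0.5, 0.5), p_value = 0.001,
                          label = c("DAL", "DAG", "DAG"),
                          stringsAsFactors = FALSE)
  chrom_calls <- data.frame(entity = "7", cancer_type = "LUAD",
                            mean_status = 0.5, p_value = 0.001,
                            label = "DCG", stringsAsFactors = FALSE)
  ev <- aneuploidy_events(arms, arm_calls, patients,
                          chrom_table = chroms, chrom_calls = chrom_calls)

  # P1: 8p status -1 on a DAL arm -> one DAL event; P2: +1 on a DAL arm -> none
  expect_equal(ev$event_class[ev$barcode == "P1"], "DAL")
  expect_false("P2" %in% ev$barcode)
  # P3 has the DCG on chromosome 7: its 7p/7q arm events are overridden
  p3 <- ev[ev$barcode == "P3", ]
  expect_setequal(p3$entity, c("7", "8p"))
  expect_setequal(p3$event_class, c("DCG", "DAL"))
  # at most one event per chromosome per patient
  arm_map <- default_arm_map()
  chrom_of <- ifelse(ev$entity %in% arm_map$arm,
                     arm_map$chromosome[match(ev$entity, arm_map$arm)],
                     ev$entity)
  expect_false(anyDuplicated(paste(ev$barcode, chrom_of)) > 0)

  expect_error(
    aneuploidy_events(matrix(0L, 1, 1, dimnames = list("P1", "99z")),
                      arm_calls, patients),
    "arm map")
})
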