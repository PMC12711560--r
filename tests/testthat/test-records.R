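test_that("reclassification merges labels and conserves individuals", {
  raw <- data.frame(
    locality_id = c("L1", "L1", "L1", "L2"),
    year = 2000L,
    taxon_id = c("Mazama americana", "Mazama nemorivaga", "red brocket",
                 "red brocket"),
    n_individuals = c(3L, 2L, 4L, 5L),
    stringsAsFactors = FALSE)
  mapping <- data.frame(
    from = c("Mazama americana", "Mazama nemorivaga", "red brocket"),
    to = c("Mazama americana", "Mazama nemorivaga", "Mazama americana"),
    stringsAsFactors = FALSE)
  out <- apply_reclassification(raw, mapping)
  expect_equal(sum(out$n_individuals), sum(raw$n_individuals))
  # vernacular merged into the binomial
  l1 <- out[out$locality_id == "L1" & out$taxon_id == "Mazama americana", ]
  expect_equal(l1$n_individuals, 7L)
  expect_equal(nrow(out[out$locality_id == "L1", ]), 2L)

  expect_error(
    apply_reclassification(raw, mapping[-3, ]),
    "unmapped labels.*red brocket")
})

test_that("many-to-few label mapping yields registry taxa plus undetermined", {
  set.seed(9)
  n_raw <- 60L
  raw_labels <- sprintf("species_%02d", seq_len(n_raw))
  to <- c(sample(sprintf("taxon_%02d", 1:14), n_raw - 5L, replace = TRUE),
          rep(UNDETERMINED, 5L))
  mapping <- data.frame(from = raw_labels, to = to, stringsAsFactors = FALSE)
  raw <- data.frame(locality_id = "L1", year = 2010L, taxon_id = raw_labels,
                    n_individuals = rep(2L, n_raw), stringsAsFactors = FALSE)
  out <- apply_reclassification(raw, mapping)
  expect_setequal(unique(out$taxon_id), unique(to))
  expect_equal(sum(out$n_individuals), 2L * n_raw)
})

test_that("study filters apply the taxa-count and effort rules separately", {
  records <- data.frame(
    locality_id = rep(c("A", "B", "C"), c(3L, 5L, 4L)),
    year = 2005L,
    taxon_id = c(paste0("t", 1:3), paste0("t", 1:5), paste0("t", 1:4)),
    n_individuals = 1L, stringsAsFactors = FALSE)
  efforts <- data.frame(locality_id = c("A", "C"),
                        n_hunters = c(5L, 4L), span_days = c(100L, 50L),
                        stringsAsFactors = FALSE)
  f <- filter_studies(records, efforts)
  # A has 3 taxa: dropped from both sets
  expect_false("A" %in% f$tsop_records$locality_id)
  expect_false("A" %in% f$hhr_records$locality_id)
  # B has 5 taxa but no effort row: composition only
  expect_true("B" %in% f$tsop_records$locality_id)
  expect_false("B" %in% f$hhr_records$locality_id)
  # C has both
  expect_true("C" %in% f$tsop_records$locality_id)
  expect_true("C" %in% f$hhr_records$locality_id)

  # when every locality passes, the two sets share locality coverage
  efforts_all <- data.frame(locality_id = c("B", "C"), n_hunters = 2L,
                            span_days = 30L, stringsAsFactors = FALSE)
  f2 <- filter_studies(records[records$locality_id != "A", ], efforts_all)
  expect_setequal(unique(f2$tsop_records$locality_id),
                  unique(f2$hhr_records$locality_id))
})

test_that("HHR is kills per hunter-day including zero-harvest effort", {
  records <- data.frame(locality_id = "L1", year = 2000L, taxon_id = "t1",
                        n_individuals = 100L, stringsAsFactors = FALSE)
  efforts <- data.frame(locality_id = c("L1", "L2"),
                        n_hunters = c(5L, 3L), span_days = c(100L, 10L),
                        stringsAsFactors = FALSE)
  h <- compute_hhr(records, efforts)
  expect_equal(h$hhr[h$locality_id == "L1"], 0.2)
  # effort but no kills: rate 0, not dropped
  expect_equal(h$hhr[h$locality_id == "L2"], 0)

  # invariance to splitting an effort row at constant total hunter-days
  split_eff <- data.frame(locality_id = c("L1", "L1", "L2"),
                          n_hunters = c(5L, 5L, 3L),
                          span_days = c(60L, 40L, 10L),
                          stringsAsFactors = FALSE)
  h2 <- compute_hhr(records, split_eff)
  expect_equal(h2$hhr, h$hhr)

  bad <- data.frame(locality_id = "L1", n_hunters = 0L, span_days = 50L)
  expect_error(compute_hhr(records, bad), "zero hunter-days")
})

test_that("HHR recovers a known Poisson harvest rate", {
  # 100 localities harvesting at a common true rate 0.07
  set.seed(31)
  n <- 100L
  hunters <- sample(5:20, n, replace = TRUE)
  days <- sample(50:200, n, replace = TRUE)
  lam <- 0.07 * hunters * days
  kills <- rpois(n, lam)
  ids <- sprintf("L%03d", seq_len(n))
  records <- data.frame(locality_id = ids, year = 2000L, taxon_id = "t1",
                        n_individuals = kills, stringsAsFactors = FALSE)
  efforts <- data.frame(locality_id = ids, n_hunters = hunters,
                        span_days = days, stringsAsFactors = FALSE)
  h <- compute_hhr(records, efforts)
  pooled <- sum(h$n_individuals) / sum(h$hunter_days)
  se <- sqrt(sum(lam)) / sum(hunters * days)
  expect_lt(abs(pooled - 0.07), 3 * se)
})

test_that("TSOP vectors are probability vectors matching the counts", {
  records <- data.frame(locality_id = c("L1", "L1", "L2"),
                        year = 2000L,
                        taxon_id = c("A", "B", "A"),
                        n_individuals = c(30L, 10L, 7L),
                        stringsAsFactors = FALSE)
  ts <- compute_tsop(records)
  expect_equal(unname(ts["L1", c("A", "B")]), c(0.75, 0.25))
  expect_equal(unname(ts["L2", "A"]), 1)
  expect_equal(unname(rowSums(ts)), c(1, 1))

  zero <- data.frame(locality_id = "L1", year = 2000L, taxon_id = "A",
                     n_individuals = 0L, stringsAsFactors = FALSE)
  expect_error(compute_tsop(zero), "zero total")
})

test_that("TSOP concentrates around multinomial proportions", {
  set.seed(17)
  counts <- as.vector(rmultinom(1, 10000L, c(0.5, 0.3, 0.2)))
  records <- data.frame(locality_id = "L1", year = 2000L,
                        taxon_id = c("a", "b", "c"),
                        n_individuals = counts, stringsAsFactors = FALSE)
  ts <- compute_tsop(records)
  expect_true(all(abs(ts["L1", c("a", "b", "c")] - c(0.5, 0.3, 0.2)) < 0.02))
})

test_that("hunter-to-consumer ratio summarises data or falls back", {
  r <- hunter_consumer_ratio(data.frame(n_hunters = c(1, 2, 3),
                                        n_consumers = c(10, 10, 10)))
  expect_equal(r$q50, 0.2)

  d <- hunter_consumer_ratio()
  expect_equal(d$q50, 0.178)
  expect_equal(c(d$q10, d$q25, d$q75, d$q90), c(0.168, 0.173, 0.183, 0.187))

  # binomial localities at the published ratio recover the median
  set.seed(72)
  consumers <- sample(50:400, 72L, replace = TRUE)
  comm <- data.frame(n_hunters = rbinom(72L, consumers, 0.178),
                     n_consumers = consumers)
  rb <- hunter_consumer_ratio(comm)
  expect_lt(abs(rb$q50 - 0.178), 0.02)

  expect_warning(
    hunter_consumer_ratio(data.frame(n_hunters = c(1, 5),
                                     n_consumers = c(10, 0))),
    "zero consumers")
})
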