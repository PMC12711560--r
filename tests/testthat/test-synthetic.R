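test_that("generation is bit-identical under a repeated seed", {
  a <- generate_landscape(landscape_config(seed = 4L))
  b <- generate_landscape(landscape_config(seed = 4L))
  expect_identical(a$stack, b$stack)
  expect_identical(a$population, b$population)
  expect_identical(a$urban, b$urban)

  s1 <- tiny_study(seed = 8L)
  s2 <- tiny_study(seed = 8L)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$efforts, s2$efforts)
  expect_identical(s1$ground_truth$true_hp, s2$ground_truth$true_hp)
})

test_that("landscape configuration switches behave as documented", {
  cfg0 <- landscape_config(urban_fraction = 0, seed = 2L)
  l0 <- generate_landscape(cfg0)
  expect_false(any(l0$urban))

  nodef <- generate_landscape(landscape_config(deforestation_max = 0,
                                               seed = 2L))
  hl <- grid_values(nodef$stack$habitat_loss)
  expect_true(all(hl[!is.na(hl)] == 0))

  expect_error(landscape_config(n_rows = 3), "configuration error")
  expect_error(landscape_config(urban_fraction = 1), "configuration error")
})

test_that("taxon traits follow the configured distributions", {
  land <- generate_landscape(landscape_config(seed = 5L))
  tx <- generate_taxa(12L, land, seed = 7L)
  expect_equal(nrow(tx$traits), 12L)
  expect_true(all(tx$traits$body_mass_mean > 0))
  dens <- tx$traits$density_mean
  expect_true(all(dens[!is.na(dens)] > 0))

  # degenerate mass range pins every mass
  tx1 <- generate_taxa(5L, land, seed = 7L, mass_range = c(1, 1))
  expect_true(all(tx1$traits$body_mass_mean == 1))

  # log-mass spread matches sigma within 15% at large n
  tx5 <- generate_taxa(500L, land, seed = 3L, mass_sdlog = 2.2,
                       range_fraction = c(0.2, 0.4))
  emp <- sd(log(tx5$traits$body_mass_mean))
  expect_lt(abs(emp - 2.2) / 2.2, 0.15)

  # every range covers at least 10% of in-boundary cells and is non-empty
  inb <- sum(land$boundary)
  cover <- vapply(tx$ranges, function(r) sum(r & land$boundary), integer(1L))
  expect_true(all(cover >= 0.1 * inb))

  expect_error(generate_taxa(1L, land), "n_taxa")
})

test_that("communities sit on eligible cells with binomial hunters", {
  land <- generate_landscape(landscape_config(seed = 6L))
  cm <- generate_communities(land, 30L, true_hunter_ratio = 0, seed = 1L)
  expect_true(all(cm$n_hunters == 0))
  expect_true(all(land$boundary[cbind(cm$row, cm$col)]))
  expect_true(all(!land$urban[cbind(cm$row, cm$col)]))

  one <- generate_communities(land, 1L, seed = 2L)
  expect_equal(nrow(one), 1L)

  # pooled ratio concentrates near the configured value
  big <- generate_communities(land, 200L, true_hunter_ratio = 0.178,
                              seed = 3L, consumers_range = c(40L, 80L))
  pooled <- sum(big$n_hunters) / sum(big$n_consumers)
  expect_lt(abs(pooled - 0.178), 0.02)

  all_urban <- land
  all_urban$urban <- land$boundary
  expect_error(generate_communities(all_urban, 5L), "placement error")
})

test_that("record counts follow the Poisson harvest model", {
  land <- generate_landscape(landscape_config(n_rows = 12L, n_cols = 12L,
                                              urban_fraction = 0, seed = 9L))
  tx <- generate_taxa(4L, land, seed = 9L, range_fraction = c(0.9, 0.95))
  gt <- flat_truth(land, tx, rate = 0.1)

  # zero rate silences all localities
  gt0 <- gt
  gt0$true_hp$values[] <- ifelse(is.na(gt$true_hp$values), NA, 0)
  comm <- data.frame(locality_id = "L001",
                     row = which(land$boundary, arr.ind = TRUE)[1, 1],
                     col = which(land$boundary, arr.ind = TRUE)[1, 2],
                     n_consumers = 56L, n_hunters = 10L,
                     stringsAsFactors = FALSE)
  out0 <- generate_hunting_records(comm, land, tx, gt0, seed = 1L)
  expect_equal(nrow(out0$records), 0L)

  # mean total count over replicate seeds matches lambda = 0.1 * 10 * 100
  totals <- vapply(1:200, function(s) {
    out <- generate_hunting_records(comm, land, tx, gt, seed = s,
                                    span_range = c(100L, 100L),
                                    undetermined_prob = 0)
    sum(out$records$n_individuals)
  }, numeric(1L))
  lambda <- 100
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(totals) - lambda), 3 * se)
})

test_that("taxa never appear outside their range and TSOP truth sums to 1", {
  sim <- tiny_study(seed = 12L)
  land <- sim$landscape
  # support restriction: recorded taxa are in range at the locality cell
  for (i in seq_len(nrow(sim$records))) {
    tid <- sim$records$taxon_id[i]
    if (tid == UNDETERMINED) next
    loc <- sim$communities[sim$communities$locality_id ==
                             sim$records$locality_id[i], ]
    expect_true(sim$taxa$ranges[[tid]][loc$row, loc$col])
  }
  # ground-truth proportions sum to one wherever a taxon is in range
  tot <- apply(sim$ground_truth$true_tsop, c(1, 2), sum)
  covered <- tot > 0
  expect_true(all(abs(tot[covered] - 1) < 1e-9))
})

test_that("pooled harvest rate converges to the truth as effort grows", {
  land <- generate_landscape(landscape_config(n_rows = 16L, n_cols = 16L,
                                              urban_fraction = 0, seed = 14L))
  tx <- generate_taxa(4L, land, seed = 14L, range_fraction = c(0.8, 0.9))
  gt <- generate_ground_truth(land, tx, seed = 14L)
  comm <- generate_communities(land, 40L, seed = 14L)
  hp <- grid_values(gt$true_hp)
  # pooled HHR weights localities by hunter-days; spans are equal within an
  # effort level, so the estimand is the hunter-weighted mean rate
  target <- weighted.mean(hp[cbind(comm$row, comm$col)], comm$n_hunters)

  mean_abs_err <- vapply(c(10L, 100L, 1000L), function(span) {
    errs <- vapply(1:20, function(s) {
      out <- generate_hunting_records(comm, land, tx, gt, seed = s,
                                      span_range = c(span, span),
                                      undetermined_prob = 0)
      eff <- out$efforts
      pooled <- sum(out$records$n_individuals) /
        sum(eff$n_hunters * eff$span_days)
      abs(pooled - target)
    }, numeric(1L))
    mean(errs)
  }, numeric(1L))
  expect_true(all(diff(mean_abs_err) < 0))
})
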