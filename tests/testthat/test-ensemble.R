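test_that("a constant response yields a degenerate but valid ensemble", {
  set.seed(1)
  df <- data.frame(x1 = rnorm(30), x2 = rnorm(30), y = 2.5)
  expect_warning(ens <- hp_ensemble(y ~ ., df, n_members = 3L, n_trees = 30L),
                 "constant response")
  nd <- data.frame(x1 = rnorm(4), x2 = rnorm(4))
  p <- predict(ens, nd)
  expect_true(all(p == 2.5))
})

test_that("ensemble fitting is reproducible and respects its spec", {
  sim <- tiny_study(seed = 21L, n_localities = 60L)
  f1 <- fit_tiny_ensemble(sim, seed = 5L)
  f2 <- fit_tiny_ensemble(sim, seed = 5L)
  p1 <- predict(f1$ensemble, f1$data)
  p2 <- predict(f2$ensemble, f2$data)
  expect_identical(p1, p2)
  expect_length(f1$ensemble$members, 5L)
  expect_error(hp_ensemble(y ~ x, data.frame(x = 1:5, y = 1:5)),
               "20 training rows")
  expect_error(hp_ensemble(y ~ x, data.frame(x = 1:30, y = rnorm(30)),
                           subsample_fraction = 0),
               "subsample_fraction")
})

test_that("quantile surfaces are cellwise sorted with consistent summaries", {
  sim <- tiny_study(seed = 21L, n_localities = 60L)
  fit <- fit_tiny_ensemble(sim, seed = 5L)
  hp <- predict_hp(fit$ensemble, sim$landscape$stack)
  ok <- !hp$q10$mask
  expect_true(all(hp$q10$values[ok] <= hp$q25$values[ok]))
  expect_true(all(hp$q25$values[ok] <= hp$q50$values[ok]))
  expect_true(all(hp$q50$values[ok] <= hp$q75$values[ok]))
  expect_true(all(hp$q75$values[ok] <= hp$q90$values[ok]))
  expect_true(all(hp$q10$values[ok] >= 0))

  # the mean grid is the arithmetic mean of the five quantile grids
  five <- cbind(hp$q10$values[ok], hp$q25$values[ok], hp$q50$values[ok],
                hp$q75$values[ok], hp$q90$values[ok])
  expect_equal(hp$mean$values[ok], rowMeans(five), tolerance = 1e-12)
  # the 90% interval is the q10-q90 pair
  expect_identical(hp$ci_lo$values, hp$q10$values)
  expect_identical(hp$ci_hi$values, hp$q90$values)

  # a single-member ensemble collapses all quantiles
  one <- hp_ensemble(hhr ~ ., data = fit$data, n_members = 1L,
                     n_trees = 40L, seed = 9L)
  hp1 <- predict_hp(one, sim$landscape$stack)
  expect_equal(hp1$q10$values, hp1$q90$values)
})

test_that("missing stack layers raise a feature-mismatch error", {
  sim <- tiny_study(seed = 21L, n_localities = 60L)
  fit <- fit_tiny_ensemble(sim, seed = 5L)
  broken <- sim$landscape$stack
  broken$evi <- NULL
  broken$evi_2020 <- NULL
  expect_error(predict_hp(fit$ensemble, broken), "feature-mismatch")
})

test_that("TSOP training rows add zeros in range and drop nested records", {
  tsop <- matrix(c(0.6, 0.0, 0.5,
                   0.4, 1.0, 0.3,
                   0.0, 0.0, 0.2),
                 nrow = 3, dimnames = list(c("L1", "L2", "L3"),
                                           c("child", "other", "parent")))
  localities <- data.frame(locality_id = c("L1", "L2", "L3"),
                           row = c(1L, 1L, 2L), col = c(1L, 2L, 2L),
                           stringsAsFactors = FALSE)
  range <- matrix(TRUE, 2, 2)
  features <- data.frame(locality_id = c("L1", "L2", "L3"),
                         x = c(0.1, 0.2, 0.3), stringsAsFactors = FALSE)
  registry <- data.frame(taxon_id = c("child", "other", "parent"),
                         parent_id = c("parent", "", ""),
                         stringsAsFactors = FALSE)

  tr <- build_tsop_training(tsop, "child", range, localities, features,
                            registry)
  # L3 records child and parent together: nested exclusion drops it;
  # L1 keeps its positive share and L2 becomes an in-range zero row
  expect_equal(nrow(tr), 2L)
  expect_setequal(tr$tsop, c(0.6, 0))

  # without the registry, L1 and L3 stay as positive rows
  tr2 <- build_tsop_training(tsop, "child", range, localities, features)
  expect_equal(sort(tr2$tsop), c(0, 0.5, 0.6))

  # out-of-range locality with no kills contributes nothing
  range2 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  tr3 <- build_tsop_training(tsop, "child", range2, localities, features)
  expect_equal(nrow(tr3), 2L)  # L1 (recorded) + nothing for L2/L3? L3 recorded
  expect_true(all(tr3$tsop > 0))
})

test_that("TSOP surfaces stay in [0, 1] with a constant fallback", {
  sim <- tiny_study(seed = 23L, n_localities = 50L)
  stack <- sim$landscape$stack
  vars <- c("evi", "elevation", "language_curr")
  small_stack <- stack[vars]

  # all-zero training: fallback constant zero surface
  tr0 <- data.frame(evi = runif(12), elevation = runif(12, 100, 200),
                    language_curr = rep(1:3, 4), tsop = 0)
  g0 <- fit_predict_tsop(tr0, small_stack)
  expect_true(all(g0$values[!g0$mask] == 0))
  expect_false(attr(g0, "modelled"))

  # modelled surface is clipped to the unit interval
  set.seed(3)
  tr <- data.frame(evi = runif(40), elevation = runif(40, 100, 200),
                   language_curr = rep(1:4, 10))
  tr$tsop <- pmin(1, pmax(0, 0.5 + 2 * (tr$evi - 0.5) + rnorm(40, 0, 0.2)))
  g <- fit_predict_tsop(tr, small_stack, n_trees = 80L, seed = 2L)
  v <- g$values[!g$mask]
  expect_true(all(v >= 0 & v <= 1))
  expect_true(attr(g, "modelled"))
})

test_that("spatially separated taxa are recovered by their TSOP models", {
  # two taxa share the full landscape but prefer opposite halves: each
  # predicted proportion must be higher inside its own high-preference half
  sim <- tiny_study(seed = 30L, nr = 24L, nc = 24L, n_taxa = 2L,
                    n_localities = 80L)
  land <- sim$landscape
  nr <- nrow(land$boundary); nc <- ncol(land$boundary)
  left <- col(matrix(0, nr, nc)) <= nc / 2
  ranges <- list(taxon_001 = land$boundary, taxon_002 = land$boundary)
  taxa2 <- list(traits = sim$taxa$traits[1:2, ], ranges = ranges)
  gt <- flat_truth(land, taxa2, rate = 0.12)
  p1 <- ifelse(left, 0.85, 0.15)
  gt$true_tsop[, , 1] <- p1
  gt$true_tsop[, , 2] <- 1 - p1
  out <- generate_hunting_records(sim$communities, land, taxa2,
                                  gt, seed = 31L, undetermined_prob = 0)
  filt <- filter_studies(out$records, out$efforts, min_taxa = 1L)
  tsop <- compute_tsop(filt$tsop_records)
  locs <- sim$communities[match(rownames(tsop),
                                sim$communities$locality_id), ]
  feats <- extract_features(land$stack, locs, years = 2010L)
  surf <- list()
  for (tid in c("taxon_001", "taxon_002")) {
    tr <- build_tsop_training(tsop, tid, ranges[[tid]], sim$communities,
                              feats)
    surf[[tid]] <- fit_predict_tsop(tr, land$stack, n_trees = 100L,
                                    seed = 32L)
  }
  m1_in <- mean(surf$taxon_001$values[land$boundary & left], na.rm = TRUE)
  m1_out <- mean(surf$taxon_001$values[land$boundary & !left], na.rm = TRUE)
  m2_in <- mean(surf$taxon_002$values[land$boundary & !left], na.rm = TRUE)
  m2_out <- mean(surf$taxon_002$values[land$boundary & left], na.rm = TRUE)
  expect_gt(m1_in, m1_out)
  expect_gt(m2_in, m2_out)
})

test_that("the proportion stack renormalises to one and masks empty cells", {
  a <- wm_grid(matrix(0.3, 2, 2))
  b <- wm_grid(matrix(0.1, 2, 2))
  ranges <- list(A = matrix(TRUE, 2, 2),
                 B = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  st <- assemble_tsop_stack(list(A = a, B = b), ranges)
  expect_equal(st$stack$A$values[1, 1], 0.75)
  expect_equal(st$stack$B$values[1, 1], 0.25)
  # single in-range taxon takes the full share
  expect_equal(st$stack$A$values[2, 2], 1)

  # zero-sum cells are masked everywhere
  z <- assemble_tsop_stack(list(A = wm_grid(matrix(0, 2, 2))),
                           list(A = matrix(TRUE, 2, 2)))
  expect_true(all(z$stack$A$mask))
  expect_true(all(z$masked))
})

test_that("dropping the driving covariate degrades spatial recovery", {
  sim <- tiny_study(seed = 33L, nr = 24L, nc = 24L, n_localities = 150L,
                    urban_fraction = 0)
  full <- fit_tiny_ensemble(sim, n_members = 8L, n_trees = 120L, seed = 6L)
  nodrv <- fit_tiny_ensemble(sim, n_members = 8L, n_trees = 120L, seed = 6L,
                             drop_vars = c("evi"))
  hp_full <- predict_hp(full$ensemble, sim$landscape$stack)
  stack2 <- sim$landscape$stack
  hp_nodrv <- predict_hp(nodrv$ensemble, stack2)
  truth <- sim$ground_truth$true_hp
  ok <- !hp_full$q50$mask & !truth$mask
  rho_full <- cor(hp_full$q50$values[ok], truth$values[ok],
                  method = "spearman")
  rho_nodrv <- cor(hp_nodrv$q50$values[ok], truth$values[ok],
                   method = "spearman")
  expect_gt(rho_full, rho_nodrv)
})
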