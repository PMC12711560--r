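# Small deterministic fixtures shared across test files.

tiny_study <- function(seed = 1L, nr = 20L, nc = 20L, n_taxa = 6L,
                       n_localities = 40L, ...) {
  simulate_harvest_study(n_rows = nr, n_cols = nc, n_taxa = n_taxa,
                         n_localities = n_localities, seed = seed, ...)
}

# uniform ground truth on a given landscape: constant rate, equal taxon
# shares inside ranges
flat_truth <- function(landscape, taxa, rate = 0.1, ratio = 0.178) {
  nr <- nrow(landscape$boundary); nc <- ncol(landscape$boundary)
  v <- matrix(rate, nr, nc)
  v[!landscape$boundary] <- NA_real_
  n_taxa <- nrow(taxa$traits)
  tsop <- array(0, dim = c(nr, nc, n_taxa),
                dimnames = list(NULL, NULL, taxa$traits$taxon_id))
  for (i in seq_len(n_taxa)) tsop[, , i] <- taxa$ranges[[i]] * 1.0
  tot <- apply(tsop, c(1, 2), sum)
  pos <- tot > 0
  for (i in seq_len(n_taxa)) {
    sl <- tsop[, , i]; sl[pos] <- sl[pos] / tot[pos]; tsop[, , i] <- sl
  }
  list(true_hp = wm_grid(v, tag = "true_hp"), true_tsop = tsop,
       true_hunter_ratio = ratio)
}

# constant-valued grid helper
const_grid <- function(value, nr = 4L, nc = 4L, tag = "const") {
  wm_grid(matrix(value, nr, nc), tag = tag)
}

# training frame + fitted mini ensemble on a tiny landscape, for reuse
fit_tiny_ensemble <- function(sim, n_members = 5L, n_trees = 60L,
                              seed = 42L, drop_vars = character()) {
  filt <- filter_studies(sim$records, sim$efforts)
  eff_kept <- sim$efforts[
    sim$efforts$locality_id %in% unique(filt$hhr_records$locality_id), ,
    drop = FALSE]
  hhr_tab <- compute_hhr(filt$hhr_records, eff_kept)
  eff <- sim$efforts[match(hhr_tab$locality_id, sim$efforts$locality_id), ]
  locs <- sim$communities[match(hhr_tab$locality_id,
                                sim$communities$locality_id), ]
  feats <- extract_features(sim$landscape$stack, locs, years = eff$year)
  feats$span_days <- eff$span_days
  df <- feats
  df$hhr <- hhr_tab$hhr
  for (nm in intersect(names(df),
                       c("language_hist", "indigenous", "language_curr",
                         "urca")))
    df[[nm]] <- factor(as.character(df[[nm]]))
  keep <- setdiff(names(df), c("locality_id", "year", drop_vars))
  ens <- hp_ensemble(hhr ~ ., data = df[keep], n_members = n_members,
                     n_trees = n_trees, seed = seed)
  list(ensemble = ens, data = df[keep], hhr = hhr_tab)
}
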