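#' Configuration for a synthetic landscape
#'
#' Defines the gridded study region emulated by the generator: lattice size,
#' number of covariate layers, the urban fraction and the strength of the
#' habitat-loss gradient. The generator is fully deterministic given `seed`.
#'
#' @param n_rows,n_cols lattice dimensions (each >= 4).
#' @param n_covariates total number of covariate layers (>= 6); the last four
#'   are categorical (historical language family, Indigenous/non-Indigenous,
#'   current language family, urban-rural catchment class), the rest
#'   continuous spatially autocorrelated fields.
#' @param urban_fraction proportion of in-boundary cells flagged urban, in
#'   `[0, 1)`.
#' @param deforestation_max maximum habitat-loss proportion; 0 gives an
#'   all-zero habitat-loss field.
#' @param smoothing number of 3x3 blur passes applied to the white-noise
#'   fields (controls autocorrelation range).
#' @param seed integer seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 40L, n_cols = 40L, n_covariates = 12L,
                             urban_fraction = 0.02, deforestation_max = 0.5,
                             smoothing = 3L, seed = 1L) {
  if (n_rows < 4L || n_cols < 4L)
    stop("configuration error: n_rows and n_cols must both be >= 4")
  if (urban_fraction < 0 || urban_fraction >= 1)
    stop("configuration error: urban_fraction must be in [0, 1)")
  if (n_covariates < 6L)
    stop("configuration error: n_covariates must be >= 6")
  if (deforestation_max < 0 || deforestation_max > 1)
    stop("configuration error: deforestation_max must be in [0, 1]")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_covariates = as.integer(n_covariates),
                 urban_fraction = urban_fraction,
                 deforestation_max = deforestation_max,
                 smoothing = as.integer(smoothing),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# spatially autocorrelated standard field: iid normal blurred `passes` times
smooth_noise <- function(nr, nc, passes = 3L) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (p in seq_len(passes)) {
    s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      kr <- rs >= 1L & rs <= nr; kc <- cs >= 1L & cs <= nc
      s[kr, kc] <- s[kr, kc] + z[rs[kr], cs[kc], drop = FALSE]
      n[kr, kc] <- n[kr, kc] + 1
    }
    z <- s / n
  }
  (z - base::mean(z)) / stats::sd(z)
}

# categorical layer from quantile slices of a smoothed field (contiguous
# patches, deterministic under the active RNG state)
categorical_layer <- function(nr, nc, n_levels, smoothing, prefix) {
  f <- smooth_noise(nr, nc, smoothing)
  br <- stats::quantile(f, probs = seq(0, 1, length.out = n_levels + 1L))
  codes <- matrix(findInterval(f, br[-c(1L, n_levels + 1L)]) + 1L, nr, nc)
  levels <- stats::setNames(seq_len(n_levels),
                            paste0(prefix, "_", seq_len(n_levels)))
  list(codes = codes, levels = levels)
}

continuous_layer_names <- function(n) {
  base <- c("evi", "gpp", "npp", "soil_fertility", "flooded", "elevation",
            "hand", "habitat_loss")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("cov_%02d", seq.int(length(base) + 1L, n)))
}

#' Generate a synthetic gridded landscape
#'
#' Produces a stack of covariate layers (continuous fields are smoothed white
#' noise, hence spatially autocorrelated; categorical layers are contiguous
#' quantile patches of smoothed fields), a population grid, an urban-cell
#' mask and a study-boundary mask. The habitat-loss and vegetation-index
#' layers additionally carry 5-yearly epoch variants to exercise temporal
#' matching. All output is reproducible from `config$seed`.
#'
#' @param config a [landscape_config()].
#' @return list with `stack` (named `wm_grid` list), `population`
#'   (`wm_grid`), `urban` and `boundary` (logical matrices) and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$n_rows; nc <- config$n_cols
  sm <- config$smoothing

  # boundary: inscribed ellipse, roughened by a smoothed field
  rr <- (row(matrix(0, nr, nc)) - (nr + 1) / 2) / (0.52 * nr)
  cc <- (col(matrix(0, nr, nc)) - (nc + 1) / 2) / (0.52 * nc)
  rough <- 0.15 * smooth_noise(nr, nc, sm)
  boundary <- (rr^2 + cc^2) <= (1 + rough)
  outside <- !boundary

  n_cont <- config$n_covariates - 4L
  stack <- list()
  for (nm in continuous_layer_names(n_cont)) {
    f <- smooth_noise(nr, nc, sm)
    v <- switch(nm,
      evi            = 0.5 + 0.18 * f,
      gpp            = pmax(2.2 + 0.6 * f, 0),
      npp            = pmax(1.1 + 0.3 * f, 0),
      soil_fertility = exp(0.5 * f),
      flooded        = stats::plogis(1.5 * f - 1),
      elevation      = pmax(150 + 80 * f, 0),
      hand           = pmax(25 + 15 * f, 0),
      habitat_loss   = {
        grad <- (col(matrix(0, nr, nc)) - 1) / max(1, nc - 1)
        config$deforestation_max *
          stats::plogis(2 * f + 2 * grad - 1) *
          (config$deforestation_max > 0)
      },
      f)
    v[outside] <- NA_real_
    stack[[nm]] <- wm_grid(v, tag = nm)
  }
  if (config$deforestation_max == 0 && "habitat_loss" %in% names(stack)) {
    z <- matrix(0, nr, nc); z[outside] <- NA_real_
    stack[["habitat_loss"]] <- wm_grid(z, tag = "habitat_loss")
  }

  # epoch variants: habitat loss ramps up through time, EVI drifts slightly
  if ("habitat_loss" %in% names(stack)) {
    epochs <- seq(1985L, 2020L, by = 5L)
    base <- grid_values(stack[["habitat_loss"]])
    for (i in seq_along(epochs)) {
      ramp <- 0.3 + 0.7 * (i - 1) / (length(epochs) - 1)
      stack[[paste0("habitat_loss_", epochs[i])]] <-
        wm_grid(base * ramp, tag = paste0("habitat_loss_", epochs[i]))
    }
    stack[["habitat_loss"]] <- stack[["habitat_loss_2020"]]
    stack[["habitat_loss"]]$tag <- "habitat_loss"
  }
  if ("evi" %in% names(stack)) {
    epochs <- seq(2000L, 2020L, by = 5L)
    base <- grid_values(stack[["evi"]])
    for (i in seq_along(epochs)) {
      drift <- 1 - 0.01 * (length(epochs) - i)
      stack[[paste0("evi_", epochs[i])]] <-
        wm_grid(base * drift, tag = paste0("evi_", epochs[i]))
    }
    stack[["evi"]] <- stack[["evi_2020"]]
    stack[["evi"]]$tag <- "evi"
  }

  cat_specs <- list(language_hist = 6L, indigenous = 2L, language_curr = 5L,
                    urca = 4L)
  for (nm in names(cat_specs)) {
    cl <- categorical_layer(nr, nc, cat_specs[[nm]], sm, nm)
    v <- cl$codes * 1.0
    v[outside] <- NA_real_
    stack[[nm]] <- wm_grid(v, tag = nm, levels = cl$levels)
  }

  pop <- exp(1.2 * smooth_noise(nr, nc, sm) + stats::rnorm(nr * nc, 0, 0.3))
  pop <- pop / base::mean(pop) * 120      # ~120 people per 100 km2 cell
  pop[outside] <- NA_real_

  urban <- matrix(FALSE, nr, nc)
  if (config$urban_fraction > 0) {
    inb <- which(boundary)
    k <- floor(config$urban_fraction * length(inb))
    if (k > 0L) {
      ord <- inb[order(pop[inb], decreasing = TRUE)]
      urban[ord[seq_len(k)]] <- TRUE
    }
  }

  list(stack = stack, population = wm_grid(pop, tag = "population"),
       urban = urban, boundary = boundary, config = config)
}

#' Generate synthetic hunted taxa
#'
#' Draws taxon trait profiles: log-normal body masses (spanning several
#' orders of magnitude by default, as hunted tetrapod assemblages do),
#' log-normal standing densities (individuals per 100 km2) for a subset of
#' taxa, an edible-yield group, and a contiguous disc-shaped range mask
#' covering a random fraction of the in-boundary cells.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param landscape output of [generate_landscape()].
#' @param seed integer seed.
#' @param mass_meanlog,mass_sdlog log-normal body-mass parameters (kg).
#' @param mass_range optional `c(lo, hi)` in kg; when supplied masses are
#'   drawn log-uniform in the range (degenerate `lo == hi` allowed).
#' @param density_meanlog,density_sdlog log-normal density parameters
#'   (individuals per 100 km2).
#' @param density_coverage fraction of taxa with a density estimate (the
#'   rest are uncapped in offtake accounting).
#' @param range_fraction `c(lo, hi)` bounds for per-taxon range coverage of
#'   in-boundary cells (lo >= 0.1 so every range is non-trivial).
#' @return list with `traits` (data frame: `taxon_id`, `body_mass_mean`,
#'   `body_mass_se`, `density_mean`, `density_se`, `edible_group`) and
#'   `ranges` (named list of logical matrices).
#' @export
generate_taxa <- function(n_taxa, landscape, seed = 1L,
                          mass_meanlog = log(2), mass_sdlog = 2.2,
                          mass_range = NULL,
                          density_meanlog = log(60), density_sdlog = 1,
                          density_coverage = 0.8,
                          range_fraction = c(0.2, 0.9)) {
  if (n_taxa < 2L) stop("configuration error: n_taxa must be >= 2")
  set.seed(seed)
  nr <- nrow(landscape$boundary); nc <- ncol(landscape$boundary)
  ids <- sprintf("taxon_%03d", seq_len(n_taxa))

  if (!is.null(mass_range)) {
    if (mass_range[1L] > mass_range[2L] || mass_range[1L] <= 0)
      stop("mass_range must be positive and non-decreasing")
    mass <- exp(stats::runif(n_taxa, log(mass_range[1L]),
                             log(mass_range[2L])))
  } else {
    mass <- stats::rlnorm(n_taxa, mass_meanlog, mass_sdlog)
  }
  mass_se <- mass * stats::runif(n_taxa, 0.02, 0.10)

  has_density <- stats::runif(n_taxa) < density_coverage
  dens <- ifelse(has_density, stats::rlnorm(n_taxa, density_meanlog,
                                            density_sdlog), NA_real_)
  dens_se <- ifelse(has_density, dens * stats::runif(n_taxa, 0.05, 0.15),
                    NA_real_)

  groups <- sample(c("mammal", "bird", "chelonian", "caiman"), n_taxa,
                   replace = TRUE, prob = c(0.66, 0.22, 0.08, 0.04))

  inb <- which(landscape$boundary, arr.ind = TRUE)
  ranges <- vector("list", n_taxa)
  names(ranges) <- ids
  d2 <- function(r0, c0) (row(matrix(0, nr, nc)) - r0)^2 +
    (col(matrix(0, nr, nc)) - c0)^2
  for (i in seq_len(n_taxa)) {
    frac <- stats::runif(1L, max(0.1, range_fraction[1L]), range_fraction[2L])
    target <- max(1L, round(frac * nrow(inb)))
    ctr <- inb[sample.int(nrow(inb), 1L), ]
    dist2 <- d2(ctr[1L], ctr[2L])
    dist2[!landscape$boundary] <- Inf
    thr <- sort(dist2[is.finite(dist2)])[target]
    ranges[[i]] <- dist2 <= thr & landscape$boundary
  }

  traits <- data.frame(taxon_id = ids,
                       body_mass_mean = mass, body_mass_se = mass_se,
                       density_mean = dens, density_se = dens_se,
                       edible_group = groups, stringsAsFactors = FALSE)
  list(traits = traits, ranges = ranges)
}

#' Generate synthetic hunting communities
#'
#' Places localities on non-urban in-boundary cells, draws consumer counts
#' and binomial hunter counts at the configured hunter-to-consumer ratio.
#'
#' @param landscape output of [generate_landscape()].
#' @param n_localities number of localities; must not exceed the number of
#'   eligible cells.
#' @param true_hunter_ratio probability that a consumer is a hunter.
#' @param seed integer seed.
#' @param consumers_range `c(lo, hi)` uniform range for per-locality
#'   consumer counts.
#' @return data frame `locality_id`, `row`, `col`, `n_consumers`,
#'   `n_hunters`.
#' @export
generate_communities <- function(landscape, n_localities,
                                 true_hunter_ratio = 0.178, seed = 1L,
                                 consumers_range = c(30L, 400L)) {
  set.seed(seed)
  eligible <- which(landscape$boundary & !landscape$urban)
  if (length(eligible) == 0L)
    stop("placement error: no eligible (non-urban, in-boundary) cells")
  if (n_localities > length(eligible))
    stop("placement error: n_localities exceeds eligible cells")
  cells <- if (length(eligible) == 1L) eligible else
    sample(eligible, n_localities)
  nr <- nrow(landscape$boundary)
  consumer_pool <- seq.int(consumers_range[1L], consumers_range[2L])
  consumers <- if (length(consumer_pool) == 1L)
    rep(consumer_pool, n_localities) else
    sample(consumer_pool, n_localities, replace = TRUE)
  hunters <- stats::rbinom(n_localities, consumers, true_hunter_ratio)
  data.frame(locality_id = sprintf("L%03d", seq_len(n_localities)),
             row = ((cells - 1L) %% nr) + 1L,
             col = ((cells - 1L) %/% nr) + 1L,
             n_consumers = consumers, n_hunters = hunters,
             stringsAsFactors = FALSE)
}

#' Build the generator's ground truth
#'
#' Defines the true harvest-productivity surface as a known monotone
#' function of the vegetation-index field (the dominant driver) with weaker
#' soil-fertility and habitat-loss effects and categorical language offsets,
#' and the true per-taxon offtake-proportion surfaces as range-restricted,
#' cellwise-normalised preference fields.
#'
#' @param landscape output of [generate_landscape()].
#' @param taxa output of [generate_taxa()].
#' @param true_hunter_ratio scalar in (0, 1).
#' @param hp_base mean harvest rate (individuals per hunter-day) over the
#'   boundary; the continental-scale reference value is about 0.07.
#' @param driver_coef strength of the dominant (vegetation-index) effect.
#' @param seed integer seed for the taxon preference fields.
#' @return list with `true_hp` (`wm_grid`), `true_tsop` (3D array cells x
#'   taxa, per-cell sums 1 over in-range taxa) and `true_hunter_ratio`.
#' @export
generate_ground_truth <- function(landscape, taxa,
                                  true_hunter_ratio = 0.178,
                                  hp_base = 0.07, driver_coef = 1.1,
                                  seed = 1L) {
  set.seed(seed + 1000L)
  nr <- nrow(landscape$boundary); nc <- ncol(landscape$boundary)
  z <- function(g) {
    v <- grid_values(g)
    mu <- base::mean(v, na.rm = TRUE); sd <- stats::sd(v, na.rm = TRUE)
    out <- (v - mu) / ifelse(sd > 0, sd, 1)
    out[is.na(out)] <- 0
    out
  }
  evi <- z(landscape$stack[["evi"]])
  soil <- if ("soil_fertility" %in% names(landscape$stack))
    z(landscape$stack[["soil_fertility"]]) else 0
  hl <- if ("habitat_loss" %in% names(landscape$stack))
    grid_values(landscape$stack[["habitat_loss"]], masked_as = 0) else 0
  lang <- grid_values(landscape$stack[["language_curr"]], masked_as = 1)
  n_lang <- length(landscape$stack[["language_curr"]]$levels)
  offsets <- seq(-0.15, 0.15, length.out = max(2L, n_lang))
  eta <- driver_coef * evi + 0.3 * soil - 0.6 * hl +
    matrix(offsets[lang], nr, nc)
  hp <- exp(eta)
  hp[!landscape$boundary] <- NA_real_
  hp <- hp / base::mean(hp, na.rm = TRUE) * hp_base
  true_hp <- wm_grid(hp, tag = "true_hp")

  n_taxa <- nrow(taxa$traits)
  tsop <- array(0, dim = c(nr, nc, n_taxa),
                dimnames = list(NULL, NULL, taxa$traits$taxon_id))
  pref <- lapply(seq_len(n_taxa), function(i)
    exp(0.8 * smooth_noise(nr, nc, landscape$config$smoothing)))
  for (i in seq_len(n_taxa)) {
    w <- pref[[i]]
    w[!taxa$ranges[[i]]] <- 0
    tsop[, , i] <- w
  }
  tot <- apply(tsop, c(1, 2), sum)
  pos <- tot > 0
  for (i in seq_len(n_taxa)) {
    sl <- tsop[, , i]
    sl[pos] <- sl[pos] / tot[pos]
    tsop[, , i] <- sl
  }
  list(true_hp = true_hp, true_tsop = tsop,
       true_hunter_ratio = true_hunter_ratio)
}

#' Generate synthetic hunting records
#'
#' For each locality the total kill count over the monitored span is Poisson
#' with mean `true_hp[cell] x hunters x span_days`; individual kills are
#' assigned to taxa by a multinomial draw from the true offtake proportions
#' restricted to taxa whose range covers the cell (renormalised), with a
#' small independent probability of being recorded as `"undetermined"`.
#'
#' @param communities output of [generate_communities()].
#' @param landscape output of [generate_landscape()].
#' @param taxa output of [generate_taxa()].
#' @param ground_truth output of [generate_ground_truth()].
#' @param seed integer seed.
#' @param span_range `c(lo, hi)` uniform range (days) for per-locality
#'   recording spans (effort heterogeneity).
#' @param years candidate record years, sampled per locality.
#' @param undetermined_prob per-kill probability of an unidentifiable record.
#' @return list with `records`, `efforts` (data frames in the standard
#'   schemas) and `ground_truth` (passed through for recovery tests).
#' @export
generate_hunting_records <- function(communities, landscape, taxa,
                                     ground_truth, seed = 1L,
                                     span_range = c(60L, 365L),
                                     years = 1995:2020,
                                     undetermined_prob = 0.03) {
  if (any(span_range < 1L)) stop("effort_days must be >= 1")
  set.seed(seed + 2000L)
  hp <- grid_values(ground_truth$true_hp)
  nr <- nrow(hp)
  # sample() treats a length-1 vector as 1:n, so guard degenerate ranges
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  rec <- list(); eff <- list()
  for (i in seq_len(nrow(communities))) {
    r <- communities$row[i]; c <- communities$col[i]
    if (!landscape$boundary[r, c])
      stop("placement error: locality ", communities$locality_id[i],
           " outside the study boundary")
    span <- pick(seq.int(span_range[1L], span_range[2L]))
    year <- pick(years)
    hunters <- communities$n_hunters[i]
    lambda <- hp[r, c] * hunters * span
    if (is.na(lambda)) lambda <- 0
    total <- stats::rpois(1L, lambda)
    eff[[i]] <- data.frame(locality_id = communities$locality_id[i],
                           n_hunters = hunters, span_days = span,
                           year = year, stringsAsFactors = FALSE)
    if (total == 0L) next
    n_und <- stats::rbinom(1L, total, undetermined_prob)
    p <- ground_truth$true_tsop[r, c, ]
    counts <- if (sum(p) > 0 && total - n_und > 0)
      as.vector(stats::rmultinom(1L, total - n_und, p))
    else rep(0L, length(p))
    keep <- counts > 0
    tax <- c(taxa$traits$taxon_id[keep],
             if (n_und > 0L || (total > 0L && sum(p) == 0)) UNDETERMINED)
    n <- c(counts[keep],
           if (n_und > 0L || (total > 0L && sum(p) == 0))
             n_und + (total - n_und) * (sum(p) == 0))
    if (length(tax) == 0L) next
    rec[[length(rec) + 1L]] <-
      data.frame(locality_id = communities$locality_id[i], year = year,
                 taxon_id = tax, n_individuals = n, stringsAsFactors = FALSE)
  }
  records <- if (length(rec) > 0L) do.call(rbind, rec) else
    data.frame(locality_id = character(), year = integer(),
               taxon_id = character(), n_individuals = integer(),
               stringsAsFactors = FALSE)
  rownames(records) <- NULL
  list(records = records, efforts = do.call(rbind, eff),
       ground_truth = ground_truth)
}

#' One-call synthetic harvest study
#'
#' Convenience wrapper chaining [generate_landscape()], [generate_taxa()],
#' [generate_communities()], [generate_ground_truth()] and
#' [generate_hunting_records()] with a single root seed (stable sub-seeds
#' per stage).
#'
#' @param n_rows,n_cols,n_taxa,n_localities study dimensions.
#' @param seed root integer seed.
#' @param true_hunter_ratio hunter-to-consumer probability.
#' @param hp_base mean true harvest rate (individuals per hunter-day).
#' @param urban_fraction proportion of urban cells.
#' @param ... further arguments passed to [generate_hunting_records()].
#' @return list with `landscape`, `taxa`, `communities`, `ground_truth`,
#'   `records`, `efforts`.
#' @export
simulate_harvest_study <- function(n_rows = 40L, n_cols = 40L, n_taxa = 12L,
                                   n_localities = 120L, seed = 1L,
                                   true_hunter_ratio = 0.178,
                                   hp_base = 0.07, urban_fraction = 0.02,
                                   ...) {
  cfg <- landscape_config(n_rows = n_rows, n_cols = n_cols,
                          urban_fraction = urban_fraction, seed = seed)
  landscape <- generate_landscape(cfg)
  taxa <- generate_taxa(n_taxa, landscape, seed = seed + 1L)
  communities <- generate_communities(landscape, n_localities,
                                      true_hunter_ratio = true_hunter_ratio,
                                      seed = seed + 2L)
  gt <- generate_ground_truth(landscape, taxa,
                              true_hunter_ratio = true_hunter_ratio,
                              hp_base = hp_base, seed = seed + 3L)
  sim <- generate_hunting_records(communities, landscape, taxa, gt,
                                  seed = seed + 4L, ...)
  list(landscape = landscape, taxa = taxa, communities = communities,
       ground_truth = gt, records = sim$records, efforts = sim$efforts)
}
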