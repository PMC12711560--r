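pipeline_defaults <- function() {
  list(
    simulate = list(n_rows = 40L, n_cols = 40L, n_taxa = 12L,
                    n_localities = 120L, hp_base = 0.07,
                    true_hunter_ratio = 0.178, urban_fraction = 0.02),
    ensemble = list(n_members = 30L, subsample_fraction = 0.70,
                    n_trees = 500L, tsop_min_rows = 10L,
                    tsop_n_trees = 300L),
    constants = list(edible_fraction = 0.585, annual_days = 365,
                     emission_t_per_km2 = 18000,
                     beef_yield_kg_ha_day = c(0.2, 0.8),
                     beef_price = NULL),
    nutrition = list(enabled = TRUE, observations = NULL, dri = NULL,
                     shares = NULL),
    paths = list(study = NULL),
    seed = 1L
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a plain list, fills defaults and checks
#' every constraint, reporting all violations at once: constants in range
#' (edible fraction in (0, 1], positive day counts and emission factor),
#' ensemble spec sane, and any referenced input path existing.
#'
#' @param config file path (`.yaml`/`.yml`/`.json`) or named list; `NULL`
#'   yields the all-defaults synthetic configuration.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  cfg <- merge_config(pipeline_defaults(), config)

  problems <- character()
  cst <- cfg$constants
  if (cst$edible_fraction <= 0 || cst$edible_fraction > 1)
    problems <- c(problems, "constants.edible_fraction must be in (0, 1]")
  if (cst$annual_days <= 0)
    problems <- c(problems, "constants.annual_days must be positive")
  if (cst$emission_t_per_km2 <= 0)
    problems <- c(problems, "constants.emission_t_per_km2 must be positive")
  if (any(cst$beef_yield_kg_ha_day <= 0))
    problems <- c(problems, "constants.beef_yield_kg_ha_day must be positive")
  ens <- cfg$ensemble
  if (ens$n_members < 1L)
    problems <- c(problems, "ensemble.n_members must be >= 1")
  if (ens$subsample_fraction <= 0 || ens$subsample_fraction > 1)
    problems <- c(problems, "ensemble.subsample_fraction must be in (0, 1]")
  if (!is.null(cfg$paths$study) && !dir.exists(cfg$paths$study))
    problems <- c(problems,
                  paste0("paths.study: directory not found: ",
                         cfg$paths$study))
  if (!is.null(cfg$nutrition$observations) &&
      !file.exists(cfg$nutrition$observations))
    problems <- c(problems, paste0("nutrition.observations: file not found: ",
                                   cfg$nutrition$observations))
  if (length(problems) > 0L)
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

fmt_num <- function(x) sprintf("%.10g", x)

write_summary_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  for (nm in names(df)[num]) df[[nm]] <- fmt_num(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full harvest-estimation pipeline
#'
#' Executes the stages in order: simulate (or ingest) -> record filters ->
#' trait metrics -> covariate extraction -> harvest-rate ensemble fit ->
#' harvest-productivity prediction -> offtake-proportion stack -> offtake
#' accounting -> edible production -> per-capita availability -> nutrient
#' adequacy (optional) -> report. Writes per-taxon and headline summary
#' CSVs, the invariant-check report and a machine-readable run manifest to
#' `output_dir`; all randomness derives from `config$seed`, so reruns with
#' the same configuration are byte-identical.
#'
#' @param config a [validate_config()] result, config path, or list.
#' @param output_dir artifact directory (created if needed); `NULL` skips
#'   file output.
#' @return invisibly, a list with the fitted ensemble, surfaces, summary
#'   tables and the manifest.
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  seed <- cfg$seed
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  stages_run <- character()

  # -- simulate / ingest ------------------------------------------------
  if (!is.null(cfg$paths$study)) {
    sim <- stage("ingest", read_study(cfg$paths$study))
    stages_run <- c(stages_run, "ingest")
  } else {
    sim <- stage("simulate", {
      s <- cfg$simulate
      simulate_harvest_study(n_rows = s$n_rows, n_cols = s$n_cols,
                             n_taxa = s$n_taxa,
                             n_localities = s$n_localities, seed = seed,
                             true_hunter_ratio = s$true_hunter_ratio,
                             hp_base = s$hp_base,
                             urban_fraction = s$urban_fraction)
    })
    stages_run <- c(stages_run, "simulate")
  }
  landscape <- sim$landscape; taxa <- sim$taxa

  # -- filter -----------------------------------------------------------
  filt <- stage("filter", filter_studies(sim$records, sim$efforts))
  stages_run <- c(stages_run, "filter")

  # -- metrics ----------------------------------------------------------
  metrics <- stage("metrics", {
    body_mass <- list(); caps <- c()
    for (i in seq_len(nrow(taxa$traits))) {
      tr <- taxa$traits[i, ]
      body_mass[[tr$taxon_id]] <- monte_carlo_metric(
        tr$body_mass_mean, tr$body_mass_se, seed = seed + 100L + i,
        positive = TRUE)
      if (!is.na(tr$density_mean)) {
        d <- monte_carlo_metric(tr$density_mean, tr$density_se,
                                seed = seed + 500L + i, positive = TRUE)
        caps[tr$taxon_id] <- d$mean   # individuals per 100 km2 = per cell
      }
    }
    ratio <- hunter_consumer_ratio(sim$communities)
    list(body_mass = body_mass, caps = caps, ratio = ratio)
  })
  stages_run <- c(stages_run, "metrics")

  # -- extract ----------------------------------------------------------
  hhr <- stage("extract", {
    eff_kept <- sim$efforts[
      sim$efforts$locality_id %in% unique(filt$hhr_records$locality_id), ,
      drop = FALSE]
    hhr_tab <- compute_hhr(filt$hhr_records, eff_kept)
    eff <- sim$efforts[match(hhr_tab$locality_id, sim$efforts$locality_id), ]
    feats <- extract_features(landscape$stack, sim$communities[
      match(hhr_tab$locality_id, sim$communities$locality_id), ],
      years = eff$year)
    feats$span_days <- eff$span_days
    list(table = hhr_tab, features = feats)
  })
  stages_run <- c(stages_run, "extract")

  # -- fit HHR ensemble -------------------------------------------------
  fit <- stage("fit_hhr", {
    df <- hhr$features
    df$hhr <- hhr$table$hhr
    for (nm in intersect(names(df), default_categorical()))
      df[[nm]] <- factor(as.character(df[[nm]]))
    model_cols <- setdiff(names(df), c("locality_id", "year"))
    hp_ensemble(hhr ~ ., data = df[model_cols],
                n_members = cfg$ensemble$n_members,
                subsample_fraction = cfg$ensemble$subsample_fraction,
                n_trees = cfg$ensemble$n_trees, seed = seed + 10L)
  })
  stages_run <- c(stages_run, "fit_hhr")

  # -- predict HP -------------------------------------------------------
  hp <- stage("predict_hp", predict_hp(fit, landscape$stack))
  stages_run <- c(stages_run, "predict_hp")

  # -- TSOP stack -------------------------------------------------------
  tsop_stack <- stage("tsop", {
    tsop <- compute_tsop(filt$tsop_records)
    feats <- extract_features(landscape$stack, sim$communities[
      match(rownames(tsop), sim$communities$locality_id), ],
      years = sim$efforts$year[
        match(rownames(tsop), sim$efforts$locality_id)])
    raw <- list()
    ids <- taxa$traits$taxon_id
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (!id %in% colnames(tsop)) next
      training <- build_tsop_training(tsop, id, taxa$ranges[[id]],
                                      sim$communities, feats)
      raw[[id]] <- fit_predict_tsop(training, landscape$stack,
                                    n_trees = cfg$ensemble$tsop_n_trees,
                                    seed = seed + 20L + i,
                                    min_rows = cfg$ensemble$tsop_min_rows)
    }
    assemble_tsop_stack(raw, taxa$ranges[names(raw)])
  })
  stages_run <- c(stages_run, "tsop")

  # -- offtake ----------------------------------------------------------
  offtake <- stage("offtake", {
    apps <- derive_apps(landscape$population, landscape$urban,
                        landscape$boundary)
    r <- metrics$ratio
    rhps <- derive_rhps(apps, c(q10 = r$q10, q25 = r$q25, q50 = r$q50,
                                q75 = r$q75, q90 = r$q90))
    taxon_hp <- taxon_individual_hp(hp$q50, tsop_stack$stack)
    ind <- individuals_offtake(taxon_hp, rhps$q50, metrics$caps,
                               annual_days = cfg$constants$annual_days)
    bio <- biomass_surfaces(ind$taxa, metrics$body_mass)
    list(apps = apps, rhps = rhps, individuals = ind, biomass = bio)
  })
  stages_run <- c(stages_run, "offtake")

  # -- edible / per-capita ----------------------------------------------
  edible <- stage("edible", {
    annual <- edible_production(offtake$biomass$headline,
                                cfg$constants$edible_fraction)
    daily <- grid_map(function(v) v / cfg$constants$annual_days, annual,
                      tag = "edible_daily_kg")
    list(annual = annual, daily = daily)
  })
  stages_run <- c(stages_run, "edible")

  percap <- stage("per_capita",
                  per_capita_availability(edible$daily, offtake$apps))
  stages_run <- c(stages_run, "per_capita")

  # -- nutrition --------------------------------------------------------
  adequacy <- NULL
  if (isTRUE(cfg$nutrition$enabled)) {
    adequacy <- stage("nutrition", {
      obs_path <- cfg$nutrition$observations
      if (is.null(obs_path))
        obs_path <- system.file("extdata",
                                "wild_meat_composition_synthetic.csv",
                                package = "wildharvest", mustWork = TRUE)
      obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
      profile <- mean_nutrient_content(obs, seed = seed + 900L)
      dri <- read_dri_table(cfg$nutrition$dri)
      shares <- if (is.null(cfg$nutrition$shares))
        read_demographic_shares() else cfg$nutrition$shares
      edible_g <- grid_map(function(v) v * 1000, edible$daily,
                           tag = "edible_g_day")
      req <- requirement_surfaces(offtake$apps, shares, dri,
                                  nutrients = intersect(unique(dri$nutrient),
                                                        names(profile)))
      adequacy_percent(edible_g, profile, req)
    })
    stages_run <- c(stages_run, "nutrition")
  }

  # -- report -----------------------------------------------------------
  report <- stage("report", {
    taxon_sum <- data.frame(
      taxon_id = names(offtake$individuals$taxa),
      annual_individuals = vapply(offtake$individuals$taxa, grid_total,
                                  numeric(1L)),
      annual_biomass_kg = vapply(names(offtake$individuals$taxa), function(t)
        grid_total(offtake$biomass$taxa[[t]]$q50), numeric(1L)),
      pct_truncated_cells = vapply(offtake$individuals$truncated, function(f)
        100 * base::mean(f[!offtake$individuals$overall$mask]), numeric(1L)),
      stringsAsFactors = FALSE)
    percap_mean <- grid_total(grid_map(function(g, p) g * p / 1000, percap,
                                       offtake$apps)) /
      (grid_total(offtake$apps) / 1000)
    annual_edible <- grid_total(edible$annual)
    beef <- lapply(cfg$constants$beef_yield_kg_ha_day, function(y)
      beef_counterfactual(annual_edible, y,
                          cfg$constants$emission_t_per_km2))
    headline <- data.frame(
      quantity = c("rural_population", "rural_hunters_q50",
                   "annual_individuals", "annual_biomass_kg",
                   "annual_edible_kg", "per_capita_g_day",
                   "pasture_km2_low_yield", "pasture_km2_high_yield",
                   "co2_mt_low_yield", "co2_mt_high_yield"),
      value = c(grid_total(offtake$apps), grid_total(offtake$rhps$q50),
                grid_total(offtake$individuals$overall),
                grid_total(offtake$biomass$headline), annual_edible,
                percap_mean,
                beef[[length(beef)]]$pasture_km2, beef[[1L]]$pasture_km2,
                beef[[length(beef)]]$co2_mt, beef[[1L]]$co2_mt),
      stringsAsFactors = FALSE)

    # invariant checks
    cons <- {
      taxon_hp <- taxon_individual_hp(hp$q50, tsop_stack$stack)
      tot <- Reduce(function(a, b) grid_map(`+`, a, b), taxon_hp)
      ok <- !tot$mask
      max(abs(tot$values[ok] - hp$q50$values[ok]) /
            pmax(hp$q50$values[ok], 1e-12))
    }
    norm_dev <- {
      tot <- Reduce(function(a, b) grid_map(`+`, a, b), tsop_stack$stack)
      max(abs(tot$values[!tot$mask] - 1))
    }
    mono <- all(hp$q10$values <= hp$q25$values + 1e-12, na.rm = TRUE) &&
      all(hp$q25$values <= hp$q50$values + 1e-12, na.rm = TRUE) &&
      all(hp$q50$values <= hp$q75$values + 1e-12, na.rm = TRUE) &&
      all(hp$q75$values <= hp$q90$values + 1e-12, na.rm = TRUE)
    checks <- data.frame(
      check = c("hp_conservation_rel_dev", "tsop_norm_abs_dev",
                "quantile_monotone"),
      value = c(cons, norm_dev, as.numeric(mono)),
      pass = c(cons <= 1e-9, norm_dev <= 1e-9, mono),
      stringsAsFactors = FALSE)
    list(taxon_summary = taxon_sum, headline = headline, checks = checks)
  })
  stages_run <- c(stages_run, "report")

  manifest <- list(
    package_version = as.character(utils::packageVersion("wildharvest")),
    seed = seed,
    stages = stages_run,
    n_localities = nrow(sim$communities),
    n_taxa = nrow(taxa$traits),
    n_records = nrow(sim$records),
    n_hhr_localities = nrow(hhr$table),
    grid = dim(landscape$boundary),
    constants = cfg$constants[c("edible_fraction", "annual_days",
                                "emission_t_per_km2")]
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary_csv(report$taxon_summary,
                      file.path(output_dir, "taxon_summary.csv"))
    write_summary_csv(report$headline,
                      file.path(output_dir, "headline_summary.csv"))
    write_summary_csv(report$checks, file.path(output_dir, "checks.csv"))
    if (!is.null(adequacy))
      write_summary_csv(adequacy$summary,
                        file.path(output_dir, "adequacy_summary.csv"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_grid(hp$q50, file.path(output_dir, "hp_q50.grid"))
    write_grid(percap, file.path(output_dir, "per_capita_g_day.grid"))
  }

  invisible(list(config = cfg, sim = sim, ensemble = fit, hp = hp,
                 tsop = tsop_stack, offtake = offtake, edible = edible,
                 per_capita = percap, adequacy = adequacy, report = report,
                 manifest = manifest))
}
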