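#' Taxon-specific harvest-productivity surfaces
#'
#' Multiplies the overall individuals harvest-productivity surface cellwise
#' by each taxon's offtake proportion; by construction the taxon surfaces
#' sum back to the overall surface wherever the proportion stack is defined.
#'
#' @param overall_hp `wm_grid` of overall individuals per hunter-day.
#' @param tsop_stack named list of normalised proportion `wm_grid`s (from
#'   [assemble_tsop_stack()]).
#' @return named list of per-taxon `wm_grid`s.
#' @export
taxon_individual_hp <- function(overall_hp, tsop_stack) {
  lapply(stats::setNames(names(tsop_stack), names(tsop_stack)), function(nm)
    grid_map(`*`, overall_hp, tsop_stack[[nm]], tag = paste0("hp_", nm)))
}

#' Annual individual-animal offtake with density truncation
#'
#' Converts per-taxon harvest productivity (individuals per hunter-day) into
#' annual per-cell offtake by multiplying by the rural-hunter grid and the
#' number of days per year, then truncates each capped taxon's offtake at
#' its standing density per cell (individuals per 100 km2 on a 100 km2
#' cell). Truncation prevents overestimation where hunter density is high.
#'
#' @param taxon_hp named list of per-taxon HP `wm_grid`s.
#' @param rhps rural-hunter `wm_grid` (hunters per cell).
#' @param density_caps named numeric vector of per-cell caps (individuals
#'   per cell per year); taxa absent from the vector (or `NA`) are uncapped.
#' @param annual_days days per year (default 365).
#' @return list with `taxa` (per-taxon offtake `wm_grid`s), `overall`
#'   (summed `wm_grid`), `uncapped_overall`, and `truncated` (named list of
#'   logical matrices flagging capped cells).
#' @export
individuals_offtake <- function(taxon_hp, rhps, density_caps = NULL,
                                annual_days = 365) {
  neg <- function(g) any(g$values[!g$mask] < 0)
  if (neg(rhps) || any(vapply(taxon_hp, neg, logical(1L))))
    stop("domain error: negative HP or hunter values")
  out <- list(); trunc_flags <- list()
  uncapped_total <- NULL
  total <- NULL
  for (nm in names(taxon_hp)) {
    raw <- grid_map(function(h, r) h * r * annual_days, taxon_hp[[nm]], rhps,
                    tag = paste0("offtake_", nm))
    cap <- if (!is.null(density_caps) && nm %in% names(density_caps))
      density_caps[[nm]] else NA_real_
    if (!is.na(cap)) {
      capped <- grid_map(function(v) pmin(v, cap), raw,
                         tag = paste0("offtake_", nm))
      flags <- !capped$mask & raw$values > cap
      flags[is.na(flags)] <- FALSE
    } else {
      capped <- raw
      flags <- matrix(FALSE, nrow(raw$values), ncol(raw$values))
    }
    out[[nm]] <- capped
    trunc_flags[[nm]] <- flags
    uncapped_total <- if (is.null(uncapped_total)) raw else
      grid_map(`+`, uncapped_total, raw, tag = "offtake_uncapped")
    total <- if (is.null(total)) capped else
      grid_map(`+`, total, capped, tag = "offtake_overall")
  }
  total$tag <- "offtake_overall"
  uncapped_total$tag <- "offtake_uncapped"
  list(taxa = out, overall = total, uncapped_overall = uncapped_total,
       truncated = trunc_flags)
}

#' Biomass surfaces from individual-animal surfaces
#'
#' Multiplies each taxon's individual-animal surface by the quantiles of its
#' average body mass (kg): one biomass surface per mass quantile per taxon,
#' plus the median-mass headline surface, and the overall biomass per
#' quantile as the sum over taxa. Uncertainty is propagated quantile by
#' quantile (q10 individuals x q10 mass, etc.).
#'
#' @param individual_grids named list of per-taxon `wm_grid`s (individuals).
#' @param body_mass named list of `metric_estimate`s (kg), one per taxon.
#' @param quantile_names which mass quantiles to propagate (default the
#'   five standard ones).
#' @return list with `taxa` (per-taxon list of per-quantile `wm_grid`s),
#'   `overall` (per-quantile summed `wm_grid`s) and `headline` (the overall
#'   median-mass surface).
#' @export
biomass_surfaces <- function(individual_grids, body_mass,
                             quantile_names = c("q10", "q25", "q50", "q75",
                                                "q90")) {
  miss <- setdiff(names(individual_grids), names(body_mass))
  if (length(miss) > 0L)
    stop("trait error: body mass missing for ",
         paste(miss, collapse = ", "))
  taxa <- list(); overall <- list()
  for (nm in names(individual_grids)) {
    bm <- body_mass[[nm]]
    if (!is.finite(bm$q50) || bm$q50 <= 0)
      stop("trait error: non-positive body mass for ", nm)
    per_q <- list()
    for (q in quantile_names) {
      g <- grid_map(function(v) v * bm[[q]], individual_grids[[nm]],
                    tag = paste0("biomass_", nm, "_", q))
      per_q[[q]] <- g
      overall[[q]] <- if (is.null(overall[[q]])) g else
        grid_map(`+`, overall[[q]], g, tag = paste0("biomass_overall_", q))
    }
    taxa[[nm]] <- per_q
  }
  for (q in names(overall)) overall[[q]]$tag <- paste0("biomass_overall_", q)
  list(taxa = taxa, overall = overall, headline = overall[["q50"]])
}

#' Default edible-yield fractions by taxonomic group
#'
#' Mean +/- sd edible (consumable) fraction of undressed carcass mass for
#' the major hunted groups, compiled from carcass-yield studies.
#' @return data frame `group`, `yield_mean`, `yield_sd`.
#' @export
edible_yield_table <- function() {
  data.frame(group = c("mammal", "bird", "chelonian", "caiman"),
             yield_mean = c(0.63, 0.73, 0.47, 0.45),
             yield_sd = c(0.11, 0.06, 0.14, 0.04),
             stringsAsFactors = FALSE)
}

#' Edible wild-meat production
#'
#' Converts undressed biomass to edible meat. The headline path multiplies
#' the overall biomass surface by the pooled edible fraction (default
#' 0.585); the group-specific path applies each group's carcass yield to the
#' per-group biomass surfaces and sums.
#'
#' @param biomass `wm_grid` of undressed biomass (kg per cell per day or
#'   year — units pass through), or for the group path a named list of
#'   per-group biomass `wm_grid`s.
#' @param edible_fraction pooled fraction (default 0.585); ignored on the
#'   group path.
#' @param yields data frame as [edible_yield_table()] for the group path.
#' @return `wm_grid` of edible meat in the input units.
#' @export
edible_production <- function(biomass, edible_fraction = 0.585,
                              yields = edible_yield_table()) {
  if (is_grid(biomass)) {
    return(grid_map(function(v) v * edible_fraction, biomass,
                    tag = "edible"))
  }
  out <- NULL
  for (grp in names(biomass)) {
    y <- yields$yield_mean[match(grp, yields$group)]
    if (is.na(y)) stop("no edible yield for group '", grp, "'")
    g <- grid_map(function(v) v * y, biomass[[grp]], tag = "edible")
    out <- if (is.null(out)) g else grid_map(`+`, out, g, tag = "edible")
  }
  out$tag <- "edible"
  out
}

#' Per-capita wild-meat availability
#'
#' Divides the daily edible-meat surface (kg/day) by the rural-population
#' surface, returning grams per person per day; cells with zero (or masked)
#' rural population are masked.
#'
#' @param edible_daily `wm_grid`, kg edible meat per cell per day.
#' @param apps rural-population `wm_grid`.
#' @return `wm_grid`, g per person per day.
#' @export
per_capita_availability <- function(edible_daily, apps) {
  g <- grid_map(function(e, p) ifelse(p > 0, 1000 * e / p, NA_real_),
                edible_daily, apps, tag = "per_capita_g_day")
  g
}

#' Beef-replacement counterfactual
#'
#' Converts an annual edible-meat production into the pasture area that
#' would be needed to replace it with beef at a given pasture yield, and the
#' associated one-off deforestation CO2 emissions.
#'
#' @param annual_edible_kg annual edible production (kg/yr).
#' @param yield_kg_per_ha_day pasture beef yield (kg per hectare per day);
#'   regional traditional-pasture yields span about 0.2-0.8.
#' @param emission_t_per_km2 deforestation emission factor (tonnes CO2 per
#'   km2; default 18000).
#' @return list with `pasture_km2` and `co2_mt` (megatonnes CO2).
#' @export
beef_counterfactual <- function(annual_edible_kg, yield_kg_per_ha_day,
                                emission_t_per_km2 = 18000) {
  if (yield_kg_per_ha_day <= 0)
    stop("argument error: yield must be positive")
  area_km2 <- annual_edible_kg / (yield_kg_per_ha_day * 365 * 100)
  list(pasture_km2 = area_km2,
       co2_mt = area_km2 * emission_t_per_km2 / 1e6)
}
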