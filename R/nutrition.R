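#' Nutrients tracked by the adequacy analysis
#' @export
NUTRIENTS <- c("energy_kcal", "protein_g", "fat_g", "iron_mg", "zinc_mg",
               "selenium_ug", "vitb1_mg", "vitb2_mg", "vitb3_mg",
               "vitb12_ug")

#' Average nutrient content of wild meat
#'
#' Summarises an observation table of nutrient contents (per 100 g edible
#' meat) into one [metric_estimate()] per nutrient, propagating the standard
#' error of the mean through the Monte Carlo engine. Nutrients with no
#' observations are excluded with a warning. When a taxon grouping is
#' supplied, taxa lacking data inherit their group mean (the FAO
#' "food-matching" convention).
#'
#' @param observations data frame with columns `nutrient`, `value`, `unit`
#'   and optionally `taxon_id`. The `unit` column is mandatory; contents are
#'   per 100 g edible meat.
#' @param n_draws,seed Monte Carlo controls.
#' @return named list of `metric_estimate`s (one per nutrient present).
#' @export
mean_nutrient_content <- function(observations, n_draws = 1000L,
                                  seed = NULL) {
  need <- c("nutrient", "value", "unit")
  miss <- setdiff(need, names(observations))
  if (length(miss) > 0L)
    stop("observation table lacks columns: ", paste(miss, collapse = ", "))
  out <- list()
  for (nu in unique(observations$nutrient)) {
    x <- observations$value[observations$nutrient == nu]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      warning("nutrient '", nu, "' has no observations; excluded")
      next
    }
    out[[nu]] <- metric_from_observations(
      x, n_draws = n_draws,
      seed = if (is.null(seed)) NULL else seed + length(out), positive = TRUE)
  }
  out
}

#' Per-taxon nutrient profiles with group fallback
#'
#' Builds per-taxon nutrient profiles from an observation table; taxa with
#' no observations for a nutrient inherit the mean over their taxonomic
#' group (food matching).
#'
#' @param observations observation table with `taxon_id`, `nutrient`,
#'   `value`, `unit`.
#' @param groups data frame `taxon_id`, `group`.
#' @return named list (by taxon) of named numeric vectors of mean contents.
#' @export
taxon_nutrient_profiles <- function(observations, groups) {
  by_taxon <- split(observations, observations$taxon_id)
  group_means <- list()
  for (grp in unique(groups$group)) {
    ids <- groups$taxon_id[groups$group == grp]
    obs <- observations[observations$taxon_id %in% ids, , drop = FALSE]
    group_means[[grp]] <- tapply(obs$value, obs$nutrient, base::mean)
  }
  out <- list()
  for (i in seq_len(nrow(groups))) {
    id <- groups$taxon_id[i]; grp <- groups$group[i]
    own <- if (id %in% names(by_taxon))
      tapply(by_taxon[[id]]$value, by_taxon[[id]]$nutrient, base::mean)
    else NULL
    prof <- group_means[[grp]]
    if (!is.null(own)) prof[names(own)] <- own
    out[[id]] <- prof
  }
  out
}

#' Read the packaged dietary-reference-intake defaults
#'
#' Editable per-group requirement table (children, women, men) with the
#' rule used for each nutrient: EAR where defined, AI/RDA otherwise, the
#' AMDR midpoint for total fat (converted to g/day via the group energy
#' requirement) and EER for energy.
#'
#' @param path optional CSV path; defaults to the packaged table.
#' @return data frame `group`, `nutrient`, `value`, `unit`, `rule`.
#' @export
read_dri_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "dri_defaults.csv",
                        package = "wildharvest", mustWork = TRUE)
  dri <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "nutrient", "value", "unit", "rule")
  miss <- setdiff(need, names(dri))
  if (length(miss) > 0L)
    stop("DRI table lacks columns: ", paste(miss, collapse = ", "))
  if (any(dri$value <= 0)) stop("DRI requirements must be positive")
  if (anyDuplicated(dri[c("group", "nutrient")]))
    stop("duplicate (group, nutrient) rows in DRI table")
  dri
}

#' Read the packaged demographic shares
#'
#' Proportions of children, women and men in the rural population.
#'
#' @param path optional CSV path; defaults to the packaged table.
#' @return named numeric vector of shares summing to 1.
#' @export
read_demographic_shares <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "demographic_shares.csv",
                        package = "wildharvest", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  shares <- stats::setNames(df$share, df$group)
  if (any(shares < 0) || abs(sum(shares) - 1) > 1e-9)
    stop("demographic shares must be non-negative and sum to 1")
  shares
}

#' Minimum daily dietary-requirement surfaces
#'
#' Splits the rural-population grid into sex-age group grids by the
#' demographic shares, multiplies each by the group's per-person daily
#' requirement and sums, giving one requirement grid per nutrient (units of
#' the DRI table per cell per day). Requirements are exactly proportional to
#' the rural population.
#'
#' @param apps rural-population `wm_grid`.
#' @param shares named shares (must cover the DRI groups and sum to 1).
#' @param dri DRI table from [read_dri_table()].
#' @param nutrients nutrients to build (default: all in the table).
#' @return named list of `wm_grid`s.
#' @export
requirement_surfaces <- function(apps, shares = read_demographic_shares(),
                                 dri = read_dri_table(),
                                 nutrients = unique(dri$nutrient)) {
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1")
  out <- list()
  for (nu in nutrients) {
    per_person <- 0
    for (grp in names(shares)) {
      v <- dri$value[dri$group == grp & dri$nutrient == nu]
      if (length(v) != 1L)
        stop("table error: missing DRI entry for (", grp, ", ", nu, ")")
      per_person <- per_person + shares[[grp]] * v
    }
    out[[nu]] <- grid_map(function(p) p * per_person, apps,
                          tag = paste0("requirement_", nu))
  }
  out
}

#' Percent of dietary requirements furnished by wild meat
#'
#' Converts the edible-meat surface into per-nutrient daily supply surfaces
#' (content per 100 g x grams available) and expresses each as a percentage
#' of the corresponding requirement surface, cellwise. Cells with zero or
#' masked requirement are masked. The population-weighted summary equals
#' total supplied / total required because both totals are sums over the
#' same cells.
#'
#' @param edible_g_day `wm_grid` of edible meat in grams per cell per day.
#' @param profile named numeric vector (or list of `metric_estimate`s, whose
#'   means are used) of nutrient contents per 100 g edible meat.
#' @param requirements named list of requirement `wm_grid`s from
#'   [requirement_surfaces()].
#' @return list with `percent` (named list of `wm_grid`s, %) and `summary`
#'   (data frame `nutrient`, `supplied`, `required`, `percent`).
#' @export
adequacy_percent <- function(edible_g_day, profile, requirements) {
  content <- vapply(names(requirements), function(nu) {
    p <- profile[[nu]]
    if (is.null(p)) stop("profile lacks nutrient '", nu, "'")
    if (inherits(p, "metric_estimate")) p$mean else as.numeric(p)
  }, numeric(1L))
  percent <- list(); summary <- list()
  for (nu in names(requirements)) {
    supplied <- grid_map(function(e) e * content[[nu]] / 100, edible_g_day,
                         tag = paste0("supplied_", nu))
    req <- requirements[[nu]]
    pct <- grid_map(function(s, r) ifelse(r > 0, 100 * s / r, NA_real_),
                    supplied, req, tag = paste0("adequacy_", nu))
    percent[[nu]] <- pct
    summary[[nu]] <- data.frame(
      nutrient = nu,
      supplied = grid_total(supplied),
      required = grid_total(req),
      percent = 100 * grid_total(supplied) / grid_total(req),
      stringsAsFactors = FALSE)
  }
  list(percent = percent, summary = do.call(rbind, c(summary,
       list(make.row.names = FALSE))))
}
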