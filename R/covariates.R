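#' Default covariate epoch table
#'
#' Habitat-loss layers are available 5-yearly from 1985 to 2020; vegetation
#' index (EVI) and gross/net primary productivity from 2000 to 2020.
#'
#' @return named list of sorted integer epoch vectors.
#' @export
default_epoch_table <- function() {
  list(habitat_loss = seq(1985L, 2020L, by = 5L),
       evi = seq(2000L, 2020L, by = 5L),
       gpp = seq(2000L, 2020L, by = 5L),
       npp = seq(2000L, 2020L, by = 5L))
}

#' Match a record year to the closest covariate epoch
#'
#' Records predating the first available epoch are assigned the first epoch
#' (e.g. a 1966 record uses the 1985 habitat-loss layer), records after the
#' last epoch use the last, and years in between snap to the nearest 5-year
#' epoch (1988-1992 to 1990, and so on).
#'
#' @param year record calendar year (vectorised).
#' @param variable layer tag present in `epoch_table`.
#' @param epoch_table named list of epoch years; see
#'   [default_epoch_table()].
#' @return integer epoch year(s).
#' @export
match_epoch <- function(year, variable, epoch_table = default_epoch_table()) {
  epochs <- epoch_table[[variable]]
  if (is.null(epochs))
    stop("lookup error: no epochs known for variable '", variable, "'")
  epochs <- sort(epochs)
  vapply(year, function(y) epochs[which.min(abs(epochs - y))], integer(1L))
}

#' Derive the rural population (APPS) grid
#'
#' Removes urban cells and cells outside the study boundary from the total
#' population grid; remaining cells keep their population, urban in-boundary
#' cells are set to zero, and out-of-boundary cells are masked. The total is
#' therefore never larger than the total population.
#'
#' @param population `wm_grid` of people per cell.
#' @param urban logical matrix flagging urban cells.
#' @param boundary logical matrix flagging in-study cells.
#' @return `wm_grid` tagged `"apps"`.
#' @export
derive_apps <- function(population, urban, boundary) {
  stopifnot(inherits(population, "wm_grid"))
  if (!identical(dim(population$values), dim(urban)) ||
      !identical(dim(population$values), dim(boundary)))
    stop("alignment error: population, urban and boundary differ in shape")
  v <- grid_values(population)
  v[urban] <- 0
  v[!boundary] <- NA_real_
  wm_grid(v, tag = "apps", cell_area = population$cell_area)
}

#' Derive rural-hunter (RHPS) grids
#'
#' Multiplies the rural-population grid cellwise by each hunter-to-consumer
#' ratio quantile, yielding one hunter grid per quantile. Totals scale
#' linearly: `grid_total(rhps[[q]]) == ratio_q * grid_total(apps)`.
#'
#' @param apps APPS `wm_grid` from [derive_apps()].
#' @param ratios named numeric vector of ratios in `[0, 1)` (a degenerate 0
#'   yields an all-zero grid); defaults to the quantiles of
#'   [hunter_consumer_ratio()] with no data (0.168, 0.173, 0.178, 0.183,
#'   0.187 for q10...q90).
#' @return named list of `wm_grid`s, one per ratio.
#' @export
derive_rhps <- function(apps, ratios = NULL) {
  if (is.null(ratios)) {
    r <- hunter_consumer_ratio()
    ratios <- c(q10 = r$q10, q25 = r$q25, q50 = r$q50, q75 = r$q75,
                q90 = r$q90)
  }
  if (any(ratios < 0 | ratios >= 1))
    stop("argument error: ratios must lie in [0, 1)")
  out <- lapply(seq_along(ratios), function(i)
    grid_map(function(a) a * ratios[i], apps,
             tag = paste0("rhps_", names(ratios)[i])))
  stats::setNames(out, names(ratios))
}

#' Extract covariate features at localities
#'
#' Builds the model feature table: one row per locality and record year,
#' with time-varying layers resolved to the epoch matched to the record year
#' and categorical layers returned as integer level codes.
#'
#' @param stack named list of `wm_grid` layers; epoch variants are named
#'   `<tag>_<year>` (e.g. `habitat_loss_1990`).
#' @param localities data frame with `locality_id`, `row`, `col`.
#' @param years vector of record years, one per locality row, or a single
#'   year recycled; rows are produced for each distinct (locality, year).
#' @param epoch_table epoch lookup; see [default_epoch_table()].
#' @return data frame with `locality_id`, `year` and one column per base
#'   variable.
#' @export
extract_features <- function(stack, localities, years,
                             epoch_table = default_epoch_table()) {
  if (length(years) == 1L) years <- rep(years, nrow(localities))
  if (length(years) != nrow(localities))
    stop("years must have one entry per locality row")
  keys <- unique(data.frame(locality_id = localities$locality_id,
                            year = years, stringsAsFactors = FALSE))
  loc_idx <- match(keys$locality_id, localities$locality_id)
  rows <- localities$row[loc_idx]; cols <- localities$col[loc_idx]

  layer_names <- names(stack)
  epoch_layers <- grep("_(19|20)[0-9]{2}$", layer_names, value = TRUE)
  base_vars <- setdiff(layer_names, epoch_layers)

  out <- keys
  for (nm in base_vars) {
    g <- stack[[nm]]
    if (nm %in% names(epoch_table)) {
      ep <- match_epoch(keys$year, nm, epoch_table)
      vals <- numeric(nrow(keys))
      for (k in seq_len(nrow(keys))) {
        lname <- paste0(nm, "_", ep[k])
        gk <- if (lname %in% layer_names) stack[[lname]] else g
        vals[k] <- gk$values[rows[k], cols[k]]
      }
    } else {
      vals <- g$values[cbind(rows, cols)]
    }
    if (anyNA(vals)) {
      bad <- keys$locality_id[is.na(vals)]
      stop("extraction error: locality on masked cell of '", nm, "': ",
           paste(unique(bad), collapse = ", "))
    }
    out[[nm]] <- vals
  }
  rownames(out) <- NULL
  out
}
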