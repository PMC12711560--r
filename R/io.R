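#' Write a harvest study to disk
#'
#' Serialises a study bundle (as produced by [simulate_harvest_study()]) to
#' plain-text artifacts: `records.csv`, `efforts.csv`, `traits.csv`,
#' `communities.csv`, one tagged grid file per covariate layer under
#' `grids/`, per-taxon range masks under `ranges/`, and — when ground truth
#' is present — the true-productivity grid and generator constants under
#' `truth/`.
#'
#' @param study list with `records`, `efforts`, `taxa`, `communities`,
#'   `landscape` and optionally `ground_truth`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(study$efforts, file.path(dir, "efforts.csv"),
                   row.names = FALSE)
  utils::write.csv(study$taxa$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(study$communities, file.path(dir, "communities.csv"),
                   row.names = FALSE)
  write_stack(study$landscape$stack, file.path(dir, "grids"))
  write_grid(study$landscape$population,
             file.path(dir, "grids", "population.grid"))
  mask_grid <- function(m, tag) wm_grid(m * 1.0, tag = tag)
  write_grid(mask_grid(study$landscape$urban, "urban"),
             file.path(dir, "urban.grid"))
  write_grid(mask_grid(study$landscape$boundary, "boundary"),
             file.path(dir, "boundary.grid"))
  rdir <- file.path(dir, "ranges")
  dir.create(rdir, showWarnings = FALSE)
  for (nm in names(study$taxa$ranges))
    write_grid(mask_grid(study$taxa$ranges[[nm]], nm),
               file.path(rdir, paste0(nm, ".grid")))
  if (!is.null(study$ground_truth)) {
    tdir <- file.path(dir, "truth")
    dir.create(tdir, showWarnings = FALSE)
    write_grid(study$ground_truth$true_hp, file.path(tdir, "true_hp.grid"))
    jsonlite::write_json(
      list(true_hunter_ratio = study$ground_truth$true_hunter_ratio),
      file.path(tdir, "constants.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a harvest study written by [write_study()]
#'
#' @param dir study directory.
#' @return study list in the same shape as [simulate_harvest_study()]
#'   (without ground truth unless present on disk).
#' @export
read_study <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    stringsAsFactors = FALSE)
  stack <- read_stack(file.path(dir, "grids"))
  population <- stack[["population"]]
  stack[["population"]] <- NULL
  as_mask <- function(g) !is.na(g$values) & g$values > 0
  urban <- as_mask(read_grid(file.path(dir, "urban.grid")))
  boundary <- as_mask(read_grid(file.path(dir, "boundary.grid")))
  rfiles <- list.files(file.path(dir, "ranges"), pattern = "\\.grid$",
                       full.names = TRUE)
  ranges <- lapply(rfiles, function(f) as_mask(read_grid(f)))
  names(ranges) <- sub("\\.grid$", "", basename(rfiles))
  study <- list(
    records = rd("records.csv"), efforts = rd("efforts.csv"),
    communities = rd("communities.csv"),
    taxa = list(traits = rd("traits.csv"), ranges = ranges),
    landscape = list(stack = stack, population = population,
                     urban = urban, boundary = boundary))
  tdir <- file.path(dir, "truth")
  if (dir.exists(tdir)) {
    consts <- jsonlite::fromJSON(file.path(tdir, "constants.json"))
    study$ground_truth <- list(
      true_hp = read_grid(file.path(tdir, "true_hp.grid")),
      true_hunter_ratio = consts$true_hunter_ratio)
  }
  study
}
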