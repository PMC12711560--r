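#' The reserved taxon code for unidentifiable records
#' @export
UNDETERMINED <- "undetermined"

check_records <- function(records) {
  need <- c("locality_id", "year", "taxon_id", "n_individuals")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records table lacks columns: ", paste(miss, collapse = ", "))
  if (any(records$n_individuals < 0, na.rm = TRUE))
    stop("n_individuals must be non-negative")
  invisible(records)
}

check_efforts <- function(efforts) {
  need <- c("locality_id", "n_hunters", "span_days")
  miss <- setdiff(need, names(efforts))
  if (length(miss) > 0L)
    stop("effort table lacks columns: ", paste(miss, collapse = ", "))
  invisible(efforts)
}

#' Merge raw taxon labels into registry taxa
#'
#' Hunting records arrive under heterogeneous labels (vernacular names,
#' outdated binomials, typos). This maps each raw label onto a registry taxon
#' (or the reserved `"undetermined"` code) and merges rows, conserving the
#' total number of individuals exactly.
#'
#' @param records data frame with columns `locality_id`, `year`, `taxon_id`,
#'   `n_individuals` where `taxon_id` holds raw labels.
#' @param mapping data frame with columns `from` (raw label) and `to`
#'   (registry taxon id or `"undetermined"`).
#' @return records data frame with mapped, merged `taxon_id`.
#' @export
apply_reclassification <- function(records, mapping) {
  check_records(records)
  if (!all(c("from", "to") %in% names(mapping)))
    stop("mapping needs columns 'from' and 'to'")
  idx <- match(records$taxon_id, mapping$from)
  if (anyNA(idx)) {
    bad <- sort(unique(records$taxon_id[is.na(idx)]))
    stop("reclassification error: unmapped labels: ",
         paste(bad, collapse = ", "))
  }
  records$taxon_id <- mapping$to[idx]
  out <- stats::aggregate(
    n_individuals ~ locality_id + year + taxon_id,
    data = records, FUN = sum)
  out <- out[order(out$locality_id, out$year, out$taxon_id), ]
  rownames(out) <- NULL
  out[, c("locality_id", "year", "taxon_id", "n_individuals")]
}

#' Apply record-level study filters
#'
#' Localities reporting fewer than `min_taxa` distinct hunted taxa are
#' removed from all analyses (they carry little compositional information).
#' Localities without a usable effort row are additionally removed from the
#' harvest-rate (HHR) set but retained for composition (TSOP).
#'
#' @param records harmonised records table.
#' @param efforts effort table (`locality_id`, `n_hunters`, `span_days`);
#'   rows with non-positive hunter-days are unusable.
#' @param min_taxa minimum distinct taxa per locality (default 4).
#' @return list with `tsop_records` and `hhr_records` data frames.
#' @export
filter_studies <- function(records, efforts, min_taxa = 4L) {
  check_records(records)
  check_efforts(efforts)
  n_taxa <- tapply(records$taxon_id, records$locality_id,
                   function(x) length(unique(x)))
  keep <- names(n_taxa)[n_taxa >= min_taxa]
  tsop <- records[records$locality_id %in% keep, , drop = FALSE]
  usable <- efforts$locality_id[efforts$n_hunters > 0 & efforts$span_days > 0]
  hhr <- tsop[tsop$locality_id %in% usable, , drop = FALSE]
  rownames(tsop) <- rownames(hhr) <- NULL
  list(tsop_records = tsop, hhr_records = hhr)
}

#' Per-locality hunter harvest rate
#'
#' HHR is the total number of animals hunted at a locality divided by the
#' total monitored hunter-days (hunters x recording-span days), counting days
#' on which nothing was harvested and days on which hunters did not go out.
#' Multiple effort rows per locality are summed, so HHR is invariant to
#' splitting an effort row while conserving total hunter-days.
#'
#' @param records harmonised records table (HHR-filtered).
#' @param efforts effort table.
#' @return data frame `locality_id`, `n_individuals`, `hunter_days`, `hhr`
#'   (individuals per hunter-day).
#' @export
compute_hhr <- function(records, efforts) {
  check_records(records)
  check_efforts(efforts)
  hd <- tapply(efforts$n_hunters * efforts$span_days, efforts$locality_id, sum)
  kills <- tapply(records$n_individuals, records$locality_id, sum)
  locs <- names(hd)
  if (any(hd <= 0))
    stop("effort error: zero hunter-days at ",
         paste(locs[hd <= 0], collapse = ", "))
  k <- ifelse(locs %in% names(kills), kills[locs], 0)
  data.frame(locality_id = locs,
             n_individuals = as.numeric(k),
             hunter_days = as.numeric(hd[locs]),
             hhr = as.numeric(k / hd[locs]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-locality taxon-specific offtake proportions
#'
#' TSOP of a taxon at a locality is its hunted count divided by the locality
#' total, so each locality's proportions (including the `"undetermined"`
#' share) form a probability vector.
#'
#' @param records harmonised records table.
#' @param taxa optional character vector fixing the taxon columns (defaults
#'   to all taxa present).
#' @return matrix of proportions, localities x taxa; rows sum to 1.
#' @export
compute_tsop <- function(records, taxa = NULL) {
  check_records(records)
  if (is.null(taxa)) taxa <- sort(unique(records$taxon_id))
  locs <- sort(unique(records$locality_id))
  tab <- matrix(0, length(locs), length(taxa),
                dimnames = list(locs, taxa))
  known <- records$taxon_id %in% taxa
  if (!all(known))
    stop("records contain taxa outside the requested set: ",
         paste(unique(records$taxon_id[!known]), collapse = ", "))
  for (i in seq_len(nrow(records)))
    tab[records$locality_id[i], records$taxon_id[i]] <-
      tab[records$locality_id[i], records$taxon_id[i]] + records$n_individuals[i]
  tot <- rowSums(tab)
  if (any(tot <= 0))
    stop("undefined TSOP: zero total harvest at ",
         paste(locs[tot <= 0], collapse = ", "))
  tab / tot
}

#' Hunter-to-consumer ratio summary
#'
#' Summarises per-locality hunters/consumers ratios by their median and 0.10,
#' 0.25, 0.75, 0.90 quantiles. When no data are supplied the published
#' continental constants are returned (median 0.178; quantiles 0.168, 0.173,
#' 0.183, 0.187), which is the default multiplier set used to derive rural
#' hunter grids from rural population grids.
#'
#' @param communities optional data frame with columns `n_hunters` and
#'   `n_consumers`, one row per locality. Localities with zero consumers are
#'   dropped with a warning.
#' @return a `metric_estimate` of the ratio.
#' @export
hunter_consumer_ratio <- function(communities = NULL) {
  if (is.null(communities)) {
    return(metric_estimate(mean = 0.178, sd = 0.008,
                           q10 = 0.168, q25 = 0.173, q50 = 0.178,
                           q75 = 0.183, q90 = 0.187))
  }
  if (!all(c("n_hunters", "n_consumers") %in% names(communities)))
    stop("communities needs columns n_hunters and n_consumers")
  zero <- communities$n_consumers == 0
  if (any(zero)) {
    warning(sum(zero), " localities with zero consumers excluded")
    communities <- communities[!zero, , drop = FALSE]
  }
  if (nrow(communities) == 0L) stop("no usable localities")
  r <- communities$n_hunters / communities$n_consumers
  metric_estimate_from_draws(r)
}
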