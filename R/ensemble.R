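#' Which stack layers are categorical by default
#' @keywords internal
default_categorical <- function()
  c("language_hist", "indigenous", "language_curr", "urca")

# coerce categorical columns of a feature frame to factors with fixed levels
apply_factor_levels <- function(df, xlevels) {
  for (nm in names(xlevels)) {
    if (!nm %in% names(df)) next
    v <- as.character(df[[nm]])
    unseen <- !(v %in% xlevels[[nm]]) & !is.na(v)
    if (any(unseen)) {
      # unseen level codes collapse onto the modal training level
      v[unseen] <- xlevels[[nm]][1L]
    }
    df[[nm]] <- factor(v, levels = xlevels[[nm]])
  }
  df
}

#' Fit a subsampled random-forest ensemble for harvest productivity
#'
#' Fits the harvest-rate model: an ensemble of `n_members` regression
#' forests, each trained on a seeded random subsample (without replacement)
#' of `subsample_fraction` of the observations, plus one full-data forest
#' used for the permutation-importance ranking. Spatial prediction
#' summarises the member predictions cellwise at the 0.10, 0.25, 0.50, 0.75
#' and 0.90 quantiles (see [predict_hp()]).
#'
#' @param formula model formula, e.g. `hhr ~ .`; the response is the
#'   per-locality harvest rate and the right-hand side the covariates
#'   (include the recording-span effort covariate for harvest-rate models).
#' @param data training data frame; categorical covariates must be factors.
#' @param n_members number of ensemble members (default 30).
#' @param subsample_fraction fraction of rows per member, in (0, 1]
#'   (default 0.70).
#' @param n_trees trees per forest (default 500).
#' @param quantiles member-summary quantiles (sorted).
#' @param seed base seed; member `i` uses `seed + i`.
#' @return an object of class `hp_ensemble` with components `members`
#'   (list of `randomForest` fits), `full_model`, `importance` (data frame
#'   ranked by permutation importance), `xlevels`, `spec` and `call`.
#' @seealso [predict_hp()], [fit_predict_tsop()]
#' @export
hp_ensemble <- function(formula, data, n_members = 30L,
                        subsample_fraction = 0.70, n_trees = 500L,
                        quantiles = c(0.10, 0.25, 0.50, 0.75, 0.90),
                        seed = 1L) {
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    stop("subsample_fraction must be in (0, 1]")
  if (is.unsorted(quantiles)) stop("quantiles must be sorted")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  if (nrow(mf) < 20L)
    stop("at least 20 training rows are required")
  response <- mf[[1L]]
  if (stats::var(response) == 0)
    warning("constant response: ensemble is valid but degenerate")
  n_sub <- max(2L, ceiling(subsample_fraction * nrow(mf)))
  terms <- stats::terms(mf)

  # a constant response is legal degenerate input; muffle the engine's
  # few-unique-values regression warning for it
  quiet_rf <- function(...) withCallingHandlers(
    randomForest::randomForest(...),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    set.seed(seed + i)
    idx <- sample.int(nrow(data), n_sub)
    members[[i]] <- quiet_rf(formula, data = data[idx, , drop = FALSE],
                             ntree = n_trees)
  }
  set.seed(seed)
  full <- quiet_rf(formula, data = data, ntree = n_trees,
                   importance = TRUE)
  imp <- randomForest::importance(full, type = 1L, scale = TRUE)
  importance <- data.frame(variable = rownames(imp),
                           importance = imp[, 1L],
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), ]
  importance$rank <- seq_len(nrow(importance))
  rownames(importance) <- NULL

  xlevels <- lapply(Filter(is.factor, mf[-1L]), levels)
  structure(
    list(members = members, full_model = full, importance = importance,
         xlevels = xlevels, terms = terms,
         training_medians = vapply(
           Filter(is.numeric, mf[-1L]), stats::median, numeric(1L)),
         spec = list(n_members = n_members,
                     subsample_fraction = subsample_fraction,
                     n_trees = n_trees, quantiles = quantiles, seed = seed),
         call = match.call()),
    class = "hp_ensemble")
}

#' @export
print.hp_ensemble <- function(x, ...) {
  cat("Subsampled random-forest harvest-productivity ensemble\n")
  cat(sprintf("  %d members x %d trees, %.0f%% subsamples (seed %d)\n",
              x$spec$n_members, x$spec$n_trees,
              100 * x$spec$subsample_fraction, x$spec$seed))
  cat("  top covariates by permutation importance:\n")
  top <- utils::head(x$importance, 5L)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %d. %s (%.2f)\n", top$rank[i], top$variable[i],
                top$importance[i]))
  invisible(x)
}

#' @export
summary.hp_ensemble <- function(object, ...) {
  out <- list(spec = object$spec, importance = object$importance,
              oob_mse = utils::tail(object$full_model$mse, 1L))
  class(out) <- "summary.hp_ensemble"
  out
}

#' @export
print.summary.hp_ensemble <- function(x, ...) {
  cat(sprintf("hp_ensemble: %d members, OOB MSE %.5g\n",
              x$spec$n_members, x$oob_mse))
  print(x$importance)
  invisible(x)
}

#' Per-member predictions on new data
#'
#' @param object an `hp_ensemble`.
#' @param newdata data frame of covariates.
#' @param ... unused.
#' @return numeric matrix, rows = `nrow(newdata)`, one column per member.
#' @export
predict.hp_ensemble <- function(object, newdata, ...) {
  newdata <- apply_factor_levels(newdata, object$xlevels)
  preds <- vapply(object$members,
                  function(m) as.numeric(stats::predict(m, newdata)),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1L)
  preds
}

# data frame of covariates for every jointly unmasked cell of a stack
stack_feature_frame <- function(stack, vars, categorical = default_categorical()) {
  miss <- setdiff(vars, names(stack))
  if (length(miss) > 0L)
    stop("feature-mismatch error: stack lacks layers: ",
         paste(miss, collapse = ", "))
  masks <- lapply(stack[vars], `[[`, "mask")
  ok <- !Reduce(`|`, masks)
  cells <- which(ok)
  df <- as.data.frame(lapply(stack[vars], function(g) g$values[cells]))
  names(df) <- vars
  for (nm in intersect(vars, categorical)) df[[nm]] <- as.character(df[[nm]])
  list(frame = df, cells = cells, dim = dim(stack[[vars[1L]]]$values),
       cell_area = stack[[vars[1L]]]$cell_area)
}

#' Quantile prediction surface
#'
#' Summarises per-cell member predictions into the five quantile grids
#' (q10, q25, q50, q75, q90) and derives the mean, standard deviation and a
#' 90% interval (q10-q90) from that five-grid stack.
#'
#' @param member_matrix cells x members prediction matrix.
#' @param cells linear cell indices into the lattice.
#' @param dims lattice dimensions `c(nr, nc)`.
#' @param cell_area cell area in km2.
#' @param tag surface name.
#' @param quantiles probability levels (must be the standard five).
#' @return object of class `quantile_surface`: named list of `wm_grid`s
#'   `q10`, `q25`, `q50`, `q75`, `q90`, `mean`, `sd`, `ci_lo`, `ci_hi`.
#' @export
quantile_surface <- function(member_matrix, cells, dims, cell_area = 100,
                             tag = "hp",
                             quantiles = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  qm <- t(apply(member_matrix, 1L, stats::quantile, probs = quantiles,
                names = FALSE, type = 7))
  if (length(cells) == 1L) qm <- matrix(qm, nrow = 1L)
  qnames <- paste0("q", round(100 * quantiles))
  empty <- function() matrix(NA_real_, dims[1L], dims[2L])
  out <- list()
  for (j in seq_along(qnames)) {
    v <- empty(); v[cells] <- pmax(0, qm[, j])
    out[[qnames[j]]] <- wm_grid(v, tag = paste0(tag, "_", qnames[j]),
                                cell_area = cell_area)
  }
  five <- vapply(qnames, function(q) out[[q]]$values[cells],
                 numeric(length(cells)))
  if (length(cells) == 1L) five <- matrix(five, nrow = 1L)
  mk <- function(vals, suffix) {
    v <- empty(); v[cells] <- vals
    wm_grid(v, tag = paste0(tag, "_", suffix), cell_area = cell_area)
  }
  out$mean <- mk(rowMeans(five), "mean")
  out$sd <- mk(apply(five, 1L, stats::sd), "sd")
  out$ci_lo <- out$q10
  out$ci_hi <- out$q90
  structure(out, class = "quantile_surface", tag = tag)
}

#' @export
print.quantile_surface <- function(x, ...) {
  cat(sprintf("<quantile_surface '%s'>\n", attr(x, "tag")))
  for (nm in c("q10", "q50", "q90")) {
    v <- x[[nm]]$values[!x[[nm]]$mask]
    cat(sprintf("  %s: mean %.5g over %d cells\n", nm, base::mean(v),
                length(v)))
  }
  invisible(x)
}

#' Predict the harvest-productivity surface
#'
#' Predicts each ensemble member over every jointly unmasked cell of the
#' covariate stack and summarises members cellwise into a
#' [quantile_surface()]. The recording-span effort covariate (a nuisance
#' control) is fixed at a reference value — by default the training-set
#' median — so that predictions are comparable across cells.
#'
#' @param ensemble an [hp_ensemble()].
#' @param stack named list of `wm_grid` covariate layers.
#' @param span_var name of the recording-span covariate, or `NULL` if the
#'   model has none.
#' @param span_value reference value for `span_var`; defaults to the
#'   training median.
#' @param categorical names of categorical layers.
#' @return a `quantile_surface` (individuals per hunter-day).
#' @export
predict_hp <- function(ensemble, stack, span_var = "span_days",
                       span_value = NULL,
                       categorical = default_categorical()) {
  vars <- attr(ensemble$terms, "term.labels")
  stack_vars <- setdiff(vars, span_var)
  sf <- stack_feature_frame(stack, stack_vars, categorical)
  df <- sf$frame
  if (!is.null(span_var) && span_var %in% vars) {
    if (is.null(span_value)) span_value <- ensemble$training_medians[[span_var]]
    df[[span_var]] <- span_value
  }
  preds <- stats::predict(ensemble, df)
  quantile_surface(preds, sf$cells, sf$dim, cell_area = sf$cell_area,
                   tag = "hp", quantiles = ensemble$spec$quantiles)
}

#' Assemble the training rows for one taxon's offtake-proportion model
#'
#' Rows are localities where the taxon was recorded (response = its observed
#' offtake proportion) plus explicit zero rows for localities inside the
#' taxon's range where other hunting was recorded but this taxon was not.
#' Localities recording both the taxon and its enclosing higher taxon are
#' excluded (nested-taxon exclusion), since the higher-taxon records would
#' siphon counts away and bias the proportion downward. Out-of-range
#' localities with no records of the taxon contribute nothing.
#'
#' @param tsop locality x taxon proportion matrix from [compute_tsop()].
#' @param taxon_id taxon being modelled.
#' @param range logical range matrix for the taxon.
#' @param localities data frame with `locality_id`, `row`, `col`.
#' @param features feature data frame with a `locality_id` column (one row
#'   per locality).
#' @param registry optional data frame `taxon_id`, `parent_id` used for
#'   nested-taxon exclusion.
#' @return data frame: `features` columns plus a `tsop` response.
#' @export
build_tsop_training <- function(tsop, taxon_id, range, localities, features,
                                registry = NULL) {
  if (!taxon_id %in% colnames(tsop))
    stop("taxon '", taxon_id, "' absent from the TSOP matrix")
  locs <- rownames(tsop)
  resp <- tsop[, taxon_id]

  drop <- rep(FALSE, length(locs))
  if (!is.null(registry)) {
    parent <- registry$parent_id[match(taxon_id, registry$taxon_id)]
    if (!is.na(parent) && nzchar(parent) && parent %in% colnames(tsop))
      drop <- resp > 0 & tsop[, parent] > 0
  }

  li <- match(locs, localities$locality_id)
  in_range <- range[cbind(localities$row[li], localities$col[li])]
  keep <- !drop & (resp > 0 | in_range)

  fi <- match(locs[keep], features$locality_id)
  if (anyNA(fi))
    stop("features missing for localities: ",
         paste(locs[keep][is.na(fi)], collapse = ", "))
  out <- features[fi, setdiff(names(features), c("locality_id", "year")),
                  drop = FALSE]
  out$tsop <- resp[keep]
  rownames(out) <- NULL
  out
}

#' Fit and spatially predict one taxon's offtake proportion
#'
#' A single seeded regression forest of the taxon's offtake proportion on
#' the covariates (no recording-span covariate), predicted over the stack
#' and clipped to [0, 1]. Taxa with fewer than `min_rows` training rows are
#' flagged unmodelled and fall back to a constant surface at the training
#' mean.
#'
#' @param training data frame from [build_tsop_training()] with a `tsop`
#'   response column.
#' @param stack covariate stack.
#' @param n_trees trees (default 500).
#' @param seed seed.
#' @param min_rows minimum training rows before the constant fallback.
#' @param categorical names of categorical layers.
#' @return a `wm_grid` of proportions with attribute `modelled`
#'   (`TRUE`/`FALSE`).
#' @export
fit_predict_tsop <- function(training, stack, n_trees = 500L, seed = 1L,
                             min_rows = 10L,
                             categorical = default_categorical()) {
  vars <- setdiff(names(training), "tsop")
  sf <- stack_feature_frame(stack, vars, categorical)
  dims <- sf$dim
  v <- matrix(NA_real_, dims[1L], dims[2L])
  modelled <- FALSE
  if (nrow(training) >= min_rows && stats::var(training$tsop) > 0) {
    df <- training
    for (nm in intersect(vars, categorical))
      df[[nm]] <- factor(as.character(df[[nm]]))
    xlev <- lapply(Filter(is.factor, df[vars]), levels)
    set.seed(seed)
    fit <- randomForest::randomForest(tsop ~ ., data = df, ntree = n_trees)
    newdata <- apply_factor_levels(sf$frame, xlev)
    v[sf$cells] <- pmin(1, pmax(0, as.numeric(stats::predict(fit, newdata))))
    modelled <- TRUE
  } else {
    v[sf$cells] <- if (nrow(training) > 0L) base::mean(training$tsop) else 0
  }
  g <- wm_grid(v, tag = "tsop_raw", cell_area = sf$cell_area)
  attr(g, "modelled") <- modelled
  g
}

#' Clip, renormalise and mask the per-taxon proportion stack
#'
#' Sets each taxon's raw proportion surface to zero outside its range, then
#' renormalises cellwise so the proportions over all taxa sum to one; cells
#' where every in-range raw proportion is zero (or no taxon is in range) are
#' masked in every layer.
#'
#' @param surfaces named list of raw proportion `wm_grid`s (one per taxon).
#' @param ranges named list of logical range matrices aligned with
#'   `surfaces`.
#' @return list with `stack` (named list of normalised `wm_grid`s) and
#'   `masked` (logical matrix of zero-sum cells).
#' @export
assemble_tsop_stack <- function(surfaces, ranges) {
  if (length(surfaces) == 0L) stop("at least one surface is required")
  nms <- names(surfaces)
  dims <- dim(surfaces[[1L]]$values)
  total <- matrix(0, dims[1L], dims[2L])
  clipped <- list()
  for (nm in nms) {
    v <- grid_values(surfaces[[nm]], masked_as = 0)
    if (!is.null(ranges[[nm]])) v[!ranges[[nm]]] <- 0
    clipped[[nm]] <- v
    total <- total + v
  }
  base_mask <- Reduce(`&`, lapply(surfaces, `[[`, "mask"))
  zero <- total <= 0 & !base_mask
  out <- list()
  for (nm in nms) {
    v <- clipped[[nm]]
    pos <- total > 0
    v[pos] <- v[pos] / total[pos]
    v[zero | base_mask] <- NA_real_
    out[[nm]] <- wm_grid(v, tag = paste0("tsop_", nm),
                         cell_area = surfaces[[nm]]$cell_area)
  }
  list(stack = out, masked = zero)
}
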