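#' Lattice grid container
#'
#' A `wm_grid` is a 2D lattice of cell values on the analysis grid (nominal
#' 10 x 10 km cells, 100 km2 each) with an explicit no-data mask, a layer tag,
#' and an optional level registry for categorical layers stored as integer
#' codes.
#'
#' @param values numeric matrix of cell values. `NA` entries are treated as
#'   missing and added to the mask.
#' @param mask logical matrix the same shape as `values`; `TRUE` marks a
#'   no-data cell. Defaults to `is.na(values)`.
#' @param tag character scalar naming the layer (e.g. `"evi"`, `"apps"`).
#' @param cell_area cell area in km2; the analysis default is 100.
#' @param levels optional named integer vector mapping level labels to the
#'   integer codes stored in `values` (categorical layers only).
#' @return an object of class `wm_grid`.
#' @examples
#' g <- wm_grid(matrix(1:12, 3, 4), tag = "elevation")
#' grid_values(g)
#' @export
wm_grid <- function(values, mask = NULL, tag = "layer", cell_area = 100,
                    levels = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("mask must be a logical matrix with the same dimensions as values")
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0)
    stop("cell_area must be a positive scalar")
  structure(
    list(values = values, mask = mask, tag = as.character(tag)[1L],
         cell_area = as.numeric(cell_area), levels = levels),
    class = "wm_grid"
  )
}

#' @export
print.wm_grid <- function(x, ...) {
  d <- dim(x$values)
  obs <- sum(!x$mask)
  cat(sprintf("<wm_grid '%s'> %d x %d cells (%d observed), %.0f km2/cell\n",
              x$tag, d[1L], d[2L], obs, x$cell_area))
  if (obs > 0L) {
    rng <- range(x$values[!x$mask])
    cat(sprintf("  range: [%.6g, %.6g]  total: %.6g\n",
                rng[1L], rng[2L], sum(x$values[!x$mask])))
  }
  if (!is.null(x$levels))
    cat("  levels:", paste(names(x$levels), x$levels, sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.wm_grid <- function(x) dim(x$values)

#' Extract the value matrix of a grid
#'
#' @param g a `wm_grid`.
#' @param masked_as value substituted at masked cells (default `NA`).
#' @return numeric matrix.
#' @export
grid_values <- function(g, masked_as = NA_real_) {
  stopifnot(inherits(g, "wm_grid"))
  v <- g$values
  if (!is.na(masked_as)) v[g$mask] <- masked_as
  v
}

#' Sum of observed cell values
#' @param g a `wm_grid`.
#' @return scalar total over unmasked cells.
#' @export
grid_total <- function(g) sum(g$values[!g$mask])

is_grid <- function(x) inherits(x, "wm_grid")

#' Cellwise arithmetic on aligned grids
#'
#' Applies a function cellwise over one or more aligned grids (or scalars);
#' the result is masked wherever any grid argument is masked.
#'
#' @param f vectorised function of the value matrices.
#' @param ... `wm_grid` objects and/or numeric scalars.
#' @param tag tag for the result.
#' @return a `wm_grid`.
#' @export
grid_map <- function(f, ..., tag = "derived") {
  args <- list(...)
  grids <- Filter(is_grid, args)
  if (length(grids) == 0L) stop("at least one wm_grid argument is required")
  check_aligned(grids)
  mask <- Reduce(`|`, lapply(grids, `[[`, "mask"))
  vals <- lapply(args, function(a) if (is_grid(a)) a$values else a)
  out <- do.call(f, vals)
  wm_grid(out, mask = mask, tag = tag, cell_area = grids[[1L]]$cell_area)
}

check_aligned <- function(grids) {
  d <- dim(grids[[1L]]$values)
  ok <- vapply(grids, function(g) identical(dim(g$values), d), logical(1L))
  if (!all(ok))
    stop("alignment error: grids do not share a common lattice")
  invisible(TRUE)
}

#' Fill missing cells by iterative neighbour averaging
#'
#' Each masked cell with at least one observed 8-neighbour is replaced by the
#' mean of its observed neighbours; the pass is repeated until no cell changes
#' state or `max_pass` passes have run. Observed cells are never altered and
#' filled values obey the maximum principle (they stay inside the observed
#' range). Cells never reached (e.g. fully detached) remain masked.
#'
#' @param g a `wm_grid`.
#' @param max_pass maximum number of filling passes (default 50).
#' @return a `wm_grid` with (partially) filled mask.
#' @export
gap_fill <- function(g, max_pass = 50L) {
  stopifnot(inherits(g, "wm_grid"))
  v <- g$values
  m <- g$mask
  nr <- nrow(v); nc <- ncol(v)
  for (pass in seq_len(max_pass)) {
    if (!any(m)) break
    # neighbour sums/counts via shifted copies (8-connectivity)
    obs <- !m
    vv <- v; vv[m] <- 0
    s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
      keep_r <- rs >= 1L & rs <= nr; keep_c <- cs >= 1L & cs <= nc
      s[keep_r, keep_c] <- s[keep_r, keep_c] +
        vv[rs[keep_r], cs[keep_c], drop = FALSE]
      n[keep_r, keep_c] <- n[keep_r, keep_c] +
        obs[rs[keep_r], cs[keep_c], drop = FALSE]
    }
    fill <- m & n > 0
    if (!any(fill)) break
    v[fill] <- s[fill] / n[fill]
    m[fill] <- FALSE
  }
  wm_grid(v, mask = m, tag = g$tag, cell_area = g$cell_area,
          levels = g$levels)
}

#' Write a grid to a tagged ASCII file
#'
#' Grids are serialised to a self-describing text format: a JSON header line
#' (tag, dimensions, cell area, level registry) followed by one row of
#' `%.17g`-formatted values per lattice row, with masked cells written as
#' `NA`. `%.17g` round-trips double precision exactly, so
#' `read_grid(write_grid(g, p))` reproduces `g` bit-for-bit.
#'
#' @param g a `wm_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path) {
  stopifnot(inherits(g, "wm_grid"))
  header <- jsonlite::toJSON(
    list(format = "wm_grid", version = 1L, tag = g$tag,
         n_rows = nrow(g$values), n_cols = ncol(g$values),
         cell_area = g$cell_area,
         levels = if (is.null(g$levels)) NULL else as.list(g$levels)),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  fmt <- function(row) {
    out <- sprintf("%.17g", row)
    out[is.na(row)] <- "NA"
    paste(out, collapse = "\t")
  }
  writeLines(apply(g$values, 1L, fmt), con)
  invisible(path)
}

#' Read a grid written by [write_grid()]
#'
#' @param path file path.
#' @return a `wm_grid`.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[[1L]])
  if (!identical(header$format, "wm_grid"))
    stop("not a wm_grid file: ", path)
  body <- lines[-1L]
  if (length(body) != header$n_rows)
    stop("corrupt grid file (row count mismatch): ", path)
  vals <- t(vapply(strsplit(body, "\t", fixed = TRUE),
                   function(x) as.numeric(ifelse(x == "NA", NA, x)),
                   numeric(header$n_cols)))
  if (header$n_rows == 1L) vals <- matrix(vals, nrow = 1L)
  levels <- header$levels
  if (!is.null(levels)) levels <- unlist(levels)
  wm_grid(vals, tag = header$tag, cell_area = header$cell_area,
          levels = levels)
}

#' Write or read a named stack of grids
#'
#' One file per layer (`<tag>.grid`) under `dir`.
#'
#' @param stack named list of `wm_grid` objects.
#' @param dir directory path.
#' @return `dir` (write) or a named list of grids (read), invisibly for write.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(stack)) write_grid(stack[[nm]], file.path(dir, paste0(nm, ".grid")))
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\.grid$", full.names = TRUE)
  stack <- lapply(files, read_grid)
  names(stack) <- sub("\\.grid$", "", basename(files))
  stack
}
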