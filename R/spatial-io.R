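#' Read and write ESRI ASCII grid rasters
#'
#' Single-band rasters are exchanged as ESRI ASCII grids (`.asc`): a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of cell values from the top row down.
#' Nodata cells are read as `NA` and written as the nodata value.
#'
#' @param path file path.
#' @param x numeric matrix (`NA` for missing cells).
#' @param xll,yll coordinates of the lower-left grid corner, meters.
#' @param cell_size cell edge length in meters.
#' @param nodata value standing for missing cells on disk.
#' @return `read_ascii_grid` returns a numeric matrix with attributes
#'   `xll`, `yll`, `cell_size`; `write_ascii_grid` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  hdr_lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in hdr_lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2L])))) break
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    n_hdr <- n_hdr + 1L
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing header fields): ", path)
  }
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  I <- as.integer(hdr$nrows)
  J <- as.integer(hdr$ncols)
  if (length(vals) != I * J) {
    stop("raster ", path, ": expected ", I * J, " cells, found ", length(vals))
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  x <- matrix(vals, nrow = I, ncol = J, byrow = TRUE)
  attr(x, "xll") <- hdr$xllcorner
  attr(x, "yll") <- hdr$yllcorner
  attr(x, "cell_size") <- hdr$cellsize
  x
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(x, path, xll = 0, yll = 0, cell_size = 50,
                             nodata = -9999) {
  x <- as.matrix(x)
  if (any(!is.na(x) & x == nodata)) {
    stop("grid contains the nodata value ", nodata, " as a data value")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(x)),
    paste("nrows", nrow(x)),
    paste("xllcorner", format(xll, scientific = FALSE)),
    paste("yllcorner", format(yll, scientific = FALSE)),
    paste("cellsize", format(cell_size, scientific = FALSE)),
    paste("NODATA_value", format(nodata, scientific = FALSE))
  ), con)
  y <- x
  y[is.na(y)] <- nodata
  utils::write.table(y, con,
    sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

grid_georef <- function(x) {
  c(xll = attr(x, "xll") %||% 0, yll = attr(x, "yll") %||% 0,
    cell_size = attr(x, "cell_size") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read aligned raster layers into an attribute stack
#'
#' Reads named attribute layers plus optional mask, zone, and
#' conservation-status rasters, verifying that every grid shares the shape,
#' origin, and cell size of the first layer.
#'
#' @param layer_files named character vector of raster paths.
#' @param mask_file,zones_file,conserved_file optional raster paths. The
#'   mask and conserved rasters are interpreted as 0/1; zones as integer
#'   labels.
#' @return An [attribute_stack()].
#' @export
read_stack <- function(layer_files, mask_file = NULL, zones_file = NULL,
                       conserved_file = NULL) {
  if (length(layer_files) == 0L || is.null(names(layer_files))) {
    stop("layer_files must be a named vector of paths")
  }
  layers <- lapply(layer_files, read_ascii_grid)
  ref <- layers[[1L]]
  ref_geo <- grid_georef(ref)
  check_aligned <- function(g, what) {
    geo <- grid_georef(g)
    if (!all(dim(g) == dim(ref)) || any(abs(geo - ref_geo) > 1e-6)) {
      stop("raster '", what, "' is not aligned with '", names(layer_files)[1L], "'")
    }
    g
  }
  for (nm in names(layers)) check_aligned(layers[[nm]], nm)
  mask <- if (!is.null(mask_file)) {
    m <- check_aligned(read_ascii_grid(mask_file), "mask")
    !is.na(m) & m != 0
  } else {
    NULL
  }
  zones <- if (!is.null(zones_file)) check_aligned(read_ascii_grid(zones_file), "zones")
  conserved <- if (!is.null(conserved_file)) {
    cg <- check_aligned(read_ascii_grid(conserved_file), "conserved")
    !is.na(cg) & cg != 0
  }
  attribute_stack(
    lapply(layers, function(g) {
      attributes(g)[c("xll", "yll", "cell_size")] <- NULL
      g
    }),
    mask = mask, zones = zones, conserved = conserved,
    cell_size = ref_geo[["cell_size"]],
    origin = c(ref_geo[["xll"]], ref_geo[["yll"]])
  )
}

#' Place Pareto ranks back on the grid
#'
#' Builds a rank raster from a ranking of a decision matrix whose
#' alternative ids are row-major cell indices of `stack`. Ranked cells carry
#' their positive integer rank; unranked (invalid) and out-of-mask cells are
#' `NA`.
#'
#' @param x the [decision_matrix()] that was ranked.
#' @param ranks the [pareto_rank()] result for `x`.
#' @param stack the [attribute_stack()] the matrix was built from.
#' @return An integer matrix of class `rank_grid` with georeference
#'   attributes.
#' @export
ranks_to_grid <- function(x, ranks, stack) {
  stopifnot(inherits(ranks, "pareto_ranking"), inherits(stack, "attribute_stack"))
  x <- as_decision_matrix(x)
  ids <- as.integer(x$ids)
  n_cells <- prod(stack$grid_shape)
  if (anyNA(ids) || any(ids < 1L) || any(ids > n_cells)) {
    stop("alternative ids do not map to cell indices of the stack")
  }
  pos <- match(x$ids, ranks$ids)
  if (anyNA(pos)) stop("ranking does not cover the decision matrix ids")
  flat <- rep(NA_integer_, n_cells) # row-major
  flat[ids] <- ranks$rank[pos]
  grid <- t(matrix(flat, nrow = stack$grid_shape[2L], ncol = stack$grid_shape[1L]))
  grid[!stack$mask] <- NA_integer_
  structure(grid,
    class = c("rank_grid", class(grid)),
    xll = stack$origin[1L], yll = stack$origin[2L], cell_size = stack$cell_size
  )
}

#' Write / read a rank raster
#'
#' Rank rasters are integer ESRI ASCII grids; since ranks start at 1,
#' nodata defaults to 0.
#'
#' @param x a `rank_grid` (or integer matrix).
#' @param path file path.
#' @param nodata nodata value, default 0.
#' @return `write_rank_grid` returns `path` invisibly; `read_rank_grid`
#'   returns a `rank_grid`.
#' @export
write_rank_grid <- function(x, path, nodata = 0) {
  write_ascii_grid(unclass(x), path,
    xll = attr(x, "xll") %||% 0, yll = attr(x, "yll") %||% 0,
    cell_size = attr(x, "cell_size") %||% 50, nodata = nodata
  )
}

#' @rdname write_rank_grid
#' @export
read_rank_grid <- function(path) {
  g <- read_ascii_grid(path)
  storage.mode(g) <- "integer"
  class(g) <- c("rank_grid", class(g))
  g
}

#' Rank-percentile threshold
#'
#' The smallest rank value `t` such that at least a fraction `q` of ranked
#' cells have rank `<= t` (nearest-rank rule on the empirical CDF). Because
#' Pareto ranks are small integers with massive ties, this always returns an
#' attained rank; cells with rank `<= t` are classified as top priority.
#'
#' @param ranks a `pareto_ranking`, `rank_grid`, or numeric vector of ranks
#'   (`NA`s ignored).
#' @param q percentile as a fraction in (0, 1); default 0.25.
#' @return Integer rank threshold.
#' @export
percentile_threshold <- function(ranks, q = 0.25) {
  if (inherits(ranks, "pareto_ranking")) ranks <- ranks$rank
  r <- as.vector(ranks)
  r <- r[!is.na(r)]
  if (length(r) == 0L) stop("no ranked cells")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("q must be a single fraction in (0, 1)")
  }
  as.integer(sort(r)[ceiling(q * length(r))])
}

#' Zonal summary of priority cells
#'
#' Classifies ranked cells as top priority when their rank is at or below
#' the `q`-percentile threshold (computed once over all ranked cells of this
#' rank grid), then tabulates counts and percentages within each
#' (zone, conservation status) stratum present on the grid.
#'
#' @param rank_grid a `rank_grid` (or integer matrix of ranks with `NA`s).
#' @param zones matrix of zone labels aligned with `rank_grid`.
#' @param conserved logical matrix aligned with `rank_grid`, or `NULL` to
#'   summarize by zone alone.
#' @param q percentile fraction for the threshold; default 0.25.
#' @param threshold optional explicit rank threshold, overriding `q` (e.g. a
#'   threshold computed globally across several rank grids).
#' @return A data frame of class `zone_summary` with columns `zone`,
#'   `conserved`, `n_cells`, `n_at_or_below`, `percent`, plus attributes
#'   `threshold` and `q`.
#' @export
zonal_summary <- function(rank_grid, zones, conserved = NULL, q = 0.25,
                          threshold = NULL) {
  r <- as.vector(unclass(rank_grid))
  if (!all(dim(as.matrix(zones)) == dim(rank_grid))) {
    stop("'zones' grid is misaligned with the rank grid")
  }
  z <- as.vector(as.matrix(zones))
  cons <- if (is.null(conserved)) {
    rep(NA, length(r))
  } else {
    as.vector(as_grid(conserved, dim(rank_grid), "conserved"))
  }
  ranked <- !is.na(r)
  if (!any(ranked & !is.na(z))) stop("no ranked cells overlap the zone layer")
  if (is.null(threshold)) threshold <- percentile_threshold(r[ranked], q)
  keep <- ranked & !is.na(z) & (is.null(conserved) | !is.na(cons))
  strata <- if (is.null(conserved)) {
    factor(z[keep])
  } else {
    interaction(z[keep], cons[keep], drop = TRUE, sep = "\r")
  }
  n_cells <- as.integer(table(strata))
  n_below <- as.integer(tapply(r[keep] <= threshold, strata, sum))
  lev <- levels(strata)
  if (is.null(conserved)) {
    zone <- lev
    cons_col <- rep(NA, length(lev))
  } else {
    parts <- strsplit(lev, "\r", fixed = TRUE)
    zone <- vapply(parts, `[`, character(1), 1L)
    cons_col <- as.logical(vapply(parts, `[`, character(1), 2L))
  }
  out <- data.frame(
    zone = zone, conserved = cons_col, n_cells = n_cells,
    n_at_or_below = n_below, percent = 100 * n_below / n_cells
  )
  out <- out[order(out$zone, out$conserved), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    class = c("zone_summary", "data.frame"),
    threshold = threshold, q = q
  )
}

#' Median rank per grid row or column
#'
#' Profiles the ranking along one grid axis, e.g. median rank per northing
#' to show how priority varies from south to north. Nodata cells are
#' ignored; lines with no ranked cells yield `NA`.
#'
#' @param rank_grid a `rank_grid` (or integer matrix with `NA`s).
#' @param axis `"row"` (profile down the rows) or `"column"`.
#' @return Numeric vector of per-line medians.
#' @export
median_rank_profile <- function(rank_grid, axis = c("row", "column")) {
  axis <- match.arg(axis)
  if (length(rank_grid) == 0L) stop("empty grid")
  m <- unclass(rank_grid)
  apply(m, if (axis == "row") 1L else 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
}
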