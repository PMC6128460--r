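#' Count overlapping fire perimeters
#'
#' Sums a set of aligned binary fire-perimeter rasters to give the number of
#' recorded fires per cell over the period covered by the perimeter layers.
#'
#' @param perimeter_layers list of aligned binary (0/1) matrices, one per
#'   fire (or fire year); `NA` allowed and propagated.
#' @return Numeric matrix of per-cell fire counts.
#' @export
count_overlapping_fires <- function(perimeter_layers) {
  if (!is.list(perimeter_layers) || length(perimeter_layers) == 0L) {
    stop("need at least one perimeter layer")
  }
  dims <- dim(as.matrix(perimeter_layers[[1L]]))
  out <- matrix(0, dims[1L], dims[2L])
  for (p in perimeter_layers) {
    p <- as_grid(p, dims, "fire perimeter")
    check_binary(p, "fire perimeter")
    out <- out + p
  }
  out
}

check_binary <- function(x, what) {
  v <- x[!is.na(x)]
  if (any(v != 0 & v != 1)) stop(what, " layer must be binary (0/1)")
  invisible(TRUE)
}

# offsets (di, dj) of cells whose centers lie within `radius` of the focal
# cell center, for square cells of edge `cell_size`
circular_offsets <- function(radius, cell_size) {
  r_cells <- radius / cell_size
  d <- floor(r_cells)
  di <- rep(-d:d, each = 2L * d + 1L)
  dj <- rep(-d:d, times = 2L * d + 1L)
  keep <- (di^2 + dj^2) <= r_cells^2
  cbind(di = di[keep], dj = dj[keep])
}

# sum of `x` over the circular window centered on each cell; out-of-grid
# positions contribute 0 (the companion count of in-grid positions is
# obtained by passing a matrix of ones)
focal_circular_sum <- function(x, offsets) {
  I <- nrow(x)
  J <- ncol(x)
  out <- matrix(0, I, J)
  for (o in seq_len(nrow(offsets))) {
    di <- offsets[o, 1L]
    dj <- offsets[o, 2L]
    i_lo <- max(1L, 1L - di) # focal rows with an in-grid source cell
    i_hi <- min(I, I - di)
    j_lo <- max(1L, 1L - dj)
    j_hi <- min(J, J - dj)
    if (i_lo > i_hi || j_lo > j_hi) next
    si <- i_lo:i_hi
    sj <- j_lo:j_hi
    out[si, sj] <- out[si, sj] + x[si + di, sj + dj, drop = FALSE]
  }
  out
}

#' Focal density within a circular window
#'
#' For each cell, the proportion of grid cells whose centers lie within
#' `radius` meters of the focal cell's center that carry the indicator (used
#' for road density with a 500 m radius). At grid borders the denominator
#' counts only in-grid cells, so the output is always a proportion in
#' `[0, 1]`. `NA` indicator cells count as 0.
#'
#' @param indicator binary (0/1) matrix.
#' @param radius window radius in meters.
#' @param cell_size cell edge length in meters; must not exceed `radius`.
#' @return Numeric matrix of proportions.
#' @export
focal_density <- function(indicator, radius, cell_size = 50) {
  indicator <- as.matrix(indicator)
  check_binary(indicator, "indicator")
  if (radius < cell_size) stop("radius must be at least one cell")
  offsets <- circular_offsets(radius, cell_size)
  ind0 <- indicator
  ind0[is.na(ind0)] <- 0
  n_in <- focal_circular_sum(matrix(1, nrow(indicator), ncol(indicator)), offsets)
  focal_circular_sum(ind0, offsets) / n_in
}

#' Development density
#'
#' Combined urban and agricultural development within a circular window:
#' `(n_urban + ag_weight * n_agriculture) / n_total`, where counts are taken
#' over the cells whose centers fall within `radius` of the focal cell
#' center and `n_total` counts all in-grid window cells. Agriculture is
#' down-weighted (default 0.3) because it degrades habitat less severely
#' than urban cover.
#'
#' @param urban,agriculture aligned binary (0/1) matrices; a cell may not be
#'   both urban and agriculture.
#' @param radius window radius in meters.
#' @param cell_size cell edge length in meters.
#' @param ag_weight non-negative weight on agriculture cells.
#' @return Numeric matrix in `[0, 1]` (for `ag_weight <= 1`).
#' @export
development_density <- function(urban, agriculture, radius, cell_size = 50,
                                ag_weight = 0.3) {
  urban <- as.matrix(urban)
  agriculture <- as_grid(agriculture, dim(urban), "agriculture")
  check_binary(urban, "urban")
  check_binary(agriculture, "agriculture")
  if (!is.numeric(ag_weight) || ag_weight < 0) stop("ag_weight must be >= 0")
  both <- !is.na(urban) & !is.na(agriculture) & urban == 1 & agriculture == 1
  if (any(both)) stop("urban and agriculture layers overlap in ", sum(both), " cell(s)")
  if (radius < cell_size) stop("radius must be at least one cell")
  offsets <- circular_offsets(radius, cell_size)
  u0 <- urban
  u0[is.na(u0)] <- 0
  a0 <- agriculture
  a0[is.na(a0)] <- 0
  n_in <- focal_circular_sum(matrix(1, nrow(urban), ncol(urban)), offsets)
  (focal_circular_sum(u0, offsets) + ag_weight * focal_circular_sum(a0, offsets)) / n_in
}

#' Habitat fragment (patch) area
#'
#' Labels connected components of open (non-blocking, in-mask) cells and
#' assigns each open cell the total area of its patch in hectares. Blocking
#' cells — typically roads plus urban cover — and out-of-mask cells are
#' missing in the output. Open cells are connected through edge-sharing
#' neighbors by default (4-connectivity), so a rasterized road line that is
#' only diagonally contiguous still severs patches.
#'
#' @param blocking binary (0/1) matrix; 1 blocks patch continuity. `NA`
#'   treated as blocking.
#' @param cell_size cell edge length in meters.
#' @param mask optional logical matrix restricting the analysis area.
#' @param connectivity 4 (edge neighbors) or 8 (edge + corner neighbors).
#' @return Numeric matrix of patch areas in hectares (`NA` on blocking or
#'   out-of-mask cells).
#' @export
patch_area <- function(blocking, cell_size = 50, mask = NULL, connectivity = 4) {
  blocking <- as.matrix(blocking)
  check_binary(blocking, "blocking")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  I <- nrow(blocking)
  J <- ncol(blocking)
  open <- !is.na(blocking) & blocking == 0
  if (!is.null(mask)) open <- open & as_grid(mask, dim(blocking), "mask")
  if (!any(open)) stop("all cells are blocking: no patches to label")

  comp <- label_components(open, connectivity)
  sizes <- tabulate(comp[open])
  out <- matrix(NA_real_, I, J)
  out[open] <- sizes[comp[open]] * cell_size^2 / 1e4
  out
}

# connected-component labels over TRUE cells of `open`; returns an integer
# matrix (0 where !open). Components found via igraph on the adjacency
# graph of open cells.
label_components <- function(open, connectivity = 4) {
  I <- nrow(open)
  J <- ncol(open)
  idx <- matrix(seq_len(I * J), I, J)
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- vector("list", length(shifts))
  for (s in seq_along(shifts)) {
    di <- shifts[[s]][1L]
    dj <- shifts[[s]][2L]
    ri <- seq_len(I - di)
    rj <- if (dj >= 0L) seq_len(J - dj) else seq.int(1L - dj, J)
    a <- open[ri, rj, drop = FALSE] & open[ri + di, rj + dj, drop = FALSE]
    edges[[s]] <- cbind(idx[ri, rj, drop = FALSE][a], idx[ri + di, rj + dj, drop = FALSE][a])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, I * J - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comp <- matrix(0L, I, J)
  comp[open] <- match(memb[idx[open]], unique(memb[idx[open]]))
  comp
}

#' Stacked species-distribution-model richness
#'
#' Sums per-species habitat-suitability surfaces into a taxon-level
#' relative-richness index. In continuous mode the suitabilities (each in
#' `[0, 1]`) are summed directly; in thresholded mode each surface is first
#' converted to a binary predicted-presence map (`suitability >= threshold`)
#' and the presences are summed, as done for plant SDMs with
#' species-specific presence thresholds.
#'
#' @param suitability list of aligned matrices with values in `[0, 1]`.
#' @param thresholds optional numeric vector, one threshold per species
#'   layer; `NULL` for continuous summation.
#' @return Numeric matrix in `[0, length(suitability)]`; `NA` where any
#'   layer is missing.
#' @export
stack_sdm_richness <- function(suitability, thresholds = NULL) {
  if (!is.list(suitability) || length(suitability) == 0L) {
    stop("need at least one suitability layer")
  }
  dims <- dim(as.matrix(suitability[[1L]]))
  if (!is.null(thresholds) && length(thresholds) != length(suitability)) {
    stop("need one threshold per suitability layer")
  }
  out <- matrix(0, dims[1L], dims[2L])
  for (s in seq_along(suitability)) {
    layer <- as_grid(suitability[[s]], dims, paste0("suitability[", s, "]"))
    v <- layer[!is.na(layer)]
    if (any(v < 0 | v > 1)) stop("suitability values must lie in [0, 1]")
    if (!is.null(thresholds)) layer <- (layer >= thresholds[s]) * 1
    out <- out + layer
  }
  out
}
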