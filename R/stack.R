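#' Construct an attribute stack
#'
#' An attribute stack bundles aligned per-cell attribute layers with the
#' analysis mask and optional ancillary grids: a categorical zone layer
#' (e.g. climate zones used for summarization) and a logical
#' conservation-status layer. All grids are `rows x cols` matrices on a
#' common georeferenced grid. Cells are identified by the row-major index
#' `k = (i - 1) * cols + j`.
#'
#' @param layers named list of numeric matrices (missing cells `NA`).
#' @param mask logical matrix, `TRUE` for cells inside the analysis area;
#'   defaults to all cells.
#' @param zones matrix of zone labels (character/factor/integer), or `NULL`.
#' @param conserved logical matrix of conservation status, or `NULL`.
#' @param cell_size cell edge length in meters.
#' @param origin numeric `(x, y)` of the lower-left corner, meters.
#' @return An object of class `attribute_stack`.
#' @export
attribute_stack <- function(layers, mask = NULL, zones = NULL, conserved = NULL,
                            cell_size = 50, origin = c(0, 0)) {
  if (!is.list(layers) || length(layers) == 0L || is.null(names(layers)) ||
    any(names(layers) == "")) {
    stop("layers must be a non-empty named list of matrices")
  }
  dims <- dim(layers[[1L]])
  for (nm in names(layers)) {
    layers[[nm]] <- as_grid(layers[[nm]], dims, nm)
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1L], dims[2L])
  mask <- as_grid(mask, dims, "mask")
  mask <- !is.na(mask) & mask
  if (!is.null(zones)) {
    if (!all(dim(zones) == dims)) stop("'zones' grid is misaligned with the layers")
  }
  if (!is.null(conserved)) conserved <- as_grid(conserved, dims, "conserved")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("cell_size must be a positive number (meters)")
  }
  structure(
    list(
      layers = layers, mask = mask, zones = zones, conserved = conserved,
      grid_shape = dims, cell_size = cell_size, origin = as.numeric(origin)
    ),
    class = "attribute_stack"
  )
}

as_grid <- function(x, dims, what) {
  x <- as.matrix(x)
  if (!all(dim(x) == dims)) {
    stop("grid '", what, "' is misaligned: expected ", dims[1L], "x", dims[2L],
      ", got ", nrow(x), "x", ncol(x))
  }
  x
}

#' @export
print.attribute_stack <- function(x, ...) {
  cat(sprintf(
    "Attribute stack: %d x %d grid (%.0f m cells), %d layer(s), %d in-mask cells\n",
    x$grid_shape[1L], x$grid_shape[2L], x$cell_size, length(x$layers), sum(x$mask)
  ))
  cat("Layers:", paste(names(x$layers), collapse = ", "), "\n")
  if (!is.null(x$zones)) {
    cat("Zones:", paste(sort(unique(as.vector(x$zones[x$mask]))), collapse = ", "), "\n")
  }
  if (!is.null(x$conserved)) {
    cat(sprintf("Conserved: %d cells\n", sum(x$conserved & x$mask, na.rm = TRUE)))
  }
  invisible(x)
}

# row-major cell ids k = (i-1)*J + j for an I x J grid
cell_ids <- function(stack) seq_len(prod(stack$grid_shape))

# convert row-major cell ids back to (i, j) grid subscripts
cell_subscripts <- function(ids, grid_shape) {
  ids <- as.integer(ids)
  J <- grid_shape[2L]
  cbind(i = (ids - 1L) %/% J + 1L, j = (ids - 1L) %% J + 1L)
}
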