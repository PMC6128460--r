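#' Synthetic primitive landscape inputs
#'
#' Generates the primitive raster inputs upstream of attribute derivation:
#' binary fire-perimeter layers (one per fire), a rasterized road network,
#' disjoint urban and agriculture cover, per-species habitat-suitability
#' surfaces for four taxa, and continuous surfaces standing in for
#' externally modeled layers (ignition probability, fire return interval
#' departure, genetic diversity and divergence), plus mask, zones, and
#' conservation status. Purely synthetic: blobs and lines with plausible
#' spatial structure, not an ecological model.
#'
#' @param rows,cols grid dimensions.
#' @param n_fires number of fire-perimeter layers.
#' @param n_species named integer vector of species counts per taxon, e.g.
#'   `c(plant = 8, herp = 5, bird = 3, mamm = 4)`.
#' @param n_roads number of straight road transects.
#' @param n_zones number of vertical zone bands.
#' @param seed integer seed.
#' @param cell_size cell edge length in meters.
#' @return A list of class `synthetic_landscape` with elements
#'   `fire_perimeters` (list of binary matrices), `roads`, `urban`,
#'   `agriculture` (binary matrices), `suitability` (list of lists of
#'   matrices per taxon), `pr_ign`, `frid`, `divers`, `diverg` (continuous
#'   matrices), `mask`, `zones`, `conserved`, `cell_size`.
#' @export
synthetic_landscape <- function(rows = 100, cols = 100, n_fires = 6,
                                n_species = c(plant = 8, herp = 5, bird = 3, mamm = 4),
                                n_roads = 6, n_zones = 4, seed = 1,
                                cell_size = 50) {
  set.seed(as.integer(seed))
  blob <- function(threshold) {
    smooth_grid(matrix(stats::rnorm(rows * cols), rows, cols), passes = 3L) > threshold
  }
  field01 <- function() {
    f <- smooth_grid(matrix(stats::rnorm(rows * cols), rows, cols), passes = 2L)
    (f - min(f)) / (max(f) - min(f))
  }

  fire_perimeters <- lapply(seq_len(n_fires), function(f) blob(0.25) * 1)

  roads <- matrix(0, rows, cols)
  for (r in seq_len(n_roads)) {
    if (r %% 2L == 0L) {
      i <- sample.int(rows, 1L)
      drift <- cumsum(sample(c(-1L, 0L, 1L), cols, replace = TRUE))
      ii <- pmin(pmax(i + drift, 1L), rows)
      roads[cbind(ii, seq_len(cols))] <- 1
    } else {
      j <- sample.int(cols, 1L)
      drift <- cumsum(sample(c(-1L, 0L, 1L), rows, replace = TRUE))
      jj <- pmin(pmax(j + drift, 1L), cols)
      roads[cbind(seq_len(rows), jj)] <- 1
    }
  }

  urban <- blob(0.45)
  agriculture <- blob(0.45) & !urban
  urban <- urban * 1
  agriculture <- agriculture * 1

  suitability <- lapply(n_species, function(n) {
    lapply(seq_len(n), function(s) field01())
  })

  mask <- matrix(TRUE, rows, cols)
  mask[blob(0.9)] <- FALSE # water bodies etc.
  zones <- matrix(
    paste0("zone", rep(ceiling(seq_len(cols) / (cols / n_zones)), each = rows)),
    rows, cols
  )
  structure(
    list(
      fire_perimeters = fire_perimeters, roads = roads, urban = urban,
      agriculture = agriculture, suitability = suitability,
      pr_ign = field01(), frid = 2 - 6 * field01(), # departure in [-4, 2]
      divers = field01(), diverg = field01(),
      mask = mask, zones = zones, conserved = blob(0),
      cell_size = cell_size
    ),
    class = "synthetic_landscape"
  )
}

#' Derive the standard attribute stack from primitive inputs
#'
#' Applies the attribute derivations to primitive landscape rasters: fire
#' counts from stacked perimeters, road density and development density in a
#' circular focal window, road-free non-urban patch area, and per-taxon
#' richness from stacked species-distribution surfaces (plant surfaces
#' thresholded, other taxa summed continuously). Externally modeled layers
#' (`pr_ign`, `frid`, `divers`, `diverg`) are forwarded as-is.
#'
#' @param land a [synthetic_landscape()] (or any list with the same
#'   elements).
#' @param radius focal window radius in meters (default 500).
#' @param ag_weight weight on agriculture cells in development density.
#' @param plant_threshold suitability threshold(s) for plant
#'   predicted-presence maps; recycled over plant layers.
#' @param urban_blocks_patches should urban cells, in addition to roads,
#'   sever habitat patches? Default `TRUE`.
#' @param connectivity patch connectivity, 4 or 8.
#' @return An [attribute_stack()] with the twelve standard layers.
#' @export
derive_attributes <- function(land, radius = 500, ag_weight = 0.3,
                              plant_threshold = 0.5,
                              urban_blocks_patches = TRUE, connectivity = 4) {
  cs <- land$cell_size %||% 50
  blocking <- if (urban_blocks_patches) {
    pmax(land$roads, land$urban)
  } else {
    land$roads
  }
  n_plant <- length(land$suitability$plant)
  layers <- list(
    nfires = count_overlapping_fires(land$fire_perimeters),
    pr_ign = land$pr_ign,
    frid = land$frid,
    road = focal_density(land$roads, radius, cs),
    dev = development_density(land$urban, land$agriculture, radius, cs, ag_weight),
    patch = patch_area(blocking, cs, mask = land$mask, connectivity = connectivity),
    plant = stack_sdm_richness(land$suitability$plant,
      thresholds = rep_len(plant_threshold, n_plant)),
    herp = stack_sdm_richness(land$suitability$herp),
    bird = stack_sdm_richness(land$suitability$bird),
    mamm = stack_sdm_richness(land$suitability$mamm),
    divers = land$divers,
    diverg = land$diverg
  )
  attribute_stack(layers,
    mask = land$mask, zones = land$zones, conserved = land$conserved,
    cell_size = cs
  )
}
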