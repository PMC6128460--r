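#' Simulate a decision matrix with equicorrelated criteria
#'
#' Draws `n_units` criteria vectors from an `n_criteria`-dimensional
#' Gaussian with unit variances and constant pairwise correlation `rho`,
#' then maps each column to `[0, 1]` with the order-preserving value
#' function. Used to study how the range of Pareto ranks depends on the
#' number of criteria, their correlation, and the number of units.
#'
#' @param n_units number of alternatives K (>= 2).
#' @param n_criteria number of criteria M (>= 1).
#' @param rho pairwise correlation; must satisfy
#'   `-1 / (n_criteria - 1) < rho <= 1` for a valid correlation matrix
#'   (ignored when `n_criteria == 1`).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return A [decision_matrix()] with ids `1:n_units`.
#' @export
simulate_criteria <- function(n_units, n_criteria, rho = 0, seed = 1) {
  if (n_units < 2L) stop("n_units must be at least 2")
  if (n_criteria < 1L) stop("n_criteria must be at least 1")
  M <- as.integer(n_criteria)
  K <- as.integer(n_units)
  if (M > 1L) {
    lower <- -1 / (M - 1)
    if (rho <= lower || rho > 1) {
      stop(sprintf(
        "rho = %g is infeasible for %d criteria (need %g < rho <= 1)",
        rho, M, lower
      ))
    }
  }
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(K * M), nrow = K, ncol = M)
  X <- if (M == 1L) {
    Z
  } else if (rho == 1) {
    Z[, rep(1L, M), drop = FALSE]
  } else if (rho == 0) {
    Z
  } else {
    sigma <- matrix(rho, M, M)
    diag(sigma) <- 1
    Z %*% chol(sigma)
  }
  X <- apply(X, 2L, value_fn_f)
  decision_matrix(X, ids = seq_len(K), criteria = paste0("c", seq_len(M)))
}

#' Rank-range simulation experiment
#'
#' For every combination of `n_units`, `n_criteria`, and `rho`, simulates
#' criteria matrices, Pareto-ranks them, and records the maximum assigned
#' rank (the range of ranks, since ranks are contiguous from 1). The range
#' tends to grow with correlation and shrink with the number of criteria:
#' negatively correlated or numerous criteria make dominance rare, piling
#' units onto few ranks.
#'
#' @param n_units,n_criteria,rho vectors of configuration values; the
#'   experiment grid is their full factorial crossing (infeasible
#'   `rho`/`n_criteria` pairs are dropped).
#' @param n_replicates replicates per configuration.
#' @param seed integer base seed; all randomness derives from it (replicates
#'   use consecutive offsets).
#' @return An object of class `rank_range_experiment`: list with
#'   `replicates` (one row per run: configuration, replicate, `max_rank`)
#'   and `summary` (per configuration: `mean_max_rank`, `sd_max_rank`).
#' @export
rank_range_experiment <- function(n_units = 1000, n_criteria = 2,
                                  rho = c(-0.9, 0, 0.9), n_replicates = 20,
                                  seed = 1) {
  grid <- expand.grid(
    n_units = n_units, n_criteria = n_criteria, rho = rho,
    KEEP.OUT.ATTRS = FALSE
  )
  feasible <- grid$n_criteria == 1L | grid$rho > -1 / pmax(grid$n_criteria - 1, 1)
  grid <- grid[feasible & grid$rho <= 1, , drop = FALSE]
  if (nrow(grid) == 0L) stop("no feasible configuration in the grid")
  rows <- vector("list", nrow(grid) * n_replicates)
  n <- 0L
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(n_replicates)) {
      n <- n + 1L
      X <- simulate_criteria(
        grid$n_units[g], grid$n_criteria[g], grid$rho[g],
        seed = seed + (g - 1L) * n_replicates + r
      )
      rows[[n]] <- cbind(grid[g, , drop = FALSE], replicate = r,
        max_rank = pareto_rank(X)$max_rank)
    }
  }
  reps <- do.call(rbind, rows)
  rownames(reps) <- NULL
  agg <- stats::aggregate(max_rank ~ n_units + n_criteria + rho, data = reps,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary_df <- data.frame(
    agg[, c("n_units", "n_criteria", "rho")],
    mean_max_rank = agg$max_rank[, "mean"],
    sd_max_rank = agg$max_rank[, "sd"]
  )
  summary_df <- summary_df[order(summary_df$n_units, summary_df$n_criteria, summary_df$rho), ]
  rownames(summary_df) <- NULL
  structure(list(replicates = reps, summary = summary_df),
    class = "rank_range_experiment"
  )
}

#' @export
print.rank_range_experiment <- function(x, ...) {
  cat("Rank-range experiment:",
    nrow(x$summary), "configuration(s),",
    max(x$replicates$replicate), "replicate(s) each\n")
  print(x$summary, ...)
  invisible(x)
}

# light smoothing by repeated 3x3 box means (reflecting borders) to give
# random layers spatial structure
smooth_grid <- function(x, passes = 2L) {
  for (p in seq_len(passes)) {
    xp <- x[c(1L, seq_len(nrow(x)), nrow(x)), c(1L, seq_len(ncol(x)), ncol(x))]
    acc <- matrix(0, nrow(x), ncol(x))
    for (di in 0:2) {
      for (dj in 0:2) {
        acc <- acc + xp[di + seq_len(nrow(x)), dj + seq_len(ncol(x))]
      }
    }
    x <- acc / 9
  }
  x
}

#' Synthetic attribute stack
#'
#' Generates an aligned stack of correlated random attribute layers with
#' controllable inter-layer correlation, random missing cells, contiguous
#' zone bands, and a spatially blocky conservation-status layer — a
#' fixture emulating the structure (not the ecology) of a real landscape
#' stack. Layers are equicorrelated Gaussian fields, lightly smoothed so
#' neighboring cells resemble each other.
#'
#' @param rows,cols grid dimensions (>= 2 each).
#' @param n_layers number of attribute layers; when 12, layers take the
#'   standard attribute names (`nfires`, `pr_ign`, `frid`, `road`, `dev`,
#'   `patch`, `plant`, `herp`, `bird`, `mamm`, `divers`, `diverg`) so the
#'   standard presets apply.
#' @param rho pairwise inter-layer correlation (per cell, before smoothing).
#' @param missing_fraction fraction of in-mask cells given a missing value
#'   in one random layer.
#' @param n_zones number of contiguous vertical zone bands.
#' @param seed integer seed.
#' @param cell_size cell edge length in meters.
#' @param layer_names optional explicit layer names.
#' @return An [attribute_stack()].
#' @export
synthetic_stack <- function(rows, cols, n_layers = 12, rho = 0.3,
                            missing_fraction = 0, n_zones = 4, seed = 1,
                            cell_size = 50, layer_names = NULL) {
  if (rows < 2L || cols < 2L) stop("grid must be at least 2 x 2")
  if (n_layers < 1L) stop("need at least one layer")
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  if (n_zones < 1L || n_zones > cols) stop("n_zones must be in 1..cols")
  if (is.null(layer_names)) {
    layer_names <- if (n_layers == 12L) {
      names(standard_directions)
    } else {
      sprintf("layer%02d", seq_len(n_layers))
    }
  }
  if (length(layer_names) != n_layers) stop("need one name per layer")
  M <- as.integer(n_layers)
  if (M > 1L && (rho <= -1 / (M - 1) || rho > 1)) {
    stop("rho infeasible for ", M, " layers")
  }
  set.seed(as.integer(seed))
  K <- rows * cols
  Z <- matrix(stats::rnorm(K * M), K, M)
  if (M > 1L && rho != 0) {
    if (rho == 1) {
      Z <- Z[, rep(1L, M), drop = FALSE]
    } else {
      sigma <- matrix(rho, M, M)
      diag(sigma) <- 1
      Z <- Z %*% chol(sigma)
    }
  }
  layers <- lapply(seq_len(M), function(m) {
    smooth_grid(matrix(Z[, m], rows, cols))
  })
  names(layers) <- layer_names

  # analysis mask: full grid minus one random rectangular hole (~2% of cells)
  mask <- matrix(TRUE, rows, cols)
  hi <- max(2L, round(rows * 0.15))
  hj <- max(2L, round(cols * 0.15))
  i0 <- sample.int(rows - hi + 1L, 1L)
  j0 <- sample.int(cols - hj + 1L, 1L)
  mask[i0:(i0 + hi - 1L), j0:(j0 + hj - 1L)] <- FALSE

  if (missing_fraction > 0) {
    in_mask <- which(mask)
    n_miss <- round(missing_fraction * length(in_mask))
    holes <- sample(in_mask, n_miss)
    which_layer <- sample.int(M, n_miss, replace = TRUE)
    for (m in seq_len(M)) {
      layers[[m]][holes[which_layer == m]] <- NA_real_
    }
  }

  zones <- matrix(
    paste0("zone", rep(ceiling(seq_len(cols) / (cols / n_zones)), each = rows)),
    rows, cols
  )
  conserved <- smooth_grid(matrix(stats::rnorm(K), rows, cols), passes = 3L) > 0

  attribute_stack(layers,
    mask = mask, zones = zones, conserved = conserved,
    cell_size = cell_size
  )
}
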