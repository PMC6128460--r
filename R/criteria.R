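#' Linear min-max value functions
#'
#' Transform a raw attribute column into a criterion on `[0, 1]` where lower
#' values mean higher priority. `value_fn_f` is the order-preserving form
#' `(a - min(a)) / (max(a) - min(a))`, used for attributes whose *low*
#' values warrant attention (e.g. fire return interval departure, fragment
#' area). `value_fn_g` is the order-reversing form
#' `(max(a) - a) / (max(a) - min(a))`, used for attributes whose *high*
#' values warrant attention (fire counts, road density, species richness,
#' ...). For any non-constant column, `value_fn_f(a) + value_fn_g(a) == 1`
#' elementwise.
#'
#' Minima and maxima are computed over non-missing entries only; missing
#' values stay missing. A constant column carries no preference information:
#' it is mapped to all zeros with a warning.
#'
#' @param a numeric vector of attribute values, possibly with `NA`s.
#' @return Numeric vector in `[0, 1]` with `NA`s preserved.
#' @examples
#' value_fn_f(c(0, 5, 10)) # 0.0 0.5 1.0
#' value_fn_g(c(0, 5, 10)) # 1.0 0.5 0.0
#' @export
value_fn_f <- function(a) {
  rng <- attr_range(a)
  if (rng[1L] == rng[2L]) {
    warning("constant attribute column: criterion carries no preference, mapped to 0")
    return(ifelse(is.na(a), NA_real_, 0))
  }
  (a - rng[1L]) / (rng[2L] - rng[1L])
}

#' @rdname value_fn_f
#' @export
value_fn_g <- function(a) {
  rng <- attr_range(a)
  if (rng[1L] == rng[2L]) {
    warning("constant attribute column: criterion carries no preference, mapped to 0")
    return(ifelse(is.na(a), NA_real_, 0))
  }
  (rng[2L] - a) / (rng[2L] - rng[1L])
}

attr_range <- function(a) {
  a <- as.numeric(a)
  ok <- !is.na(a)
  if (!any(ok)) stop("attribute column is entirely missing")
  if (any(!is.finite(a[ok]))) stop("attribute values must be finite or missing")
  range(a[ok])
}

#' Criteria specification
#'
#' Pairs attribute-layer names with preference directions.
#' `direction = "higher_is_priority"` applies the order-reversing value
#' function [value_fn_g()] (large attribute -> small criterion);
#' `direction = "lower_is_priority"` applies the order-preserving
#' [value_fn_f()].
#'
#' @param attribute character vector of attribute-layer names.
#' @param direction character vector, each `"higher_is_priority"` or
#'   `"lower_is_priority"`; recycled if length 1.
#' @return A data frame of class `criteria_spec` with columns `attribute`
#'   and `direction`.
#' @export
criteria_spec <- function(attribute, direction) {
  direction <- rep_len(direction, length(attribute))
  ok <- direction %in% c("higher_is_priority", "lower_is_priority")
  if (!all(ok)) stop("direction must be 'higher_is_priority' or 'lower_is_priority'")
  structure(
    data.frame(attribute = as.character(attribute), direction = direction),
    class = c("criteria_spec", "data.frame")
  )
}

# direction registry for the twelve standard attributes: threats and
# biodiversity are priorities when high, except FRID (more-negative departure
# = more excess fire) and fragment area (small patches = more fragmented)
standard_directions <- c(
  nfires = "higher_is_priority",
  pr_ign = "higher_is_priority",
  frid = "lower_is_priority",
  road = "higher_is_priority",
  dev = "higher_is_priority",
  patch = "lower_is_priority",
  plant = "higher_is_priority",
  herp = "higher_is_priority",
  bird = "higher_is_priority",
  mamm = "higher_is_priority",
  divers = "higher_is_priority",
  diverg = "higher_is_priority"
)

criteria_blocks <- list(
  F = c("nfires", "pr_ign", "frid"),
  H = c("road", "dev", "patch"),
  S = c("plant", "herp", "bird", "mamm"),
  G = c("divers", "diverg")
)

#' Named presets for the standard decision matrices
#'
#' The six standard decision matrices combine blocks of related criteria:
#' fire threat `F' = (nfires, pr_ign, frid)`, fragmentation threat
#' `H' = (road, dev, patch)`, species richness
#' `S' = (plant, herp, bird, mamm)`, and genetic biodiversity
#' `G' = (divers, diverg)`. Presets are named by their blocks: `"FS"`,
#' `"HS"`, `"FG"`, `"HG"`, `"FSG"`, `"HSG"`.
#'
#' @param name preset name, e.g. `"FS"` for the fire + species matrix.
#' @return A [criteria_spec()].
#' @seealso [composite_presets()] for the standard composite pairings.
#' @export
criteria_preset <- function(name) {
  name <- toupper(gsub("[^A-Za-z]", "", name))
  presets <- names(criteria_presets_table())
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; available: ", paste(presets, collapse = ", "))
  }
  attrs <- criteria_presets_table()[[name]]
  criteria_spec(attrs, standard_directions[attrs])
}

criteria_presets_table <- function() {
  b <- criteria_blocks
  list(
    FS = c(b$F, b$S), HS = c(b$H, b$S),
    FG = c(b$F, b$G), HG = c(b$H, b$G),
    FSG = c(b$F, b$S, b$G), HSG = c(b$H, b$S, b$G)
  )
}

#' Standard composite pairings
#'
#' The three standard composite Pareto rankings pair the fire-based and
#' fragmentation-based matrices that share their biodiversity block:
#' `r[r(F'|S') | r(H'|S')]`, `r[r(F'|G') | r(H'|G')]`, and
#' `r[r(F'|S'|G') | r(H'|S'|G')]`.
#'
#' @return Named list of character vectors of preset names.
#' @export
composite_presets <- function() {
  list(
    FS_HS = c("FS", "HS"),
    FG_HG = c("FG", "HG"),
    FSG_HSG = c("FSG", "HSG")
  )
}

#' Build a decision matrix from an attribute stack
#'
#' Extracts the requested attribute layers for every in-mask cell, applies
#' the direction-appropriate value function per column (normalization
#' statistics are computed over in-mask non-missing cells only), and flags a
#' cell invalid — excluded from ranking — if any of its criteria is missing.
#' Alternative ids are row-major cell indices `k = (i - 1) * ncols + j`.
#'
#' @param stack an [attribute_stack()].
#' @param specs a [criteria_spec()] (or anything coercible: a named
#'   character vector of directions, or a preset name for
#'   [criteria_preset()]).
#' @return A [decision_matrix()] with one row per in-mask cell.
#' @export
build_decision_matrix <- function(stack, specs) {
  stopifnot(inherits(stack, "attribute_stack"))
  if (is.character(specs) && length(specs) == 1L && is.null(names(specs))) {
    specs <- criteria_preset(specs)
  } else if (!inherits(specs, "criteria_spec")) {
    if (is.character(specs) && !is.null(names(specs))) {
      specs <- criteria_spec(names(specs), unname(specs))
    } else {
      stop("specs must be a criteria_spec, a named direction vector, or a preset name")
    }
  }
  missing_layers <- setdiff(specs$attribute, names(stack$layers))
  if (length(missing_layers) > 0L) {
    stop("unknown attribute layer(s): ", paste(missing_layers, collapse = ", "))
  }
  in_mask <- which(t(stack$mask)) # row-major (k) order
  if (length(in_mask) == 0L) stop("analysis mask is empty")

  vals <- matrix(NA_real_, nrow = length(in_mask), ncol = nrow(specs))
  for (m in seq_len(nrow(specs))) {
    layer <- stack$layers[[specs$attribute[m]]]
    a <- t(layer)[in_mask]
    fn <- if (specs$direction[m] == "higher_is_priority") value_fn_g else value_fn_f
    vals[, m] <- fn(a)
  }
  decision_matrix(vals,
    ids = cell_ids(stack)[in_mask],
    criteria = specs$attribute,
    valid = stats::complete.cases(vals)
  )
}
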