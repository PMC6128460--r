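#' Weak Pareto dominance between two criteria vectors
#'
#' Under the minimization convention, `u` weakly dominates `v` when every
#' element of `u` is less than or equal to the corresponding element of `v`
#' and at least one element is strictly less. Identical vectors do not
#' dominate each other.
#'
#' @param u,v numeric vectors of equal length with finite values.
#' @return `TRUE` if `u` weakly dominates `v`, else `FALSE`.
#' @examples
#' weakly_dominates(c(1, 2), c(1, 3)) # TRUE
#' weakly_dominates(c(1, 4), c(2, 2)) # FALSE (trade-off)
#' @export
weakly_dominates <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  if (length(u) != length(v)) stop("criteria vectors must have the same length")
  if (!all(is.finite(u)) || !all(is.finite(v))) stop("criteria vectors must be finite")
  all(u <= v) && any(u < v)
}

#' Non-dominated set of a decision matrix
#'
#' Returns the ids of the valid alternatives not weakly dominated by any
#' other valid alternative — the rank-1 Pareto front.
#'
#' @param x a [decision_matrix()] (or a plain numeric matrix).
#' @return Vector of alternative ids in the non-dominated set.
#' @export
non_dominated_set <- function(x) {
  r <- pareto_rank(x)
  r$ids[!is.na(r$rank) & r$rank == 1L]
}

#' Pareto-rank the alternatives of a decision matrix
#'
#' Iterative non-dominated-set extraction ("front peeling"): the
#' non-dominated set of all valid alternatives receives rank 1, the
#' non-dominated set of the remainder rank 2, and so on until every valid
#' alternative is ranked. A lower rank means a higher priority. Alternatives
#' with identical criteria vectors are mutually non-dominating and always
#' share a rank; invalid alternatives (missing criteria) are left unranked.
#'
#' Identical rows are collapsed before ranking (they provably share a rank)
#' and unique vectors are ranked with an efficient non-dominated sort in
#' compiled code, so the result is deterministic and independent of row
#' order.
#'
#' @param x a [decision_matrix()] (or a plain numeric matrix, in which case
#'   all rows with complete finite values are ranked).
#' @return An object of class `pareto_ranking`: list with `ids`, `rank`
#'   (positive integer per alternative, `NA` where unranked), `max_rank`,
#'   and `n_ranked`. Ranks over ranked alternatives form the contiguous set
#'   `1:max_rank`.
#' @examples
#' X <- decision_matrix(
#'   rbind(A = c(1, 4), B = c(2, 2), C = c(4, 1), D = c(3, 3), E = c(4, 4)),
#'   ids = c("A", "B", "C", "D", "E")
#' )
#' pareto_rank(X)$rank # 1 1 1 2 3
#' @export
pareto_rank <- function(x) {
  x <- as_decision_matrix(x)
  if (!any(x$valid)) stop("no valid alternatives to rank")
  V <- x$values[x$valid, , drop = FALSE]

  # collapse identical criteria vectors; ties provably co-rank
  key <- do.call(paste, c(lapply(seq_len(ncol(V)), function(m) V[, m]), sep = "\r"))
  first <- !duplicated(key)
  grp <- match(key, key[first])
  uniq_rank <- ens_pareto_rank(V[first, , drop = FALSE])

  rank <- rep(NA_integer_, length(x$ids))
  rank[x$valid] <- uniq_rank[grp]
  structure(
    list(
      ids = x$ids,
      rank = rank,
      max_rank = max(rank, na.rm = TRUE),
      n_ranked = sum(!is.na(rank))
    ),
    class = "pareto_ranking"
  )
}

#' @export
print.pareto_ranking <- function(x, ...) {
  cat(sprintf(
    "Pareto ranking: %d alternatives ranked (%d unranked), max rank %d\n",
    x$n_ranked, length(x$ids) - x$n_ranked, x$max_rank
  ))
  invisible(x)
}

#' @export
summary.pareto_ranking <- function(object, ...) {
  tab <- table(factor(object$rank, levels = seq_len(object$max_rank)))
  out <- data.frame(rank = as.integer(names(tab)), n = as.integer(tab))
  cat(sprintf(
    "Pareto ranking of %d alternatives (max rank %d, %d unranked)\n",
    object$n_ranked, object$max_rank, length(object$ids) - object$n_ranked
  ))
  cat(sprintf("Median rank %s; %d alternatives on the first front\n",
    format(stats::median(object$rank, na.rm = TRUE)), out$n[1L]
  ))
  invisible(out)
}

#' @export
as.data.frame.pareto_ranking <- function(x, ...) {
  data.frame(id = x$ids, rank = x$rank)
}

#' Write Pareto ranks as a two-column table
#'
#' @param x a `pareto_ranking`.
#' @param path file path; tab-separated `id`, `rank` (empty where unranked).
#' @return `path`, invisibly.
#' @export
write_ranks <- function(x, path) {
  stopifnot(inherits(x, "pareto_ranking"))
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Composite Pareto ranks (rank of ranks)
#'
#' Takes two or more Pareto rankings of the same alternatives, treats the
#' component ranks as criteria (lower is better), and Pareto-ranks them
#' again. Composite ranking widens the range of assigned ranks relative to
#' ranking once on the union of all criteria, which is useful because with
#' many criteria most units end up mutually non-dominated. An alternative
#' unranked in any component is unranked in the composite.
#'
#' @param components list of `pareto_ranking` objects over the same
#'   alternative set (ids matched by value).
#' @return A `pareto_ranking`.
#' @export
composite_pareto_rank <- function(components) {
  if (!is.list(components) || length(components) < 2L) {
    stop("need at least two component rankings")
  }
  if (!all(vapply(components, inherits, logical(1), "pareto_ranking"))) {
    stop("all components must be pareto_ranking objects")
  }
  ids <- components[[1L]]$ids
  ranks <- matrix(NA_real_, nrow = length(ids), ncol = length(components))
  ranks[, 1L] <- components[[1L]]$rank
  for (j in seq_along(components)[-1L]) {
    cmp <- components[[j]]
    pos <- match(ids, cmp$ids)
    if (anyNA(pos) || length(cmp$ids) != length(ids)) {
      stop("component rankings cover different alternative sets")
    }
    ranks[, j] <- cmp$rank[pos]
  }
  X <- decision_matrix(ranks,
    ids = ids,
    criteria = paste0("component_rank_", seq_along(components)),
    valid = stats::complete.cases(ranks)
  )
  pareto_rank(X)
}

#' Check rank consistency with weighted-sum scoring
#'
#' For additive multi-attribute value scoring with any strictly positive
#' weights, a weakly dominating alternative can never score worse than the
#' alternative it dominates. This utility verifies that property on a
#' decision matrix: for every dominating pair (k, l) it checks
#' `sum(w * x_k) <= sum(w * x_l)`. It demonstrates why choosing weights is
#' unnecessary before Pareto ranking.
#'
#' @param x a [decision_matrix()].
#' @param ranks optional `pareto_ranking` of `x`; when supplied, also checks
#'   that every dominating pair has strictly ordered ranks.
#' @param w numeric vector of strictly positive weights, one per criterion.
#' @return `TRUE` if consistent (invisibly errors are never raised for
#'   inconsistency; the value is `FALSE`).
#' @export
check_weighted_consistency <- function(x, ranks = NULL, w = NULL) {
  x <- as_decision_matrix(x)
  M <- ncol(x$values)
  if (is.null(w)) w <- rep(1, M)
  if (length(w) != M || any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be strictly positive, one per criterion")
  }
  V <- x$values[x$valid, , drop = FALSE]
  K <- nrow(V)
  if (K < 2L) return(TRUE)
  s <- as.numeric(V %*% w)
  r <- if (!is.null(ranks)) ranks$rank[x$valid] else NULL
  for (k in seq_len(K)) {
    le <- rowSums(sweep(V, 2L, V[k, ], `>=`) * 1) == M # rows l with V[k,] <= V[l,]
    lt <- le & (rowSums(sweep(V, 2L, V[k, ], `>`) * 1) > 0)
    if (!any(lt)) next
    if (any(s[k] > s[lt])) return(FALSE)
    if (!is.null(r) && any(r[k] >= r[lt])) return(FALSE)
  }
  TRUE
}
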