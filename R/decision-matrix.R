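#' Construct a decision matrix
#'
#' A decision matrix holds one row per alternative (here, a raster grid
#' cell) and one column per criterion. All criteria are expressed on a
#' minimization scale: a *lower* value means a *higher* conservation
#' priority. Rows flagged invalid (e.g. cells with a missing criterion)
#' carry `NA`s and are excluded from ranking.
#'
#' @param values numeric matrix, alternatives x criteria.
#' @param ids vector of unique alternative identifiers; defaults to
#'   `rownames(values)` or `1:nrow(values)`.
#' @param criteria character vector of criterion names; defaults to
#'   `colnames(values)` or `c1, c2, ...`.
#' @param valid logical vector marking alternatives that participate in
#'   ranking; defaults to rows with no missing value.
#' @return An object of class `decision_matrix`: a list with elements
#'   `ids`, `criteria`, `values`, `valid`.
#' @examples
#' X <- decision_matrix(rbind(c(1, 4), c(2, 2), c(4, 1)))
#' pareto_rank(X)
#' @export
decision_matrix <- function(values, ids = NULL, criteria = NULL, valid = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 1L) stop("decision matrix needs at least one criterion")
  if (is.null(ids)) ids <- if (!is.null(rownames(values))) rownames(values) else seq_len(nrow(values))
  if (anyDuplicated(ids)) stop("alternative ids must be unique")
  if (length(ids) != nrow(values)) stop("length(ids) must equal nrow(values)")
  if (is.null(criteria)) {
    criteria <- if (!is.null(colnames(values))) colnames(values) else paste0("c", seq_len(ncol(values)))
  }
  if (length(criteria) != ncol(values)) stop("length(criteria) must equal ncol(values)")
  if (is.null(valid)) valid <- stats::complete.cases(values)
  valid <- as.logical(valid)
  if (length(valid) != nrow(values)) stop("length(valid) must equal nrow(values)")
  valid[is.na(valid)] <- FALSE
  if (any(valid) && !all(is.finite(values[valid, , drop = FALSE]))) {
    stop("valid alternatives must have finite values in every criterion")
  }
  dimnames(values) <- list(NULL, criteria)
  structure(
    list(ids = ids, criteria = criteria, values = values, valid = valid),
    class = "decision_matrix"
  )
}

#' @export
print.decision_matrix <- function(x, ...) {
  cat(sprintf(
    "Decision matrix: %d alternatives x %d criteria (%d valid)\n",
    nrow(x$values), ncol(x$values), sum(x$valid)
  ))
  cat("Criteria (lower = higher priority):", paste(x$criteria, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.decision_matrix <- function(x, ...) {
  out <- data.frame(id = x$ids, x$values, valid = x$valid, check.names = FALSE)
  names(out) <- c("id", x$criteria, "valid")
  out
}

as_decision_matrix <- function(x) {
  if (inherits(x, "decision_matrix")) return(x)
  decision_matrix(x)
}

#' Concatenate decision matrices column-wise
#'
#' Appends the criteria columns of several decision matrices over the same
#' alternatives, e.g. joining a fire-threat block and a species-richness
#' block into one matrix. A row of the result is valid only if it is valid
#' in every component.
#'
#' @param ... `decision_matrix` objects, or a single list of them.
#' @return A `decision_matrix` with the columns of all components.
#' @export
concat_matrices <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !inherits(mats[[1L]], "decision_matrix")) {
    mats <- mats[[1L]]
  }
  if (length(mats) < 1L) stop("nothing to concatenate")
  mats <- lapply(mats, as_decision_matrix)
  ids <- mats[[1L]]$ids
  for (m in mats[-1L]) {
    if (length(m$ids) != length(ids) || !all(m$ids == ids)) {
      stop("decision matrices must share identical alternative ids in identical order")
    }
  }
  criteria <- unlist(lapply(mats, `[[`, "criteria"))
  if (anyDuplicated(criteria)) stop("duplicate criteria names after concatenation")
  values <- do.call(cbind, lapply(mats, `[[`, "values"))
  valid <- Reduce(`&`, lapply(mats, `[[`, "valid"))
  decision_matrix(values, ids = ids, criteria = criteria, valid = valid)
}

#' Read / write a decision matrix as a delimited table
#'
#' The on-disk form is a tab-separated table with an `id` column, one
#' column per criterion, and a logical `valid` column; missing criteria are
#' empty fields.
#'
#' @param path file path.
#' @param x a `decision_matrix`.
#' @return `read_decision_matrix` returns a `decision_matrix`;
#'   `write_decision_matrix` returns `path` invisibly.
#' @export
read_decision_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"id" %in% names(tab)) stop("decision-matrix table must have an 'id' column")
  valid <- if ("valid" %in% names(tab)) as.logical(tab$valid) else NULL
  crit <- setdiff(names(tab), c("id", "valid"))
  decision_matrix(as.matrix(tab[, crit, drop = FALSE]),
    ids = tab$id, criteria = crit, valid = valid
  )
}

#' @rdname read_decision_matrix
#' @export
write_decision_matrix <- function(x, path) {
  x <- as_decision_matrix(x)
  utils::write.table(as.data.frame(x), path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
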