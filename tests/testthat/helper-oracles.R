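# Independent brute-force oracles used to validate the implementation.
# They deliberately share no code with the package internals: dominance is
# evaluated all-pairs and fronts are peeled by repeated scans.

oracle_dominates <- function(u, v) all(u <= v) && any(u < v)

# K x K dominance matrix: dom[l, k] TRUE iff row l weakly dominates row k
oracle_dominance_matrix <- function(V) {
  K <- nrow(V)
  M <- ncol(V)
  dom <- matrix(FALSE, K, K)
  for (k in seq_len(K)) {
    vk <- matrix(V[k, ], K, M, byrow = TRUE)
    dom[, k] <- (rowSums(V <= vk) == M) & (rowSums(V < vk) > 0)
  }
  dom
}

oracle_nds <- function(V) which(colSums(oracle_dominance_matrix(V)) == 0)

# front peeling over the dominance matrix
oracle_pareto_rank <- function(V) {
  V <- as.matrix(V)
  K <- nrow(V)
  dom <- oracle_dominance_matrix(V)
  rank <- rep(NA_integer_, K)
  remaining <- seq_len(K)
  r <- 0L
  while (length(remaining) > 0L) {
    r <- r + 1L
    nd <- colSums(dom[remaining, remaining, drop = FALSE]) == 0L
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  rank
}

# per-cell exhaustive circular-window statistics
oracle_window_stat <- function(numerator, radius, cell_size) {
  I <- nrow(numerator)
  J <- ncol(numerator)
  ci <- rep(seq_len(I), times = J)
  cj <- rep(seq_len(J), each = I)
  out <- matrix(NA_real_, I, J)
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      inside <- ((ci - i)^2 + (cj - j)^2) * cell_size^2 <= radius^2
      out[i, j] <- sum(numerator[cbind(ci[inside], cj[inside])]) / sum(inside)
    }
  }
  out
}

# BFS flood fill giving per-cell open-patch cell counts
oracle_patch_cells <- function(open, connectivity = 4) {
  I <- nrow(open)
  J <- ncol(open)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  label <- matrix(0L, I, J)
  cur <- 0L
  for (i0 in seq_len(I)) {
    for (j0 in seq_len(J)) {
      if (!open[i0, j0] || label[i0, j0] != 0L) next
      cur <- cur + 1L
      queue <- list(c(i0, j0))
      label[i0, j0] <- cur
      while (length(queue) > 0L) {
        cell <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (n in seq_len(nrow(nb))) {
          ii <- cell[1L] + nb[n, 1L]
          jj <- cell[2L] + nb[n, 2L]
          if (ii >= 1L && ii <= I && jj >= 1L && jj <= J &&
            open[ii, jj] && label[ii, jj] == 0L) {
            label[ii, jj] <- cur
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  sizes <- tabulate(label[open])
  counts <- matrix(NA_real_, I, J)
  counts[open] <- sizes[label[open]]
  counts
}

# random decision-matrix values; with_duplicates repeats a block of rows and
# discretizes so exact ties occur
random_criteria <- function(K, M, with_duplicates = FALSE) {
  V <- matrix(stats::runif(K * M), K, M)
  if (with_duplicates) {
    V <- round(V * 8) / 8
    dup <- sample(seq_len(K), ceiling(K / 4), replace = TRUE)
    V[sample(seq_len(K), length(dup)), ] <- V[dup, , drop = FALSE]
  }
  V
}
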