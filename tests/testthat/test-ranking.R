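test_that("weak dominance follows the minimization definition", {
  expect_true(weakly_dominates(c(1, 2), c(1, 3)))
  expect_false(weakly_dominates(c(1, 2), c(1, 2))) # identical: no strict element
  expect_false(weakly_dominates(c(1, 4), c(2, 2))) # trade-off, mutually
  expect_false(weakly_dominates(c(2, 2), c(1, 4))) # non-dominated
  expect_error(weakly_dominates(c(1, 2), c(1, 2, 3)), "length")
  expect_error(weakly_dominates(c(1, NA), c(1, 2)), "finite")
})

test_that("non-dominated set keeps duplicates and never comes back empty", {
  V <- rbind(c(1, 4), c(2, 2), c(4, 1), c(3, 3), c(4, 4), c(2, 2))
  X <- decision_matrix(V, ids = letters[1:6])
  expect_setequal(non_dominated_set(X), c("a", "b", "c", "f"))
  expect_setequal(non_dominated_set(X), letters[oracle_nds(V)])
  expect_setequal(non_dominated_set(decision_matrix(rbind(c(7, 7)))), 1)
  expect_setequal(non_dominated_set(rbind(c(0, 0), c(1, 1))), 1)
})

test_that("front peeling matches the worked example and handles ties", {
  X <- decision_matrix(
    rbind(c(1, 4), c(2, 2), c(4, 1), c(3, 3), c(4, 4), c(2, 2)),
    ids = c("A", "B", "C", "D", "E", "F")
  )
  r <- pareto_rank(X)
  expect_equal(setNames(r$rank, r$ids),
    c(A = 1L, B = 1L, C = 1L, D = 2L, E = 3L, F = 1L))
  expect_equal(r$max_rank, 3L)

  # one criterion: Pareto ranking reduces to dense sorting
  r1 <- pareto_rank(decision_matrix(cbind(c(3, 1, 2))))
  expect_equal(r1$rank, c(3L, 1L, 2L))

  # all rows identical: single shared front
  same <- pareto_rank(decision_matrix(matrix(0.4, 5, 3)))
  expect_equal(same$rank, rep(1L, 5))
})

test_that("invalid alternatives stay unranked and valid ranks stay contiguous", {
  V <- rbind(c(1, 2), c(NA, 1), c(2, 3), c(0, 0))
  r <- pareto_rank(decision_matrix(V))
  expect_true(is.na(r$rank[2]))
  expect_setequal(r$rank[!is.na(r$rank)], seq_len(r$max_rank))
  expect_error(pareto_rank(decision_matrix(matrix(NA_real_, 2, 2))), "no valid")
})

test_that("ranking is row-order invariant and deterministic", {
  set.seed(42)
  for (rep in 1:5) {
    V <- random_criteria(80, 3, with_duplicates = rep %% 2 == 0)
    ids <- paste0("u", seq_len(nrow(V)))
    r1 <- pareto_rank(decision_matrix(V, ids = ids))
    perm <- sample(nrow(V))
    r2 <- pareto_rank(decision_matrix(V[perm, , drop = FALSE], ids = ids[perm]))
    expect_equal(r1$rank, r2$rank[match(ids, r2$ids)])
  }
})

test_that("dominance implies strictly lower rank; equal vectors co-rank", {
  set.seed(7)
  V <- random_criteria(60, 3, with_duplicates = TRUE)
  r <- pareto_rank(decision_matrix(V))$rank
  for (k in seq_len(nrow(V))) {
    for (l in seq_len(nrow(V))) {
      if (oracle_dominates(V[k, ], V[l, ])) expect_lt(r[k], r[l])
      if (all(V[k, ] == V[l, ])) expect_identical(r[k], r[l])
    }
  }
})

test_that("ranks are invariant to monotone column transforms and positive weights", {
  set.seed(11)
  V <- random_criteria(70, 4)
  base <- pareto_rank(decision_matrix(V))$rank
  Vt <- V
  Vt[, 2] <- Vt[, 2]^3 # strictly increasing on [0, 1]
  expect_equal(pareto_rank(decision_matrix(Vt))$rank, base)
  Vw <- sweep(V, 2, c(0.1, 7, 2.5, 100), `*`)
  expect_equal(pareto_rank(decision_matrix(Vw))$rank, base)
})

test_that("anticorrelated and duplicate-column limits behave analytically", {
  set.seed(19)
  x <- sort(runif(40))
  anti <- pareto_rank(decision_matrix(cbind(x, 1 - x)))
  expect_equal(anti$rank, rep(1L, 40)) # all mutually non-dominated
  dup <- pareto_rank(decision_matrix(cbind(x, x)))
  expect_equal(dup$rank, pareto_rank(decision_matrix(cbind(x)))$rank)
})

test_that("composite ranking peels component ranks and propagates unranked", {
  mk <- function(rank, ids = seq_along(rank)) {
    structure(
      list(ids = ids, rank = as.integer(rank),
        max_rank = max(rank, na.rm = TRUE), n_ranked = sum(!is.na(rank))),
      class = "pareto_ranking"
    )
  }
  concordant <- composite_pareto_rank(list(mk(1:3), mk(1:3)))
  expect_equal(concordant$rank, 1:3)
  discordant <- composite_pareto_rank(list(mk(c(1, 3, 2)), mk(c(3, 1, 2))))
  expect_equal(discordant$rank, rep(1L, 3)) # mutually non-dominated rank pairs
  partial <- composite_pareto_rank(list(mk(c(1, 1, NA)), mk(c(1, 2, 1))))
  expect_equal(partial$rank, c(1L, 2L, NA))
  expect_error(
    composite_pareto_rank(list(mk(1:3), mk(1:3, ids = c("a", "b", "c")))),
    "different alternative sets"
  )
  expect_error(composite_pareto_rank(list(mk(1:3))), "at least two")
})

test_that("composite ids are matched by value, not position", {
  mk <- function(rank, ids) {
    structure(
      list(ids = ids, rank = as.integer(rank), max_rank = max(rank),
        n_ranked = length(rank)),
      class = "pareto_ranking"
    )
  }
  a <- mk(c(1, 2, 3), c("x", "y", "z"))
  b <- mk(c(3, 2, 1), c("z", "y", "x")) # same ranking, permuted storage
  comp <- composite_pareto_rank(list(a, b))
  expect_equal(setNames(comp$rank, comp$ids), c(x = 1L, y = 2L, z = 3L))
})

test_that("weighted-sum screening can never contradict dominance", {
  X <- decision_matrix(rbind(c(0, 0), c(1, 1), c(0.2, 0.9)))
  r <- pareto_rank(X)
  expect_true(check_weighted_consistency(X, r, w = c(1, 1)))
  expect_true(check_weighted_consistency(X, r, w = c(0.1, 10)))
  set.seed(3)
  Xr <- decision_matrix(random_criteria(100, 4))
  expect_true(check_weighted_consistency(Xr, pareto_rank(Xr), w = runif(4, 0.01, 5)))
  expect_error(check_weighted_consistency(Xr, w = c(1, -1, 1, 1)), "positive")
})
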