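test_that("ASCII grid rasters round-trip values, nodata, and georeference", {
  set.seed(41)
  x <- matrix(rnorm(120), 10, 12)
  x[sample(120, 15)] <- NA
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(x, p, xll = 1000, yll = -500, cell_size = 25)
  y <- read_ascii_grid(p)
  expect_equal(unclass(y), x, ignore_attr = TRUE)
  expect_equal(attr(y, "xll"), 1000)
  expect_equal(attr(y, "yll"), -500)
  expect_equal(attr(y, "cell_size"), 25)
  expect_error(read_ascii_grid(file.path(tempdir(), "no-such.asc")), "cannot read")
})

test_that("rank grids round-trip bit-exactly through integer rasters", {
  set.seed(42)
  g <- matrix(sample(c(NA, 1:7), 80, replace = TRUE), 8, 10)
  class(g) <- c("rank_grid", class(g))
  attr(g, "cell_size") <- 50
  p <- withr::local_tempfile(fileext = ".asc")
  write_rank_grid(g, p)
  g2 <- read_rank_grid(p)
  expect_identical(unclass(g2)[, ], matrix(as.integer(g), 8, 10))
})

test_that("read_stack assembles aligned layers and rejects misalignment", {
  dir <- withr::local_tempdir()
  set.seed(43)
  for (nm in c("a", "b", "c")) {
    write_ascii_grid(matrix(runif(36), 6, 6), file.path(dir, paste0(nm, ".asc")),
      cell_size = 50)
  }
  m <- matrix(1, 6, 6)
  m[1, 1] <- 0
  write_ascii_grid(m, file.path(dir, "mask.asc"), cell_size = 50)
  files <- setNames(file.path(dir, c("a.asc", "b.asc", "c.asc")), c("a", "b", "c"))
  stack <- read_stack(files, mask_file = file.path(dir, "mask.asc"))
  expect_s3_class(stack, "attribute_stack")
  expect_equal(names(stack$layers), c("a", "b", "c"))
  expect_equal(sum(stack$mask), 35)

  write_ascii_grid(matrix(0, 5, 6), file.path(dir, "bad.asc"), cell_size = 50)
  expect_error(read_stack(c(files, bad = file.path(dir, "bad.asc"))), "not aligned")

  write_ascii_grid(matrix(0, 6, 6), file.path(dir, "off.asc"), xll = 999, cell_size = 50)
  expect_error(read_stack(c(files, off = file.path(dir, "off.asc"))), "not aligned")

  # nodata cells arrive as missing
  z <- matrix(1:36 / 10, 6, 6)
  z[2, 2] <- NA
  write_ascii_grid(z, file.path(dir, "z.asc"), cell_size = 50)
  expect_true(is.na(read_stack(c(files, z = file.path(dir, "z.asc")))$layers$z[2, 2]))
})

test_that("ranks map back onto the grid with nodata on invalid and masked cells", {
  layers <- list(a = matrix(runif(16), 4, 4), b = matrix(runif(16), 4, 4))
  layers$b[2, 3] <- NA
  mask <- matrix(TRUE, 4, 4)
  mask[4, 4] <- FALSE
  stack <- attribute_stack(layers, mask = mask)
  X <- build_decision_matrix(stack, criteria_spec(c("a", "b"), "higher_is_priority"))
  r <- pareto_rank(X)
  g <- ranks_to_grid(X, r, stack)
  expect_true(is.na(g[2, 3])) # invalid: missing criterion
  expect_true(is.na(g[4, 4])) # out of mask
  expect_equal(sum(!is.na(g)), 14)
  # ranks land on the right cells: id k = (i-1)*J + j
  k_of <- function(i, j) (i - 1) * 4 + j
  expect_equal(g[3, 2], r$rank[match(k_of(3, 2), r$ids)])
})

test_that("percentile threshold follows the nearest-rank rule", {
  expect_equal(percentile_threshold(c(1, 2, 3, 4), 0.25), 1L)
  expect_equal(percentile_threshold(rep(1, 10), 0.9), 1L)
  set.seed(45)
  r <- sample(1:40, 1000, replace = TRUE, prob = 1 / sqrt(1:40))
  for (q in c(0.1, 0.25, 0.5, 0.75)) {
    t_got <- percentile_threshold(r, q)
    expect_equal(t_got, sort(r)[ceiling(q * 1000)]) # sort-and-index oracle
    expect_gte(mean(r <= t_got), q) # smallest attained rank reaching q
    expect_lt(mean(r <= t_got - 1), q)
  }
  # q -> 1 recovers the max rank, q at 1/n the min
  expect_equal(percentile_threshold(r, 0.999), max(r))
  expect_equal(percentile_threshold(r, 1 / length(r)), min(r))
  expect_error(percentile_threshold(r, 0), "fraction")
  expect_error(percentile_threshold(rep(NA, 3), 0.25), "no ranked cells")
})

test_that("zonal summaries count classified cells per stratum consistently", {
  g <- matrix(c(1, 1, 2, 2), 1, 4)
  zones <- matrix("z1", 1, 4)
  cons <- matrix(TRUE, 1, 4)
  zs <- zonal_summary(g, zones, cons, q = 0.5)
  expect_equal(zs$percent, 50)
  expect_equal(attr(zs, "threshold"), 1L)

  set.seed(46)
  g2 <- matrix(sample(c(NA, 1:6), 400, TRUE), 20, 20)
  zones2 <- matrix(sample(c("north", "south"), 400, TRUE), 20, 20)
  cons2 <- matrix(sample(c(TRUE, FALSE), 400, TRUE), 20, 20)
  zs2 <- zonal_summary(g2, zones2, cons2, q = 0.25)
  thr <- percentile_threshold(g2, 0.25)
  expect_equal(sum(zs2$n_at_or_below), sum(g2 <= thr, na.rm = TRUE))
  expect_equal(sum(zs2$n_cells), sum(!is.na(g2)))
  expect_equal(zs2$percent, 100 * zs2$n_at_or_below / zs2$n_cells)

  # identical rank multisets in two zones give identical percentages
  g3 <- matrix(rep(c(1, 2, 3, 4), 2), 2, 4, byrow = TRUE)
  zones3 <- matrix(rep(c("a", "b"), each = 4), 2, 4, byrow = TRUE)
  zs3 <- zonal_summary(g3, zones3, q = 0.5)
  expect_equal(zs3$percent[1], zs3$percent[2])
  expect_error(zonal_summary(g3, matrix(NA, 2, 4)), "no ranked cells overlap")
})

test_that("explicit global thresholds override the per-grid percentile", {
  g <- matrix(1:8, 2, 4)
  zs <- zonal_summary(g, matrix("z", 2, 4), threshold = 3L)
  expect_equal(zs$n_at_or_below, 3L)
  expect_equal(attr(zs, "threshold"), 3L)
})

test_that("median rank profiles ignore nodata and flag empty lines", {
  g <- rbind(c(1, 3, 5, NA), c(NA, NA, NA, NA), c(2, 2, 4, 6))
  expect_equal(median_rank_profile(g, "row"), c(3, NA, 3))
  set.seed(47)
  g2 <- matrix(sample(c(NA, 1:9), 300, TRUE), 15, 20)
  want <- apply(g2, 2, function(v) if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE))
  expect_equal(median_rank_profile(g2, "column"), want)
})
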