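ref_types <- function(codes, cell_size = 30) {
  side <- ceiling(sqrt(length(codes)))
  m <- matrix(NA_real_, side, side)
  m[seq_along(codes)] <- codes
  lcv_grid(m, cell_size)
}

test_that("matrix lookup assigns published cell values and propagates nodata", {
  m <- load_reference_matrix()
  # Forest (5) on Summit (5) -> 9.41; Barren (1) on Flat land (1) -> 1.00
  types <- ref_types(c(55, 11, 11, NA))
  lcv <- apply_lcv_matrix(types, m)
  expect_identical(lcv$values[1], 9.41)
  expect_identical(lcv$values[2], 1)
  expect_true(is.na(lcv$values[4]))

  only_barren_flat <- ref_types(rep(11, 9))
  expect_true(all(apply_lcv_matrix(only_barren_flat, m)$values == 1))

  raw <- lcv_matrix(matrix(1:35, 7, 5), normalized = FALSE)
  expect_error(apply_lcv_matrix(types, raw), "normalized")
})

test_that("mapped values stay inside the matrix range for arbitrary type grids", {
  m <- load_reference_matrix()
  set.seed(12)
  codes <- as.vector(outer(1:5 * 10, 1:7, `+`))
  types <- ref_types(sample(codes, 100, replace = TRUE))
  lcv <- apply_lcv_matrix(types, m)
  v <- lcv$values[!is.na(lcv$values)]
  expect_true(all(v >= min(m) & v <= max(m)))
})

test_that("zonal statistics match the direct definition and recombine to the whole site", {
  # constant grid: mean equals the constant, SD 0
  g <- lcv_grid(matrix(5, 10, 10), 30)
  disc <- zones(list(list(name = "d", x = c(60, 240, 240, 60),
                          y = c(60, 60, 240, 240))))
  zs <- zonal_lcv_stats(g, disc)
  expect_equal(zs$mean_lcv, c(5, 5), tolerance = 1e-12)
  expect_equal(zs$sd, c(0, 0), tolerance = 1e-12)

  # cells {1, 4, 10}: mean 5, population SD sqrt(14)
  g2 <- lcv_grid(matrix(c(1, 4, 10, 7, 7, 7, 7, 7, 7), 3, 3), 30)
  col1 <- zones(list(list(name = "col1", x = c(0, 30, 30, 0),
                          y = c(0, 0, 90, 90))))
  zs2 <- zonal_lcv_stats(g2, col1)
  expect_equal(zs2$mean_lcv[1], 5, tolerance = 1e-12)
  expect_equal(zs2$sd[1], sqrt(14), tolerance = 1e-12)

  # a zone covering the whole footprint duplicates the whole-site row
  all_zone <- zones(list(list(name = "all", x = c(-1, 301, 301, -1),
                              y = c(-1, -1, 301, 301))))
  g3 <- lcv_grid(matrix(runif(100, 1, 10), 10, 10), 30)
  zs3 <- zonal_lcv_stats(g3, all_zone)
  expect_equal(zs3$mean_lcv[1], zs3$mean_lcv[2], tolerance = 1e-12)
  expect_equal(zs3$sd[1], zs3$sd[2], tolerance = 1e-12)
  expect_identical(zs3$cells[1], zs3$cells[2])

  # empty zone: flagged NA row with a warning
  far <- zones(list(list(name = "far", x = c(1e6, 1e6 + 1, 1e6),
                         y = c(0, 0, 1))))
  expect_warning(zs4 <- zonal_lcv_stats(g3, far), "covers no cell")
  expect_true(is.na(zs4$mean_lcv[1]))
})

test_that("disjoint zonal means recombine area-weighted to the whole-site mean", {
  set.seed(5)
  g <- lcv_grid(matrix(runif(144, 1, 10), 12, 12), 30)
  # two half-plane zones partitioning the footprint
  left <- list(name = "left", x = c(-1, 180, 180, -1), y = c(-1, -1, 400, 400))
  right <- list(name = "right", x = c(180, 400, 400, 180), y = c(-1, -1, 400, 400))
  zs <- suppressWarnings(zonal_lcv_stats(g, zones(list(left, right))))
  expect_identical(sum(zs$cells[1:2]), zs$cells[3])
  recombined <- sum(zs$mean_lcv[1:2] * zs$cells[1:2]) / zs$cells[3]
  expect_equal(recombined, zs$mean_lcv[3], tolerance = 1e-9)
})

test_that("focal SD matches closed forms and scales homogeneously", {
  const <- lcv_grid(matrix(7, 6, 6), 30)
  expect_true(all(focal_sd(const)$values == 0))

  # 3x3 grid of 1..9: centre window SD is sqrt(60/9)
  g <- lcv_grid(matrix(1:9, 3, 3), 30)
  expect_equal(focal_sd(g, 3)$values[2, 2], sqrt(60 / 9), tolerance = 1e-12)

  set.seed(17)
  r <- lcv_grid(matrix(runif(64, 1, 10), 8, 8), 30)
  f1 <- focal_sd(r, 3)$values
  f2 <- focal_sd(lcv_grid(3.5 * r$values, 30), 3)$values
  expect_equal(f2, 3.5 * f1, tolerance = 1e-9)

  expect_error(focal_sd(r, 4), "odd")
  expect_error(focal_sd(r, 1), "odd|>= 3")
})

test_that("focal SD agrees with the brute-force window oracle", {
  set.seed(99)
  for (i in 1:25) {
    v <- matrix(runif(64, 0, 10), 8, 8)
    if (i %% 5 == 0) v[sample(64, 6)] <- NA
    g <- lcv_grid(v, 30)
    for (w in c(3L, 5L)) {
      expect_equal(focal_sd(g, w)$values, focal_sd_oracle(v, w),
                   tolerance = 1e-9)
    }
  }
})

test_that("susceptibility threshold and mask follow the percentile contract", {
  # SD values 1..10: the 80th linear-interpolation percentile cut
  sd_g <- lcv_grid(matrix(c(1:10, rep(NA, 6)), 4, 4), 30)
  res <- susceptibility_mask(sd_g, 80)
  expect_equal(res$threshold, stats::quantile(1:10, 0.8, names = FALSE),
               tolerance = 1e-12)
  # sort-based oracle: exactly the values at or above the cut are masked
  vals <- sort(c(sd_g$values[!is.na(sd_g$values)]))
  expected_masked <- vals[vals >= res$threshold]
  got_masked <- sd_g$values[!is.na(res$mask$values) & res$mask$values == 1]
  expect_identical(sort(got_masked), expected_masked)

  # degenerate constant field: threshold equals the constant, all cells masked
  const <- lcv_grid(matrix(2, 3, 3), 30)
  resc <- susceptibility_mask(const, 80)
  expect_identical(resc$threshold, 2)
  expect_true(all(resc$mask$values == 1))

  # raising the percentile never grows the mask
  set.seed(23)
  g <- lcv_grid(matrix(runif(100), 10, 10), 30)
  masks <- lapply(c(50, 70, 90), function(p) {
    susceptibility_mask(g, p)$mask$values == 1
  })
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))

  expect_error(susceptibility_mask(g, 0), "percentile")
  expect_error(susceptibility_mask(lcv_grid(matrix(NA_real_, 2, 2), 30), 80),
               "nodata")
})

test_that("a boundary between two constant-value regions lights up in focal SD", {
  v <- matrix(2, 12, 12)
  v[, 7:12] <- 9
  lcv <- lcv_grid(v, 30)
  fsd <- focal_sd(lcv, 3)
  interior_left <- fsd$values[2:11, 2:5]
  interior_right <- fsd$values[2:11, 8:11]
  boundary <- fsd$values[, 6:7]
  expect_true(all(interior_left == 0))
  expect_true(all(interior_right == 0))
  expect_true(all(boundary > 0))
  # boundary cells are ~17% of the grid, so a 90th-percentile cut lands
  # inside the positive SD values and the mask traces exactly the boundary
  res <- susceptibility_mask(fsd, 90)
  expect_identical(unname(which(colSums(res$mask$values == 1) > 0)), c(6L, 7L))
})
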