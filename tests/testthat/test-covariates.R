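# Covariate derivation: focal Shannon diversity, terrain ruggedness,
# proximity to water, grid resampling, season calendar, moon series.

test_that("focal Shannon matches analytic values for known class mixtures", {
  # radius larger than the grid: every cell sees the global proportions
  all_of <- function(classes) grid_from(matrix(classes, 4, 4), cell = 30)
  one <- shannon_focal(all_of(rep(1, 16)), radius = 1e6)
  expect_equal(max(abs(one$values)), 0)

  two <- shannon_focal(all_of(rep(c(1, 2), 8)), radius = 1e6)
  expect_equal(two$values[2, 3], log(2), tolerance = 1e-10)

  # proportions (0.5, 0.25, 0.125, 0.125): frozen oracle value 1.2130
  mix <- all_of(c(rep(1, 8), rep(2, 4), rep(3, 2), rep(4, 2)))
  h <- shannon_focal(mix, radius = 1e6)
  expect_equal(h$values[1, 1], 1.21301, tolerance = 1e-4)
  expect_equal(h$values[1, 1],
               oracle_shannon(c(0.5, 0.25, 0.125, 0.125)), tolerance = 1e-10)
})

test_that("focal Shannon equals the brute-force windowed scan", {
  set.seed(31)
  lc <- grid_from(matrix(sample(1:4, 400, TRUE), 20, 20), cell = 30,
                  categorical = TRUE)
  lc$values[sample(400, 20)] <- NA  # nodata excluded from proportions
  got <- shannon_focal(lc, radius = 100)
  want <- oracle_shannon_focal(lc, radius = 100)
  expect_equal(got$values, want, tolerance = 1e-8)
  # bounded by log of the number of classes present anywhere
  expect_lte(max(got$values, na.rm = TRUE), log(4) + 1e-12)
})

test_that("all-nodata windows give nodata and fractional weights differ at borders", {
  lc <- grid_from(matrix(c(NA, NA, NA, NA, 1, 2, NA, 1, 2), 3, 3), cell = 30)
  h <- shannon_focal(lc, radius = 31)
  expect_true(is.na(h$values[1, 1]))  # window holds only nodata
  set.seed(5)
  lc2 <- grid_from(matrix(sample(1:3, 225, TRUE), 15, 15), cell = 30)
  hc <- shannon_focal(lc2, radius = 75, weights = "centre")
  hf <- shannon_focal(lc2, radius = 75, weights = "fractional")
  expect_false(isTRUE(all.equal(hc$values, hf$values)))
  expect_lt(max(abs(hc$values - hf$values)), 0.5)  # same field, softer edge
})

test_that("terrain ruggedness reproduces hand-computed neighbourhoods", {
  flat <- terrain_ruggedness(grid_from(matrix(7, 5, 5)))
  expect_equal(max(abs(flat$values)), 0)

  bump <- matrix(0, 3, 3); bump[2, 2] <- 1
  tri <- terrain_ruggedness(grid_from(bump))
  expect_equal(tri$values[2, 2], sqrt(8), tolerance = 1e-12)

  # inclined plane with rise s per cell: interior TRI = s * sqrt(6)
  s <- 2.5
  plane <- grid_from(matrix(rep(s * (1:6), each = 6), 6, 6))
  tri2 <- terrain_ruggedness(plane)
  expect_equal(tri2$values[3, 3], s * sqrt(6), tolerance = 1e-12)
  expect_equal(tri2$values[4, 4], s * sqrt(6), tolerance = 1e-12)
})

test_that("terrain ruggedness is translation-invariant and a 3x3 minimum is enforced", {
  set.seed(8)
  dem <- grid_from(matrix(rnorm(100, 1500, 30), 10, 10))
  dem2 <- dem; dem2$values <- dem2$values + 500
  expect_equal(terrain_ruggedness(dem)$values,
               terrain_ruggedness(dem2)$values, tolerance = 1e-9)
  expect_error(terrain_ruggedness(grid_from(matrix(0, 2, 5))), "3x3")
})

test_that("proximity to water matches axis-aligned and 3-4-5 geometry", {
  m <- matrix(0, 9, 9); m[, 2] <- 1  # straight north-south river
  d <- proximity_to_water(grid_from(m, cell = 30))
  expect_equal(d$values[5, 2], 0)
  expect_equal(d$values[5, 5], 90)   # 3 cells due east
  m2 <- matrix(0, 9, 9); m2[1, 1] <- 1
  d2 <- proximity_to_water(grid_from(m2, cell = 30))
  expect_equal(d2$values[5, 4], 150) # offset (3, 4) cells: 3-4-5 triangle
  expect_error(proximity_to_water(grid_from(matrix(0, 4, 4))), "no water")
})

test_that("distance transform equals the brute-force nearest-cell scan", {
  set.seed(12)
  for (dims in list(c(17, 23), c(50, 50))) {
    m <- matrix(0, dims[1], dims[2])
    m[sample(prod(dims), 12)] <- 1
    g <- grid_from(m, cell = 30)
    expect_equal(proximity_to_water(g)$values, oracle_distance(g),
                 tolerance = 1e-9)
  }
})

test_that("resampling is exact on matched grids and constants", {
  set.seed(3)
  g <- grid_from(matrix(rnorm(120), 10, 12), cell = 30)
  out <- resample_to_common_grid(list(g), cell_size = 30)[[1]]
  expect_equal(out$values, g$values, tolerance = 1e-12)
  expect_equal(out$origin, g$origin)

  const <- grid_from(matrix(4.2, 7, 7), cell = 90)
  out2 <- resample_to_common_grid(list(const), cell_size = 30)[[1]]
  expect_equal(max(abs(out2$values - 4.2)), 0, tolerance = 1e-12)
})

test_that("bilinear resampling interpolates a linear ramp exactly (interior)", {
  # 60 m ramp in x: value = x-coordinate of the cell centre
  nc <- 10
  ramp <- grid_from(matrix(rep(60 * (1:nc) - 30, each = 8), 8, nc), cell = 60)
  out <- resample_to_common_grid(list(ramp), cell_size = 30)[[1]]
  ctr <- grid_centres(out)
  interior <- ctr$x > 30 & ctr$x < 60 * nc - 30
  for (j in which(interior))
    expect_equal(out$values[4, j], ctr$x[j], tolerance = 1e-9)
  # mean of a linear surface is preserved over the interior
  expect_equal(mean(out$values[, which(interior)]),
               mean(ctr$x[interior]), tolerance = 1e-9)
})

test_that("categorical layers resample by nearest neighbour and stay integer", {
  set.seed(9)
  lc <- grid_from(matrix(sample(1:5, 36, TRUE), 6, 6), cell = 90,
                  categorical = TRUE)
  out <- resample_to_common_grid(list(lc), cell_size = 30)[[1]]
  expect_true(all(out$values %in% 1:5))
  # centre 30 m cell of each 90 m cell keeps its source class
  expect_equal(out$values[2, 2], lc$values[1, 1])
})

test_that("grids with disjoint extents refuse to resample", {
  a <- grid_from(matrix(1, 5, 5), cell = 30, origin = c(0, 0))
  b <- grid_from(matrix(1, 5, 5), cell = 30, origin = c(10000, 10000))
  expect_error(resample_to_common_grid(list(a, b)), "disjoint")
})

test_that("season calendar maps months to the four three-month seasons", {
  expect_equal(season_of(as.Date("2017-01-15")), "short_dry")
  expect_equal(season_of(as.Date("2017-04-01")), "long_rain")
  expect_equal(season_of(as.Date("2017-12-31")), "short_rain")
  expect_equal(season_of(as.Date("2017-07-01")), "long_dry")
  all_m <- season_of(as.Date(sprintf("2017-%02d-10", 1:12)))
  expect_equal(as.vector(table(all_m)[c("short_dry", "long_rain",
                                        "long_dry", "short_rain")]),
               rep(3L, 4))
})

test_that("synthetic moon series follows the circalunar cosine", {
  nm <- as.Date("2016-05-06")
  ms <- moon_series_synthetic(nm - 5, nm + 40, new_moon = nm)
  expect_equal(moon_at(ms, as.POSIXct(paste(nm, "13:00"), tz = "UTC")), 0)
  full <- nm + round(29.53 / 2)
  expect_gt(moon_at(ms, full), 99.5)
  quarter <- nm + 29.53 / 4
  expect_equal(moon_at(ms, as.Date(round(quarter))), 50, tolerance = 3)
  # daily resolution: all hours of one date share the value
  hrs <- as.POSIXct(paste(nm + 10, sprintf("%02d:00", c(0, 9, 23))), tz = "UTC")
  expect_equal(length(unique(moon_at(ms, hrs))), 1L)
  expect_error(moon_at(ms, as.POSIXct("2030-01-01", tz = "UTC")), "span")
})

test_that("moon CSV and ASCII grids round-trip through their readers", {
  ms <- moon_series_synthetic("2016-05-01", "2016-06-01")
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(date = ms$date, illumination_pct = ms$illumination_pct),
            f, row.names = FALSE)
  back <- read_moon_series(f)
  expect_equal(back$illumination_pct, ms$illumination_pct, tolerance = 1e-9)

  set.seed(2)
  g <- grid_from(matrix(rnorm(30), 5, 6), cell = 30, origin = c(100, 200))
  g$values[2, 3] <- NA
  fg <- tempfile(fileext = ".asc")
  write_ascii_grid(g, fg)
  back_g <- read_ascii_grid(fg)
  expect_equal(back_g$values, g$values, tolerance = 1e-6)
  expect_equal(back_g$origin, g$origin)
  expect_equal(back_g$cell_size, g$cell_size)
})
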