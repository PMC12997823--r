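# Synthetic landscape / track generator: determinism, invariants, and
# parameter-recovery-friendly behaviour of the generative selection model.

test_that("landscape generation is deterministic and respects layer ranges", {
  a <- generate_landscape(extent = c(0, 0, 10000, 10500), cell_size = 250,
                          seed = 5, svd_radius = 500)
  b <- generate_landscape(extent = c(0, 0, 10000, 10500), cell_size = 250,
                          seed = 5, svd_radius = 500)
  expect_identical(a$grids$WC$values, b$grids$WC$values)
  expect_identical(a$grids$LANDCOVER$values, b$grids$LANDCOVER$values)
  expect_identical(a$grids$ProxW$values, b$grids$ProxW$values)

  expect_true(all(a$grids$WC$values >= 0 & a$grids$WC$values <= 100))
  expect_true(all(a$grids$TRI$values >= 0))
  expect_true(all(a$grids$SVD$values >= 0))
  expect_gte(length(unique(as.vector(a$grids$LANDCOVER$values))), 4)
  for (s in names(a$grids$NDVI))
    expect_true(all(abs(a$grids$NDVI[[s]]$values) <= 1))
  expect_error(generate_landscape(extent = c(0, 0, 4000, 4000)), "degenerate")
})

test_that("generated Shannon layer matches the brute-force focal scan", {
  a <- generate_landscape(extent = c(0, 0, 10000, 10000), cell_size = 250,
                          seed = 9, svd_radius = 500)
  want <- oracle_shannon_focal(a$grids$LANDCOVER, radius = 500)
  expect_equal(a$grids$SVD$values, want, tolerance = 1e-8)
})

test_that("management areas tile the extent", {
  a <- fix_bundle()
  set.seed(1)
  px <- runif(300, a$extent[1], a$extent[3])
  py <- runif(300, a$extent[2], a$extent[4])
  hits <- rowSums(vapply(a$areas, function(p) point_in_polygon(p, px, py),
                         logical(300)))
  expect_true(all(hits >= 1))  # every point belongs to at least one area
})

test_that("mcp reproduces simple hulls and the halfplane oracle", {
  sq <- mcp(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  expect_equal(attr(sq, "area_km2"), 1.0, tolerance = 1e-12)
  with_interior <- mcp(c(0, 1000, 1000, 0, 500), c(0, 0, 1000, 1000, 500))
  expect_equal(attr(with_interior, "area_km2"), 1.0, tolerance = 1e-12)
  expect_equal(length(with_interior$x), 4L)
  expect_error(mcp(c(0, 1, 2), c(0, 1, 2)), "non-collinear")

  set.seed(21)
  x <- rnorm(100); y <- rnorm(100)
  hull <- mcp(x, y)
  want <- sort(oracle_hull_vertices(x, y))
  got <- sort(match(paste(hull$x, hull$y), paste(x, y)))
  expect_equal(got, want)
})

test_that("track simulation is reproducible and satisfies track invariants", {
  tr1 <- fix_tracks()
  tr2 <- simulate_tracks(fix_bundle(),
                         truth_config(n_individuals = 8,
                                      fixes_per_individual = 600,
                                      home_range_scale = 600, seed = 7))
  expect_identical(tr1[[3]]$relocations, tr2[[3]]$relocations)

  region <- study_region(fix_bundle())
  for (t in tr1) {
    expect_true(all(diff(as.numeric(t$relocations$timestamp)) == 3600))
    expect_true(all(point_in_polygon(region, t$relocations$x,
                                     t$relocations$y)))
    expect_true(all(point_in_polygon(t$mcp, t$relocations$x,
                                     t$relocations$y)))
    expect_true(t$area_id %in% names(fix_bundle()$areas))
  }
  # both sides of the protected core are populated
  sides <- vapply(tr1, function(t)
    point_in_polygon(fix_bundle()$core, t$centre[1], t$centre[2]), NA)
  expect_true(any(sides) && any(!sides))
})

test_that("null selection coefficients leave used points matching availability", {
  truth0 <- truth_config(
    beta_landscape = c(WC = 0), beta_within = c(WC = 0),
    delta_outside = c(WC = 0),
    n_individuals = 8, fixes_per_individual = 600,
    home_range_scale = 600, seed = 19)
  tr <- simulate_tracks(fix_bundle(), truth0)
  mp <- draw_available(tracks = tr, n = 4800, seed = 3)
  used <- do.call(rbind, lapply(tr, function(t) t$relocations[, c("x", "y")]))
  eu <- extract_covariates(fix_bundle(), used$x, used$y, "mean")
  ea <- extract_covariates(fix_bundle(), mp$x, mp$y, "mean")
  sc <- landscape_scaling(fix_bundle())
  for (cv in c("WC", "SVD", "NDVI", "ProxW", "TRI")) {
    dz <- (mean(eu[[cv]]) - mean(ea[[cv]])) / sc$sd[sc$covariate == cv]
    expect_lt(abs(dz), 0.25)
  }
})

test_that("positive woody-cover selection raises woody cover at used points", {
  truth <- truth_config(
    beta_landscape = c(WC = 0), delta_outside = c(WC = 0),
    beta_within = c(WC = 1.0, SVD = 0, NDVI = 0, ProxW = 0, TRI = 0),
    n_individuals = 6, fixes_per_individual = 500,
    home_range_scale = 600, seed = 23)
  tr <- simulate_tracks(fix_bundle(), truth)
  mp <- draw_available(tracks = tr, n = 3000, seed = 4)
  used <- do.call(rbind, lapply(tr, function(t) t$relocations[, c("x", "y")]))
  wc_used <- mean(extract_covariates(fix_bundle(), used$x, used$y, "mean")$WC)
  wc_avail <- mean(extract_covariates(fix_bundle(), mp$x, mp$y, "mean")$WC)
  expect_gt(wc_used, wc_avail)
})

test_that("diel modulation of one covariate shows up as a cosine on that covariate only", {
  truth <- truth_config(
    beta_landscape = c(WC = 0), delta_outside = c(WC = 0),
    diel_single = c(WC = 1.2),
    n_individuals = 6, fixes_per_individual = 720,
    home_range_scale = 600, seed = 29)
  tr <- simulate_tracks(fix_bundle(), truth)
  used <- do.call(rbind, lapply(tr, function(t) t$relocations))
  hr <- (as.POSIXlt(used$timestamp, tz = "UTC")$hour + 3L) %% 24L
  e <- extract_covariates(fix_bundle(), used$x, used$y, "mean")
  sc <- landscape_scaling(fix_bundle())
  r1 <- (1 + cos(2 * pi * ((0:23) - 12) / 24)) / 2
  slope <- vapply(c("WC", "SVD", "NDVI", "ProxW", "TRI"), function(cv) {
    z <- (e[[cv]] - sc$mean[sc$covariate == cv]) / sc$sd[sc$covariate == cv]
    unname(coef(lm(tapply(z, hr, mean)[as.character(0:23)] ~ r1))[2])
  }, 0)
  expect_gt(cor(tapply(e$WC, hr, mean)[as.character(0:23)], r1), 0.8)
  # the modulated covariate dominates; spatially correlated layers may
  # inherit a weak echo of the pattern but stay well below it
  expect_gt(abs(slope["WC"]), 2 * max(abs(slope[-1])))
})

test_that("home-range area scales with the squared kernel scale", {
  areas <- c(); scales <- c()
  for (s in c(400, 700, 1000)) {
    tr <- simulate_tracks(fix_bundle(),
                          truth_config(n_individuals = 4,
                                       fixes_per_individual = 300,
                                       home_range_scale = s, seed = 31))
    areas <- c(areas, vapply(tr, function(t) attr(t$mcp, "area_km2"), 0))
    scales <- c(scales, rep(s^2, 4))
  }
  expect_gt(cor(areas, scales, method = "spearman"), 0.9)
})

test_that("runaway coefficients abort with the offending covariate named", {
  expect_error(
    simulate_tracks(fix_bundle(),
                    truth_config(beta_within = c(NDVI = 50),
                                 n_individuals = 2,
                                 fixes_per_individual = 50, seed = 1)),
    "NDVI")
})

test_that("tracks export as CSV with one row per fix", {
  tr <- fix_tracks()
  f <- tempfile(fileext = ".csv")
  write_tracks_csv(tr, f)
  d <- read.csv(f)
  expect_equal(nrow(d), sum(vapply(tr, function(t) nrow(t$relocations), 0L)))
  expect_equal(sort(unique(d$individual_id)),
               sort(vapply(tr, `[[`, "", "individual_id")))
})
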