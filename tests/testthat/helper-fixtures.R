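# Shared synthetic fixtures, built once per test run (all generated in code;
# sizes kept small so the default suite stays fast).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

fix_bundle <- function() memo("bundle", function()
  generate_landscape(extent = c(0, 0, 12000, 12000), cell_size = 100,
                     seed = 42, svd_radius = 500))

fix_tracks <- function() memo("tracks", function()
  simulate_tracks(fix_bundle(),
                  truth_config(n_individuals = 8, fixes_per_individual = 600,
                               home_range_scale = 600, seed = 7)))

fix_points <- function() memo("points", function() {
  tr <- fix_tracks()
  n <- availability_count(sum(vapply(tr, function(t) nrow(t$relocations), 0L)))
  list(region = draw_available(region = study_region(fix_bundle()), n = n,
                               seed = 11),
       mcp = draw_available(tracks = tr, n = n, seed = 12))
})

fix_tables <- function() memo("tables", function() {
  tr <- fix_tracks(); pts <- fix_points()
  moon <- attr(tr, "moon")
  list(landscape = build_landscape_table(pts$region, pts$mcp, fix_bundle(),
                                         tracks = tr, seed = 13),
       homerange = build_homerange_table(pts$mcp, tr, fix_bundle(), moon,
                                         seed = 14),
       moon = moon)
})

# small grid helpers for covariate unit tests
grid_from <- function(m, cell = 30, origin = c(0, 0), ...)
  cov_grid(m, origin = origin, cell_size = cell, ...)

# synthetic use-availability-shaped table generated straight from a logistic
# model (no landscape involved), for engine-level checks
glmm_table <- function(n = 3000, beta = c(WC = 0.5, SVD = 0, NDVI = 0,
                                          ProxW = 0, TRI = -0.3),
                       intercept = log(1 / 10), u_ind = 0, n_ind = 10,
                       seed = 1) {
  b <- setNames(rep(0, 5), c("WC", "SVD", "NDVI", "ProxW", "TRI"))
  b[names(beta)] <- beta
  beta <- b
  set.seed(seed)
  d <- data.frame(WC = rnorm(n, 40, 12), SVD = rnorm(n, 1, 0.3),
                  NDVI = rnorm(n, 0.4, 0.15), ProxW = rnorm(n, 2000, 900),
                  TRI = rnorm(n, 8, 3),
                  in_out = sample(c("inside", "outside"), n, TRUE),
                  moon_pct = runif(n, 0, 100),
                  hour = sample(0:23, n, TRUE),
                  season = sample(c("short_dry", "long_rain"), n, TRUE),
                  year = sample(2016:2017, n, TRUE),
                  area_id = sample(paste0("a", 1:4), n, TRUE),
                  individual_id = sample(paste0("id", 1:n_ind), n, TRUE))
  z <- scale(as.matrix(d[, c("WC", "SVD", "NDVI", "ProxW", "TRI")]))
  u <- rnorm(n_ind, 0, u_ind)
  eta <- intercept + as.vector(z %*% beta) +
    u[as.integer(factor(d$individual_id))]
  d$response <- rbinom(n, 1, plogis(eta))
  class(d) <- c("useavail", "data.frame")
  d
}
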