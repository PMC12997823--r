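# Synthetic landscape and GPS-track generator. Every downstream stage of the
# pipeline (sampling, mixed-model fitting, model selection, cross-validation,
# diel and lunar analyses) is exercised against tracks simulated from known
# selection coefficients, so correctness is checked by parameter recovery
# rather than against external data.

COVARIATES <- c("WC", "SVD", "NDVI", "ProxW", "TRI")
SEASONS <- c("short_dry", "long_rain", "long_dry", "short_rain")

#' Ground-truth simulation parameters
#'
#' Encodes the generative resource-selection model: coefficients for
#' home-range placement over the landscape (2nd order) and for use within the
#' home range (3rd order), an additive shift applied outside the protected
#' core, and optional diel (raised-cosine) and circalunar modulation of the
#' within-range coefficients. All coefficients are on the z-score scale of
#' the landscape's covariates, so one unit is one landscape standard
#' deviation.
#'
#' Defaults describe a stationary mixed-feeding ungulate that places ranges
#' in woody, water-proximate, gentle terrain and, within the range, trades
#' forage (woody cover, vegetation diversity, greenness) against exposure,
#' with an additional shift in woody-cover and water affinity outside the
#' protected core. Temporal modulation defaults to zero (the purely spatial
#' "risky places" truth); tests of the diel and lunar machinery switch it on
#' explicitly.
#'
#' @param beta_landscape,beta_within named numeric vectors over
#'   `c("WC","SVD","NDVI","ProxW","TRI")`.
#' @param delta_outside additive coefficient shift outside the protected
#'   core.
#' @param diel_single per-covariate amplitude of a noon-peaked raised-cosine
#'   modulation of the within-range coefficients.
#' @param diel_double per-covariate amplitude of a dawn/dusk (06:00/18:00
#'   peaks) raised-cosine modulation.
#' @param lunar per-covariate coefficient on moon illumination (fraction
#'   0-1): at full moon the within-range coefficient is shifted by this
#'   amount.
#' @param n_individuals number of tracked individuals.
#' @param fixes_per_individual hourly fixes per individual.
#' @param fix_interval_h fix interval in hours.
#' @param home_range_scale kernel scale sigma of the home-range (metres); the
#'   home-range support is the disc of radius `trunc * home_range_scale`
#'   around the range centre.
#' @param trunc truncation radius of the home-range kernel, in sigmas.
#' @param kernel base density over the home-range support: `"uniform"`
#'   (default; habitat weights act on a flat base, so the use-availability
#'   likelihood recovers the selection coefficients exactly) or
#'   `"gaussian"` (centre-weighted truncated-Gaussian base, a more peaked
#'   utilisation whose radial gradient is *not* part of the fitted model).
#' @param start_window `Date` length-2: individual tracking start dates are
#'   drawn uniformly in this window (staggered deployment).
#' @param seed integer seed for the simulation.
#' @return object of class `truth_config`.
#' @export
truth_config <- function(
    beta_landscape = c(WC = 0.5, SVD = -0.2, NDVI = 0.3, ProxW = -0.4, TRI = -0.2),
    beta_within = c(WC = 0.5, SVD = 0.35, NDVI = 0.35, ProxW = -0.4, TRI = 0.45),
    delta_outside = c(WC = 0.5, SVD = 0, NDVI = 0, ProxW = 0.5, TRI = -0.6),
    diel_single = c(WC = 0, SVD = 0, NDVI = 0, ProxW = 0, TRI = 0),
    diel_double = c(WC = 0, SVD = 0, NDVI = 0, ProxW = 0, TRI = 0),
    lunar = c(WC = 0, SVD = 0, NDVI = 0, ProxW = 0, TRI = 0),
    n_individuals = 36, fixes_per_individual = 5000, fix_interval_h = 1,
    home_range_scale = 750, trunc = 3, kernel = c("uniform", "gaussian"),
    start_window = as.Date(c("2016-04-27", "2017-09-01")),
    seed = 1L) {
  kernel <- match.arg(kernel)
  fix <- function(b) {
    out <- stats::setNames(rep(0, length(COVARIATES)), COVARIATES)
    out[names(b)] <- b
    out
  }
  if (fix_interval_h <= 0) stop("fix_interval_h must be > 0")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  cfg <- list(beta_landscape = fix(beta_landscape),
              beta_within = fix(beta_within),
              delta_outside = fix(delta_outside),
              diel_single = fix(diel_single), diel_double = fix(diel_double),
              lunar = fix(lunar),
              n_individuals = as.integer(n_individuals),
              fixes_per_individual = as.integer(fixes_per_individual),
              fix_interval_h = fix_interval_h,
              home_range_scale = home_range_scale, trunc = trunc,
              kernel = kernel,
              start_window = as.Date(start_window), seed = as.integer(seed))
  if (!all(vapply(cfg[1:6], function(b) all(is.finite(b)), logical(1))))
    stop("truth coefficients must be finite")
  structure(cfg, class = "truth_config")
}

# Spatially autocorrelated standard-normal field: white noise smoothed with a
# truncated-Gaussian kernel by FFT, then re-standardised.
gaussian_field <- function(nr, nc, range_cells) {
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  r <- max(1L, ceiling(2.5 * range_cells))
  off <- seq(-r, r)
  k <- exp(-(outer(off^2, off^2, "+")) / (2 * range_cells^2))
  s <- focal_sum_fft(w, k / sum(k))
  (s - mean(s)) / stats::sd(s)
}

#' Generate a synthetic landscape bundle
#'
#' Builds spatially autocorrelated covariate grids on a common projected
#' grid: woody cover (`WC`, percent), a DEM, a land-cover classification
#' (`n_landcover` classes), four seasonal NDVI layers, and a river/drainage
#' mask, plus a protected-core polygon and management-area polygons tiling
#' the extent. The derived layers `TRI`, `SVD` and `ProxW` are computed with
#' [terrain_ruggedness()], [shannon_focal()] and [proximity_to_water()].
#'
#' @param extent numeric `(xmin, ymin, xmax, ymax)` in metres; at least
#'   10 x 10 km.
#' @param cell_size cell size in metres (default 30).
#' @param seed integer seed.
#' @param n_landcover number of land-cover classes (>= 4).
#' @param svd_radius focal radius for Shannon diversity, metres.
#' @param n_rivers number of river courses.
#' @param range_m autocorrelation range of the random fields, metres.
#' @return object of class `landscape_bundle`: list with `grids` (named
#'   [cov_grid()]s, NDVI as a list by season), `core` (protected-core
#'   polygon), `areas` (management-area polygons tiling the extent),
#'   `extent`, `cell_size`.
#' @export
generate_landscape <- function(extent = c(0, 0, 20000, 20000), cell_size = 30,
                               seed = 1L, n_landcover = 5, svd_radius = 1000,
                               n_rivers = 3, range_m = 600) {
  dx <- extent[3] - extent[1]; dy <- extent[4] - extent[2]
  if (!is.numeric(extent) || length(extent) != 4L || dx < 10000 || dy < 10000)
    stop("degenerate extent: landscape must span at least 10 x 10 km")
  if (n_landcover < 4) stop("need at least 4 land-cover classes")
  set.seed(seed)
  nc <- floor(dx / cell_size); nr <- floor(dy / cell_size)
  org <- extent[1:2]
  rc <- range_m / cell_size
  f_wc <- gaussian_field(nr, nc, rc)
  f_dem <- gaussian_field(nr, nc, 2 * rc)
  f_lc <- gaussian_field(nr, nc, rc)
  f_nd <- gaussian_field(nr, nc, rc)

  wc <- cov_grid(100 * stats::plogis(1.3 * f_wc - 0.2), org, cell_size, "WC")
  xr <- (col(f_dem) - 1) / max(1, nc - 1)
  dem <- cov_grid(1450 + 120 * f_dem + 180 * xr, org, cell_size, "DEM")
  mix <- 0.7 * f_lc + 0.3 * f_wc
  br <- stats::quantile(mix, probs = seq_len(n_landcover - 1) / n_landcover)
  lc <- cov_grid(matrix(findInterval(mix, br) + 1, nr, nc), org, cell_size,
                 "LANDCOVER", categorical = TRUE)

  ndvi <- list()
  # seasonal mean shifts are kept small relative to the spatial variation:
  # the hypothesis models carry no fixed seasonal terms, and under the
  # ratio-matched sampling design season intercepts are unidentifiable, so
  # large shifts would attenuate the NDVI slope by
  # var_spatial / (var_spatial + var_offset) rather than test it
  offs <- c(short_dry = -0.03, long_rain = 0.04, long_dry = -0.04,
            short_rain = 0.02)
  for (s in SEASONS) {
    v <- 0.35 + 0.18 * f_nd + offs[[s]] +
      0.02 * gaussian_field(nr, nc, rc)
    ndvi[[s]] <- cov_grid(pmin(pmax(v, -1), 1), org, cell_size, "NDVI",
                          season_tag = s)
  }

  riv <- matrix(0, nr, nc)
  for (r in seq_len(n_rivers)) {
    i <- sample.int(nr, 1L)
    drift <- cumsum(stats::rnorm(nc, 0, 0.9))
    rows <- pmin(pmax(round(i + drift), 1L), nr)
    riv[cbind(rows, seq_len(nc))] <- 1
  }
  rivers <- cov_grid(riv, org, cell_size, "RIVERS", categorical = TRUE)

  core_frac <- 0.55
  xc <- extent[1] + core_frac * dx
  core <- rect_polygon(extent[1], extent[2], xc, extent[4], id = "core")
  areas <- list(
    core = core,
    buffer_n = rect_polygon(xc, extent[2] + 2 * dy / 3, extent[3], extent[4],
                            id = "buffer_n"),
    buffer_c = rect_polygon(xc, extent[2] + dy / 3, extent[3],
                            extent[2] + 2 * dy / 3, id = "buffer_c"),
    unprotected_s = rect_polygon(xc, extent[2], extent[3],
                                 extent[2] + dy / 3, id = "unprotected_s"))

  grids <- list(WC = wc, DEM = dem, LANDCOVER = lc, NDVI = ndvi,
                RIVERS = rivers,
                TRI = terrain_ruggedness(dem),
                SVD = shannon_focal(lc, radius = svd_radius),
                ProxW = proximity_to_water(rivers))
  structure(list(grids = grids, core = core, areas = areas, extent = extent,
                 cell_size = cell_size, seed = seed),
            class = "landscape_bundle")
}

#' @export
print.landscape_bundle <- function(x, ...) {
  cat(sprintf("<landscape_bundle> %g x %g km @ %g m, %d management areas\n",
              (x$extent[3] - x$extent[1]) / 1000,
              (x$extent[4] - x$extent[2]) / 1000,
              x$cell_size, length(x$areas)))
  invisible(x)
}

#' The five analysis grids of a bundle
#'
#' Returns the `WC`, `SVD`, `NDVI`, `ProxW`, `TRI` grids, with NDVI for one
#' season (`"mean"` = across-season mean layer, the landscape-level
#' convention).
#'
#' @param bundle a [generate_landscape()] bundle.
#' @param season season label or `"mean"`.
#' @return named list of [cov_grid()]s.
#' @export
covariate_stack <- function(bundle, season = "mean") {
  g <- bundle$grids
  ndvi <- if (identical(season, "mean")) {
    m <- Reduce(`+`, lapply(g$NDVI, function(x) x$values)) / length(g$NDVI)
    cov_grid(m, g$WC$origin, g$WC$cell_size, "NDVI")
  } else g$NDVI[[season]]
  list(WC = g$WC, SVD = g$SVD, NDVI = ndvi, ProxW = g$ProxW, TRI = g$TRI)
}

#' Landscape-wide z-scaling of the five covariates
#'
#' Mean and standard deviation of each covariate over all landscape cells
#' (NDVI pooled across the four seasonal layers). The truth coefficients of
#' [truth_config()] are expressed per one of these standard deviations.
#'
#' @param bundle a [generate_landscape()] bundle.
#' @return data.frame with `covariate`, `mean`, `sd`.
#' @export
landscape_scaling <- function(bundle) {
  vals <- lapply(COVARIATES, function(cv) {
    if (cv == "NDVI")
      unlist(lapply(bundle$grids$NDVI, function(x) as.vector(x$values)))
    else as.vector(bundle$grids[[cv]]$values)
  })
  data.frame(covariate = COVARIATES,
             mean = vapply(vals, function(v) mean(v, na.rm = TRUE), 0),
             sd = vapply(vals, function(v) stats::sd(v, na.rm = TRUE), 0))
}

#' Raised-cosine daily templates
#'
#' The two diel template regressors, shared by the track generator and the
#' diel analysis: `single` = `(1 + cos(2 pi (h - 12) / 24)) / 2` (peak noon,
#' trough midnight); `double` = `(1 + cos(2 pi (h - 6) / 12)) / 2` (peaks
#' 06:00 and 18:00).
#'
#' @param hour hour of day (0-23, fractions allowed).
#' @param template `"single"` or `"double"`.
#' @return numeric template values in `[0, 1]`.
#' @export
raised_cosine_template <- function(hour, template = c("single", "double")) {
  template <- match.arg(template)
  if (template == "single") (1 + cos(2 * pi * (hour - 12) / 24)) / 2
  else (1 + cos(2 * pi * (hour - 6) / 12)) / 2
}

#' Simulate GPS tracks from known selection parameters
#'
#' Realises the point-process resource-selection model: (i) each individual's
#' range centre is drawn over the landscape with probability proportional to
#' `exp(beta_landscape . x)` of kernel-smoothed local mean covariates
#' (half of the individuals inside the protected core and half outside, so
#' the inside/outside contrast is always populated); (ii) given the centre,
#' hourly used points are drawn from the cells of the home-range support
#' (the disc of radius `trunc * home_range_scale`) with weight proportional
#' to `base(cell) * exp(b(t) . x(cell))`, where the base density is uniform
#' by default (see the `kernel` argument of [truth_config()]) and
#' `b(t) = beta_within + delta_outside * [outside core] + diel and lunar
#' modulation` at the hour and moon illumination of `t`. Moon illumination is
#' discretised to 5% steps inside the sampler.
#'
#' @param bundle a [generate_landscape()] bundle.
#' @param truth a [truth_config()].
#' @param moon a moon series covering the tracking period; default is the
#'   synthetic circalunar cosine.
#' @return object of class `track_list`: a list of `track` objects (fields
#'   `individual_id`, `relocations` data.frame with `timestamp`, `x`, `y`,
#'   `mcp`, `area_id`, `centre`), with attributes `scaling` (the landscape
#'   z-scaling the truth coefficients refer to) and `truth`.
#' @export
simulate_tracks <- function(bundle, truth, moon = NULL) {
  stopifnot(inherits(bundle, "landscape_bundle"),
            inherits(truth, "truth_config"))
  set.seed(truth$seed)
  scaling <- landscape_scaling(bundle)
  cs <- bundle$cell_size
  sigma_c <- truth$home_range_scale / cs
  trunc_c <- truth$trunc * sigma_c

  # guard against weight overflow before any sampling
  worst <- abs(truth$beta_within) + abs(truth$delta_outside) +
    abs(truth$diel_single) + abs(truth$diel_double) + abs(truth$lunar)
  if (any(worst * 4 > 40)) # |z| rarely exceeds 4
    stop("selection weights collapse: coefficient too large for covariate ",
         COVARIATES[which.max(worst)])

  if (is.null(moon))
    moon <- moon_series_synthetic(
      truth$start_window[1] - 1,
      truth$start_window[2] +
        ceiling(truth$fixes_per_individual * truth$fix_interval_h / 24) + 2)

  stacks <- lapply(c(SEASONS), function(s) covariate_stack(bundle, s))
  names(stacks) <- SEASONS
  zmat <- function(stack, idx) {
    m <- vapply(COVARIATES, function(cv) stack[[cv]]$values[idx],
                numeric(nrow(idx)))
    sweep(sweep(m, 2, scaling$mean), 2, scaling$sd, "/")
  }

  # --- range centres -------------------------------------------------------
  ref <- bundle$grids$WC
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  ctr <- grid_centres(ref)
  sm_k <- {
    r <- max(1L, ceiling(2 * sigma_c)); off <- seq(-r, r)
    k <- exp(-outer(off^2, off^2, "+") / (2 * sigma_c^2)); k / sum(k)
  }
  mean_stack <- covariate_stack(bundle, "mean")
  lp <- matrix(0, nr, nc)
  for (cv in COVARIATES) {
    sm <- focal_sum_fft(mean_stack[[cv]]$values, sm_k)
    z <- (sm - scaling$mean[scaling$covariate == cv]) /
      scaling$sd[scaling$covariate == cv]
    lp <- lp + truth$beta_landscape[[cv]] * z
  }
  margin <- ceiling(trunc_c) + 1L
  ok <- matrix(FALSE, nr, nc)
  ok[margin:(nr - margin), margin:(nc - margin)] <- TRUE
  cx <- rep(ctr$x, each = nr); cy <- rep(ctr$y, times = nc)
  inside_core <- matrix(point_in_polygon(bundle$core, cx, cy), nr, nc)
  pick_centres <- function(cand, n) {
    w <- exp(lp[cand] - max(lp[cand]))
    cand[sample.int(length(cand), n, replace = FALSE, prob = w)]
  }
  n_out <- ceiling(truth$n_individuals / 2)
  n_in <- truth$n_individuals - n_out
  id_in <- which(ok & inside_core); id_out <- which(ok & !inside_core)
  if (length(id_in) < n_in || length(id_out) < n_out)
    stop("extent too small to place range centres on both sides of the core")
  centres <- c(if (n_in > 0) pick_centres(id_in, n_in),
               if (n_out > 0) pick_centres(id_out, n_out))
  if (length(centres) > 1L)
    centres <- sample(centres)  # shuffle so ids are not ordered by side

  # --- per-individual hourly draws ----------------------------------------
  # systematically staggered deployment: one start per equal slice of the
  # window (jittered within the slice), so the year and season-in-year
  # factors are populated even with few individuals
  W <- as.integer(diff(truth$start_window))
  slice <- (seq_len(truth$n_individuals) - stats::runif(truth$n_individuals)) /
    truth$n_individuals
  start_dates <- truth$start_window[1] + floor(slice * W)
  tracks <- vector("list", truth$n_individuals)
  for (ind in seq_len(truth$n_individuals)) {
    cell <- centres[ind]
    ci <- ((cell - 1L) %% nr) + 1L; cj <- ((cell - 1L) %/% nr) + 1L
    ri <- max(1L, ci - ceiling(trunc_c)):min(nr, ci + ceiling(trunc_c))
    rj <- max(1L, cj - ceiling(trunc_c)):min(nc, cj + ceiling(trunc_c))
    loc <- expand.grid(i = ri, j = rj)
    d2 <- (loc$i - ci)^2 + (loc$j - cj)^2
    keep <- d2 <= trunc_c^2
    loc <- loc[keep, ]; d2 <- d2[keep]
    idx <- cbind(loc$i, loc$j)
    # log base density over the support: flat (uniform) or centre-weighted
    lk <- if (truth$kernel == "uniform") 0 else -d2 / (2 * sigma_c^2)
    px <- ctr$x[loc$j]; py <- ctr$y[loc$i]
    outside <- !point_in_polygon(bundle$core, px, py)
    Xs <- lapply(stacks, zmat, idx = idx)
    delta_term <- lapply(Xs, function(X)
      as.vector(X %*% truth$delta_outside) * outside)

    ts <- as.POSIXct(paste(start_dates[ind], "00:00:00"), tz = "UTC") +
      (seq_len(truth$fixes_per_individual) - 1L) * truth$fix_interval_h * 3600
    hour_local <- (as.POSIXlt(ts, tz = "UTC")$hour + 3L) %% 24L # UTC+3
    seas <- season_of(ts)
    mpct <- round(moon_at(moon, ts) / 5) * 5
    # weight vectors are shared across fixes whose b(t) coincides; hour and
    # moon only enter the key when they actually modulate the coefficients
    mod_hour <- any(truth$diel_single != 0) || any(truth$diel_double != 0)
    mod_moon <- any(truth$lunar != 0)
    combo <- paste(seas,
                   if (mod_hour) hour_local else 0L,
                   if (mod_moon) mpct else 0L)
    xy <- matrix(NA_real_, length(ts), 2L)
    for (cmb in unique(combo)) {
      rows <- which(combo == cmb)
      s <- seas[rows[1L]]; h <- hour_local[rows[1L]]; m <- mpct[rows[1L]]
      b <- truth$beta_within +
        truth$diel_single * raised_cosine_template(h, "single") +
        truth$diel_double * raised_cosine_template(h, "double") +
        truth$lunar * (m / 100)
      lw <- lk + as.vector(Xs[[s]] %*% b) + delta_term[[s]]
      w <- exp(lw - max(lw))
      cw <- cumsum(w)
      pick <- findInterval(stats::runif(length(rows)) * cw[length(cw)], cw) + 1L
      xy[rows, 1L] <- px[pick] + stats::runif(length(rows), -0.5, 0.5) * cs
      xy[rows, 2L] <- py[pick] + stats::runif(length(rows), -0.5, 0.5) * cs
    }
    reloc <- data.frame(timestamp = ts, x = xy[, 1L], y = xy[, 2L])
    hull <- mcp(reloc$x, reloc$y, id = sprintf("id%02d", ind))
    cxy <- c(ctr$x[cj], ctr$y[ci])
    area_id <- names(bundle$areas)[vapply(bundle$areas, function(p)
      point_in_polygon(p, cxy[1], cxy[2]), logical(1))][1L]
    tracks[[ind]] <- structure(
      list(individual_id = sprintf("id%02d", ind), relocations = reloc,
           mcp = hull, area_id = area_id, centre = cxy),
      class = "track")
  }
  structure(tracks, class = "track_list", scaling = scaling, truth = truth,
            moon = moon)
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> %d fixes, MCP %.1f km2, area %s\n",
              x$individual_id, nrow(x$relocations),
              attr(x$mcp, "area_km2"), x$area_id))
  invisible(x)
}

#' @export
print.track_list <- function(x, ...) {
  cat(sprintf("<track_list> %d individuals, %d fixes total\n", length(x),
              sum(vapply(x, function(t) nrow(t$relocations), 0L))))
  invisible(x)
}

#' Truth coefficients on the raw covariate scale
#'
#' Converts the z-scale truth coefficients of a [truth_config()] into
#' per-raw-unit coefficients using the landscape scaling attached to a
#' simulated [simulate_tracks()] result, for comparison with back-transformed
#' fitted coefficients.
#'
#' @param tracks a `track_list`.
#' @param component `"beta_within"`, `"beta_landscape"` or `"delta_outside"`.
#' @return named numeric vector over the five covariates.
#' @export
truth_raw_coefficients <- function(tracks, component = "beta_within") {
  truth <- attr(tracks, "truth"); scaling <- attr(tracks, "scaling")
  truth[[component]] / stats::setNames(scaling$sd, scaling$covariate)
}

#' Write tracks to CSV
#'
#' @param tracks a `track_list`.
#' @param path output CSV path (columns `individual_id`, `timestamp`, `x`,
#'   `y`).
#' @return `path` invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  d <- do.call(rbind, lapply(tracks, function(t)
    data.frame(individual_id = t$individual_id,
               timestamp = format(t$relocations$timestamp,
                                  "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               x = t$relocations$x, y = t$relocations$y)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
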