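# Two-level use-availability sampling design: landscape-level (2nd order,
# range placement) and home-range-level (3rd order, within-range use) tables,
# plus the 24 hourly split tables.

#' Number of available points for a relocation total
#'
#' Ten times the average number of relocations per hour of day, rounded to
#' the nearest integer: `round(10 * n / 24)`.
#'
#' @param n_relocations total relocation count.
#' @return integer count of available points.
#' @export
availability_count <- function(n_relocations) {
  stopifnot(n_relocations >= 0)
  round(10 * n_relocations / 24)
}

#' Study-region polygon of a landscape bundle
#'
#' @param bundle a [generate_landscape()] bundle.
#' @return a [simple_polygon()] covering the extent.
#' @export
study_region <- function(bundle) {
  e <- bundle$extent
  rect_polygon(e[1], e[2], e[3], e[4], id = "study_region")
}

# Largest-remainder apportionment of n among weights (exact total).
apportion <- function(weights, n) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(q - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Draw available points
#'
#' Uniform random points either across one region polygon (landscape level)
#' or within each individual's MCP with per-individual counts proportional to
#' that individual's number of relocations (home-range level). If `grids` is
#' supplied, points falling on nodata background are dropped and the dropped
#' count is reported in attribute `n_dropped` (they are not resampled).
#'
#' @param region a [simple_polygon()]; mutually exclusive with `tracks`.
#' @param tracks a `track_list` (uses each track's MCP).
#' @param n total number of points.
#' @param seed integer seed.
#' @param proportional_by_individual if `FALSE`, points are split equally
#'   among individuals.
#' @param grids optional named list of [cov_grid()]s used to drop
#'   nodata-background points.
#' @return data.frame with `x`, `y` and (for MCP draws) `individual_id`;
#'   attribute `n_dropped`.
#' @export
draw_available <- function(region = NULL, tracks = NULL, n, seed = 1L,
                           proportional_by_individual = TRUE, grids = NULL) {
  set.seed(seed)
  if (!is.null(region) && !is.null(tracks))
    stop("give either a region or tracks, not both")
  if (is.null(region) && is.null(tracks))
    stop("give a region or tracks")
  if (!is.null(region)) {
    pts <- runif_in_polygon(region, n)
  } else {
    n_fix <- vapply(tracks, function(t) nrow(t$relocations), 0L)
    counts <- if (proportional_by_individual) apportion(n_fix, n)
              else apportion(rep(1, length(tracks)), n)
    pts <- do.call(rbind, lapply(seq_along(tracks), function(i) {
      p <- runif_in_polygon(tracks[[i]]$mcp, counts[i])
      if (counts[i] > 0) p$individual_id <- tracks[[i]]$individual_id
      p
    }))
  }
  n_dropped <- 0L
  if (!is.null(grids)) {
    vals <- vapply(grids, function(g) grid_lookup(g, pts$x, pts$y),
                   numeric(nrow(pts)))
    keep <- stats::complete.cases(vals)
    n_dropped <- sum(!keep)
    pts <- pts[keep, , drop = FALSE]
  }
  attr(pts, "n_dropped") <- n_dropped
  pts
}

# Management-area id containing each point (areas tile the extent).
area_of_points <- function(bundle, x, y) {
  out <- rep(NA_character_, length(x))
  for (nm in names(bundle$areas)) {
    hit <- is.na(out) & point_in_polygon(bundle$areas[[nm]], x, y)
    out[hit] <- nm
  }
  out
}

#' Extract the five analysis covariates at points
#'
#' Nearest-cell lookup of `WC`, `SVD`, `NDVI`, `ProxW`, `TRI` at point
#' locations. `season` selects the NDVI layer: `"mean"` (across-season mean,
#' the landscape-level convention) or a per-point vector of season labels.
#'
#' @param bundle a [generate_landscape()] bundle.
#' @param x,y point coordinates, metres.
#' @param season `"mean"` or a character vector of season labels per point.
#' @return data.frame with one column per covariate.
#' @export
extract_covariates <- function(bundle, x, y, season = "mean") {
  if (length(season) == 1L && season == "mean") {
    stack <- covariate_stack(bundle, "mean")
    out <- vapply(stack, function(g) grid_lookup(g, x, y), numeric(length(x)))
    return(as.data.frame(out))
  }
  out <- matrix(NA_real_, length(x), length(COVARIATES),
                dimnames = list(NULL, COVARIATES))
  for (s in unique(season)) {
    rows <- which(season == s)
    stack <- covariate_stack(bundle, s)
    out[rows, ] <- vapply(stack, function(g) grid_lookup(g, x[rows], y[rows]),
                          numeric(length(rows)))
  }
  as.data.frame(out)
}

# Assemble a use-availability data.frame with the fixed column order.
ua_table <- function(response, cov, in_out, moon_pct, hour, season, year,
                     area_id, individual_id, level) {
  d <- data.frame(response = as.integer(response), cov,
                  in_out = factor(in_out, levels = c("inside", "outside")),
                  moon_pct = moon_pct, hour = hour, season = season,
                  year = year, area_id = area_id,
                  individual_id = individual_id, level = level,
                  stringsAsFactors = FALSE)
  keep <- stats::complete.cases(d[, COVARIATES])
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("useavail", "data.frame")
  out
}

in_out_of <- function(bundle, x, y)
  ifelse(point_in_polygon(bundle$core, x, y), "inside", "outside")

all_relocations <- function(tracks) {
  do.call(rbind, lapply(tracks, function(t)
    data.frame(individual_id = t$individual_id, t$relocations)))
}

# Local solar hour used throughout (fixed UTC+3 offset of the synthetic
# world); hour = floor of the clock hour.
local_hour <- function(timestamp) (as.POSIXlt(timestamp, tz = "UTC")$hour + 3L) %% 24L

local_year <- function(timestamp) as.POSIXlt(timestamp, tz = "UTC")$year + 1900L

#' Build the landscape-level use-availability table
#'
#' Available rows are all study-region random points; used rows are a seeded
#' 10% subsample of the MCP random points. NDVI is the across-season mean
#' layer at this level (rows carry no timestamp). Rows with missing
#' background are dropped and counted in attribute `n_dropped`.
#'
#' @param region_points data.frame of study-region random points.
#' @param mcp_points data.frame of MCP random points with `individual_id`.
#' @param bundle a [generate_landscape()] bundle.
#' @param tracks optional `track_list`; when given, available rows are
#'   assigned an individual id drawn proportional to relocation counts so
#'   the individual random intercept is defined for every row (rows without
#'   an id would otherwise fall out of the mixed-model fit).
#' @param seed integer seed for the used-point subsample.
#' @param used_fraction fraction of MCP points taken as used rows (default
#'   0.10).
#' @return a `useavail` data.frame (`level = "landscape"`).
#' @export
build_landscape_table <- function(region_points, mcp_points, bundle,
                                  tracks = NULL, seed = 1L,
                                  used_fraction = 0.1) {
  stopifnot(nrow(region_points) > 0, nrow(mcp_points) > 0)
  set.seed(seed)
  n_used <- round(nrow(mcp_points) * used_fraction)
  if (n_used < 1L) stop("used subsample is empty")
  used <- mcp_points[sample.int(nrow(mcp_points), n_used), , drop = FALSE]
  avail_id <- rep(NA_character_, nrow(region_points))
  if (!is.null(tracks)) {
    n_fix <- vapply(tracks, function(t) nrow(t$relocations), 0L)
    ids <- vapply(tracks, `[[`, "", "individual_id")
    avail_id <- sample(ids, nrow(region_points), replace = TRUE,
                       prob = n_fix / sum(n_fix))
  }
  x <- c(used$x, region_points$x); y <- c(used$y, region_points$y)
  ua_table(
    response = rep(c(1L, 0L), c(nrow(used), nrow(region_points))),
    cov = extract_covariates(bundle, x, y, "mean"),
    in_out = in_out_of(bundle, x, y),
    moon_pct = NA_real_, hour = NA_integer_,
    season = NA_character_, year = NA_integer_,
    area_id = area_of_points(bundle, x, y),
    individual_id = c(used$individual_id, avail_id),
    level = "landscape")
}

# Season of the midpoint of an individual's tracking period, per track.
midpoint_season <- function(tracks) {
  vapply(tracks, function(t) {
    ts <- t$relocations$timestamp
    season_of(ts[1] + (as.numeric(ts[length(ts)]) - as.numeric(ts[1])) / 2)
  }, character(1))
}

# Assign each available point a timestamp drawn from its individual's
# relocations (restricted to `hour_filter` when given), so temporal
# covariates and grouping factors are populated for available rows.
assign_available_timestamps <- function(mcp_points, tracks, hour_filter = NULL) {
  ts_by_id <- lapply(tracks, function(t) {
    ts <- t$relocations$timestamp
    if (!is.null(hour_filter)) ts <- ts[local_hour(ts) == hour_filter]
    ts
  })
  names(ts_by_id) <- vapply(tracks, `[[`, "", "individual_id")
  out <- as.POSIXct(rep(NA_real_, nrow(mcp_points)), origin = "1970-01-01",
                    tz = "UTC")
  for (id in unique(mcp_points$individual_id)) {
    rows <- which(mcp_points$individual_id == id)
    pool <- ts_by_id[[id]]
    out[rows] <- pool[sample.int(length(pool), length(rows), replace = TRUE)]
  }
  out
}

#' Build the home-range-level use-availability table
#'
#' Available rows are all MCP random points; used rows are a seeded `frac`
#' (default 1/24) subsample of all relocations, carrying their own hour,
#' season, year and moon illumination. Available rows draw a timestamp from
#' the same individual's relocations so that temporal terms and grouping
#' factors are defined; their NDVI follows `ndvi_available`: the season at
#' the midpoint of the individual's tracking period (default) or the season
#' of the drawn timestamp.
#'
#' @param mcp_points data.frame of MCP random points with `individual_id`.
#' @param tracks a `track_list`.
#' @param bundle a [generate_landscape()] bundle.
#' @param moon a moon series.
#' @param seed integer seed.
#' @param frac fraction of relocations used (default 1/24).
#' @param ndvi_available `"midpoint"` or `"timestamp"`.
#' @return a `useavail` data.frame (`level = "homerange"`).
#' @export
build_homerange_table <- function(mcp_points, tracks, bundle, moon,
                                  seed = 1L, frac = 1 / 24,
                                  ndvi_available = c("midpoint", "timestamp")) {
  ndvi_available <- match.arg(ndvi_available)
  set.seed(seed)
  reloc <- all_relocations(tracks)
  n_used <- round(nrow(reloc) * frac)
  used <- reloc[sample.int(nrow(reloc), n_used), , drop = FALSE]
  av_ts <- assign_available_timestamps(mcp_points, tracks)
  mseason <- midpoint_season(tracks)
  names(mseason) <- vapply(tracks, `[[`, "", "individual_id")
  av_season_ndvi <- switch(ndvi_available,
    midpoint = unname(mseason[mcp_points$individual_id]),
    timestamp = season_of(av_ts))
  x <- c(used$x, mcp_points$x); y <- c(used$y, mcp_points$y)
  ua_table(
    response = rep(c(1L, 0L), c(nrow(used), nrow(mcp_points))),
    cov = extract_covariates(bundle, x, y,
                             c(season_of(used$timestamp), av_season_ndvi)),
    in_out = in_out_of(bundle, x, y),
    moon_pct = c(moon_at(moon, used$timestamp), moon_at(moon, av_ts)),
    hour = c(local_hour(used$timestamp), local_hour(av_ts)),
    season = c(season_of(used$timestamp), season_of(av_ts)),
    year = c(local_year(used$timestamp), local_year(av_ts)),
    area_id = area_of_points(bundle, x, y),
    individual_id = c(used$individual_id, mcp_points$individual_id),
    level = "homerange")
}

#' Build the 24 hourly use-availability tables
#'
#' For each hour of day `h`, used rows are all relocations whose local hour
#' equals `h` and available rows are all MCP random points (the same set in
#' every table).
#'
#' @inheritParams build_homerange_table
#' @return named list of 24 `useavail` data.frames (`"h0"` ... `"h23"`).
#' @export
build_hourly_tables <- function(mcp_points, tracks, bundle, moon, seed = 1L,
                                ndvi_available = c("midpoint", "timestamp")) {
  ndvi_available <- match.arg(ndvi_available)
  set.seed(seed)
  reloc <- all_relocations(tracks)
  hr <- local_hour(reloc$timestamp)
  missing_h <- setdiff(0:23, unique(hr))
  if (length(missing_h) > 0)
    stop("no relocations for hour ", paste(missing_h, collapse = ", "))
  mseason <- midpoint_season(tracks)
  names(mseason) <- vapply(tracks, `[[`, "", "individual_id")
  out <- vector("list", 24L)
  names(out) <- paste0("h", 0:23)
  for (h in 0:23) {
    used <- reloc[hr == h, , drop = FALSE]
    av_ts <- assign_available_timestamps(mcp_points, tracks, hour_filter = h)
    av_season_ndvi <- switch(ndvi_available,
      midpoint = unname(mseason[mcp_points$individual_id]),
      timestamp = season_of(av_ts))
    x <- c(used$x, mcp_points$x); y <- c(used$y, mcp_points$y)
    out[[h + 1L]] <- ua_table(
      response = rep(c(1L, 0L), c(nrow(used), nrow(mcp_points))),
      cov = extract_covariates(bundle, x, y,
                               c(season_of(used$timestamp), av_season_ndvi)),
      in_out = in_out_of(bundle, x, y),
      moon_pct = c(moon_at(moon, used$timestamp), moon_at(moon, av_ts)),
      hour = h,
      season = c(season_of(used$timestamp), season_of(av_ts)),
      year = c(local_year(used$timestamp), local_year(av_ts)),
      area_id = area_of_points(bundle, x, y),
      individual_id = c(used$individual_id, mcp_points$individual_id),
      level = "hourly")
  }
  out
}

#' Write a use-availability table to CSV with a manifest
#'
#' @param table a `useavail` data.frame.
#' @param path CSV path; a `<path>.manifest.json` records row counts and the
#'   dropped-point count.
#' @return `path` invisibly.
#' @export
write_useavail_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(
    list(n_rows = nrow(table), n_used = sum(table$response == 1),
         n_available = sum(table$response == 0),
         n_dropped = attr(table, "n_dropped")),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}
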