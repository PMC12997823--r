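# Derivation of the five analysis covariates and the temporal covariates
# (season calendar, moon illumination) on a common 30 m grid.

# Focal sums of a (possibly weighted) indicator matrix via FFT convolution.
# Zero-padded linear convolution; values outside the grid contribute nothing.
focal_sum_fft <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  pm <- matrix(0, pr, pc); pm[1:nr, 1:nc] <- m
  pk <- matrix(0, pr, pc); pk[1:kr, 1:kc] <- kernel
  conv <- Re(stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE)) / (pr * pc)
  off <- (kr - 1L) %/% 2L
  conv[(off + 1L):(off + nr), (off + 1L):(off + nc), drop = FALSE]
}

# Circular focal kernel: cell at offset (dy, dx) belongs to the buffer iff its
# centre lies within `radius` metres of the focal cell centre. With
# fractional = TRUE each cell is weighted by the fraction of a 5x5 subgrid of
# its area falling inside the circle.
focal_kernel <- function(radius, cell_size, fractional = FALSE, max_r = Inf) {
  r <- min(ceiling(radius / cell_size), max_r)
  off <- seq(-r, r)
  dx <- outer(rep(1, length(off)), off) * cell_size
  dy <- outer(off, rep(1, length(off))) * cell_size
  if (!fractional) {
    k <- (sqrt(dx^2 + dy^2) <= radius) * 1
  } else {
    s <- (seq_len(5) - 3) / 5 * cell_size
    k <- matrix(0, length(off), length(off))
    for (ax in s) for (ay in s)
      k <- k + (sqrt((dx + ax)^2 + (dy + ay)^2) <= radius)
    k <- k / 25
  }
  k
}

#' Focal Shannon diversity of a land-cover grid
#'
#' For every cell, computes the Shannon diversity index
#' \eqn{H = -\sum_k p_k \ln p_k} of land-cover class proportions among the
#' cells of a circular buffer around the focal cell (default radius 1 km). A
#' cell belongs to the buffer iff its centre lies within `radius` of the focal
#' cell centre; `weights = "fractional"` instead weights border cells by the
#' approximate fraction of their area inside the circle. Nodata cells are
#' excluded from the proportions; a window containing only nodata yields a
#' nodata cell.
#'
#' @param landcover a categorical [cov_grid()] of integer class codes.
#' @param radius buffer radius in metres (default 1000).
#' @param weights `"centre"` (default) or `"fractional"`.
#' @return a [cov_grid()] named `"SVD"`.
#' @export
shannon_focal <- function(landcover, radius = 1000,
                          weights = c("centre", "fractional")) {
  weights <- match.arg(weights)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  v <- landcover$values
  classes <- sort(unique(as.vector(v[!is.na(v)])))
  if (length(classes) == 0L) stop("landcover grid holds no data")
  kern <- focal_kernel(radius, landcover$cell_size,
                       fractional = weights == "fractional",
                       max_r = max(dim(v)))  # wider reaches every cell anyway
  counts <- vector("list", length(classes))
  total <- matrix(0, nrow(v), ncol(v))
  for (k in seq_along(classes)) {
    ind <- (!is.na(v) & v == classes[k]) * 1
    ck <- focal_sum_fft(ind, kern)
    ck[ck < 0] <- 0
    if (weights == "centre") ck <- round(ck)  # integer counts, kill FFT noise
    counts[[k]] <- ck
    total <- total + ck
  }
  H <- matrix(0, nrow(v), ncol(v))
  for (k in seq_along(classes)) {
    p <- counts[[k]] / total
    term <- -p * log(p)
    term[!is.finite(term)] <- 0  # p = 0 contributes nothing
    H <- H + term
  }
  H[total < 1e-9] <- NA_real_  # all-nodata window
  H[abs(H) < 1e-12] <- 0
  cov_grid(H, landcover$origin, landcover$cell_size, name = "SVD")
}

#' Terrain ruggedness index
#'
#' Riley-style TRI: for each cell, the square root of the summed squared
#' elevation differences between the cell and its eight neighbours. Edge and
#' corner cells use the available neighbour subset, so the index is defined to
#' the grid edge. `NA` elevations propagate: a neighbour with `NA` is skipped,
#' and an `NA` focal cell stays `NA`.
#'
#' @param dem a [cov_grid()] of elevations (metres), at least 3x3.
#' @return a [cov_grid()] named `"TRI"`.
#' @export
terrain_ruggedness <- function(dem) {
  v <- dem$values
  if (nrow(v) < 3L || ncol(v) < 3L) stop("DEM must be at least 3x3 cells")
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(0, nr, nc)
  shift <- function(m, di, dj) {
    out <- matrix(NA_real_, nr, nc)
    ri <- seq_len(nr) + di; rj <- seq_len(nc) + dj
    ok_i <- ri >= 1L & ri <= nr; ok_j <- rj >= 1L & rj <= nc
    out[ok_i, ok_j] <- m[ri[ok_i], rj[ok_j]]
    out
  }
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    d2 <- (v - shift(v, di, dj))^2
    d2[is.na(d2)] <- 0  # missing neighbour: excluded from the sum
    acc <- acc + d2
  }
  out <- sqrt(acc)
  out[is.na(v)] <- NA_real_
  cov_grid(out, dem$origin, dem$cell_size, name = "TRI")
}

#' Proximity to water
#'
#' Euclidean distance (metres, cell centre to cell centre) from every cell to
#' the nearest river/drainage cell of a binary mask, computed with the exact
#' two-pass parabolic-envelope distance transform (linear in the number of
#' cells).
#'
#' @param rivers a [cov_grid()] where river cells are `1` (non-river `0` or
#'   `NA`).
#' @return a [cov_grid()] named `"ProxW"`.
#' @export
proximity_to_water <- function(rivers) {
  v <- rivers$values
  is_river <- !is.na(v) & v == 1
  if (!any(is_river)) stop("no water features in river mask")
  BIG <- 1e20
  f <- matrix(BIG, nrow(v), ncol(v))
  f[is_river] <- 0
  # pass 1: squared distance along each row (over columns)
  for (i in seq_len(nrow(f))) f[i, ] <- dt1d_sq(f[i, ])
  # pass 2: combine along each column
  for (j in seq_len(ncol(f))) f[, j] <- dt1d_sq(f[, j])
  cov_grid(sqrt(f) * rivers$cell_size, rivers$origin, rivers$cell_size,
           name = "ProxW")
}

# Exact 1-D squared-distance transform (lower envelope of parabolas),
# Felzenszwalb-Huttenlocher style. `f` holds squared costs; sites use 0.
dt1d_sq <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2L:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    while (k > 1L && s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
    }
    if (s <= z[k]) { v[k] <- q } else { k <- k + 1L; v[k] <- q }
    z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Resample grids to a common grid
#'
#' Brings a bundle of overlapping grids onto one origin, cell size and set of
#' dimensions (default 30 m). Continuous layers are interpolated bilinearly
#' between source cell centres (clamped at the edges); categorical layers use
#' nearest-neighbour lookup.
#'
#' @param grids list of [cov_grid()] objects with overlapping extents.
#' @param cell_size target cell size in metres (default 30).
#' @return list of aligned [cov_grid()] objects.
#' @export
resample_to_common_grid <- function(grids, cell_size = 30) {
  stopifnot(length(grids) >= 1L)
  exts <- vapply(grids, grid_extent, numeric(4))
  xmin <- max(exts["xmin", ]); ymin <- max(exts["ymin", ])
  xmax <- min(exts["xmax", ]); ymax <- min(exts["ymax", ])
  if (xmax - xmin < cell_size || ymax - ymin < cell_size)
    stop("grids have disjoint (or sub-cell) common extent")
  nc <- floor((xmax - xmin) / cell_size + 1e-9)
  nr <- floor((ymax - ymin) / cell_size + 1e-9)
  tx <- xmin + (seq_len(nc) - 0.5) * cell_size
  ty <- ymin + (seq_len(nr) - 0.5) * cell_size
  lapply(grids, function(g) {
    vals <- if (g$categorical) {
      matrix(grid_lookup(g, rep(tx, each = nr), rep(ty, times = nc)), nr, nc)
    } else {
      bilinear_grid(g, tx, ty)
    }
    cov_grid(vals, origin = c(xmin, ymin), cell_size = cell_size,
             name = g$name, categorical = g$categorical,
             season_tag = g$season_tag)
  })
}

# Bilinear interpolation of grid g at the tensor grid (tx x ty) of target
# cell centres; queries beyond the outermost source centres are clamped.
bilinear_grid <- function(g, tx, ty) {
  ctr <- grid_centres(g)
  fx <- (tx - ctr$x[1]) / g$cell_size
  fy <- (ty - ctr$y[1]) / g$cell_size
  j0 <- pmin(pmax(floor(fx), 0), length(ctr$x) - 2L)
  i0 <- pmin(pmax(floor(fy), 0), length(ctr$y) - 2L)
  wx <- pmin(pmax(fx - j0, 0), 1)
  wy <- pmin(pmax(fy - i0, 0), 1)
  if (length(ctr$x) == 1L) { j0 <- rep(0L, length(tx)); wx <- rep(0, length(tx)) }
  if (length(ctr$y) == 1L) { i0 <- rep(0L, length(ty)); wy <- rep(0, length(ty)) }
  v <- g$values
  nr <- length(ty); nc <- length(tx)
  I0 <- rep(i0 + 1L, times = nc); J0 <- rep(j0 + 1L, each = nr)
  WX <- rep(wx, each = nr); WY <- rep(wy, times = nc)
  i1 <- pmin(I0 + 1L, nrow(v)); j1 <- pmin(J0 + 1L, ncol(v))
  out <- (1 - WX) * (1 - WY) * v[cbind(I0, J0)] +
    WX * (1 - WY) * v[cbind(I0, j1)] +
    (1 - WX) * WY * v[cbind(i1, J0)] +
    WX * WY * v[cbind(i1, j1)]
  matrix(out, nr, nc)
}

#' Season of a timestamp
#'
#' Quarterly calendar used throughout: short dry (Jan-Mar), long rain
#' (Apr-Jun), long dry (Jul-Sep), short rain (Oct-Dec).
#'
#' @param timestamp `POSIXct`/`Date` vector (or anything `as.POSIXlt` takes).
#' @return character vector in
#'   `c("short_dry", "long_rain", "long_dry", "short_rain")`.
#' @export
season_of <- function(timestamp) {
  m <- as.POSIXlt(timestamp, tz = "UTC")$mon + 1L
  c("short_dry", "long_rain", "long_dry", "short_rain")[ceiling(m / 3)]
}

#' Moon illumination series
#'
#' A daily series of percent moon illumination. [moon_series_synthetic()]
#' builds one from the idealised circalunar cosine
#' \eqn{50 (1 - \cos(2\pi (t - t_{new}) / 29.53\,\mathrm{d}))};
#' [read_moon_series()] reads a CSV with columns `date` (ISO-8601) and
#' `illumination_pct`.
#'
#' @param from,to `Date` (or coercible) span of the series, inclusive.
#' @param new_moon `Date` of a reference new moon.
#' @param period synodic period in days.
#' @return data.frame of class `moon_series` with columns `date`,
#'   `illumination_pct`.
#' @export
moon_series_synthetic <- function(from, to, new_moon = as.Date("2016-05-06"),
                                  period = 29.53) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  phase <- as.numeric(dates - as.Date(new_moon)) / period
  pct <- 50 * (1 - cos(2 * pi * phase))
  structure(data.frame(date = dates, illumination_pct = pct),
            class = c("moon_series", "data.frame"))
}

#' @rdname moon_series_synthetic
#' @param path CSV path.
#' @export
read_moon_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "illumination_pct") %in% names(d)))
    stop("moon CSV needs columns date, illumination_pct")
  if (any(d$illumination_pct < 0 | d$illumination_pct > 100))
    stop("illumination_pct must lie in [0, 100]")
  structure(data.frame(date = as.Date(d$date),
                       illumination_pct = d$illumination_pct),
            class = c("moon_series", "data.frame"))
}

#' @rdname moon_series_synthetic
#' @param series a `moon_series`.
#' @param timestamp timestamps to query; the series has daily resolution and
#'   every hour of a date shares that date's value.
#' @export
moon_at <- function(series, timestamp) {
  d <- as.Date(as.POSIXlt(timestamp, tz = "UTC"))
  idx <- match(d, series$date)
  if (anyNA(idx))
    stop("timestamp outside moon series span: ",
         paste(utils::head(unique(d[is.na(idx)]), 3), collapse = ", "))
  series$illumination_pct[idx]
}
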