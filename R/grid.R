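#' Covariate grid container
#'
#' A `cov_grid` is a regular single-band raster on a projected metre
#' coordinate system: a numeric matrix of cell values plus its georeference
#' (lower-left corner and cell size). Rows index northing (row 1 is the
#' southernmost row), columns index easting. Missing cells are `NA`
#' internally; a nodata sentinel is only used on disk.
#'
#' @param values numeric matrix of cell values (class codes for categorical
#'   layers). Row 1 is the southern edge.
#' @param origin numeric length-2, `(x0, y0)` of the lower-left *corner* in
#'   metres.
#' @param cell_size cell edge length in metres, `> 0`.
#' @param name covariate label, e.g. `"WC"`, `"TRI"`, `"SVD"`, `"ProxW"`,
#'   `"NDVI"`, `"DEM"`, `"LANDCOVER"`.
#' @param categorical logical; `TRUE` for class-coded layers (resampled by
#'   nearest neighbour rather than bilinearly).
#' @param season_tag optional season label (used for seasonal NDVI layers).
#' @return an object of class `cov_grid`.
#' @export
cov_grid <- function(values, origin, cell_size, name = "layer",
                     categorical = FALSE, season_tag = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values) || is.logical(values))
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2L) stop("origin must be (x0, y0)")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("grid must be at least 1x1")
  structure(
    list(name = name, origin = as.numeric(origin), cell_size = cell_size,
         values = values, categorical = isTRUE(categorical),
         season_tag = season_tag),
    class = "cov_grid")
}

#' @export
print.cov_grid <- function(x, ...) {
  cat(sprintf("<cov_grid '%s'> %d x %d cells @ %g m, origin (%g, %g)%s\n",
              x$name, nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2],
              if (is.null(x$season_tag)) "" else paste0(" [", x$season_tag, "]")))
  invisible(x)
}

#' @export
dim.cov_grid <- function(x) dim(x$values)

#' Grid extent
#'
#' @param g a [cov_grid()].
#' @return named numeric `(xmin, ymin, xmax, ymax)` of the outer cell edges.
#' @export
grid_extent <- function(g) {
  c(xmin = g$origin[1], ymin = g$origin[2],
    xmax = g$origin[1] + ncol(g$values) * g$cell_size,
    ymax = g$origin[2] + nrow(g$values) * g$cell_size)
}

#' Cell-centre coordinates
#'
#' @param g a [cov_grid()].
#' @return list with numeric vectors `x` (column centres, west to east) and
#'   `y` (row centres, south to north).
#' @export
grid_centres <- function(g) {
  list(x = g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$cell_size,
       y = g$origin[2] + (seq_len(nrow(g$values)) - 0.5) * g$cell_size)
}

#' Look up grid values at points
#'
#' Values are taken from the cell containing each point (no interpolation),
#' matching a nearest-cell extraction. Points outside the grid return `NA`.
#'
#' @param g a [cov_grid()].
#' @param x,y point coordinates in metres.
#' @return numeric vector of cell values.
#' @export
grid_lookup <- function(g, x, y) {
  j <- floor((x - g$origin[1]) / g$cell_size) + 1L
  i <- floor((y - g$origin[2]) / g$cell_size) + 1L
  # points exactly on the top/right edge belong to the last cell
  j[x == g$origin[1] + ncol(g$values) * g$cell_size] <- ncol(g$values)
  i[y == g$origin[2] + nrow(g$values) * g$cell_size] <- nrow(g$values)
  ok <- !is.na(i) & !is.na(j) &
    i >= 1L & i <= nrow(g$values) & j >= 1L & j <= ncol(g$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- g$values[cbind(i[ok], j[ok])]
  out
}

#' Check that grids share one georeference
#'
#' @param grids list of [cov_grid()] objects.
#' @param tol numeric tolerance on origins/cell size, metres.
#' @return `TRUE` invisibly; stops otherwise.
#' @export
assert_aligned <- function(grids, tol = 1e-6) {
  stopifnot(length(grids) >= 1L)
  ref <- grids[[1L]]
  for (g in grids[-1L]) {
    if (any(abs(g$origin - ref$origin) > tol) ||
        abs(g$cell_size - ref$cell_size) > tol ||
        !identical(dim(g$values), dim(ref$values)))
      stop(sprintf("grid '%s' is not aligned with '%s'", g$name, ref$name))
  }
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `nodata_value`) followed by rows of values from
#' north to south.
#'
#' @param path file path.
#' @param name,categorical,season_tag passed to [cov_grid()].
#' @return a [cov_grid()].
#' @export
read_ascii_grid <- function(path, name = NULL, categorical = FALSE,
                            season_tag = NULL) {
  lines <- readLines(path)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1L])) {
      hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("missing ASCII grid header field: ", k)
  vals <- scan(text = paste(lines[-seq_len(n_hdr)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("ASCII grid value count does not match header")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  m <- m[nr:1, , drop = FALSE]  # file is north-to-south; store south-up
  cov_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
           cell_size = hdr$cellsize,
           name = if (is.null(name)) basename(path) else name,
           categorical = categorical, season_tag = season_tag)
}

#' Write an ESRI ASCII grid
#'
#' @param g a [cov_grid()].
#' @param path output path.
#' @param nodata sentinel written for `NA` cells.
#' @return `path` invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(g$origin[1], scientific = FALSE)),
    paste("yllcorner", format(g$origin[2], scientific = FALSE)),
    paste("cellsize", format(g$cell_size, scientific = FALSE)),
    paste("nodata_value", nodata)), con)
  m <- g$values[nr:1, , drop = FALSE]
  m[is.na(m)] <- nodata
  for (i in seq_len(nr))
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}
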