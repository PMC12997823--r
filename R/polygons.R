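# Lightweight planar polygon utilities: the study region, protected core and
# management areas are simple polygons on a projected metre CRS, and home
# ranges are convex hulls, so a ray-casting test, the shoelace formula and
# grDevices::chull cover everything the pipeline needs.

#' Simple polygon constructor
#'
#' @param x,y vertex coordinates in metres (the closing vertex may be
#'   omitted).
#' @param id optional label.
#' @return object of class `simple_polygon`.
#' @export
simple_polygon <- function(x, y, id = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), id = id),
            class = "simple_polygon")
}

#' Rectangle polygon from an extent
#'
#' @param xmin,ymin,xmax,ymax extent in metres.
#' @param id optional label.
#' @export
rect_polygon <- function(xmin, ymin, xmax, ymax, id = NULL) {
  simple_polygon(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax), id = id)
}

#' Polygon area
#'
#' Shoelace formula.
#'
#' @param poly a [simple_polygon()].
#' @param unit `"m2"` or `"km2"`.
#' @return area.
#' @export
polygon_area <- function(poly, unit = c("km2", "m2")) {
  unit <- match.arg(unit)
  x <- poly$x; y <- poly$y
  n <- length(x)
  a <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  if (unit == "km2") a / 1e6 else a
}

#' Point-in-polygon test
#'
#' Ray casting with an explicit on-boundary check; boundary points count as
#' inside (closed polygons).
#'
#' @param poly a [simple_polygon()].
#' @param x,y point coordinates.
#' @param eps boundary tolerance in metres.
#' @return logical vector.
#' @export
point_in_polygon <- function(poly, x, y, eps = 1e-9) {
  px <- poly$x; py <- poly$y
  n <- length(px)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # distance from points to segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(pmax(((x - xi) * dx + (y - yi) * dy) / L2, 0), 1) else 0
    d2 <- (x - (xi + t * dx))^2 + (y - (yi + t * dy))^2
    on_edge <- on_edge | d2 <= eps^2 + eps * sqrt(L2)
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' 100% minimum convex polygon
#'
#' Convex hull of all relocations, the classical 100% MCP home-range
#' estimator. The hull area (km^2) is attached as attribute `area_km2`.
#'
#' @param x,y relocation coordinates in metres (at least three non-collinear
#'   points).
#' @param id optional individual id.
#' @return a [simple_polygon()] with attribute `area_km2`.
#' @export
mcp <- function(x, y, id = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("MCP needs at least 3 points")
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) stop("MCP needs at least 3 non-collinear points")
  poly <- simple_polygon(x[h], y[h], id = id)
  a <- polygon_area(poly, "km2")
  if (a <= 0) stop("MCP needs at least 3 non-collinear points")
  attr(poly, "area_km2") <- a
  poly
}

#' Uniform random points in a polygon
#'
#' Rejection sampling from the polygon's bounding box.
#'
#' @param poly a [simple_polygon()].
#' @param n number of points.
#' @return data.frame with columns `x`, `y`.
#' @keywords internal
runif_in_polygon <- function(poly, n) {
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  bbox <- c(range(poly$x), range(poly$y))
  if (diff(bbox[1:2]) <= 0 || diff(bbox[3:4]) <= 0)
    stop("cannot sample points in a zero-area polygon")
  out_x <- numeric(0); out_y <- numeric(0)
  while (length(out_x) < n) {
    m <- max(2L * (n - length(out_x)), 100L)
    cx <- stats::runif(m, bbox[1], bbox[2])
    cy <- stats::runif(m, bbox[3], bbox[4])
    keep <- point_in_polygon(poly, cx, cy)
    out_x <- c(out_x, cx[keep]); out_y <- c(out_y, cy[keep])
  }
  data.frame(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

#' Write polygons as GeoJSON
#'
#' @param polys named list of [simple_polygon()] objects.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(polys, function(p) {
    ring <- cbind(c(p$x, p$x[1]), c(p$y, p$y[1]))
    list(type = "Feature",
         properties = list(id = if (is.null(p$id)) NA else p$id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
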