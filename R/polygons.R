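# Polygon handling: GeoJSON reading, cell-center rasterization, and the patch
# shape metrics (depth index, maximum inscribed circle) that guide the choice
# of analysis cell size.
#
# A polygon is a list of rings (first outer, later ones holes); each ring is
# an n x 2 matrix of x,y in projected meters. A bare matrix is accepted as a
# single-ring polygon.

as_polygon <- function(p) {
  if (is.matrix(p)) p <- list(p)
  if (!is.list(p) || !all(vapply(p, is.matrix, TRUE)))
    stop("a polygon must be a matrix or list of n x 2 ring matrices")
  lapply(p, function(r) {
    if (ncol(r) != 2) stop("rings must have two columns (x, y)")
    storage.mode(r) <- "double"
    r
  })
}

ring_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  n <- nrow(r)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_area <- function(p) {
  p <- as_polygon(p)
  a <- ring_area(p[[1]])
  if (length(p) > 1) a <- a - sum(vapply(p[-1], ring_area, 0))
  max(a, 0)
}

ring_perimeter <- function(r) {
  n <- nrow(r)
  j <- c(2:n, 1)
  sum(sqrt((r[j, 1] - r[, 1])^2 + (r[j, 2] - r[, 2])^2))
}

# even-odd point-in-polygon with holes (boundary counts as inside)
points_in_polygon <- function(x, y, p) {
  p <- as_polygon(p)
  inside <- pracma::inpolygon(x, y, p[[1]][, 1], p[[1]][, 2], boundary = TRUE)
  for (h in p[-1])
    inside <- inside & !pracma::inpolygon(x, y, h[, 1], h[, 2], boundary = FALSE)
  inside
}

#' Read polygons from a GeoJSON file
#'
#' Supports FeatureCollection / Feature / Polygon / MultiPolygon geometries in
#' a single projected CRS. Every (multi)polygon part becomes one polygon: a
#' list of ring matrices, the first ring outer, the rest holes.
#'
#' @param path GeoJSON file path.
#' @return A list of polygons.
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(gj$type,
    FeatureCollection = lapply(gj$features, `[[`, "geometry"),
    Feature = list(gj$geometry),
    list(gj))
  out <- list()
  ring_mat <- function(r) do.call(rbind, lapply(r, function(pt)
    c(pt[[1]], pt[[2]])))
  for (g in geoms) {
    if (g$type == "Polygon") {
      out[[length(out) + 1]] <- lapply(g$coordinates, ring_mat)
    } else if (g$type == "MultiPolygon") {
      for (part in g$coordinates)
        out[[length(out) + 1]] <- lapply(part, ring_mat)
    } else stop("unsupported geometry type: ", g$type)
  }
  out
}

#' Read point locations (e.g. river outlets)
#'
#' Accepts a GeoJSON file of Point/MultiPoint features or a CSV with `x`,`y`
#' columns.
#'
#' @param path file path.
#' @return An n x 2 matrix of x,y coordinates (m).
#' @export
read_points <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path)
    return(cbind(x = d$x, y = d$y))
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(gj$type,
    FeatureCollection = lapply(gj$features, `[[`, "geometry"),
    Feature = list(gj$geometry),
    list(gj))
  pts <- list()
  for (g in geoms) {
    if (g$type == "Point") {
      pts[[length(pts) + 1]] <- c(g$coordinates[[1]], g$coordinates[[2]])
    } else if (g$type == "MultiPoint") {
      for (p in g$coordinates)
        pts[[length(pts) + 1]] <- c(p[[1]], p[[2]])
    } else stop("unsupported geometry type: ", g$type)
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("x", "y")
  out
}

#' Rasterize presence polygons onto a template extent
#'
#' A cell is occupied iff its center lies inside (or on the boundary of) any
#' polygon — the deterministic cell-center rule.
#'
#' @param polygons list of polygons (possibly empty).
#' @param cell_size output cell size in meters (may differ from the
#'   template's).
#' @param template an [rgrid] supplying origin and extent.
#' @param site,year passed to [presence_grid].
#' @return A [presence_grid].
#' @export
rasterize_polygons <- function(polygons, cell_size, template,
                               site = "site", year = NA_integer_) {
  if (!inherits(template, "rgrid")) stop("`template` must be an rgrid")
  d <- dim(template$values)
  if (any(d == 0)) stop("empty template grid")
  if (cell_size <= 0) stop("`cell_size` must be > 0")
  ext_x <- d[2] * template$cell_size
  ext_y <- d[1] * template$cell_size
  nc <- ceiling(ext_x / cell_size - 1e-9)
  nr <- ceiling(ext_y / cell_size - 1e-9)
  occ <- matrix(FALSE, nr, nc)
  cx <- template$origin_x + (seq_len(nc) - 0.5) * cell_size
  cy <- template$origin_y - (seq_len(nr) - 0.5) * cell_size
  for (i in seq_along(polygons)) {
    p <- tryCatch(as_polygon(polygons[[i]]),
                  error = function(e) stop("invalid geometry in patch ", i,
                                           ": ", conditionMessage(e)))
    bb <- apply(do.call(rbind, p), 2, range)
    js <- which(cx >= bb[1, 1] - cell_size & cx <= bb[2, 1] + cell_size)
    is <- which(cy >= bb[1, 2] - cell_size & cy <= bb[2, 2] + cell_size)
    if (!length(js) || !length(is)) next
    gx <- rep(cx[js], each = length(is))
    gy <- rep(cy[is], times = length(js))
    hit <- points_in_polygon(gx, gy, p)
    occ[is, js] <- occ[is, js] | matrix(hit, length(is), length(js))
  }
  g <- rgrid(occ, origin_x = template$origin_x, origin_y = template$origin_y,
             cell_size = cell_size, kind = "boolean")
  presence_grid(g, site = site, year = year)
}

dist_to_rings <- function(x, y, rings) {
  d <- rep(Inf, length(x))
  for (r in rings) {
    n <- nrow(r)
    j <- c(2:n, 1)
    for (e in seq_len(n)) {
      ax <- r[e, 1]; ay <- r[e, 2]
      bx <- r[j[e], 1]; by <- r[j[e], 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx * vx + vy * vy
      t <- if (L2 == 0) 0 else pmin(pmax(((x - ax) * vx + (y - ay) * vy) / L2, 0), 1)
      dd <- sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2)
      d <- pmin(d, dd)
    }
  }
  d
}

#' Patch shape metrics: depth index and maximum inscribed circle
#'
#' The depth index is the mean distance from the polygon's interior points to
#' the nearest point on its perimeter; the maximum inscribed diameter is twice
#' the largest such distance. Both are approximated on a fine auxiliary raster
#' (cell size `min(0.5, width/20)` m where width is the shorter bounding-box
#' side) using exact point-to-segment distances to the polygon boundary.
#'
#' @param polygon a polygon (ring matrix or list of ring matrices).
#' @return A list with `area`, `depth_index` and `max_inscribed_diameter`
#'   (all meters / square meters).
#' @export
patch_metrics <- function(polygon) {
  p <- as_polygon(polygon)
  area <- polygon_area(p)
  if (area <= 0) {
    warning("degenerate (zero-area) polygon; metrics set to 0")
    return(list(area = 0, depth_index = 0, max_inscribed_diameter = 0))
  }
  bb <- apply(do.call(rbind, p), 2, range)
  width <- min(bb[2, ] - bb[1, ])
  aux <- min(0.5, width / 20)
  xs <- seq(bb[1, 1] + aux / 2, bb[2, 1], by = aux)
  ys <- seq(bb[1, 2] + aux / 2, bb[2, 2], by = aux)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  inside <- points_in_polygon(gx, gy, p)
  if (!any(inside)) {
    warning("no interior sample points; polygon thinner than auxiliary raster")
    return(list(area = area, depth_index = 0, max_inscribed_diameter = 0))
  }
  d <- dist_to_rings(gx[inside], gy[inside], p)
  # refine the inscribed-circle center beyond the auxiliary grid resolution
  top <- which.max(d)
  cx <- gx[inside][top]; cy <- gy[inside][top]
  fx <- seq(cx - aux, cx + aux, by = aux / 10)
  fy <- seq(cy - aux, cy + aux, by = aux / 10)
  rx <- rep(fx, each = length(fy)); ry <- rep(fy, times = length(fx))
  rin <- points_in_polygon(rx, ry, p)
  dmax <- max(d)
  if (any(rin)) dmax <- max(dmax, dist_to_rings(rx[rin], ry[rin], p))
  list(area = area, depth_index = mean(d), max_inscribed_diameter = 2 * dmax)
}

#' Shape metrics for a set of patches
#'
#' @param polygons list of polygons.
#' @return A data frame with columns `patch_id`, `area_m2`, `depth_index_m`,
#'   `max_inscribed_diameter_m`.
#' @export
patch_metrics_table <- function(polygons) {
  rows <- lapply(seq_along(polygons), function(i) {
    m <- patch_metrics(polygons[[i]])
    data.frame(patch_id = i, area_m2 = m$area, depth_index_m = m$depth_index,
               max_inscribed_diameter_m = m$max_inscribed_diameter)
  })
  do.call(rbind, rows)
}

#' Analysis cell-size bounds from inscribed-circle diameters
#'
#' Returns the requested quantiles (default lower/upper quartiles) of the
#' maximum inscribed diameters of a patch set; these bracket sensible raster
#' cell sizes for neighborhood analysis.
#'
#' @param metrics data frame from [patch_metrics_table] (or any object with a
#'   `max_inscribed_diameter_m` column / `max_inscribed_diameter` field list).
#' @param quantiles length-2 vector of probabilities.
#' @return Named numeric vector `c(lower=, upper=)` in meters.
#' @export
choose_cell_size <- function(metrics, quantiles = c(0.25, 0.75)) {
  d <- if (is.data.frame(metrics)) metrics$max_inscribed_diameter_m
       else vapply(metrics, `[[`, 0, "max_inscribed_diameter")
  if (!length(d)) stop("empty metrics list")
  q <- stats::quantile(d, quantiles, names = FALSE)
  c(lower = q[1], upper = q[2])
}
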