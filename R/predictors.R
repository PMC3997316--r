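# Static predictor grids: distance to river outlets, wave-fetch openness, and
# the offshore extension of the coastal land-cover classes that also defines
# the analysis mask (shoreline + water shallower than 3 m).

#' Euclidean distance to the closest river outlet
#'
#' @param template an [rgrid] supplying the geometry.
#' @param outlets n x 2 matrix of outlet coordinates (m).
#' @return A continuous [rgrid] of distances in meters.
#' @export
distance_to_outlets <- function(template, outlets) {
  if (is.null(outlets) || NROW(outlets) < 1) stop("at least one outlet required")
  outlets <- matrix(as.numeric(outlets), ncol = 2)
  cc <- cell_centers(template)
  d <- dim(template$values)
  best <- matrix(Inf, d[1], d[2])
  X <- matrix(cc$x, d[1], d[2], byrow = TRUE)
  Y <- matrix(cc$y, d[1], d[2])
  for (k in seq_len(nrow(outlets)))
    best <- pmin(best, sqrt((X - outlets[k, 1])^2 + (Y - outlets[k, 2])^2))
  rgrid(best, origin_x = template$origin_x, origin_y = template$origin_y,
        cell_size = template$cell_size, kind = "continuous")
}

#' Shore openness from wave fetch
#'
#' For each water cell, rays are cast in `n_directions` equally spaced
#' directions and marched until they hit land or reach `max_fetch`; openness
#' is the mean fetch in meters. The area beyond the grid is treated as open
#' water. Land cells are nodata.
#'
#' @param land_sea boolean [rgrid], `TRUE` = land.
#' @param n_directions number of rays, >= 4.
#' @param max_fetch fetch cap in meters.
#' @return A continuous [rgrid] of mean fetch (m) with attribute `max_fetch`;
#'   divide by `max_fetch` (see [relative_openness]) for relative openness.
#' @export
openness_fetch <- function(land_sea, n_directions = 16, max_fetch = 10000) {
  if (land_sea$kind != "boolean") stop("`land_sea` must be a boolean grid")
  if (n_directions < 4) stop("`n_directions` must be >= 4")
  if (max_fetch <= 0) stop("`max_fetch` must be > 0")
  land <- land_sea$values
  land[is.na(land)] <- TRUE
  if (all(land)) warning("all-land mask: openness grid is all nodata")
  m <- cpp_fetch(land, land_sea$cell_size, as.integer(n_directions), max_fetch)
  g <- rgrid(m, origin_x = land_sea$origin_x, origin_y = land_sea$origin_y,
             cell_size = land_sea$cell_size, kind = "continuous")
  attr(g, "max_fetch") <- max_fetch
  g
}

#' Relative openness (mean fetch / fetch cap)
#'
#' @param openness grid produced by [openness_fetch].
#' @param max_fetch cap used; defaults to the grid's `max_fetch` attribute.
#' @export
relative_openness <- function(openness, max_fetch = attr(openness, "max_fetch")) {
  if (is.null(max_fetch)) stop("`max_fetch` not supplied and not an attribute")
  out <- openness
  out$values <- openness$values / max_fetch
  out
}

#' Distance from water cells to the nearest land cell
#'
#' @param land_sea boolean [rgrid], `TRUE` = land.
#' @return A continuous [rgrid]: distance (m) on water cells, nodata on land.
#' @export
shore_distance <- function(land_sea) {
  land <- land_sea$values
  land[is.na(land)] <- TRUE
  res <- cpp_nearest_land(land, matrix(0L, nrow(land), ncol(land)), !land)
  rgrid(res$dist * land_sea$cell_size, origin_x = land_sea$origin_x,
        origin_y = land_sea$origin_y, cell_size = land_sea$cell_size,
        kind = "continuous")
}

#' Extend coastal land cover offshore and build the analysis mask
#'
#' The analysis mask consists of shoreline land cells (land cells with at
#' least one water 8-neighbor) plus water cells with depth below `max_depth`.
#' Each masked water cell receives the land-cover class of the nearest land
#' cell (Euclidean between cell centers; ties broken by the smallest class
#' code). Water deeper than `max_depth` is nodata and outside the mask.
#'
#' @param landcover categorical [rgrid] with classes on land.
#' @param bathymetry continuous [rgrid], water depth in m positive downward;
#'   land cells carry depth <= 0.
#' @param land_sea boolean [rgrid], `TRUE` = land.
#' @param max_depth analysis depth limit in meters (default 3).
#' @return A list with `landcover` (extended categorical grid over the mask)
#'   and `mask` (boolean grid).
#' @export
extend_landcover <- function(landcover, bathymetry, land_sea, max_depth = 3) {
  stopifnot_aligned(landcover, bathymetry, land_sea)
  land <- land_sea$values
  land[is.na(land)] <- TRUE
  water <- !land
  shallow <- water & !is.na(bathymetry$values) & bathymetry$values < max_depth
  shoreline <- land & neighbor_any(water)
  cls <- matrix(as.integer(landcover$values), nrow(land), ncol(land))
  res <- cpp_nearest_land(land, cls, shallow)
  out <- matrix(NA_real_, nrow(land), ncol(land))
  out[shoreline] <- cls[shoreline]
  out[shallow] <- res$class[shallow]
  mask <- shoreline | shallow
  list(
    landcover = rgrid(out, origin_x = land_sea$origin_x,
                      origin_y = land_sea$origin_y,
                      cell_size = land_sea$cell_size, kind = "categorical"),
    mask = rgrid(mask, origin_x = land_sea$origin_x,
                 origin_y = land_sea$origin_y,
                 cell_size = land_sea$cell_size, kind = "boolean")
  )
}

# TRUE where any 8-neighbor of a cell is TRUE
neighbor_any <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out | p[(2:(nr + 1)) + di, (2:(nc + 1)) + dj]
  }
  out
}
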