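# Raster data model ----------------------------------------------------------
#
# A grid is a light S3 wrapper around a numeric matrix in projected meters:
# top-left origin, rows running down (y decreasing), columns right (x
# increasing), 0-based cell (1,1) center at (origin_x + cs/2, origin_y - cs/2).
# Missing cells are NA internally; a nodata sentinel only appears on disk.

#' Construct a raster grid
#'
#' @param values numeric or logical matrix; rows run from north (top) to
#'   south, columns west to east. Missing cells are `NA`.
#' @param origin_x,origin_y coordinates (m) of the top-left corner of the
#'   top-left cell.
#' @param cell_size cell edge length in meters, > 0.
#' @param kind one of `"continuous"`, `"categorical"`, `"boolean"`.
#' @return An object of class `rgrid`.
#' @export
rgrid <- function(values, origin_x = 0, origin_y = nrow(values) * cell_size,
                  cell_size = 1, kind = c("continuous", "categorical", "boolean")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  if (kind == "boolean") {
    storage.mode(values) <- "logical"
  } else {
    storage.mode(values) <- "double"
  }
  structure(
    list(values = values, origin_x = origin_x, origin_y = origin_y,
         cell_size = cell_size, kind = kind),
    class = "rgrid"
  )
}

#' @export
dim.rgrid <- function(x) dim(x$values)

#' @export
as.matrix.rgrid <- function(x, ...) x$values

#' @export
print.rgrid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rgrid %s> %d x %d cells @ %g m, origin (%g, %g)\n",
              x$kind, d[1], d[2], x$cell_size, x$origin_x, x$origin_y))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  valid cells: %d, range [%g, %g]\n", length(v),
                min(as.numeric(v)), max(as.numeric(v))))
  invisible(x)
}

#' Coordinates of cell centers
#'
#' @param g an [rgrid].
#' @return A list with vectors `x` (per column) and `y` (per row) of cell
#'   center coordinates in meters.
#' @export
cell_centers <- function(g) {
  d <- dim(g$values)
  list(x = g$origin_x + (seq_len(d[2]) - 0.5) * g$cell_size,
       y = g$origin_y - (seq_len(d[1]) - 0.5) * g$cell_size)
}

#' Test that two grids share geometry
#'
#' Same extent, origin and cell size (within 1e-6 m).
#' @param a,b [rgrid] objects.
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < 1e-6 &&
    abs(a$origin_y - b$origin_y) < 1e-6 &&
    abs(a$cell_size - b$cell_size) < 1e-6
}

stopifnot_aligned <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!grids_aligned(gs[[1]], gs[[i]]))
      stop("grids are not aligned (origin/extent/cell size mismatch)")
  invisible(TRUE)
}

#' Tag a boolean grid as a species presence snapshot
#'
#' @param grid a boolean [rgrid] (or logical matrix plus geometry arguments
#'   passed on to [rgrid]).
#' @param site site identifier.
#' @param year integer year of the snapshot.
#' @export
presence_grid <- function(grid, site, year) {
  if (!inherits(grid, "rgrid")) stop("`grid` must be an rgrid")
  if (grid$kind != "boolean") stop("presence grids must be boolean")
  grid$site <- site
  grid$year <- as.integer(year)
  class(grid) <- c("presence_grid", "rgrid")
  grid
}

#' Read an ESRI ASCII grid
#'
#' @param path file path to a `.asc` grid.
#' @param kind grid kind, see [rgrid].
#' @export
read_esri_ascii <- function(path, kind = "continuous") {
  hdr <- readLines(path, n = 6)
  kv <- lapply(strsplit(trimws(hdr), "\\s+"), function(p)
    stats::setNames(as.numeric(p[2]), tolower(p[1])))
  kv <- unlist(kv)
  ncols <- kv[["ncols"]]; nrows <- kv[["nrows"]]
  cs <- kv[["cellsize"]]
  nodata <- if ("nodata_value" %in% names(kv)) kv[["nodata_value"]] else -9999
  nskip <- if ("nodata_value" %in% names(kv)) 6L else 5L
  vals <- scan(path, skip = nskip, quiet = TRUE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  ox <- kv[["xllcorner"]]
  oy <- kv[["yllcorner"]] + nrows * cs
  if (kind == "boolean") m <- m > 0
  rgrid(m, origin_x = ox, origin_y = oy, cell_size = cs, kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' @param g an [rgrid].
#' @param path destination path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_esri_ascii <- function(g, path, nodata = -9999) {
  d <- dim(g$values)
  m <- g$values
  storage.mode(m) <- "double"
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y - d[1] * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
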