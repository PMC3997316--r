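# Areal-cover accounting and the intrinsic rate of natural increase r solving
# N = N0 * exp(r t) between occupancy snapshots.

#' Areal cover of a presence snapshot
#'
#' @param presence a [presence_grid].
#' @param mask boolean [rgrid] analysis mask (same geometry).
#' @return A list with `area_ha` (occupied area, hectares), `mask_ha`, and
#'   `percent` (integer-rounded percent of the mask area, as reported).
#' @export
areal_cover <- function(presence, mask) {
  stopifnot_aligned(presence, mask)
  n_mask <- sum(mask$values, na.rm = TRUE)
  if (n_mask == 0) stop("empty analysis mask")
  occ <- sum(presence$values & mask$values, na.rm = TRUE)
  cs2 <- presence$cell_size^2
  area <- occ * cs2 / 1e4
  total <- n_mask * cs2 / 1e4
  list(area_ha = area, mask_ha = total, percent = cover_percent(area, total))
}

#' Integer coverage percent from areas
#'
#' @param area_ha occupied area (ha).
#' @param total_ha total analysed area (ha).
#' @return Rounded percent (integer-valued numeric).
#' @export
cover_percent <- function(area_ha, total_ha) {
  if (any(total_ha <= 0)) stop("total area must be > 0")
  round(100 * area_ha / total_ha)
}

#' Intrinsic rate of natural increase
#'
#' Solves N = N0 * exp(r t) for r, returned in percent per year:
#' r = 100 * ln(N / N0) / t.
#'
#' @param N0 areal cover at time 0 (ha), > 0.
#' @param N areal cover at time 1 (ha), > 0.
#' @param t elapsed time in years, > 0.
#' @param digits decimals for reporting (default 1, as in the growth tables);
#'   use `Inf` for full precision.
#' @return r in percent per year.
#' @export
intrinsic_rate <- function(N0, N, t, digits = 1) {
  if (any(N0 <= 0) || any(N <= 0) || any(t <= 0))
    stop("N0, N and t must all be positive")
  r <- 100 * log(N / N0) / t
  if (is.finite(digits)) round(r, digits) else r
}

#' Growth table across a series of snapshots
#'
#' One record per site for the overall period plus one per consecutive pair
#' of snapshots.
#'
#' @param areas data frame with columns `site`, `year`, `area_ha` (one row
#'   per snapshot), or a list of [presence_grid] plus `mask` to compute areas
#'   from rasters.
#' @param mask optional boolean [rgrid] when `areas` is a presence list.
#' @return Data frame with columns `site`, `year0`, `year1`, `N0_ha`, `N_ha`,
#'   `r_pct_per_year`.
#' @export
growth_table <- function(areas, mask = NULL) {
  if (!is.data.frame(areas)) {
    stopifnot(!is.null(mask))
    areas <- do.call(rbind, lapply(areas, function(p) {
      a <- areal_cover(p, mask)
      data.frame(site = p$site, year = p$year, area_ha = a$area_ha)
    }))
  }
  out <- list()
  for (s in unique(areas$site)) {
    d <- areas[areas$site == s, ]
    if (nrow(d) < 2) stop("site ", s, " has fewer than 2 snapshots")
    if (is.unsorted(d$year)) {
      warning("snapshots of site ", s, " not in year order; sorting")
      d <- d[order(d$year), ]
    }
    rec <- function(i0, i1) data.frame(
      site = s, year0 = d$year[i0], year1 = d$year[i1],
      N0_ha = d$area_ha[i0], N_ha = d$area_ha[i1],
      r_pct_per_year = intrinsic_rate(d$area_ha[i0], d$area_ha[i1],
                                      d$year[i1] - d$year[i0]))
    out[[length(out) + 1]] <- rec(1, nrow(d))
    if (nrow(d) > 2)
      for (i in seq_len(nrow(d) - 1))
        out[[length(out) + 1]] <- rec(i, i + 1)
  }
  do.call(rbind, out)
}
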