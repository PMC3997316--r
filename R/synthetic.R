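# Synthetic coastal landscape and reed-occupancy generator.
#
# The generator supplies the study conditions every downstream stage is
# exercised against: an irregular coastline from thresholded smooth noise, a
# bathymetry field deepening offshore, fetch-derived openness, point river
# outlets, a small categorical land-cover map (Voronoi regions with CORINE
# level-2 style codes), and occupancy time series driven by a known logistic
# suitability surface plus neighbor-count-dependent colonization/extinction.

# separable Gaussian smoothing with zero padding and edge renormalization
gauss_smooth <- function(m, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_col <- function(mm) {
    nr <- nrow(mm); nc <- ncol(mm)
    pad <- rbind(matrix(0, r, nc), mm, matrix(0, r, nc))
    w <- rbind(matrix(0, r, nc), matrix(1, nr, nc), matrix(0, r, nc))
    num <- matrix(0, nr, nc); den <- num
    for (t in seq_along(k)) {
      num <- num + k[t] * pad[t:(t + nr - 1), , drop = FALSE]
      den <- den + k[t] * w[t:(t + nr - 1), , drop = FALSE]
    }
    num / den
  }
  t(conv_col(t(conv_col(m))))
}

# sum of occupied 8-neighbors (zero-padded edges)
neighbor_sum3 <- function(occ) {
  nr <- nrow(occ); nc <- ncol(occ)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- occ * 1
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out + p[(2:(nr + 1)) + di, (2:(nc + 1)) + dj]
  }
  out
}

corine_codes <- c(11, 12, 14, 21, 24, 31, 32)

#' Generate a synthetic coastal site
#'
#' Builds an aligned bundle of layers: land/sea mask, bathymetry (m, positive
#' down; land carries -0.5), openness from wave fetch, distance to river
#' outlets, land cover extended offshore, and the analysis mask (shoreline +
#' water < 3 m deep). Deterministic under a fixed seed; a degenerate all-land
#' or all-sea draw is resampled with an incremented seed (at most 10 times).
#'
#' @param extent numeric length-2, site extent in meters (>= 200 each).
#' @param cell_size cell size in meters, in \[1, 10\].
#' @param n_outlets number of river outlets placed on the shoreline, >= 1.
#' @param n_classes number of land-cover classes (2..7).
#' @param seed integer RNG seed.
#' @param max_fetch fetch cap (m) for the openness layer.
#' @return A `site_bundle` list: `land_sea`, `bathymetry`, `openness`,
#'   `outlet_distance`, `landcover`, `mask` ([rgrid] layers), `outlets`
#'   (matrix), `cell_size`, `seed`.
#' @export
make_site <- function(extent = c(1000, 1000), cell_size = 5, n_outlets = 2,
                      n_classes = 5, seed = 1, max_fetch = 5000) {
  if (any(extent < 200)) stop("extent must be >= 200 m on each side")
  if (cell_size < 1 || cell_size > 10) stop("cell_size must be in [1, 10] m")
  if (n_outlets < 1) stop("at least one river outlet required")
  if (n_classes < 2 || n_classes > length(corine_codes))
    stop("n_classes must be in 2..", length(corine_codes))

  nx <- round(extent[1] / cell_size)
  ny <- round(extent[2] / cell_size)
  sigma <- max(2, 50 / cell_size)   # ~50 m correlation length

  land <- NULL
  for (try in 0:10) {
    if (try == 10) stop("degenerate coastline draw after 10 retries")
    set.seed(seed + try)
    noise <- gauss_smooth(matrix(stats::rnorm(ny * nx), ny, nx), sigma)
    noise <- noise / stats::sd(noise)
    ramp <- matrix(1 - 2 * (seq_len(ny) - 0.5) / ny, ny, nx)
    land <- (ramp + 0.9 * noise) > 0
    frac <- mean(land)
    if (frac > 0.05 && frac < 0.95) break
  }

  land_sea <- rgrid(land, origin_x = 0, origin_y = ny * cell_size,
                    cell_size = cell_size, kind = "boolean")

  sd_grid <- shore_distance(land_sea)
  depth_noise <- gauss_smooth(matrix(stats::rnorm(ny * nx), ny, nx), sigma / 2)
  depth_noise <- depth_noise / stats::sd(depth_noise)
  depth <- 0.02 * sd_grid$values + 0.3 * depth_noise
  depth[!land] <- pmax(depth[!land], 0.01)
  depth[land] <- -0.5
  bathymetry <- rgrid(depth, origin_x = 0, origin_y = ny * cell_size,
                      cell_size = cell_size, kind = "continuous")

  openness <- openness_fetch(land_sea, n_directions = 16, max_fetch = max_fetch)
  op <- openness$values
  op[land] <- NA
  openness$values <- op

  shoreline <- which(land & neighbor_any(!land), arr.ind = TRUE)
  if (nrow(shoreline) < n_outlets) stop("coastline too short for outlets")
  pick <- shoreline[sample.int(nrow(shoreline), n_outlets), , drop = FALSE]
  outlets <- cbind(x = (pick[, 2] - 0.5) * cell_size,
                   y = ny * cell_size - (pick[, 1] - 0.5) * cell_size)
  outlet_distance <- distance_to_outlets(land_sea, outlets)

  # Voronoi land-cover regions of random seed cells on land
  land_idx <- which(land, arr.ind = TRUE)
  seeds <- land_idx[sample.int(nrow(land_idx), n_classes), , drop = FALSE]
  codes <- corine_codes[seq_len(n_classes)]
  dd <- vapply(seq_len(n_classes), function(k)
    (land_idx[, 1] - seeds[k, 1])^2 + (land_idx[, 2] - seeds[k, 2])^2,
    numeric(nrow(land_idx)))
  cls_land <- codes[max.col(-dd, ties.method = "first")]
  lc <- matrix(NA_real_, ny, nx)
  lc[land_idx] <- cls_land
  landcover_land <- rgrid(lc, origin_x = 0, origin_y = ny * cell_size,
                          cell_size = cell_size, kind = "categorical")

  ext <- extend_landcover(landcover_land, bathymetry, land_sea)

  structure(
    list(land_sea = land_sea, bathymetry = bathymetry, openness = openness,
         outlet_distance = outlet_distance, landcover = ext$landcover,
         mask = ext$mask, outlets = outlets, cell_size = cell_size,
         seed = seed),
    class = "site_bundle"
  )
}

#' @export
print.site_bundle <- function(x, ...) {
  d <- dim(x$land_sea$values)
  cat(sprintf("<site_bundle> %d x %d cells @ %g m, seed %d\n", d[1], d[2],
              x$cell_size, x$seed))
  cat(sprintf("  land fraction %.2f, mask cells %d, outlets %d\n",
              mean(x$land_sea$values), sum(x$mask$values), nrow(x$outlets)))
  invisible(x)
}

pw_response <- function(f, v) stats::approx(f$x, f$y, xout = v, rule = 2)$y

#' Parameters of the synthetic spread model
#'
#' Defaults encode a habitat where shallow (< 1 m), sheltered water near (but
#' not right at) river outlets is strongly suitable, with water depth the
#' dominant axis; colonization odds rise and extinction odds fall with every
#' occupied Moore neighbor.
#'
#' @param beta0 suitability intercept (log-odds).
#' @param f_depth,f_open,f_dist piecewise-linear log-odds responses, each a
#'   list with knot vectors `x` (m) and `y` (log-odds); extrapolation is flat.
#' @param colonize_base probability a clear cell with no occupied neighbors
#'   becomes colonized in one year.
#' @param colonize_gain log-odds increment per occupied neighbor.
#' @param extinct_base probability an isolated occupied cell disappears.
#' @param extinct_decay log-odds decrement per occupied neighbor.
#' @param n_years number of simulated transitions after the initial year.
#' @param seed RNG seed for the occupancy draws.
#' @param preset `"default"`, or `"depth_dominant"` for a habitat where the
#'   depth response is by far the steepest axis (used for recoverability
#'   studies where water depth should rank first in variable influence);
#'   explicit response arguments override the preset.
#' @export
spread_params <- function(beta0 = -1,
                          f_depth = list(x = c(0, 0.5, 1, 2, 3),
                                         y = c(2, 2, 0, -6, -10)),
                          f_open = list(x = c(0, 500, 2000, 5000),
                                        y = c(1, 0.5, -2, -6)),
                          f_dist = list(x = c(0, 250, 1000, 3000),
                                        y = c(0.5, 1, -1, -3)),
                          colonize_base = 0.02, colonize_gain = 0.55,
                          extinct_base = 0.25, extinct_decay = 0.65,
                          n_years = 8, seed = 1,
                          preset = c("default", "depth_dominant")) {
  preset <- match.arg(preset)
  if (preset == "depth_dominant") {
    if (missing(f_depth))
      f_depth <- list(x = c(0, 0.5, 1, 2, 3), y = c(3, 3, 0, -9, -14))
    if (missing(f_open))
      f_open <- list(x = c(0, 500, 2000, 5000), y = c(0.5, 0, -1.5, -3))
    if (missing(f_dist))
      f_dist <- list(x = c(0, 250, 1000, 3000), y = c(0.3, 0.6, -0.8, -2))
  }
  stopifnot(colonize_base >= 0, colonize_base <= 1,
            extinct_base >= 0, extinct_base <= 1, n_years >= 0)
  structure(list(beta0 = beta0, f_depth = f_depth, f_open = f_open,
                 f_dist = f_dist, colonize_base = colonize_base,
                 colonize_gain = colonize_gain, extinct_base = extinct_base,
                 extinct_decay = extinct_decay, n_years = as.integer(n_years),
                 seed = as.integer(seed)),
            class = "spread_params")
}

#' Programmed suitability surface of a synthetic site
#'
#' logit p = beta0 + f_depth(depth) + f_open(openness) + f_dist(outlet
#' distance), evaluated on the analysis mask.
#'
#' @param site a `site_bundle`.
#' @param params a [spread_params].
#' @return A continuous [rgrid] of probabilities on the mask.
#' @export
suitability <- function(site, params) {
  lp <- params$beta0 +
    pw_response(params$f_depth, as.vector(site$bathymetry$values)) +
    pw_response(params$f_open, as.vector(site$openness$values)) +
    pw_response(params$f_dist, as.vector(site$outlet_distance$values))
  p <- matrix(stats::plogis(lp), nrow(site$bathymetry$values))
  p[!site$mask$values] <- NA
  # shoreline land cells have no openness; treat as fully sheltered there
  shore_land <- site$mask$values & site$land_sea$values
  if (any(shore_land)) {
    lp2 <- params$beta0 +
      pw_response(params$f_depth, pmax(site$bathymetry$values[shore_land], 0.01)) +
      pw_response(params$f_open, 0) +
      pw_response(params$f_dist, site$outlet_distance$values[shore_land])
    p[shore_land] <- stats::plogis(lp2)
  }
  rgrid(p, origin_x = site$land_sea$origin_x,
        origin_y = site$land_sea$origin_y,
        cell_size = site$cell_size, kind = "continuous")
}

#' Simulate reed occupancy dynamics on a synthetic site
#'
#' Year 0 seeds each masked cell independently as Bernoulli(p_suit) from
#' [suitability]. Each following year, synchronously, a clear cell becomes
#' colonized with probability `plogis(qlogis(colonize_base) + colonize_gain *
#' k)` and an occupied cell disappears with probability
#' `plogis(qlogis(extinct_base) - extinct_decay * k)`, where k is the count
#' of occupied cells among the 8 Moore neighbors (the center cell excluded).
#'
#' @param site a `site_bundle`.
#' @param params a [spread_params].
#' @param site_id identifier stamped on the snapshots.
#' @return A list of [presence_grid] snapshots, years `0..n_years`.
#' @export
simulate_spread <- function(site, params, site_id = "synthetic") {
  mask <- site$mask$values
  p_suit <- suitability(site, params)$values
  set.seed(params$seed)
  occ <- mask & !is.na(p_suit) &
    (matrix(stats::runif(length(mask)), nrow(mask)) < p_suit)

  lo_col <- stats::qlogis(params$colonize_base)
  lo_ext <- stats::qlogis(params$extinct_base)
  out <- vector("list", params$n_years + 1)
  wrap <- function(o, yr) presence_grid(
    rgrid(ifelse(mask, o, NA), origin_x = site$land_sea$origin_x,
          origin_y = site$land_sea$origin_y, cell_size = site$cell_size,
          kind = "boolean"),
    site = site_id, year = yr)
  out[[1]] <- wrap(occ, 0L)
  if (params$n_years > 0) {
    for (yr in seq_len(params$n_years)) {
      k <- neighbor_sum3(occ)
      p_col <- stats::plogis(lo_col + params$colonize_gain * k)
      p_ext <- stats::plogis(lo_ext - params$extinct_decay * k)
      u <- matrix(stats::runif(length(mask)), nrow(mask))
      occ_new <- ifelse(occ, u >= p_ext, u < p_col)
      occ <- occ_new & mask
      out[[yr + 1]] <- wrap(occ, yr)
    }
  }
  out
}
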