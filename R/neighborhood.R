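# Multi-scale cellular analysis of how neighborhood occupancy at t0
# conditions colonization (0->1) and disappearance (1->0) by t1.

#' Resample a fine presence grid to a coarser cell size
#'
#' A coarse cell is occupied iff the occupied area fraction among overlapping
#' fine cells is >= 0.5, area-weighted for partial overlaps. Coarse cells
#' whose valid (non-nodata) coverage is zero are nodata.
#'
#' @param fine a [presence_grid] (e.g. the 2 m rasterization).
#' @param target coarse cell size in meters, >= the fine size.
#' @return A [presence_grid] at the target cell size.
#' @export
resample_presence <- function(fine, target) {
  f <- fine$cell_size
  if (target < f) stop("target cell size must be >= fine cell size")
  if (abs(target - f) < 1e-9) return(fine)
  d <- dim(fine$values)
  ext_x <- d[2] * f; ext_y <- d[1] * f
  nc <- ceiling(ext_x / target - 1e-9)
  nr <- ceiling(ext_y / target - 1e-9)

  # per fine cell: its x/y interval split across (at most 2) coarse columns/rows
  split1d <- function(n_fine) {
    lo <- (seq_len(n_fine) - 1) * f
    list(lo = lo, hi = lo + f)
  }
  xs <- split1d(d[2]); ys <- split1d(d[1])

  accum_occ <- matrix(0, nr, nc)
  accum_val <- matrix(0, nr, nc)

  col0 <- pmin(floor(xs$lo / target + 1e-12) + 1, nc)
  col_brk <- pmin(col0 * target, xs$hi)            # x where first coarse col ends
  wx1 <- pmax(col_brk - xs$lo, 0)
  wx2 <- pmax(xs$hi - col_brk, 0)
  col1 <- pmin(col0 + 1, nc)

  row0 <- pmin(floor(ys$lo / target + 1e-12) + 1, nr)
  row_brk <- pmin(row0 * target, ys$hi)
  wy1 <- pmax(row_brk - ys$lo, 0)
  wy2 <- pmax(ys$hi - row_brk, 0)
  row1 <- pmin(row0 + 1, nr)

  occ <- fine$values
  valid <- !is.na(occ)
  occ1 <- ifelse(valid, occ * 1, 0)

  add <- function(ri, ci, w) {
    # w: outer product weights (rows = fine rows, cols = fine cols)
    idx <- cbind(as.vector(matrix(ri, d[1], d[2])),
                 as.vector(matrix(ci, d[1], d[2], byrow = TRUE)))
    lin <- (idx[, 2] - 1) * nr + idx[, 1]
    wv <- as.vector(w)
    keep <- wv > 0
    if (!any(keep)) return()
    ov <- rowsum(wv[keep] * as.vector(occ1)[keep], lin[keep])
    vv <- rowsum(wv[keep] * as.vector(valid * 1)[keep], lin[keep])
    at <- as.integer(rownames(ov))
    accum_occ[at] <<- accum_occ[at] + ov[, 1]
    accum_val[at] <<- accum_val[at] + vv[, 1]
  }
  add(row0, col0, outer(wy1, wx1))
  add(row0, col1, outer(wy1, wx2))
  add(row1, col0, outer(wy2, wx1))
  add(row1, col1, outer(wy2, wx2))

  frac <- accum_occ / accum_val
  out <- frac >= 0.5
  out[accum_val <= 0] <- NA
  g <- rgrid(out, origin_x = fine$origin_x, origin_y = fine$origin_y,
             cell_size = target, kind = "boolean")
  presence_grid(g, site = fine$site, year = fine$year)
}

#' Cell state transitions between two snapshots
#'
#' States are coded 0 = 0->0, 1 = 0->1, 2 = 1->0, 3 = 1->1; nodata where
#' either snapshot is nodata.
#'
#' @param t0,t1 aligned [presence_grid] snapshots.
#' @return A categorical [rgrid] with attribute `cell_size`.
#' @export
transition_grid <- function(t0, t1) {
  stopifnot_aligned(t0, t1)
  st <- 2 * (t0$values * 1) + (t1$values * 1)
  st[is.na(t0$values) | is.na(t1$values)] <- NA
  # recode: 0->0 = 0, 0->1 = 1, 1->0 = 2, 1->1 = 3
  rgrid(st, origin_x = t0$origin_x, origin_y = t0$origin_y,
        cell_size = t0$cell_size, kind = "categorical")
}

#' Count of occupied neighbors within a window
#'
#' Number of occupied cells in the w x w window centered on each cell, the
#' center excluded. Cells whose window exits the grid or touches nodata are
#' nodata (no zero padding).
#'
#' @param t0 a [presence_grid].
#' @param window odd window width in cells (3, 5, 7 or 9 typical).
#' @return A continuous [rgrid] of counts.
#' @export
neighbor_counts <- function(t0, window = 3) {
  if (window %% 2 != 1 || window < 3) stop("window must be an odd integer >= 3")
  occ <- t0$values * 1   # NA propagates
  nr <- nrow(occ); nc <- ncol(occ)
  h <- (window - 1) / 2
  p <- matrix(NA_real_, nr + 2 * h, nc + 2 * h)
  p[(h + 1):(h + nr), (h + 1):(h + nc)] <- occ
  out <- matrix(0, nr, nc)
  for (di in -h:h) for (dj in -h:h) {
    if (di == 0 && dj == 0) next
    out <- out + p[(h + 1):(h + nr) + di, (h + 1):(h + nc) + dj]
  }
  out[is.na(occ)] <- NA    # the window includes its own center
  g <- rgrid(out, origin_x = t0$origin_x, origin_y = t0$origin_y,
             cell_size = t0$cell_size, kind = "continuous")
  attr(g, "window") <- as.integer(window)
  g
}

#' Transition proportions conditioned on neighbor count
#'
#' Cross-tabulates the state-transition grid with the occupied-neighbor-count
#' grid. For each neighbor count k, `p_colonize(k)` is the proportion of
#' initially clear cells that became occupied and `p_disappear(k)` the
#' proportion of initially occupied cells that disappeared. Counts with a
#' zero denominator are reported as `NA` (undefined), never zero.
#'
#' @param st grid from [transition_grid].
#' @param counts grid from [neighbor_counts].
#' @param window window width used for `counts` (recorded in the table).
#' @return Data frame with columns `cell_size_m`, `window`, `k`, `n00`,
#'   `n01`, `n10`, `n11`, `p_colonize`, `p_disappear`.
#' @export
transition_curves <- function(st, counts, window = attr(counts, "window")) {
  stopifnot_aligned(st, counts)
  if (is.null(window)) window <- NA_integer_
  kmax <- if (is.na(window)) max(counts$values, na.rm = TRUE)
          else window^2 - 1
  ok <- !is.na(st$values) & !is.na(counts$values)
  tab <- table(factor(st$values[ok], levels = 0:3),
               factor(counts$values[ok], levels = 0:kmax))
  k <- 0:kmax
  n00 <- as.numeric(tab["0", ]); n01 <- as.numeric(tab["1", ])
  n10 <- as.numeric(tab["2", ]); n11 <- as.numeric(tab["3", ])
  p_col <- ifelse(n00 + n01 > 0, n01 / (n00 + n01), NA_real_)
  p_dis <- ifelse(n10 + n11 > 0, n10 / (n10 + n11), NA_real_)
  data.frame(cell_size_m = st$cell_size, window = window, k = k,
             n00 = n00, n01 = n01, n10 = n10, n11 = n11,
             p_colonize = p_col, p_disappear = p_dis)
}

#' Multi-scale neighborhood transition sweep
#'
#' Resamples the fine snapshots to each cell size, computes the transition
#' grid and neighbor counts, and tabulates transition proportions for every
#' (cell size, window) combination.
#'
#' @param t0,t1 fine-resolution [presence_grid] snapshots (same geometry).
#' @param cell_sizes analysis cell sizes in meters.
#' @param windows odd window widths in cells.
#' @return A list of transition tables (one data frame per combination), in
#'   cell-size-major order; also row-bindable with `do.call(rbind, .)`.
#' @export
run_multiscale <- function(t0, t1, cell_sizes = c(3, 5, 7, 9),
                           windows = c(3, 5, 7, 9)) {
  stopifnot_aligned(t0, t1)
  out <- list()
  for (cs in cell_sizes) {
    a0 <- resample_presence(t0, cs)
    a1 <- resample_presence(t1, cs)
    st <- transition_grid(a0, a1)
    for (w in windows) {
      cnt <- neighbor_counts(a0, w)
      out[[sprintf("cs%g_w%d", cs, w)]] <- transition_curves(st, cnt, window = w)
    }
  }
  out
}

#' Plot transition curves (colonization solid, disappearance open)
#'
#' One panel per (cell size, window) combination, neighbor count on the x
#' axis and transition proportion on the y axis.
#'
#' @param tables list returned by [run_multiscale] (or a single table).
#' @return A ggplot object.
#' @export
plot_transition_curves <- function(tables) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (is.data.frame(tables)) tables <- list(tables)
  d <- do.call(rbind, tables)
  long <- rbind(
    data.frame(d[c("cell_size_m", "window", "k")], p = d$p_colonize,
               which = "colonization"),
    data.frame(d[c("cell_size_m", "window", "k")], p = d$p_disappear,
               which = "disappearance"))
  long <- long[!is.na(long$p), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$p,
                                     shape = .data$which)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(colonization = 16,
                                           disappearance = 1)) +
    ggplot2::facet_grid(ggplot2::vars(.data$cell_size_m),
                        ggplot2::vars(.data$window), scales = "free_x") +
    ggplot2::labs(x = "occupied neighbors at t0", y = "transition proportion",
                  shape = NULL)
}
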