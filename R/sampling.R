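# Per-cell sample frame and conditioned Latin hypercube sampling.
#
# The frame has one row per masked cell; the sampler selects n rows without
# replacement, annealing an objective that measures (a) for each continuous
# variable (the predictors plus x and y) the deviation of per-equal-
# probability-bin counts from 1 sample per bin, and (b) for categorical
# variables (occurrence, land cover) the deviation of sampled class counts
# from the frame's proportions.

#' Build the per-cell sample frame of a site
#'
#' @param site a `site_bundle` (or any list exposing aligned `bathymetry`,
#'   `openness`, `outlet_distance`, `landcover` and `mask` grids).
#' @param presence a [presence_grid] aligned with the site (its cell size
#'   must equal the site's; rasterize/resample first if needed).
#' @return Data frame with columns `cell_id`, `x`, `y`, `occurrence`,
#'   `depth`, `openness`, `outlet_distance`, `landcover`; one row per masked
#'   cell, rows with any missing predictor dropped.
#' @export
build_frame <- function(site, presence) {
  layers <- list(bathymetry = site$bathymetry, openness = site$openness,
                 outlet_distance = site$outlet_distance,
                 landcover = site$landcover)
  missing <- names(layers)[vapply(layers, is.null, TRUE)]
  if (length(missing)) stop("missing predictor layer(s): ",
                            paste(missing, collapse = ", "))
  for (nm in names(layers)) stopifnot_aligned(site$mask, layers[[nm]])
  stopifnot_aligned(site$mask, presence)
  mask <- site$mask$values
  idx <- which(mask)
  d <- dim(mask)
  cc <- cell_centers(site$mask)
  row_i <- (idx - 1) %% d[1] + 1
  col_i <- (idx - 1) %/% d[1] + 1
  op <- site$openness$values[idx]
  # shoreline land cells carry no fetch; they are fully sheltered (fetch 0)
  op[is.na(op) & site$land_sea$values[idx]] <- 0
  out <- data.frame(
    cell_id = idx,
    x = cc$x[col_i],
    y = cc$y[row_i],
    occurrence = as.integer(presence$values[idx]),
    depth = site$bathymetry$values[idx],
    openness = op,
    outlet_distance = site$outlet_distance$values[idx],
    landcover = site$landcover$values[idx]
  )
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Conditioned Latin hypercube draw from a sample frame
#'
#' Selects `n` rows without replacement by simulated annealing (swap
#' proposals, geometric cooling) over the stratification objective described
#' above. Deterministic under a fixed seed. Constant variables are dropped
#' from the objective with a warning.
#'
#' @param frame data frame from [build_frame].
#' @param n sample size, <= `nrow(frame)`.
#' @param seed RNG seed.
#' @param iterations annealing iterations (default 10000).
#' @param continuous,categorical variable names entering the objective.
#' @return The sampled rows of `frame`; the achieved objective value is in
#'   attribute `objective`, its trace in attribute `trace`.
#' @export
draw_lhs <- function(frame, n, seed = 1, iterations = 10000,
                     continuous = c("x", "y", "depth", "openness",
                                    "outlet_distance"),
                     categorical = c("occurrence", "landcover")) {
  N <- nrow(frame)
  if (n > N) stop("n exceeds the frame size")
  if (n == N) {
    attr(frame, "objective") <- 0
    return(frame)
  }
  continuous <- intersect(continuous, names(frame))
  categorical <- intersect(categorical, names(frame))

  keep <- function(v) length(unique(frame[[v]])) > 1
  drop_c <- continuous[!vapply(continuous, keep, TRUE)]
  drop_k <- categorical[!vapply(categorical, keep, TRUE)]
  if (length(c(drop_c, drop_k)))
    warning("constant variable(s) dropped from objective: ",
            paste(c(drop_c, drop_k), collapse = ", "))
  continuous <- setdiff(continuous, drop_c)
  categorical <- setdiff(categorical, drop_k)

  # precompute per-row bin index for each objective variable
  bins <- list()
  nbin <- integer()
  target <- list()
  for (v in continuous) {
    q <- stats::quantile(frame[[v]], probs = seq(0, 1, length.out = n + 1),
                         names = FALSE, type = 7)
    b <- findInterval(frame[[v]], q, rightmost.closed = TRUE,
                      all.inside = TRUE)
    bins[[v]] <- b
    nbin[v] <- n
    target[[v]] <- rep(1, n)
  }
  for (v in categorical) {
    f <- factor(frame[[v]])
    bins[[v]] <- as.integer(f)
    nbin[v] <- nlevels(f)
    target[[v]] <- as.numeric(table(f)) / N * n
  }
  vars <- c(continuous, categorical)
  if (!length(vars)) stop("no usable objective variables")

  set.seed(seed)
  sel <- sample.int(N, n)
  in_sample <- logical(N)
  in_sample[sel] <- TRUE
  counts <- lapply(vars, function(v) tabulate(bins[[v]][sel], nbin[v]))
  names(counts) <- vars
  obj_v <- vapply(vars, function(v) sum(abs(counts[[v]] - target[[v]])), 0)
  obj <- sum(obj_v)
  init_obj <- obj

  temp0 <- max(obj / 20, 1e-6)
  cool_every <- max(1L, as.integer(iterations / 200))
  trace <- numeric(0)
  out_pool <- which(!in_sample)
  # positions: sel vector; propose swapping sel[i] with a random unsampled row
  for (it in seq_len(iterations)) {
    temp <- temp0 * 0.95^(it %/% cool_every)
    i <- sample.int(n, 1)
    j <- sample.int(N - n, 1)
    rem <- sel[i]
    add <- out_pool[j]
    delta <- 0
    for (v in vars) {
      b_rem <- bins[[v]][rem]; b_add <- bins[[v]][add]
      if (b_rem == b_add) next
      cr <- counts[[v]][b_rem]; ca <- counts[[v]][b_add]
      tr <- target[[v]][b_rem]; ta <- target[[v]][b_add]
      delta <- delta +
        (abs(cr - 1 - tr) - abs(cr - tr)) +
        (abs(ca + 1 - ta) - abs(ca - ta))
    }
    if (delta < 0 || stats::runif(1) < exp(-delta / max(temp, 1e-12))) {
      sel[i] <- add
      out_pool[j] <- rem
      for (v in vars) {
        b_rem <- bins[[v]][rem]; b_add <- bins[[v]][add]
        counts[[v]][b_rem] <- counts[[v]][b_rem] - 1
        counts[[v]][b_add] <- counts[[v]][b_add] + 1
      }
      obj <- obj + delta
    }
    if (it %% 500 == 0) trace <- c(trace, obj)
  }
  out <- frame[sel, , drop = FALSE]
  attr(out, "objective") <- obj
  attr(out, "initial_objective") <- init_obj
  attr(out, "trace") <- trace
  out
}
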