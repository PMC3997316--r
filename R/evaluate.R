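# Map and model evaluation: descriptive occurrence analysis, rank-based AUC,
# minimized-difference thresholding, confusion statistics, and the
# interpolation/extrapolation transfer harness.

#' Area under the ROC curve
#'
#' Probability that a random positive outscores a random negative, ties
#' counted one half; computed from midranks (Mann-Whitney).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 (or logical) labels.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Minimized-difference threshold
#'
#' The cutoff (scores >= threshold classified positive) minimizing
#' |sensitivity - specificity|; candidates are the unique observed scores
#' plus midpoints between adjacent unique scores; ties are broken by the
#' lower threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return The threshold; attributes `sensitivity` and `specificity` hold
#'   the values achieved at it.
#' @export
min_diff_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  best <- Inf; best_t <- cand[1]; best_se <- NA; best_sp <- NA
  for (t in cand) {
    pred <- scores >= t
    se <- sum(pred & labels == 1) / np
    sp <- sum(!pred & labels == 0) / nn
    d <- abs(se - sp)
    if (d < best - 1e-12) {
      best <- d; best_t <- t; best_se <- se; best_sp <- sp
    }
  }
  structure(best_t, sensitivity = best_se, specificity = best_sp)
}

#' Sensitivity and specificity from a cell-by-cell comparison
#'
#' @param predicted,truth aligned [presence_grid]s (or logical vectors);
#'   nodata cells are excluded pairwise.
#' @return List with `sensitivity`, `specificity`, `n_pos`, `n_neg` and the
#'   2x2 table counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_stats <- function(predicted, truth) {
  if (inherits(predicted, "rgrid")) {
    stopifnot_aligned(predicted, truth)
    predicted <- as.vector(predicted$values)
    truth <- as.vector(truth$values)
  }
  ok <- !is.na(predicted) & !is.na(truth)
  if (!any(ok)) stop("no valid overlapping cells")
  p <- as.logical(predicted[ok]); y <- as.logical(truth[ok])
  tp <- sum(p & y); fn <- sum(!p & y)
  tn <- sum(!p & !y); fp <- sum(p & !y)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n_pos = tp + fn, n_neg = tn + fp, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Descriptive occurrence analysis
#'
#' Splits the sampled cells into ever-occupied (occupied in any snapshot of
#' the series) and never-occupied, and summarizes each predictor by
#' quantiles for the two groups; additionally summarizes the occupied cells
#' of every snapshot year for the static predictors (depth, openness,
#' outlet distance) — land cover is excluded from the temporal comparison.
#'
#' @param sample data frame from [build_frame]/[draw_lhs] (large descriptive
#'   draw recommended).
#' @param presence_series list of [presence_grid]s aligned with the sampled
#'   site.
#' @param probs quantile probabilities.
#' @return List of data frames `overall` (per variable and group) and
#'   `by_year` (per year and static variable, occupied cells only).
#' @export
describe_occurrence <- function(sample, presence_series,
                                probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  ever <- rep(FALSE, nrow(sample))
  for (p in presence_series)
    ever <- ever | (p$values[sample$cell_id] %in% TRUE)
  vars <- c("depth", "openness", "outlet_distance")
  qrow <- function(v, grp, vals) {
    if (!length(vals)) return(NULL)
    q <- stats::quantile(vals, probs, names = FALSE, na.rm = TRUE)
    cbind(data.frame(variable = v, group = grp, n = length(vals),
                     mean = mean(vals, na.rm = TRUE)),
          stats::setNames(as.data.frame(t(q)), paste0("q", probs * 100)))
  }
  if (all(ever)) warning("all sampled cells were occupied at some point; ",
                         "never-occupied summary is empty")
  overall <- do.call(rbind, c(
    lapply(vars, function(v) qrow(v, "ever_occupied", sample[[v]][ever])),
    lapply(vars, function(v) qrow(v, "never_occupied", sample[[v]][!ever]))))
  lc <- table(factor(sample$landcover), ever)
  by_year <- do.call(rbind, lapply(presence_series, function(p) {
    occ <- p$values[sample$cell_id] %in% TRUE
    do.call(rbind, lapply(vars, function(v)
      cbind(year = p$year, qrow(v, "occupied", sample[[v]][occ]))))
  }))
  list(overall = overall, by_year = by_year, landcover = lc)
}

#' Interpolation / extrapolation transfer harness
#'
#' Trains a boosted model on an LHS sample of the training site and predicts
#' every listed site. Interpolation (predict site == training site) is
#' evaluated on the cells outside the training sample; extrapolation on all
#' masked cells of the other site. Each prediction is summarized by AUC, the
#' minimized-difference threshold computed on the prediction site's scores,
#' and the resulting sensitivity/specificity; suitability and thresholded
#' presence grids are returned (and written as ESRI ASCII when `out_dir` is
#' given).
#'
#' @param train list with elements `site` (a `site_bundle`), `presence` (a
#'   [presence_grid]) and `name`.
#' @param predict_sites list of such lists (may include the training site).
#' @param params a [brt_params].
#' @param n_sample LHS sample size drawn from the training frame.
#' @param n_trees fixed ensemble size; if `NULL`, selected by
#'   cross-validation.
#' @param lhs_iterations annealing iterations for the training draw.
#' @param out_dir optional output directory for grids and the evaluation CSV.
#' @return List with `evaluation` (data frame), `model`, and `maps` (per
#'   site: `suitability` and `presence` grids).
#' @export
transfer_harness <- function(train, predict_sites, params = brt_params(),
                             n_sample = 2000, n_trees = NULL,
                             lhs_iterations = 2000, out_dir = NULL) {
  frame_tr <- build_frame(train$site, train$presence)
  samp <- draw_lhs(frame_tr, min(n_sample, nrow(frame_tr)),
                   seed = params$seed, iterations = lhs_iterations)
  if (is.null(n_trees)) {
    model <- fit_brt_cv(samp, params)
  } else {
    model <- fit_brt(samp, params, n_trees = n_trees)
  }
  train_classes <- model$cat_levels[[which(model$var_names == "landcover")]]

  rows <- list(); maps <- list()
  for (ps in predict_sites) {
    interp <- identical(ps$name, train$name)
    frame_pr <- build_frame(ps$site, ps$presence)
    if (!all(unique(frame_pr$landcover) %in% train_classes))
      warning("site ", ps$name, " has land-cover classes unseen in training; ",
              "parent-node values are used for them")
    if (interp) {
      eval_rows <- frame_pr[!(frame_pr$cell_id %in% samp$cell_id), ,
                            drop = FALSE]
    } else {
      eval_rows <- frame_pr
    }
    if (!nrow(eval_rows)) stop("no cells to evaluate for site ", ps$name)
    scores <- predict(model, eval_rows)
    if (length(unique(eval_rows$occurrence)) < 2)
      stop("prediction site ", ps$name, " has a single-class truth")
    a <- auc(scores, eval_rows$occurrence)
    th <- min_diff_threshold(scores, eval_rows$occurrence)
    cs <- confusion_stats(scores >= as.numeric(th),
                          eval_rows$occurrence == 1)
    rows[[ps$name]] <- data.frame(
      train_site = train$name, predict_site = ps$name,
      mode = if (interp) "interpolation" else "extrapolation",
      auc = a, threshold = as.numeric(th),
      sensitivity = cs$sensitivity, specificity = cs$specificity,
      n_pos = cs$n_pos, n_neg = cs$n_neg)
    suit <- predict(model, ps$site)
    pres <- suit
    pres$values <- pres$values >= as.numeric(th)
    pres$kind <- "boolean"
    maps[[ps$name]] <- list(suitability = suit, presence = pres)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_esri_ascii(suit, file.path(out_dir,
                                       paste0(ps$name, "_suitability.asc")))
      write_esri_ascii(pres, file.path(out_dir,
                                       paste0(ps$name, "_presence.asc")))
    }
  }
  evaluation <- do.call(rbind, rows)
  rownames(evaluation) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(evaluation, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
  list(evaluation = evaluation, model = model, maps = maps)
}
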