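# Stochastic gradient boosted regression trees with Bernoulli deviance:
# R-side interface over the compiled core, cross-validated tree-count
# selection, relative influence, prediction, and JSON serialization.

#' Boosting parameters
#'
#' @param lr learning rate (shrinkage), >= 0.
#' @param tc tree complexity: number of splits per tree, >= 1.
#' @param bf bag fraction in (0, 1]: share of rows subsampled (without
#'   replacement) per boosting stage.
#' @param step trees added per cross-validation evaluation step.
#' @param max_trees ceiling on the ensemble size.
#' @param folds cross-validation folds.
#' @param min_obs minimum observations per terminal node.
#' @param seed RNG seed (bagging and fold assignment).
#' @export
brt_params <- function(lr = 0.005, tc = 10, bf = 0.75, step = 50,
                       max_trees = 10000, folds = 10, min_obs = 10,
                       seed = 1) {
  stopifnot(lr >= 0, tc >= 1, bf > 0, bf <= 1, step >= 1, max_trees >= 1,
            folds >= 2, min_obs >= 1)
  structure(list(lr = lr, tc = as.integer(tc), bf = bf,
                 step = as.integer(step), max_trees = as.integer(max_trees),
                 folds = as.integer(folds), min_obs = as.integer(min_obs),
                 seed = as.integer(seed)),
            class = "brt_params")
}

brt_predictors <- c("depth", "openness", "outlet_distance", "landcover")

# build the numeric design matrix; categorical columns become 0-based codes
brt_design <- function(data, var_names, is_cat, cat_levels = NULL) {
  miss <- setdiff(var_names, names(data))
  if (length(miss)) stop("missing model variable(s): ",
                         paste(miss, collapse = ", "))
  X <- matrix(NA_real_, nrow(data), length(var_names))
  levels_out <- vector("list", length(var_names))
  for (j in seq_along(var_names)) {
    v <- data[[var_names[j]]]
    if (is_cat[j]) {
      lev <- if (is.null(cat_levels)) sort(unique(v[!is.na(v)]))
             else cat_levels[[j]]
      code <- match(v, lev) - 1
      X[, j] <- as.numeric(code)   # unseen level -> NA -> parent-node value
      levels_out[[j]] <- lev
    } else {
      X[, j] <- as.numeric(v)
    }
  }
  list(X = X, cat_levels = levels_out)
}

#' Fit a boosted regression tree ensemble
#'
#' Stagewise Bernoulli-deviance boosting: the intercept is the logit of the
#' response prevalence; each stage fits a `tc`-split regression tree (grown
#' best-first) to the gradient residuals y - p of a bag-fraction subsample,
#' with one-step Newton terminal values; tree contributions are shrunk by
#' `lr`. Deterministic under a fixed seed.
#'
#' @param sample data frame holding `occurrence` (0/1) and the predictor
#'   columns.
#' @param params a [brt_params].
#' @param n_trees number of trees to fit (defaults to `params$max_trees`).
#' @param vars predictor column names.
#' @param categorical names of categorical predictors.
#' @return A `brt_model`: intercept, trees, `n_trees`, per-stage split-gain
#'   matrix, training deviance path, variable metadata.
#' @export
fit_brt <- function(sample, params = brt_params(), n_trees = params$max_trees,
                    vars = brt_predictors, categorical = "landcover") {
  y <- sample$occurrence
  if (is.null(y)) stop("`sample` must contain an `occurrence` column")
  if (length(unique(y)) < 2) stop("single-class response; cannot fit")
  is_cat <- vars %in% categorical
  des <- brt_design(sample, vars, is_cat)
  ncat <- vapply(seq_along(vars), function(j)
    if (is_cat[j]) length(des$cat_levels[[j]]) else 0L, 0L)
  intercept <- stats::qlogis(mean(y))
  fit <- cpp_brt_fit(des$X, as.numeric(y), as.integer(is_cat),
                     as.integer(ncat), intercept, params$lr, params$tc,
                     params$bf, as.integer(n_trees), params$min_obs,
                     params$seed)
  structure(
    list(intercept = intercept, trees = fit$trees, n_trees = length(fit$trees),
         gains = fit$gains, train_dev = fit$train_dev, params = params,
         var_names = vars, is_cat = is_cat, ncat = ncat,
         cat_levels = des$cat_levels, prevalence = mean(y),
         cv_stats = NULL),
    class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("<brt_model> %d trees (lr=%g, tc=%d, bf=%g), intercept %.3f\n",
              x$n_trees, x$params$lr, x$params$tc, x$params$bf, x$intercept))
  inf <- relative_influence(x)
  cat("  relative influence:",
      paste(sprintf("%s %.1f", names(inf), inf), collapse = ", "), "\n")
  if (!is.null(x$cv_stats))
    cat(sprintf("  CV (%d folds): AUC %.3f (se %.3f), cor %.3f (se %.3f)\n",
                x$params$folds, x$cv_stats$auc_mean, x$cv_stats$auc_se,
                x$cv_stats$cor_mean, x$cv_stats$cor_se))
  invisible(x)
}

#' Predict occurrence probabilities
#'
#' @param object a `brt_model`.
#' @param newdata data frame of predictor columns, or a `site_bundle` (then a
#'   suitability [rgrid] over the analysis mask is returned).
#' @param n_trees number of leading trees to use (default the model's).
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param ... unused.
#' @export
predict.brt_model <- function(object, newdata, n_trees = object$n_trees,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "site_bundle")) {
    frame <- site_frame(newdata)
    p <- predict(object, frame, n_trees = n_trees, type = "response")
    m <- matrix(NA_real_, nrow(newdata$mask$values), ncol(newdata$mask$values))
    m[frame$cell_id] <- p
    return(rgrid(m, origin_x = newdata$mask$origin_x,
                 origin_y = newdata$mask$origin_y,
                 cell_size = newdata$cell_size, kind = "continuous"))
  }
  des <- brt_design(newdata, object$var_names, object$is_cat,
                    object$cat_levels)
  F <- cpp_brt_predict(object$trees, des$X, as.integer(object$ncat),
                       object$intercept, object$params$lr,
                       as.integer(n_trees))
  if (type == "link") F else stats::plogis(F)
}

# frame of predictors over the mask (occurrence-free; used for map prediction)
site_frame <- function(site) {
  dummy <- presence_grid(rgrid(matrix(FALSE, nrow(site$mask$values),
                                      ncol(site$mask$values)),
                               origin_x = site$mask$origin_x,
                               origin_y = site$mask$origin_y,
                               cell_size = site$cell_size, kind = "boolean"),
                         site = "tmp", year = 0)
  build_frame(site, dummy)
}

#' Relative influence of the predictors
#'
#' Per split, the squared-error improvement is attributed to the split
#' variable; attributions are summed over the first `n_trees` trees and
#' normalized to 100.
#'
#' @param model a `brt_model`.
#' @param n_trees trees to include (default the model's).
#' @return Named numeric vector summing to 100 (all zeros if no splits).
#' @export
relative_influence <- function(model, n_trees = model$n_trees) {
  g <- colSums(model$gains[seq_len(min(n_trees, nrow(model$gains))), ,
                           drop = FALSE])
  names(g) <- model$var_names
  tot <- sum(g)
  if (tot <= 0) return(g * 0)
  100 * g / tot
}

#' Cross-validated selection of the ensemble size
#'
#' Trees are added in increments of `params$step`; the selected size
#' minimizes the mean held-out Bernoulli deviance across occurrence-
#' stratified folds. AUC and Pearson correlation between the held-out 0/1
#' response and the predicted probability are reported at the selected size,
#' per fold (mean and standard error) and pooled over all held-out rows.
#'
#' @param sample data frame with `occurrence` and predictors.
#' @param params a [brt_params].
#' @param vars,categorical predictor specification as in [fit_brt].
#' @return A list: `n_trees`, `cv_stats` (auc_mean/auc_se/cor_mean/cor_se/
#'   auc_pooled/cor_pooled), `deviance` (mean held-out deviance per evaluated
#'   size), `folds` (fold assignment).
#' @export
cv_select_trees <- function(sample, params = brt_params(),
                            vars = brt_predictors, categorical = "landcover") {
  y <- sample$occurrence
  n <- length(y)
  if (params$folds > n) stop("more folds than rows")
  set.seed(params$seed)
  fold <- integer(n)
  for (cl in unique(y)) {
    id <- which(y == cl)
    fold[id] <- sample(rep_len(seq_len(params$folds), length(id)))
  }
  for (f in seq_len(params$folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2)
      stop("fold ", f, " leaves a single-class training set")
  }
  is_cat <- vars %in% categorical
  des <- brt_design(sample, vars, is_cat)
  ncat <- vapply(seq_along(vars), function(j)
    if (is_cat[j]) length(des$cat_levels[[j]]) else 0L, 0L)

  dev_mat <- matrix(NA_real_, params$max_trees, params$folds)
  fold_fits <- vector("list", params$folds)
  for (f in seq_len(params$folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    intercept <- stats::qlogis(mean(y[tr]))
    fit <- cpp_brt_fit(des$X[tr, , drop = FALSE], as.numeric(y[tr]),
                       as.integer(is_cat), as.integer(ncat), intercept,
                       params$lr, params$tc, params$bf, params$max_trees,
                       params$min_obs, params$seed + f,
                       des$X[te, , drop = FALSE], as.numeric(y[te]))
    dev_mat[, f] <- fit$val_dev
    fold_fits[[f]] <- list(trees = fit$trees, intercept = intercept, te = te)
  }
  eval_at <- seq(params$step, params$max_trees, by = params$step)
  # empty folds (possible when folds ~ n) contribute NaN deviance; drop them
  mean_dev <- rowMeans(dev_mat, na.rm = TRUE)[eval_at]
  if (all(!is.finite(mean_dev))) stop("no fold produced a held-out deviance")
  n_trees <- eval_at[which.min(mean_dev)]

  auc_f <- cor_f <- rep(NA_real_, params$folds)
  pooled_p <- numeric(n)
  for (f in seq_len(params$folds)) {
    ff <- fold_fits[[f]]
    Fv <- cpp_brt_predict(ff$trees, des$X[ff$te, , drop = FALSE],
                          as.integer(ncat), ff$intercept, params$lr,
                          as.integer(n_trees))
    p <- stats::plogis(Fv)
    pooled_p[ff$te] <- p
    yy <- y[ff$te]
    if (length(unique(yy)) == 2) {
      auc_f[f] <- auc(p, yy)
      cor_f[f] <- suppressWarnings(stats::cor(yy, p))
    }
  }
  se <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  cv_stats <- list(
    auc_mean = mean(auc_f, na.rm = TRUE), auc_se = se(auc_f),
    cor_mean = mean(cor_f, na.rm = TRUE), cor_se = se(cor_f),
    auc_pooled = auc(pooled_p, y),
    cor_pooled = suppressWarnings(stats::cor(y, pooled_p)))
  list(n_trees = n_trees, cv_stats = cv_stats,
       deviance = data.frame(n_trees = eval_at, mean_heldout_dev = mean_dev),
       folds = fold)
}

#' Fit with cross-validated tree count
#'
#' Convenience wrapper: runs [cv_select_trees], then fits the final model on
#' all rows with the selected number of trees and attaches the CV statistics.
#'
#' @inheritParams cv_select_trees
#' @export
fit_brt_cv <- function(sample, params = brt_params(), vars = brt_predictors,
                       categorical = "landcover") {
  sel <- cv_select_trees(sample, params, vars, categorical)
  model <- fit_brt(sample, params, n_trees = sel$n_trees, vars = vars,
                   categorical = categorical)
  model$cv_stats <- sel$cv_stats
  model$cv_deviance <- sel$deviance
  model
}

#' Serialize a model to JSON
#'
#' The schema records the intercept, parameters, variable metadata and
#' per-tree node arrays (var, split/category-mask, is_cat, left, right,
#' value; 1-based child indices, var 0 marking leaves).
#'
#' @param model a `brt_model`.
#' @param path destination file.
#' @export
write_brt_json <- function(model, path) {
  obj <- list(
    format = "reedgrid-brt-1",
    intercept = model$intercept,
    prevalence = model$prevalence,
    n_trees = model$n_trees,
    params = unclass(model$params),
    var_names = model$var_names,
    is_cat = model$is_cat,
    cat_levels = model$cat_levels,
    gains = model$gains,
    trees = lapply(model$trees[seq_len(model$n_trees)], unclass)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model from JSON
#'
#' @param path file written by [write_brt_json].
#' @return A `brt_model`.
#' @export
read_brt_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(obj$format, "reedgrid-brt-1")) stop("unrecognized model file")
  tr <- obj$trees
  trees <- if (is.array(tr) && length(dim(tr)) == 3) {
    # equally sized trees collapse to an (n_trees x nodes x 6) array
    lapply(seq_len(dim(tr)[1]), function(i) matrix(tr[i, , ], ncol = 6))
  } else {
    lapply(tr, function(m) matrix(as.numeric(unlist(m)), ncol = 6))
  }
  p <- obj$params
  structure(
    list(intercept = obj$intercept, trees = trees, n_trees = obj$n_trees,
         gains = matrix(obj$gains, ncol = length(obj$var_names)),
         train_dev = NULL,
         params = brt_params(lr = p$lr, tc = p$tc, bf = p$bf, step = p$step,
                             max_trees = p$max_trees, folds = p$folds,
                             min_obs = p$min_obs, seed = p$seed),
         var_names = obj$var_names, is_cat = obj$is_cat,
         ncat = vapply(obj$cat_levels, length, 0L),
         cat_levels = obj$cat_levels, prevalence = obj$prevalence,
         cv_stats = NULL),
    class = "brt_model")
}
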