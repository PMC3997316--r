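sim_rows <- function(n, seed = 1, noise = TRUE) {
  set.seed(seed)
  d <- data.frame(depth = runif(n, 0, 3), openness = runif(n, 0, 5000),
                  outlet_distance = runif(n, 0, 2000),
                  landcover = sample(c(11, 21, 31), n, replace = TRUE))
  lp <- 2 - 2.5 * d$depth + 0.0004 * d$openness - 0.0008 * d$outlet_distance
  d$occurrence <- if (noise) rbinom(n, 1, plogis(lp)) else as.integer(lp > 0)
  d
}

test_that("degenerate responses and parameters are rejected or handled", {
  d <- sim_rows(100)
  d$occurrence <- 1L
  expect_error(fit_brt(d, brt_params()), "single-class")

  # lr = 0 with one tree: intercept-only, predictions at prevalence
  d <- sim_rows(200, seed = 2)
  m <- fit_brt(d, brt_params(lr = 0, tc = 1, bf = 1), n_trees = 1)
  expect_equal(unique(round(predict(m, d), 12)), round(mean(d$occurrence), 12))
})

test_that("a separable step function is fit to perfection by stumps", {
  set.seed(3)
  n <- 400
  d <- data.frame(depth = runif(n, 0, 2), openness = runif(n, 0, 100),
                  outlet_distance = runif(n, 0, 100),
                  landcover = rep(11, n))
  d$occurrence <- as.integer(d$depth < 1)
  m <- fit_brt(d, brt_params(lr = 0.1, tc = 1, bf = 1), n_trees = 500)
  expect_true(all(diff(m$train_dev) <= 1e-9))     # monotone with bf = 1
  expect_equal(auc(predict(m, d), d$occurrence), 1.0)
  # a variable that is never split has zero influence
  inf <- relative_influence(m)
  expect_equal(sum(inf), 100, tolerance = 1e-9)
  expect_equal(unname(inf["landcover"]), 0)
  expect_gt(unname(inf["depth"]), 95)
})

test_that("fitting is reproducible under a fixed seed", {
  d <- sim_rows(300, seed = 4)
  p1 <- predict(fit_brt(d, brt_params(lr = 0.05, tc = 3, bf = 0.6, seed = 9),
                        n_trees = 80), d)
  p2 <- predict(fit_brt(d, brt_params(lr = 0.05, tc = 3, bf = 0.6, seed = 9),
                        n_trees = 80), d)
  expect_identical(p1, p2)
})

test_that("predictions respect monotone structure and representations", {
  set.seed(5)
  n <- 500
  d <- data.frame(depth = runif(n, 0, 3), openness = rep(1, n),
                  outlet_distance = rep(1, n), landcover = rep(11, n))
  d$occurrence <- as.integer(d$depth < 1.5)   # noiseless monotone response
  m <- fit_brt(d, brt_params(lr = 0.05, tc = 1, bf = 1), n_trees = 200)
  grid_d <- data.frame(depth = seq(0.1, 2.9, 0.2), openness = 1,
                       outlet_distance = 1, landcover = 11)
  p <- predict(m, grid_d)
  expect_true(all(diff(p) <= 1e-9))               # non-increasing in depth
  expect_true(all(p > 0 & p < 1))

  # grid prediction equals row-wise prediction of the same cells
  s <- small_site()
  ser <- simulate_spread(s, spread_params(n_years = 0, seed = 2,
                                          preset = "depth_dominant"))
  fr <- build_frame(s, ser[[1]])
  ms <- fit_brt(fr, brt_params(lr = 0.05, tc = 3, bf = 1), n_trees = 100)
  suit <- predict(ms, s)
  expect_equal(unname(suit$values[fr$cell_id]), unname(predict(ms, fr)))
  expect_true(all(is.na(suit$values[!s$mask$values])))

  fr2 <- fr; fr2$depth <- NULL
  expect_error(predict(ms, fr2), "depth")
})

test_that("unseen land-cover classes fall back to parent-node values", {
  d <- sim_rows(400, seed = 6)
  m <- fit_brt(d, brt_params(lr = 0.05, tc = 3, bf = 1), n_trees = 100)
  new <- d[1:5, ]
  new$landcover <- 99   # class absent from training
  p <- predict(m, new)
  expect_true(all(is.finite(p) & p > 0 & p < 1))
})

test_that("stump ensembles track a reference gradient-boosting implementation", {
  skip_if_not_installed("xgboost")
  set.seed(42)
  n <- 200
  d <- data.frame(depth = runif(n, 0, 3), openness = runif(n, 0, 5000))
  d$occurrence <- rbinom(n, 1, plogis(2 - 2.5 * d$depth + 4e-4 * d$openness))
  m <- fit_brt(d, brt_params(lr = 0.1, tc = 1, bf = 1), n_trees = 100,
               vars = c("depth", "openness"), categorical = character(0))
  pr <- predict(m, d)
  dm <- xgboost::xgb.DMatrix(as.matrix(d[, 1:2]), label = d$occurrence)
  xm <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 1, eta = 0.1,
                  lambda = 0, gamma = 0, min_child_weight = 0,
                  base_score = mean(d$occurrence), tree_method = "exact"),
    data = dm, nrounds = 100, verbose = 0)
  px <- predict(xm, dm)
  expect_gt(cor(pr, px), 0.99)
})

test_that("cross-validation selects trees and reports finite statistics", {
  d <- sim_rows(600, seed = 7)
  sel <- cv_select_trees(d, brt_params(lr = 0.05, tc = 3, bf = 0.75,
                                       folds = 5, step = 25, max_trees = 300,
                                       seed = 2))
  expect_true(sel$n_trees %in% seq(25, 300, 25))
  expect_true(is.finite(sel$cv_stats$auc_mean))
  expect_gt(sel$cv_stats$auc_mean, 0.6)
  expect_equal(which.min(sel$deviance$mean_heldout_dev),
               which(sel$deviance$n_trees == sel$n_trees))

  # leave-one-out on 20 rows still runs; pooled statistics are finite
  d20 <- sim_rows(20, seed = 8)
  sel20 <- cv_select_trees(d20, brt_params(lr = 0.1, tc = 1, bf = 1,
                                           folds = 20, step = 10,
                                           max_trees = 50, min_obs = 2,
                                           seed = 1))
  expect_true(is.finite(sel20$cv_stats$auc_pooled))
  expect_true(is.finite(sel20$cv_stats$cor_pooled))
})

test_that("models serialize to JSON and back without changing predictions", {
  d <- sim_rows(300, seed = 9)
  m <- fit_brt(d, brt_params(lr = 0.05, tc = 3, bf = 0.8, seed = 3),
               n_trees = 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_brt_json(m, path)
  m2 <- read_brt_json(path)
  expect_equal(predict(m2, d), predict(m, d), tolerance = 1e-12)
  expect_equal(relative_influence(m2), relative_influence(m),
               tolerance = 1e-12)
})
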