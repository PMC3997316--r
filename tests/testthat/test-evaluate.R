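test_that("AUC equals the exhaustive pair-counting oracle", {
  # perfectly separated and all-ties endpoints
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(31)
  for (rep in 1:3) {
    s <- round(runif(100), 2)    # rounding forces ties
    y <- rbinom(100, 1, 0.4)
    expect_equal(auc(s, y), auc_oracle(s, y))
  }
})

test_that("AUC is antisymmetric under score negation", {
  set.seed(32)
  s <- round(rnorm(200), 1)
  y <- rbinom(200, 1, 0.5)
  expect_equal(auc(s, y) + auc(-s, y), 1)
})

test_that("the minimized-difference threshold matches an exhaustive scan", {
  # symmetric well-separated classes: |se - sp| = 0 between clusters
  s <- c(0.1, 0.15, 0.2, 0.8, 0.85, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  th <- min_diff_threshold(s, y)
  expect_gt(as.numeric(th), 0.2)
  expect_lte(as.numeric(th), 0.8)
  expect_equal(attr(th, "sensitivity"), attr(th, "specificity"))

  # degenerate all-equal scores
  th0 <- min_diff_threshold(rep(0.5, 8), c(0, 1, 0, 1, 0, 1, 0, 1))
  expect_equal(as.numeric(th0), 0.5)
  expect_equal(attr(th0, "sensitivity"), 1)
  expect_equal(attr(th0, "specificity"), 0)

  set.seed(33)
  for (rep in 1:3) {
    s <- round(runif(150), 2)
    y <- rbinom(150, 1, 0.35)
    th <- min_diff_threshold(s, y)
    # oracle: scan every candidate cutpoint
    u <- sort(unique(s))
    cand <- sort(unique(c(u, (u[-1] + u[-length(u)]) / 2)))
    diffs <- vapply(cand, function(t) {
      se <- mean(s[y == 1] >= t); sp <- mean(s[y == 0] < t)
      abs(se - sp)
    }, 0)
    best <- min(diffs)
    expect_equal(abs(attr(th, "sensitivity") - attr(th, "specificity")), best)
    expect_equal(as.numeric(th), cand[which(diffs <= best + 1e-12)[1]])
  }
})

test_that("confusion statistics match direct counting", {
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, NA), 2, 3)
  pg <- function(v) presence_grid(rgrid(v, cell_size = 1, kind = "boolean"),
                                  "t", 0)
  same <- confusion_stats(pg(m), pg(m))
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 1)
  opp <- confusion_stats(pg(!m), pg(m))
  expect_equal(opp$sensitivity, 0)
  expect_equal(opp$specificity, 0)

  set.seed(34)
  p <- runif(500) < 0.5; y <- runif(500) < 0.4
  cs <- confusion_stats(p, y)
  expect_equal(cs$sensitivity, sum(p & y) / sum(y))
  expect_equal(cs$specificity, sum(!p & !y) / sum(!y))
  expect_equal(cs$n_pos + cs$n_neg, 500)
  expect_error(confusion_stats(c(NA, NA), c(TRUE, FALSE)), "valid")
})

test_that("occurrence description separates suitable from unsuitable water", {
  s <- small_site()
  ser <- simulate_spread(s, spread_params(n_years = 2, seed = 6,
                                          preset = "depth_dominant"))
  fr <- build_frame(s, ser[[1]])
  desc <- describe_occurrence(fr, ser)
  ev <- desc$overall[desc$overall$group == "ever_occupied", ]
  nv <- desc$overall[desc$overall$group == "never_occupied", ]
  # depth response collapses beyond 1 m: occupied cells sit in shallow water
  expect_lt(ev$q75[ev$variable == "depth"], 1)
  expect_lt(ev$q75[ev$variable == "depth"], nv$q75[nv$variable == "depth"])
  # quantiles equal the sort-based oracle
  ever <- rep(FALSE, nrow(fr))
  for (p in ser) ever <- ever | (p$values[fr$cell_id] %in% TRUE)
  expect_equal(ev$q50[ev$variable == "depth"],
               quantile_oracle(fr$depth[ever], 0.5))
  expect_equal(nrow(desc$by_year), 3 * 3)   # 3 years x 3 static predictors
})

test_that("interpolation outperforms extrapolation on shifted sites", {
  siteA <- cached_site("thA", make_site(extent = c(600, 600), cell_size = 5,
                                        n_outlets = 2, n_classes = 4,
                                        seed = 21))
  siteB <- cached_site("thB", make_site(extent = c(600, 600), cell_size = 5,
                                        n_outlets = 2, n_classes = 4,
                                        seed = 22))
  serA <- simulate_spread(siteA, spread_params(n_years = 0, seed = 1,
                                               preset = "depth_dominant"))
  shifted <- spread_params(
    beta0 = -0.5,
    f_depth = list(x = c(0, 1, 1.7, 2.7, 3.7), y = c(1, 2.5, 0, -7, -11)),
    f_open = list(x = c(0, 500, 2000, 5000), y = c(-1, 0.5, 0, -4)),
    f_dist = list(x = c(0, 250, 1000, 3000), y = c(1.2, -0.3, 0.4, -2.5)),
    n_years = 0, seed = 31)
  serB <- simulate_spread(siteB, shifted)
  h <- transfer_harness(
    list(site = siteA, presence = serA[[1]], name = "A"),
    list(list(site = siteA, presence = serA[[1]], name = "A"),
         list(site = siteB, presence = serB[[1]], name = "B")),
    params = brt_params(lr = 0.02, tc = 5, bf = 0.75, seed = 4),
    n_sample = 1200, n_trees = 300, lhs_iterations = 1000)
  ev <- h$evaluation
  expect_equal(ev$mode, c("interpolation", "extrapolation"))
  expect_gt(ev$auc[1], ev$auc[2])
  expect_true(all(ev$sensitivity >= 0 & ev$sensitivity <= 1))
  # suitability maps stay inside (0, 1) with nodata off the mask
  suit <- h$maps[["A"]]$suitability$values
  expect_true(all(is.na(suit) | (suit > 0 & suit < 1)))
  expect_true(all(is.na(suit[!siteA$mask$values])))
})

test_that("training-set AUC is at least the cross-validated AUC", {
  s <- small_site()
  ser <- simulate_spread(s, spread_params(n_years = 0, seed = 3,
                                          preset = "depth_dominant"))
  fr <- build_frame(s, ser[[1]])
  samp <- draw_lhs(fr, 1200, seed = 2, iterations = 1500)
  params <- brt_params(lr = 0.02, tc = 5, bf = 0.75, folds = 5, step = 25,
                       max_trees = 400, seed = 5)
  m <- fit_brt_cv(samp, params)
  train_auc <- auc(predict(m, samp), samp$occurrence)
  expect_gte(train_auc, m$cv_stats$auc_mean - 0.01)
})
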