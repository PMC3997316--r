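make_unit_site <- function(p_cells = 1, depth = 0.5) {
  # minimal hand-built bundle: p_cells water cells in a row, all masked
  nr <- 1; nc <- p_cells
  land <- matrix(FALSE, nr, nc)
  g <- function(m, kind) rgrid(m, origin_x = 0, origin_y = nr,
                               cell_size = 1, kind = kind)
  structure(list(
    land_sea = g(land, "boolean"),
    bathymetry = g(matrix(depth, nr, nc), "continuous"),
    openness = g(matrix(10, nr, nc), "continuous"),
    outlet_distance = g(matrix(100, nr, nc), "continuous"),
    landcover = g(matrix(11, nr, nc), "categorical"),
    mask = g(matrix(TRUE, nr, nc), "boolean"),
    outlets = cbind(x = 0, y = 0), cell_size = 1, seed = 1),
    class = "site_bundle")
}

flat_params <- function(p0, colonize_base, extinct_base, n_years, seed,
                        colonize_gain = 0, extinct_decay = 0) {
  spread_params(beta0 = qlogis(p0),
                f_depth = list(x = c(0, 1), y = c(0, 0)),
                f_open = list(x = c(0, 1), y = c(0, 0)),
                f_dist = list(x = c(0, 1), y = c(0, 0)),
                colonize_base = colonize_base, colonize_gain = colonize_gain,
                extinct_base = extinct_base, extinct_decay = extinct_decay,
                n_years = n_years, seed = seed)
}

test_that("site generation is deterministic under a fixed seed", {
  a <- make_site(extent = c(300, 300), cell_size = 5, n_outlets = 2,
                 n_classes = 3, seed = 42)
  b <- make_site(extent = c(300, 300), cell_size = 5, n_outlets = 2,
                 n_classes = 3, seed = 42)
  expect_identical(a$land_sea$values, b$land_sea$values)
  expect_identical(a$bathymetry$values, b$bathymetry$values)
  expect_identical(a$outlets, b$outlets)
  expect_identical(a$landcover$values, b$landcover$values)
})

test_that("site generation validates its inputs and invariants", {
  expect_error(make_site(extent = c(100, 300)), "200")
  expect_error(make_site(n_outlets = 0), "outlet")
  s <- small_site()
  # bathymetry positive exactly on water; mask consistent with < 3 m
  w <- !s$land_sea$values
  expect_true(all(s$bathymetry$values[w] > 0))
  expect_true(all(s$bathymetry$values[!w] <= 0))
  expect_true(all(s$bathymetry$values[s$mask$values & w] < 3))
  deep <- w & s$bathymetry$values >= 3
  expect_false(any(s$mask$values[deep]))
})

test_that("synthetic outlet distances equal the exhaustive oracle", {
  s <- cached_site("od", make_site(extent = c(500, 500), cell_size = 5,
                                   n_outlets = 3, n_classes = 3, seed = 1))
  expect_equal(s$outlet_distance$values, distance_oracle(s$land_sea,
                                                         s$outlets),
               tolerance = 1e-10)
})

test_that("frozen dynamics leave occupancy constant; certain extinction empties it", {
  s <- small_site()
  frozen <- spread_params(colonize_base = 0, colonize_gain = 0,
                          extinct_base = 0, n_years = 3, seed = 5)
  ser <- simulate_spread(s, frozen)
  for (i in 2:4) expect_identical(ser[[i]]$values, ser[[1]]$values)

  doom <- spread_params(colonize_base = 0, colonize_gain = 0,
                        extinct_base = 1, extinct_decay = 0, n_years = 2,
                        seed = 5)
  ser <- simulate_spread(s, doom)
  expect_gt(sum(ser[[1]]$values, na.rm = TRUE), 0)
  expect_equal(sum(ser[[2]]$values, na.rm = TRUE), 0)
  expect_equal(sum(ser[[3]]$values, na.rm = TRUE), 0)
})

test_that("single-cell occupancy follows the two-state Markov closed form", {
  # k = 0 always, so P(occ, t) = pi + (p0 - pi) (1 - c - e)^t, pi = c/(c+e)
  p0 <- 0.5; cc <- 0.2; ee <- 0.3; n_years <- 5
  site <- make_unit_site(1)
  reps <- 3000
  occ <- matrix(NA, reps, n_years + 1)
  for (r in seq_len(reps)) {
    ser <- simulate_spread(site, flat_params(p0, cc, ee, n_years, seed = r))
    occ[r, ] <- vapply(ser, function(p) p$values[1, 1], TRUE)
  }
  pi_st <- cc / (cc + ee)
  for (t in 0:n_years) {
    expected <- pi_st + (p0 - pi_st) * (1 - cc - ee)^t
    se <- sqrt(expected * (1 - expected) / reps)
    expect_lt(abs(mean(occ[, t + 1]) - expected), 3.5 * se)
  }
})

test_that("positive neighbor gain produces clustering over time", {
  # mean distance to the nearest other occupied cell shrinks (or stays flat)
  nn_mean <- function(p) {
    m <- p$values
    m[is.na(m)] <- FALSE
    id <- which(m, arr.ind = TRUE)
    if (nrow(id) < 20) return(NA_real_)
    pick <- id[seq(1, nrow(id), length.out = min(150, nrow(id))), ,
               drop = FALSE]
    d <- vapply(seq_len(nrow(pick)), function(q) {
      dd <- sqrt((id[, 1] - pick[q, 1])^2 + (id[, 2] - pick[q, 2])^2)
      min(dd[dd > 0])
    }, 0)
    mean(d)
  }
  wins <- 0; valid <- 0
  for (sd in 1:20) {
    site <- cached_site(paste0("clu", sd %% 4),
                        make_site(extent = c(400, 400), cell_size = 5,
                                  n_outlets = 2, n_classes = 3, seed = sd %% 4 + 50))
    pars <- spread_params(beta0 = -3.5,
                          f_depth = list(x = c(0, 1), y = c(0, 0)),
                          f_open = list(x = c(0, 1), y = c(0, 0)),
                          f_dist = list(x = c(0, 1), y = c(0, 0)),
                          colonize_base = 0.01, colonize_gain = 0.8,
                          extinct_base = 0.05, extinct_decay = 0.5,
                          n_years = 5, seed = sd)
    ser <- simulate_spread(site, pars)
    a <- nn_mean(ser[[1]]); b <- nn_mean(ser[[6]])
    if (is.na(a) || is.na(b)) next
    valid <- valid + 1
    if (b <= a + 1e-9) wins <- wins + 1
  }
  expect_gte(valid, 15)
  expect_gte(wins / valid, 0.75)
})
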