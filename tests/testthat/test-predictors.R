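test_that("outlet distance matches the exhaustive pairwise oracle", {
  template <- rgrid(matrix(0, 50, 50), origin_x = 0, origin_y = 250,
                    cell_size = 5)
  # single outlet at a cell center: zero there
  cc <- cell_centers(template)
  g1 <- distance_to_outlets(template, cbind(cc$x[10], cc$y[20]))
  expect_equal(g1$values[20, 10], 0)

  # two outlets: per-cell minimum of the single-outlet grids
  o2 <- cbind(cc$x[40], cc$y[5])
  g2 <- distance_to_outlets(template, o2)
  g12 <- distance_to_outlets(template, rbind(cbind(cc$x[10], cc$y[20]), o2))
  expect_equal(g12$values, pmin(g1$values, g2$values))

  # random outlets vs brute force over all (cell, outlet) pairs
  set.seed(9)
  pts <- cbind(runif(5, 0, 250), runif(5, 0, 250))
  g <- distance_to_outlets(template, pts)
  expect_equal(g$values, distance_oracle(template, pts), tolerance = 1e-10)
  expect_error(distance_to_outlets(template, NULL), "outlet")
})

test_that("outlet distance is 1-Lipschitz across 8-neighbors", {
  template <- rgrid(matrix(0, 30, 30), origin_x = 0, origin_y = 60,
                    cell_size = 2)
  set.seed(14)
  g <- distance_to_outlets(template, cbind(runif(3, 0, 60), runif(3, 0, 60)))
  v <- g$values
  lim <- 2 * sqrt(2) + 1e-9
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    a <- v[2:29, 2:29]
    b <- v[2:29 + di, 2:29 + dj]
    expect_lt(max(abs(a - b)), lim)
  }
})

test_that("openness obeys enclosure, nodata and rotation properties", {
  # 1-cell pond enclosed by land
  land <- matrix(TRUE, 5, 5); land[3, 3] <- FALSE
  ls <- rgrid(land, cell_size = 2, kind = "boolean")
  op <- openness_fetch(ls, n_directions = 16, max_fetch = 100)
  expect_true(is.na(op$values[1, 1]))        # land cell -> nodata
  expect_lte(op$values[3, 3], 2)             # fetch bounded by the enclosure

  # 90-degree rotation invariance for direction counts divisible by 4
  set.seed(3)
  land <- matrix(runif(20 * 20) < 0.4, 20, 20)
  ls <- rgrid(land, cell_size = 5, kind = "boolean")
  op <- openness_fetch(ls, n_directions = 16, max_fetch = 400)
  rot <- function(m) t(m)[, nrow(m):1]       # 90 degrees counterclockwise
  ls_r <- rgrid(rot(land), cell_size = 5, kind = "boolean")
  op_r <- openness_fetch(ls_r, n_directions = 16, max_fetch = 400)
  expect_equal(op_r$values, rot(op$values), tolerance = 1e-9)
})

test_that("channel openness matches an explicit ray-march oracle", {
  # horizontal channel: rows 10..14 water, all else land, 60 columns
  land <- matrix(TRUE, 25, 60)
  land[10:14, ] <- FALSE
  cs <- 2
  ls <- rgrid(land, cell_size = cs, kind = "boolean")
  maxf <- 500
  op <- openness_fetch(ls, n_directions = 16, max_fetch = maxf)
  # oracle: independent fine-step march from the cell center
  oracle_cell <- function(i, j) {
    cx <- j - 0.5; cy <- i - 0.5
    f <- 0
    for (d in 0:15) {
      th <- 2 * pi * d / 16
      dx <- cos(th); dy <- sin(th)
      t <- 0; hit <- maxf / cs
      while (t < maxf / cs) {
        t <- t + 0.01
        x <- cx + t * dx; y <- cy + t * dy
        ci <- floor(y) + 1; cj <- floor(x) + 1
        if (cj < 1 || cj > 60 || ci < 1 || ci > 25) { hit <- maxf / cs; break }
        if (land[ci, cj]) { hit <- t; break }
      }
      f <- f + min(hit, maxf / cs)
    }
    f / 16 * cs
  }
  for (cell in list(c(12, 30), c(10, 25))) {
    expect_lt(abs(op$values[cell[1], cell[2]] - oracle_cell(cell[1], cell[2])),
              cs)
  }
})

test_that("all-land mask warns and returns all nodata", {
  ls <- rgrid(matrix(TRUE, 4, 4), cell_size = 2, kind = "boolean")
  expect_warning(op <- openness_fetch(ls, 8, 100), "all-land")
  expect_true(all(is.na(op$values)))
})

test_that("offshore land-cover extension matches the exhaustive oracle", {
  set.seed(8)
  nr <- 25; nc <- 25
  land <- matrix(FALSE, nr, nc); land[1:10, ] <- TRUE
  land[11, sample(nc, 6)] <- TRUE
  lc <- matrix(NA_real_, nr, nc)
  lc[land] <- sample(c(11, 21, 31), sum(land), replace = TRUE)
  depth <- matrix(-0.5, nr, nc)
  depth[!land] <- (row(depth)[!land] - 10) * 0.4   # deepens southward
  ls <- rgrid(land, cell_size = 5, kind = "boolean")
  lcg <- rgrid(lc, cell_size = 5, origin_y = nr * 5, kind = "categorical")
  bg <- rgrid(depth, cell_size = 5, origin_y = nr * 5, kind = "continuous")
  ext <- extend_landcover(lcg, bg, ls)

  # oracle: exhaustive nearest land cell with smallest-class tie-break
  li <- which(land, arr.ind = TRUE)
  for (idx in which(!land & depth < 3)) {
    i <- (idx - 1) %% nr + 1; j <- (idx - 1) %/% nr + 1
    d2 <- (li[, 1] - i)^2 + (li[, 2] - j)^2
    best <- min(d2)
    cls <- min(lc[li[d2 <= best + 1e-9, , drop = FALSE]])
    expect_equal(ext$landcover$values[i, j], cls)
  }
  # deep water outside the mask and nodata
  expect_true(all(is.na(ext$landcover$values[!land & depth >= 3])))
  expect_false(any(ext$mask$values[!land & depth >= 3]))
  # no class invented
  got <- unique(na.omit(as.vector(ext$landcover$values)))
  expect_true(all(got %in% unique(na.omit(as.vector(lc)))))
  # misaligned grids rejected
  bad <- rgrid(depth[1:10, ], cell_size = 5, kind = "continuous")
  expect_error(extend_landcover(lcg, bad, ls), "aligned")
})

test_that("equidistant land-cover ties go to the smallest class code", {
  # water cell exactly between class 31 (left) and class 11 (right)
  land <- matrix(FALSE, 3, 3); land[2, 1] <- TRUE; land[2, 3] <- TRUE
  lc <- matrix(NA_real_, 3, 3); lc[2, 1] <- 31; lc[2, 3] <- 11
  depth <- matrix(1, 3, 3); depth[land] <- -0.5
  ext <- extend_landcover(rgrid(lc, cell_size = 2, kind = "categorical"),
                          rgrid(depth, cell_size = 2, kind = "continuous"),
                          rgrid(land, cell_size = 2, kind = "boolean"))
  expect_equal(ext$landcover$values[2, 2], 11)
})
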