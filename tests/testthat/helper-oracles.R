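# Independent oracle implementations used across the suite. These deliberately
# re-derive quantities by the most literal method available (brute force,
# enumeration, closed form) and never call the code paths they check.

# crossing-number point-in-polygon (single ring, boundary points may go
# either way; callers avoid boundary-touching centers)
pip_oracle <- function(px, py, ring) {
  n <- nrow(ring)
  out <- logical(length(px))
  for (q in seq_along(px)) {
    x <- px[q]; y <- py[q]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      if ((yi > y) != (yj > y) &&
          x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
      j <- i
    }
    out[q] <- inside
  }
  out
}

# type-7 quantile by explicit sort-and-interpolate indexing
quantile_oracle <- function(v, p) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# random star-shaped (simple) polygon around a center
random_polygon <- function(cx, cy, r_mean, n_vert = 12) {
  th <- sort(runif(n_vert, 0, 2 * pi))
  r <- r_mean * runif(n_vert, 0.4, 1.6)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# regular polygon approximating a circle
circle_polygon <- function(cx, cy, R, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + R * cos(th), cy + R * sin(th))
}

# exhaustive per-(cell, point) minimum distance
distance_oracle <- function(template, pts) {
  cc <- cell_centers(template)
  d <- dim(template$values)
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    dd <- sqrt((cc$x[j] - pts[, 1])^2 + (cc$y[i] - pts[, 2])^2)
    out[i, j] <- min(dd)
  }
  out
}

# sliding-window occupied-neighbor count with nodata/edge exclusion
neighbor_count_oracle <- function(occ, window) {
  h <- (window - 1) / 2
  nr <- nrow(occ); nc <- ncol(occ)
  out <- matrix(NA_real_, nr, nc)
  if (nr < window || nc < window) return(out)
  for (i in (h + 1):(nr - h)) for (j in (h + 1):(nc - h)) {
    w <- occ[(i - h):(i + h), (j - h):(j + h)]
    if (any(is.na(w))) next
    out[i, j] <- sum(w) - occ[i, j]
  }
  out
}

# O(n^2) AUC by pair counting with half credit for ties
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small synthetic sites are reused across test files
.site_cache <- new.env(parent = emptyenv())
cached_site <- function(key, expr) {
  if (!exists(key, .site_cache)) assign(key, force(expr), .site_cache)
  get(key, .site_cache)
}

small_site <- function(seed = 3)
  cached_site(paste0("small", seed),
              make_site(extent = c(500, 500), cell_size = 5, n_outlets = 2,
                        n_classes = 4, seed = seed))

# printed growth-table inputs (areas in ha per site and year)
printed_areas <- function() {
  data.frame(
    site = rep(c("Ruissalo", "Kramppi", "Redamo", "Svartback"),
               times = c(3, 3, 3, 2)),
    year = c(1962, 1982, 1996, 1962, 1977, 1995, 1963, 1982, 1995, 2003, 2006),
    area_ha = c(48.05, 59.78, 69.87, 2.58, 19.36, 17.86, 14.79, 15.05, 20.83,
                226.73, 288.36))
}
printed_totals <- c(Ruissalo = 427.16, Kramppi = 170.51, Redamo = 259.30,
                    Svartback = 1083.70)
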