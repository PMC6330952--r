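# Independent oracles and fixture builders shared across tests.
# These reimplement the checked operations from first principles (explicit
# per-pixel loops, brute-force enumeration) so they share no code with the
# package internals they validate.

# Two-band cube (red @ 680 nm, NIR @ 810 nm) from plain matrices.
toy_cube <- function(nir, red = nir * 0.1, res = 1, crs = "") {
  arr <- array(NA_real_, c(nrow(nir), ncol(nir), 2))
  arr[, , 1] <- red
  arr[, , 2] <- nir
  hyper_cube(arr, c(680, 810), 0, 0, res, crs)
}

# Exhaustive per-pixel moving-window maximum scan.
oracle_seeds <- function(v, ok, w) {
  h <- (w - 1) / 2
  nr <- nrow(v); nc <- ncol(v)
  hits <- NULL
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!ok[r, c]) next
    win_r <- max(1, r - h):min(nr, r + h)
    win_c <- max(1, c - h):min(nc, c + h)
    vals <- v[win_r, win_c][ok[win_r, win_c]]
    if (v[r, c] == max(vals)) hits <- rbind(hits, c(r, c))
  }
  hits
}

# Level-synchronous breadth-first region growth, looping from labeled pixels
# outward; claims are collected per pixel and resolved (nearest seed, then
# lower label) before the next sweep.
oracle_grow <- function(v, seeds, ok, perc, dmax) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  for (s in seq_len(nrow(seeds)))
    lab[seeds$row[s], seeds$col[s]] <- seeds$seed_id[s]
  nbrs <- list(c(0, -1), c(-1, 0), c(0, 1), c(1, 0))
  repeat {
    claims <- list()
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      k <- lab[r, c]
      if (k == 0L) next
      for (d in nbrs) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (lab[r2, c2] != 0L || !ok[r2, c2]) next
        s <- which(seeds$seed_id == k)
        d2 <- (r2 - seeds$row[s])^2 + (c2 - seeds$col[s])^2
        if (d2 >= dmax^2) next
        if (!(v[r2, c2] > seeds$value[s] * perc)) next
        key <- paste(r2, c2)
        claims[[key]] <- rbind(claims[[key]], c(k, d2))
      }
    }
    if (length(claims) == 0) break
    for (key in names(claims)) {
      cl <- claims[[key]]
      cl <- cl[order(cl[, 2], cl[, 1]), , drop = FALSE]
      rc <- as.integer(strsplit(key, " ")[[1]])
      lab[rc[1], rc[2]] <- cl[1, 1]
    }
  }
  lab
}

# Greedy one-to-one assignment by repeated global minimum of the distance
# table (rows = crowns, cols = trees).
oracle_greedy_match <- function(d) {
  pairs <- NULL
  d <- as.matrix(d)
  while (any(is.finite(d))) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, ij)
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  pairs
}

# Grid-sampling approximation of polygon intersection area.
approx_intersection_area <- function(a, b, n = 500) {
  bb <- c(min(a[, 1], b[, 1]), min(a[, 2], b[, 2]),
          max(a[, 1], b[, 1]), max(a[, 2], b[, 2]))
  xs <- seq(bb[1], bb[3], length.out = n)
  ys <- seq(bb[2], bb[4], length.out = n)
  g <- expand.grid(x = xs, y = ys)
  ina <- points_in_polygon(g$x, g$y, a)
  inb <- points_in_polygon(g$x, g$y, b)
  mean(ina & inb) * (bb[3] - bb[1]) * (bb[4] - bb[2])
}

# Random convex polygon: hull of n random points.
random_convex_poly <- function(n = 8, scale = 4, shift = c(0, 0)) {
  repeat {
    p <- convex_hull(stats::runif(n) * scale + shift[1],
                     stats::runif(n) * scale + shift[2])
    if (!is.null(p)) return(p)
  }
}

unit_square <- function(x0 = 0, y0 = 0, s = 1) {
  cbind(x = c(x0, x0 + s, x0 + s, x0), y = c(y0, y0, y0 + s, y0 + s))
}

# Gaussian class fixture in `nb` bands: each class shifts the mean of its
# `informative` bands; other bands are pure noise.
gaussian_band_fixture <- function(n_class = 3, n_px = 60, nb = 6,
                                  informative = list(1, 2, 3),
                                  shift = 0.5, sd = 0.1, seed = 99) {
  set.seed(seed)
  x <- NULL; y <- NULL
  for (k in seq_len(n_class)) {
    m <- matrix(rnorm(n_px * nb, 0, sd), n_px, nb)
    for (b in informative[[((k - 1) %% length(informative)) + 1]])
      m[, b] <- m[, b] + k * shift
    x <- rbind(x, m)
    y <- c(y, rep(paste0("C", k), n_px))
  }
  list(x = x, y = y)
}

# Two radial crowns with distinct apex intensities, close enough that a
# large seed window suppresses the weaker apex.
twin_peak_cube <- function(gap = 6, radius = 3, peaks = c(1, 0.8),
                           size = 20) {
  nir <- matrix(0.02, size, size)
  centers <- list(c(10, 7), c(10, 7 + gap))
  for (i in 1:2) {
    for (r in seq_len(size)) for (c in seq_len(size)) {
      d <- sqrt((r - centers[[i]][1])^2 + (c - centers[[i]][2])^2)
      if (d <= radius)
        nir[r, c] <- max(nir[r, c], peaks[i] * exp(-0.92 * (d / radius)^2))
    }
  }
  cube <- toy_cube(nir, red = matrix(0.01, size, size))
  truth <- crown_set(
    lapply(centers, function(ct) {
      g <- cube_band(cube, 1)
      xy <- canopyseg:::cell_center(g, ct[1], ct[2])
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      cbind(xy[1, "x"] + radius * cos(th), xy[1, "y"] + radius * sin(th))
    }),
    crown_id = 1:2, plot_id = "p1")
  list(cube = cube, truth = truth)
}
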