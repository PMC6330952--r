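# Power-law allometry, gap-filling, CHM heights and crown-stem matching.

test_that("power-law fit recovers exact and degenerate models", {
  x <- c(1, 4, 9, 16)
  m <- fit_power_law(x, 2 * sqrt(x))
  expect_equal(m$a, 2, tolerance = 1e-6)
  expect_equal(m$b, 0.5, tolerance = 1e-6)
  mc <- fit_power_law(c(1, 2, 3, 4), rep(3, 4))  # constant y
  expect_equal(mc$b, 0, tolerance = 1e-6)
  expect_equal(mc$a, 3, tolerance = 1e-6)
  expect_error(fit_power_law(1:2, 1:2), "at least 3")
})

test_that("power-law fit recovers noisy truth within tolerance", {
  d <- make_allometric_sample(1.5, 0.8, noise_sd = 0.05, n = 200, seed = 11)
  m <- fit_power_law(d$x, d$y)
  expect_lt(abs(m$a - 1.5), 0.1)
  expect_lt(abs(m$b - 0.8), 0.05)
  # cross-check against stats::nls on the same data
  ref <- stats::nls(y ~ a * x^b, data = d, start = list(a = 1, b = 1))
  expect_equal(m$a, coef(ref)[["a"]], tolerance = 1e-4)
  expect_equal(m$b, coef(ref)[["b"]], tolerance = 1e-4)
})

test_that("field radius imputation fills only the gaps", {
  mk_trees <- function(r) field_tree_set(data.frame(
    stem_id = seq_along(r), x = 0, y = 0,
    height_m = seq(10, 30, length.out = length(r)),
    dbh_cm = seq(15, 60, length.out = length(r)), crown_radius_m = r))
  h <- seq(10, 30, length.out = 8); d <- seq(15, 60, length.out = 8)
  r_true <- 0.5 * (h * d)^0.4
  full <- mk_trees(r_true)
  expect_identical(impute_field_radius(full)$crown_radius_m,
                   full$crown_radius_m)  # no-op
  holed <- r_true; holed[4] <- NA
  imp <- impute_field_radius(mk_trees(holed))
  expect_equal(imp$crown_radius_m[4], r_true[4], tolerance = 1e-6)
  expect_equal(imp$crown_radius_m[-4], r_true[-4])  # measured untouched
})

test_that("noisy radius imputation stays within 1.5x the generator noise", {
  set.seed(19)
  n <- 100; noise <- 0.3
  h <- runif(n, 8, 32); d <- runif(n, 10, 70)
  r_true <- 0.5 * (h * d)^0.4
  r_meas <- pmax(r_true + rnorm(n, 0, noise), 0.2)
  blank <- sample(n, 30)
  trees <- field_tree_set(data.frame(
    stem_id = 1:n, x = 0, y = 0, height_m = h, dbh_cm = d,
    crown_radius_m = replace(r_meas, blank, NA)))
  imp <- impute_field_radius(trees)
  rmse <- sqrt(mean((imp$crown_radius_m[blank] - r_true[blank])^2))
  expect_lt(rmse, 1.5 * noise)
})

test_that("crown height from CHM is the in-polygon maximum", {
  chm <- raster_grid(matrix(20, 6, 6))
  crown <- unit_square(1, 1, 3)
  expect_equal(itc_height_from_chm(crown, chm), 20)
  # cone peaking at 23 inside the crown
  v <- matrix(0, 6, 6)
  for (r in 1:6) for (c in 1:6)
    v[r, c] <- max(0, 23 - 4 * sqrt((r - 3)^2 + (c - 3)^2))
  chm2 <- raster_grid(v)
  crown2 <- unit_square(0.5, 0.5, 5)
  expect_equal(itc_height_from_chm(crown2, chm2), 23)
  # random fixture: exhaustive pixel scan oracle
  set.seed(41)
  v3 <- matrix(runif(100, 0, 30), 10, 10)
  chm3 <- raster_grid(v3)
  poly <- random_convex_poly(10, scale = 8, shift = c(1, 1))
  inside <- NULL
  for (r in 1:10) for (c in 1:10) {
    xy <- canopyseg:::cell_center(chm3, r, c)
    if (points_in_polygon(xy[1, "x"], xy[1, "y"], poly))
      inside <- c(inside, v3[r, c])
  }
  expect_equal(itc_height_from_chm(poly, chm3), max(inside))
  # no pixel center inside -> NA
  expect_true(is.na(itc_height_from_chm(unit_square(0.6, 0.6, 0.2), chm3)))
})

test_that("crown height imputation mirrors the radius imputation contract", {
  circ <- function(x, r) canopyseg:::circle_polygon(x, 0, r)
  r <- seq(1.5, 5, length.out = 8)
  h_true <- 10 * r^0.5
  cs <- crown_set(lapply(seq_along(r), function(i) circ(20 * i, r[i])),
                  height_m = h_true, radius_m = r)
  expect_identical(impute_itc_height(cs)$height_m, h_true)  # no-op
  holed <- h_true; holed[3] <- NA
  cs2 <- crown_set(lapply(seq_along(r), function(i) circ(20 * i, r[i])),
                   height_m = holed, radius_m = r)
  expect_equal(impute_itc_height(cs2)$height_m[3], h_true[3],
               tolerance = 1e-6)
})

test_that("matching distances follow D = D_pos + D_attr", {
  one <- crown_set(list(unit_square(-0.5, -0.5)), crown_id = 1,
                   height_m = 20, radius_m = 2)
  trees <- field_tree_set(data.frame(
    stem_id = 1:2, x = c(3, 6), y = c(4, 8), height_m = 20, dbh_cm = 30,
    crown_radius_m = 2))
  m <- match_crowns(one, trees)
  expect_equal(m$pairs$stem_id, 1)
  expect_equal(m$pairs$d_pos, 5)       # 3-4-5 triangle
  expect_equal(m$pairs$d_attr, 0)
  expect_equal(m$pairs$d_total, 5)
  # identical crown and tree -> D = 0
  t0 <- field_tree_set(data.frame(stem_id = 1, x = 0, y = 0, height_m = 20,
                                  dbh_cm = 30, crown_radius_m = 2))
  m0 <- match_crowns(one, t0)
  expect_equal(m0$pairs$d_total, 0)
})

test_that("one-to-one matching equals the exhaustive greedy oracle", {
  set.seed(43)
  n <- 10
  itcs <- crown_set(lapply(1:n, function(i)
    unit_square(runif(1, 0, 50), runif(1, 0, 50))),
    crown_id = 1:n, height_m = runif(n, 10, 30),
    radius_m = runif(n, 1, 5))
  trees <- field_tree_set(data.frame(
    stem_id = 1:n, x = runif(n, 0, 50), y = runif(n, 0, 50),
    height_m = runif(n, 10, 30), dbh_cm = runif(n, 10, 60),
    crown_radius_m = runif(n, 1, 5)))
  m <- match_crowns(itcs, trees, mode = "one-to-one")
  # rebuild the 10x10 distance table independently
  ctr <- crown_centroids(itcs)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- sqrt((ctr[i, 1] - trees$x[j])^2 + (ctr[i, 2] - trees$y[j])^2) +
      sqrt((itcs$height_m[i] - trees$height_m[j])^2 +
             (itcs$radius_m[i] - trees$crown_radius_m[j])^2)
  oracle <- oracle_greedy_match(d)
  got <- m$pairs[order(m$pairs$itc_id), ]
  orc <- oracle[order(oracle[, 1]), ]
  expect_equal(got$itc_id, as.numeric(orc[, 1]))
  expect_equal(got$stem_id, as.numeric(orc[, 2]))
  expect_equal(nrow(m$pairs), n)  # a perfect matching
  expect_equal(anyDuplicated(m$pairs$stem_id), 0)
  # stable under row reordering
  m2 <- match_crowns(itcs[sample(n), ], trees[sample(n), ],
                     mode = "one-to-one")
  expect_equal(m2$pairs[order(m2$pairs$itc_id), c("itc_id", "stem_id")],
               got[, c("itc_id", "stem_id")], ignore_attr = TRUE)
})

test_that("nearest-mode matches are local: far trees never interfere", {
  itcs <- crown_set(list(unit_square(0, 0), unit_square(30, 30)),
                    crown_id = 1:2, height_m = c(15, 25),
                    radius_m = c(2, 4))
  trees <- field_tree_set(data.frame(
    stem_id = 1:3, x = c(0.5, 30.5, 100), y = c(0.5, 30.5, 100),
    height_m = c(15, 25, 10), dbh_cm = 30, crown_radius_m = c(2, 4, 1)))
  m1 <- match_crowns(itcs, trees)
  trees$x[3] <- 500  # perturb the unrelated tree
  m2 <- match_crowns(itcs, trees)
  expect_equal(m1$pairs$stem_id, m2$pairs$stem_id)
  expect_equal(m1$pairs$stem_id, c(1, 2))
})

test_that("synthetic stem maps recover their generating crowns", {
  sc <- make_scene(scene_config(seed = 77))
  crowns <- impute_itc_height(measure_crowns(
    delineate(sc$cube, delineation_params()), sc$chm))
  trees <- impute_field_radius(sc$trees)
  m <- match_crowns(crowns, trees, mode = "nearest")
  ok <- 0
  for (r in seq_len(nrow(m$pairs))) {
    i <- which(crowns$crown_id == m$pairs$itc_id[r])
    k <- which(sc$crowns$crown_id == m$pairs$stem_id[r])
    if (points_in_polygon(sc$crowns$apex_x[k], sc$crowns$apex_y[k],
                          crowns$geometry[[i]]))
      ok <- ok + 1
  }
  expect_gte(ok / nrow(m$pairs), 0.95)
})
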