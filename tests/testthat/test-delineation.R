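# NDVI masking, seed detection, region growing, polygonization, tuning.

all_ok_mask <- function(v) raster_grid((v * 0) + 1)

test_that("NDVI mask keeps the boundary value and masks invalid pixels", {
  nir <- matrix(c(0.5, 0.3, 0.4, NA), 2, 2)
  red <- matrix(c(0.1, 0.3, 0.1, 0.2), 2, 2)
  mask <- compute_ndvi_mask(toy_cube(nir, red))
  expect_equal(mask$values[1, 1], 1)  # NDVI = 0.667
  expect_equal(mask$values[2, 1], 0)  # NDVI = 0
  expect_equal(mask$values[1, 2], 1)  # NDVI = 0.6 exactly -> kept
  expect_equal(mask$values[2, 2], 0)  # nodata NIR
  expect_warning(
    compute_ndvi_mask(toy_cube(matrix(0.1, 2, 2), matrix(0.4, 2, 2))),
    "every pixel")
})

test_that("seed detection finds window maxima, honors plateaus and edges", {
  v <- matrix(8, 3, 3); v[2, 2] <- 9
  g <- raster_grid(v)
  s <- detect_seeds(g, all_ok_mask(v), delineation_params(window_px = 3))
  expect_equal(nrow(s), 1)
  expect_equal(c(s$row, s$col, s$value), c(2, 2, 9))
  # constant grid: every unmasked pixel ties the window max
  vc <- matrix(5, 5, 5)
  sc <- detect_seeds(raster_grid(vc), all_ok_mask(vc), delineation_params())
  expect_equal(nrow(sc), 25)
})

test_that("seed detection equals the exhaustive window-max oracle", {
  set.seed(31)
  for (i in 1:20) {
    v <- matrix(runif(400), 20, 20)
    ok <- matrix(runif(400) > 0.2, 20, 20)
    w <- sample(c(3, 5), 1)
    s <- detect_seeds(raster_grid(v), raster_grid(ok + 0),
                      delineation_params(window_px = w))
    oracle <- oracle_seeds(v, ok, w)
    expect_equal(nrow(s), nrow(oracle))
    expect_equal(cbind(s$row, s$col), unname(oracle))
  }
})

test_that("region growth respects the strict distance and intensity rules", {
  # neighbors exactly at seed * perc_thresh: strict '>' blocks growth
  v <- matrix(4, 3, 3); v[2, 2] <- 10
  g <- raster_grid(v)
  p <- delineation_params(perc_thresh = 0.4, dist_max = 4)
  s <- detect_seeds(g, all_ok_mask(v), p)
  lab <- grow_regions(g, s, all_ok_mask(v), p)
  expect_equal(sum(lab$values > 0), 1)
  # dist_max = 1: strict '<' blocks the 4-neighbors at distance exactly 1
  v2 <- matrix(9, 3, 3); v2[2, 2] <- 10
  p2 <- delineation_params(dist_max = 1)
  s2 <- detect_seeds(raster_grid(v2), all_ok_mask(v2), p2)
  lab2 <- grow_regions(raster_grid(v2), s2, all_ok_mask(v2), p2)
  expect_equal(sum(lab2$values > 0), nrow(s2))  # seeds only
})

test_that("region growth equals the independent BFS oracle", {
  # deterministic two-peak fixture at challenge parameters
  tp <- twin_peak_cube()
  band <- cube_band(tp$cube, 2)
  p <- delineation_params(window_px = 3, perc_thresh = 0.4, dist_max = 4)
  mask <- compute_ndvi_mask(tp$cube, p)
  seeds <- detect_seeds(band, mask, p)
  lab <- grow_regions(band, seeds, mask, p)
  oracle <- oracle_grow(band$values, seeds, mask$values > 0, 0.4, 4)
  expect_equal(lab$values, oracle)
  # random scenes
  set.seed(17)
  for (i in 1:15) {
    v <- matrix(runif(400), 20, 20)
    ok <- matrix(runif(400) > 0.15, 20, 20)
    pr <- delineation_params(perc_thresh = runif(1, 0.2, 0.8),
                             dist_max = sample(2:6, 1))
    s <- detect_seeds(raster_grid(v), raster_grid(ok + 0), pr)
    lab <- grow_regions(raster_grid(v), s, raster_grid(ok + 0), pr)
    expect_equal(lab$values,
                 oracle_grow(v, s, ok, pr$perc_thresh, pr$dist_max))
  }
})

test_that("every grown pixel satisfies its region's membership certificate", {
  sc <- make_scene(scene_config(n_crowns = 12, seed = 5))
  p <- delineation_params()
  mask <- compute_ndvi_mask(sc$cube, p)
  band <- cube_band(sc$cube, band_nearest(sc$cube, 810))
  seeds <- detect_seeds(band, mask, p)
  lab <- grow_regions(band, seeds, mask, p)
  expect_lte(length(unique(lab$values[lab$values > 0])), nrow(seeds))
  for (k in seeds$seed_id)  # seeds keep their own label
    expect_equal(lab$values[seeds$row[k], seeds$col[k]], k)
  px <- which(lab$values > 0, arr.ind = TRUE)
  for (j in seq_len(nrow(px))) {
    k <- lab$values[px[j, 1], px[j, 2]]
    d <- sqrt((px[j, 1] - seeds$row[k])^2 + (px[j, 2] - seeds$col[k])^2)
    expect_lt(d, p$dist_max)
    if (d > 0)
      expect_gt(band$values[px[j, 1], px[j, 2]],
                seeds$value[k] * p$perc_thresh)
  }
})

test_that("region growth is invariant to seed enumeration order", {
  tp <- twin_peak_cube(gap = 9)  # regions never compete
  band <- cube_band(tp$cube, 2)
  p <- delineation_params()
  mask <- compute_ndvi_mask(tp$cube, p)
  seeds <- detect_seeds(band, mask, p)
  lab1 <- grow_regions(band, seeds, mask, p)
  lab2 <- grow_regions(band, seeds[rev(seq_len(nrow(seeds))), ], mask, p)
  expect_equal(lab1$values, lab2$values)
})

test_that("polygonization yields hulls of pixel centers with footprint fallback", {
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L            # 2x2 block
  lab[4, 4] <- 2L                # single pixel
  lm <- raster_grid(lab)
  crowns <- regions_to_crowns(lm)
  expect_equal(crown_areas(crowns), c(1, 1), tolerance = 1e-9)
  # L-shaped region: hull equals the brute-force hull of the 5 centers
  lab2 <- matrix(0L, 5, 5)
  lab2[cbind(c(1, 2, 3, 3, 3), c(1, 1, 1, 2, 3))] <- 1L
  cr2 <- regions_to_crowns(raster_grid(lab2))
  ctr <- canopyseg:::cell_center(raster_grid(lab2),
                                 c(1, 2, 3, 3, 3), c(1, 1, 1, 2, 3))
  idx <- grDevices::chull(ctr[, "x"], ctr[, "y"])
  expect_equal(crown_areas(cr2),
               poly_area(ctr[idx, ]), tolerance = 1e-9)
  # collinear 3-pixel region dissolves to a 3 m2 rectangle of footprints
  lab3 <- matrix(0L, 3, 3); lab3[2, ] <- 1L
  expect_equal(crown_areas(regions_to_crowns(raster_grid(lab3))), 3,
               tolerance = 1e-9)
})

test_that("delineation recovers isolated synthetic crowns exactly", {
  sc <- make_scene(scene_config(n_crowns = 5, extent_px = c(60, 60),
                                seed = 21))
  crowns <- delineate(sc$cube, delineation_params())
  expect_equal(nrow(crowns), 5)
  for (i in seq_len(5)) {
    hits <- vapply(crowns$geometry, function(g)
      points_in_polygon(sc$crowns$apex_x[i], sc$crowns$apex_y[i], g),
      logical(1))
    expect_equal(sum(hits), 1)
  }
  # empty scene delineates to an empty crown set
  sc0 <- make_scene(scene_config(n_crowns = 0, extent_px = c(30, 30),
                                 seed = 3))
  expect_warning(cr0 <- delineate(sc0$cube, delineation_params()),
                 "removed every pixel")
  expect_equal(nrow(cr0), 0)
})

test_that("raising perc_thresh never enlarges a crown", {
  sc <- make_scene(scene_config(n_crowns = 8, extent_px = c(80, 80),
                                seed = 13))
  lo <- delineate(sc$cube, delineation_params(perc_thresh = 0.4))
  hi <- delineate(sc$cube, delineation_params(perc_thresh = 0.99))
  common <- intersect(lo$crown_id, hi$crown_id)
  a_lo <- crown_areas(lo)[match(common, lo$crown_id)]
  a_hi <- crown_areas(hi)[match(common, hi$crown_id)]
  expect_true(all(a_hi <= a_lo + 1e-9))
})

test_that("parameter tuning returns the highest two-level Jaccard candidate", {
  tp <- twin_peak_cube()
  grid1 <- data.frame(window_px = 3, perc_thresh = 0.4, dist_max = 4)
  t1 <- tune_parameters(tp$cube, tp$truth, grid1)
  expect_equal(t1$best_params$window_px, 3L)
  grid3 <- data.frame(window_px = c(3, 3, 3),
                      perc_thresh = c(0.4, 0.7, 0.9),
                      dist_max = c(4, 4, 4))
  t3 <- tune_parameters(tp$cube, tp$truth, grid3)
  # exhaustive check
  scores <- vapply(seq_len(3), function(i) {
    p <- delineation_params(grid3$window_px[i], grid3$perc_thresh[i],
                            grid3$dist_max[i])
    score_dataset(tp$truth, delineate(tp$cube, p))$dataset_score
  }, numeric(1))
  expect_equal(t3$best_score, max(scores), tolerance = 1e-12)
  expect_equal(t3$table$score, scores, tolerance = 1e-12)
  # a 7x7 window swallows the weaker of two nearby apices; tuner prefers 3x3
  tw <- tune_parameters(tp$cube, tp$truth,
                        data.frame(window_px = c(3, 7), perc_thresh = 0.4,
                                   dist_max = 4))
  expect_equal(tw$best_params$window_px, 3L)
  expect_error(tune_parameters(tp$cube, tp$truth, data.frame()), "empty")
})
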