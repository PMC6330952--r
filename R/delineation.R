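# Individual tree crown delineation by seeded region growing.
#
# Pipeline: NDVI mask -> near-infrared band selection -> local-maximum seed
# detection in a moving window -> region growing constrained by a distance
# cap (DistMax, pixels) and a fraction of the seed intensity (PercThresh) ->
# convex hull of member pixel centers.
#
# Region growing is level-synchronous: every sweep each region may claim the
# unlabeled, unmasked 4-neighbors of its current pixels that satisfy both
# constraints; a pixel reachable by several regions in the same sweep goes to
# the region whose seed is nearest (ties to the lower seed id), which makes
# the result independent of seed enumeration order.

#' Delineation parameters
#'
#' @param window_px Odd moving-window side (pixels) for seed detection.
#' @param perc_thresh Fraction in (0,1): a pixel joins a region only when its
#'   intensity exceeds `perc_thresh` times the seed intensity.
#' @param dist_max Maximum Euclidean distance (pixels, strict) from a region
#'   pixel to its seed.
#' @param ndvi_threshold Pixels with NDVI below this are masked out.
#' @param ndvi_red_nm,ndvi_nir_nm Wavelengths used to resolve the NDVI bands.
#' @param band_nm Wavelength whose nearest band carries the region growing.
#' @return A `delineation_params` list.
#' @export
delineation_params <- function(window_px = 3, perc_thresh = 0.4, dist_max = 4,
                               ndvi_threshold = 0.6, ndvi_red_nm = 680,
                               ndvi_nir_nm = 800, band_nm = 810) {
  stopifnot(window_px >= 3, window_px %% 2 == 1,
            perc_thresh > 0, perc_thresh < 1, dist_max > 0)
  structure(list(window_px = as.integer(window_px),
                 perc_thresh = perc_thresh, dist_max = dist_max,
                 ndvi_threshold = ndvi_threshold, ndvi_red_nm = ndvi_red_nm,
                 ndvi_nir_nm = ndvi_nir_nm, band_nm = band_nm),
            class = "delineation_params")
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill = NA) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) > 0 && length(cs) > 0)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Vegetation mask from NDVI
#'
#' NDVI = (NIR - RED) / (NIR + RED) on the bands nearest the configured red
#' and near-infrared wavelengths.  A pixel is kept (TRUE) when NDVI is at or
#' above the threshold and both inputs are valid; pixels strictly below the
#' threshold, nodata pixels and zero-denominator pixels are masked.
#'
#' @param cube A `hyper_cube`.
#' @param params A `delineation_params`.
#' @return A `raster_grid` of 0/1 values (1 = vegetated, kept).
#' @export
compute_ndvi_mask <- function(cube, params = delineation_params()) {
  red <- cube$values[, , band_nearest(cube, params$ndvi_red_nm)]
  nir <- cube$values[, , band_nearest(cube, params$ndvi_nir_nm)]
  den <- nir + red
  ndvi <- ifelse(is.na(den) | den == 0, NA, (nir - red) / den)
  keep <- !is.na(ndvi) & ndvi >= params$ndvi_threshold
  if (!any(keep)) warning("NDVI mask removed every pixel")
  raster_grid(keep + 0, cube$xmin, cube$ymin, cube$res, cube$crs, cube$nodata)
}

#' Detect tree-top seeds as moving-window maxima
#'
#' A pixel is a seed when it is unmasked and equals the maximum intensity in
#' the window centered on it; the window is clipped at image edges and masked
#' pixels are excluded from the maximum.  Plateaus yield one seed per tied
#' pixel.  Seeds are numbered 1..N in row-major (row, then column) order.
#'
#' @param band A `raster_grid` of intensities.
#' @param mask A 0/1 `raster_grid` (1 = usable pixel), aligned with `band`.
#' @param params A `delineation_params` (window size).
#' @return A `seed_set` data.frame: seed_id, row, col, value.
#' @export
detect_seeds <- function(band, mask, params = delineation_params()) {
  v <- band$values
  ok <- mask$values > 0 & !is.na(v)
  vv <- ifelse(ok, v, -Inf)
  h <- (params$window_px - 1L) / 2L
  wmax <- matrix(-Inf, nrow(v), ncol(v))
  for (dr in -h:h) for (dc in -h:h)
    wmax <- pmax(wmax, shift_matrix(vv, dr, dc, fill = -Inf))
  is_seed <- ok & vv == wmax & is.finite(vv)
  idx <- which(is_seed, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(seed_id = seq_len(nrow(idx)),
                    row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                    value = v[idx])
  class(out) <- c("seed_set", "data.frame")
  out
}

#' Grow crown regions from seeds
#'
#' Starting from a label map with each seed labeled by its id, regions expand
#' sweep by sweep into unlabeled, unmasked 4-neighbors whose (i) Euclidean
#' pixel distance to the region's seed is strictly below `dist_max` and whose
#' (ii) intensity strictly exceeds `perc_thresh` times the seed intensity.
#' Growth stops when a full sweep adds no pixel.
#'
#' @param band A `raster_grid` of intensities.
#' @param seeds A `seed_set` from [detect_seeds()].
#' @param mask A 0/1 `raster_grid` (1 = usable).
#' @param params A `delineation_params`.
#' @return A `raster_grid` of integer labels (0 = unassigned, k = region of
#'   seed k), with attribute "sweeps" recording the sweep count.
#' @export
grow_regions <- function(band, seeds, mask, params = delineation_params()) {
  v <- band$values
  nr <- nrow(v); nc <- ncol(v)
  valid <- mask$values > 0 & !is.na(v)
  if (nrow(seeds) > 0) {
    seeds <- seeds[order(seeds$seed_id), , drop = FALSE]
    if (!identical(as.integer(seeds$seed_id), seq_len(nrow(seeds))))
      stop("seed_id must be 1..N")
  }
  labels <- matrix(0L, nr, nc)
  if (nrow(seeds) > 0)
    labels[cbind(seeds$row, seeds$col)] <- seeds$seed_id
  srow <- seeds$row; scol <- seeds$col; sval <- seeds$value
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2max <- params$dist_max^2
  dirs <- list(c(0, -1), c(-1, 0), c(0, 1), c(1, 0))
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    best_lab <- matrix(0L, nr, nc)
    best_d2 <- matrix(Inf, nr, nc)
    open <- labels == 0L & valid
    for (d in dirs) {
      nb <- shift_matrix(labels, d[1], d[2], fill = 0L)
      cand <- which(open & nb > 0L)
      if (length(cand) == 0) next
      k <- nb[cand]
      d2 <- (rows[cand] - srow[k])^2 + (cols[cand] - scol[k])^2
      ok <- d2 < d2max & v[cand] > sval[k] * params$perc_thresh
      cand <- cand[ok]; k <- k[ok]; d2 <- d2[ok]
      if (length(cand) == 0) next
      better <- d2 < best_d2[cand] |
        (d2 == best_d2[cand] & k < best_lab[cand])
      cand <- cand[better]; k <- k[better]; d2 <- d2[better]
      best_lab[cand] <- k
      best_d2[cand] <- d2
    }
    claimed <- which(best_lab > 0L)
    if (length(claimed) == 0) break
    labels[claimed] <- best_lab[claimed]
  }
  out <- raster_grid(labels, band$xmin, band$ymin, band$res, band$crs,
                     band$nodata)
  attr(out, "sweeps") <- sweeps
  out
}

# One-pixel footprint square centered on a pixel center (x, y).
pixel_square <- function(x, y, res) {
  h <- res / 2
  cbind(x = c(x - h, x + h, x + h, x - h),
        y = c(y - h, y - h, y + h, y + h))
}

#' Polygonize labeled regions as convex hulls of pixel centers
#'
#' For every region the member pixel centers (map coordinates) are collected
#' and their 2-D convex hull becomes the crown polygon.  Regions whose
#' centers are fewer than 3 or collinear get the dissolved union of their
#' one-pixel footprint squares instead, so every crown has positive area.
#'
#' @param label_map Integer `raster_grid` from [grow_regions()].
#' @return A `crown_set` with crown_id = region label.
#' @export
regions_to_crowns <- function(label_map) {
  labs <- label_map$values
  ids <- sort(unique(labs[labs > 0]))
  if (length(ids) == 0) return(empty_crown_set(label_map$crs))
  geoms <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    px <- which(labs == ids[i], arr.ind = TRUE)
    ctr <- cell_center(label_map, px[, 1], px[, 2])
    hull <- convex_hull(ctr[, "x"], ctr[, "y"])
    if (is.null(hull)) {
      sqs <- lapply(seq_len(nrow(ctr)), function(j)
        pixel_square(ctr[j, "x"], ctr[j, "y"], label_map$res))
      u <- poly_union(sqs)
      # 4-connected regions dissolve to a single ring; keep largest if not
      areas <- vapply(u, poly_area, numeric(1))
      hull <- ring_to_matrix(u[[which.max(areas)]])
    }
    geoms[[i]] <- hull
  }
  crown_set(geoms, crown_id = ids, crs = label_map$crs)
}

#' Delineate individual tree crowns on a hyperspectral cube
#'
#' Runs the full chain: NDVI mask, selection of the band nearest the
#' configured near-infrared wavelength, seed detection, region growing and
#' convex-hull polygonization.  Crown ids equal seed ids.
#'
#' @param cube A `hyper_cube`.
#' @param params A `delineation_params`.
#' @param verbose Log seed/region/sweep counts.
#' @return A `crown_set`.
#' @export
delineate <- function(cube, params = delineation_params(), verbose = FALSE) {
  mask <- compute_ndvi_mask(cube, params)
  band <- cube_band(cube, band_nearest(cube, params$band_nm))
  seeds <- detect_seeds(band, mask, params)
  if (nrow(seeds) == 0) return(empty_crown_set(cube$crs))
  labmap <- grow_regions(band, seeds, mask, params)
  crowns <- regions_to_crowns(labmap)
  if (verbose)
    message(sprintf("delineate: %d seeds, %d regions, %d sweeps",
                    nrow(seeds), nrow(crowns), attr(labmap, "sweeps")))
  crowns
}

#' Tune delineation parameters against reference crowns
#'
#' Supervised grid search: each candidate parameter set is run through
#' [delineate()] and scored with the two-level (crown-within-plot, then
#' across-plot) mean Jaccard of [score_dataset()]; the highest-scoring
#' candidate wins, ties resolving to the earliest row of the grid.
#'
#' @param cube A `hyper_cube`.
#' @param reference A `crown_set` with plot_id set.
#' @param grid Data frame of candidate parameters; columns must be arguments
#'   of [delineation_params()] (e.g. window_px, perc_thresh, dist_max).
#' @return List with `best_params` (a `delineation_params`), `best_score`,
#'   and `table` (the grid with a `score` column).
#' @export
tune_parameters <- function(cube, reference, grid) {
  if (nrow(grid) == 0) stop("empty parameter grid")
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- do.call(delineation_params, as.list(grid[i, , drop = FALSE]))
    pred <- delineate(cube, p)
    scores[i] <- score_dataset(reference, pred)$dataset_score
  }
  best <- which.max(scores)  # first max: ties go to the earliest candidate
  tab <- cbind(grid, score = scores)
  list(best_params = do.call(delineation_params,
                             as.list(grid[best, , drop = FALSE])),
       best_score = scores[best], table = tab)
}
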