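# Synthetic forest scenes with known ground truth.
#
# Emulates the structure the pipeline assumes: a 1 m hyperspectral cube
# whose near-infrared radiance peaks at each tree apex and decays radially,
# NDVI > 0.6 inside crowns and < 0.6 on background, per-species
# multivariate-normal spectra, a conical CHM consistent with crown size, and
# a field-stem table tied to the crowns by known power-law allometries
# (crown radius vs height x diameter; height vs crown radius).

#' Per-species spectral profiles
#'
#' Builds vegetation-shaped mean spectra (green bump, red trough, red edge,
#' near-infrared plateau) that differ between species in plateau level,
#' green-bump strength and red-edge position, so class separation survives
#' sum normalization.  Covariances are diagonal.
#'
#' @param wavelengths_nm Band center wavelengths (nm).
#' @param n_species Number of species (up to 8).
#' @param noise_sd Per-band standard deviation of the Gaussian spectra.
#' @return Named list of species, each with `mean` and `cov`.
#' @export
species_profiles <- function(wavelengths_nm, n_species = 4,
                             noise_sd = 0.0025) {
  stopifnot(n_species >= 1, n_species <= 8)
  nir <- c(0.38, 0.50, 0.42, 0.46, 0.40, 0.48, 0.44, 0.52)
  bump <- c(0.030, 0.060, 0.045, 0.052, 0.058, 0.035, 0.040, 0.048)
  edge <- c(712, 721, 715, 718, 714, 719, 716, 722)
  out <- lapply(seq_len(n_species), function(i) {
    m <- 0.04 + bump[i] * exp(-((wavelengths_nm - 550) / 35)^2) +
      nir[i] * stats::plogis((wavelengths_nm - edge[i]) / 12)
    list(mean = m, cov = diag(noise_sd^2, length(wavelengths_nm)))
  })
  names(out) <- paste0("SP", seq_len(n_species))
  out
}

#' Synthetic scene configuration
#'
#' Defaults describe the study conditions the pipeline targets: a 1 m
#' resolution scene, 25 non-overlapping circular crowns of radius 2-5 m,
#' radially decaying crown radiance reaching about 40% of the apex value at
#' the crown edge, a conical CHM, and power-law allometric truth giving a
#' mean canopy height around 23 m for mid-sized crowns.
#'
#' @param extent_px c(rows, cols) of the scene.
#' @param res Pixel size (m).
#' @param n_crowns Number of crowns to place.
#' @param radius_range c(min, max) crown radius (m).
#' @param wavelengths_nm Band grid (default 50 bands, 400-1000 nm).
#' @param species Species list as from [species_profiles()].
#' @param noise_sd Per-band spectral noise SD (used when `species` is NULL).
#' @param decay Radial decay rate k in exp(-k (d/R)^2); the default 0.92
#'   puts the crown-edge intensity at exp(-0.92) ~ 0.40 of the apex.
#' @param chm_noise_sd CHM noise SD (m).
#' @param jitter_sd Field-stem positional jitter SD (m).
#' @param a_r,b_r Allometric truth R = a_r * (H * D)^b_r (R, H in m; D cm).
#' @param a_h,b_h Allometric truth H = a_h * R^b_h.
#' @param radius_fraction Fraction of field trees with measured crown radius.
#' @param allow_overlap Relax crown spacing so crowns may touch/overlap
#'   (exercises region contention); ground truth stays nearest-apex.
#' @param seed RNG seed; the whole scene is deterministic given the config.
#' @return A `scene_config` list.
#' @export
scene_config <- function(extent_px = c(120, 120), res = 1, n_crowns = 25,
                         radius_range = c(2, 5),
                         wavelengths_nm = seq(400, 1000, length.out = 50),
                         species = NULL, noise_sd = 0.0025, decay = 0.92,
                         chm_noise_sd = 0.3, jitter_sd = 1,
                         a_r = 0.28, b_r = 0.4, a_h = 10.5, b_h = 0.55,
                         radius_fraction = 0.6, allow_overlap = FALSE,
                         seed = 42) {
  if (is.null(species))
    species <- species_profiles(wavelengths_nm, 4, noise_sd)
  stopifnot(all(vapply(species, function(s)
    length(s$mean) == length(wavelengths_nm), logical(1))))
  structure(list(extent_px = extent_px, res = res, n_crowns = n_crowns,
                 radius_range = radius_range,
                 wavelengths_nm = wavelengths_nm, species = species,
                 noise_sd = noise_sd, decay = decay,
                 chm_noise_sd = chm_noise_sd, jitter_sd = jitter_sd,
                 a_r = a_r, b_r = b_r, a_h = a_h, b_h = b_h,
                 radius_fraction = radius_fraction,
                 allow_overlap = allow_overlap, seed = seed),
            class = "scene_config")
}

# Soil-like background spectrum: rises gently with wavelength, NDVI ~ 0.06.
background_mean <- function(wavelengths_nm) {
  0.15 + 0.15 * (wavelengths_nm - 400) / 600
}

# Draw n spectra from a species' multivariate normal.
draw_spectra <- function(sp, n) {
  nb <- length(sp$mean)
  z <- matrix(stats::rnorm(n * nb), n, nb)
  sweep(z %*% chol(sp$cov), 2, sp$mean, "+")
}

#' Draw pure (profile-free) pixel samples per species
#'
#' @param config A `scene_config`.
#' @param n Pixels per species.
#' @param seed RNG seed.
#' @return List with `spectra` matrix and `labels` vector.
#' @export
species_sample <- function(config, n = 500, seed = config$seed) {
  set.seed(seed)
  specs <- lapply(config$species, draw_spectra, n = n)
  list(spectra = do.call(rbind, specs),
       labels = rep(names(config$species), each = n))
}

#' Pairwise Jeffries-Matusita separability implied by a scene config
#'
#' @param config A `scene_config`.
#' @return Symmetric matrix of analytic JM distances between the configured
#'   species distributions.
#' @export
analytic_jm <- function(config) {
  sp <- config$species
  k <- length(sp)
  m <- matrix(0, k, k, dimnames = list(names(sp), names(sp)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    m[i, j] <- m[j, i] <- jm_distance(sp[[i]], sp[[j]], ridge = 0)
  m
}

# Rejection-sample non-overlapping crown centers (pixel-center coordinates).
place_crowns <- function(config) {
  rows <- config$extent_px[1]; cols <- config$extent_px[2]
  rr <- config$radius_range
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  tries <- 0
  while (nrow(centers) < config$n_crowns) {
    tries <- tries + 1
    if (tries > 5000 * config$n_crowns)
      stop("infeasible packing: too many crowns for the extent")
    r <- stats::runif(1, rr[1], rr[2])
    margin <- r / config$res + 1
    prow <- round(stats::runif(1, margin + 1, rows - margin))
    pcol <- round(stats::runif(1, margin + 1, cols - margin))
    if (nrow(centers) > 0) {
      dd <- sqrt((centers[, 1] - prow)^2 + (centers[, 2] - pcol)^2) *
        config$res
      lim <- if (config$allow_overlap) pmax(radii, r) + 1 else
        radii + r + 2
      if (any(dd <= lim)) next
    }
    centers <- rbind(centers, c(prow, pcol))
    radii <- c(radii, r)
  }
  list(row = centers[, 1], col = centers[, 2], radius = radii)
}

circle_polygon <- function(x, y, r, n = 32) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = x + r * cos(th), y = y + r * sin(th))
}

#' Generate a synthetic scene
#'
#' Builds the hyperspectral cube, the CHM, the ground-truth crown set
#' (circles around each apex, with species, true height and radius, and
#' apex coordinates in columns apex_x/apex_y) and the field-tree table
#' (stems at jittered apex positions, diameters consistent with the
#' configured allometric truth, crown radius recorded for a configurable
#' fraction of trees).  The near-infrared maximum of every crown is enforced
#' to lie at its apex pixel, so seed detection at the apex is guaranteed by
#' construction.  Deterministic given `config$seed`.
#'
#' @param config A `scene_config`.
#' @return List: `cube` (hyper_cube), `chm` (raster_grid), `crowns`
#'   (truth crown_set), `trees` (field_tree_set).
#' @export
make_scene <- function(config = scene_config()) {
  set.seed(config$seed)
  rows <- config$extent_px[1]; cols <- config$extent_px[2]
  wl <- config$wavelengths_nm
  nb <- length(wl)
  res <- config$res
  crs <- "local"

  # background cube
  bg <- list(mean = background_mean(wl), cov = diag(config$noise_sd^2, nb))
  cube_vals <- array(draw_spectra(bg, rows * cols), c(rows, cols, nb))
  chm_vals <- matrix(pmax(0, stats::rnorm(rows * cols, 0,
                                          config$chm_noise_sd)), rows, cols)

  geom <- raster_grid(matrix(0, rows, cols), 0, 0, res, crs)
  nir_band <- which.min(abs(wl - 810))

  if (config$n_crowns > 0) {
    pl <- place_crowns(config)
    n <- config$n_crowns
    sp_names <- rep_len(names(config$species), n)
    h_true <- config$a_h * pl$radius^config$b_h *
      exp(stats::rnorm(n, 0, 0.03))
    for (k in seq_len(n)) {
      apex <- cell_center(geom, pl$row[k], pl$col[k])
      rpx <- pl$radius[k] / res
      # member pixels = centers inside the truth polygon, so generation and
      # evaluation agree exactly on the crown footprint
      poly <- circle_polygon(apex[1, "x"], apex[1, "y"], pl$radius[k])
      idx <- pixels_in_polygon(geom, poly)
      d <- sqrt((idx$row - pl$row[k])^2 + (idx$col - pl$col[k])^2)
      profile <- exp(-config$decay * (d / rpx)^2)
      sp <- config$species[[sp_names[k]]]
      spec <- draw_spectra(sp, nrow(idx)) * profile
      # enforce the NIR maximum at the apex pixel (strict, by rescaling)
      at_apex <- d == 0
      apex_nir <- spec[at_apex, nir_band]
      hot <- !at_apex & spec[, nir_band] >= apex_nir
      if (any(hot))
        spec[hot, ] <- spec[hot, ] * (0.995 * apex_nir / spec[hot, nir_band])
      for (j in seq_len(nrow(idx)))
        cube_vals[idx$row[j], idx$col[j], ] <- spec[j, ]
      # conical canopy: apex height tapering to 40% at the crown edge
      chm_vals[cbind(idx$row, idx$col)] <-
        pmax(0, h_true[k] * (1 - 0.6 * d / rpx) +
               stats::rnorm(nrow(idx), 0, config$chm_noise_sd))
      chm_vals[pl$row[k], pl$col[k]] <- h_true[k]
    }
    apex_xy <- cell_center(geom, pl$row, pl$col)
    plot_id <- paste0("p", 1 + (apex_xy[, "x"] > cols * res / 2) +
                        2 * (apex_xy[, "y"] > rows * res / 2))
    crowns <- crown_set(
      lapply(seq_len(n), function(k)
        circle_polygon(apex_xy[k, "x"], apex_xy[k, "y"], pl$radius[k])),
      crown_id = seq_len(n), plot_id = plot_id, species = sp_names,
      height_m = h_true, radius_m = pl$radius, crs = crs)
    crowns$apex_x <- apex_xy[, "x"]
    crowns$apex_y <- apex_xy[, "y"]

    # field stems: jittered apex positions, allometric diameters
    d_cm <- (pl$radius / config$a_r)^(1 / config$b_r) / h_true *
      exp(stats::rnorm(n, 0, 0.02))
    has_r <- stats::runif(n) < config$radius_fraction
    trees <- field_tree_set(data.frame(
      stem_id = seq_len(n),
      x = apex_xy[, "x"] + stats::rnorm(n, 0, config$jitter_sd),
      y = apex_xy[, "y"] + stats::rnorm(n, 0, config$jitter_sd),
      height_m = h_true * exp(stats::rnorm(n, 0, 0.01)),
      dbh_cm = d_cm,
      crown_radius_m = ifelse(has_r, pl$radius, NA_real_)), crs = crs)
  } else {
    crowns <- empty_crown_set(crs)
    trees <- field_tree_set(data.frame(
      stem_id = integer(), x = numeric(), y = numeric(),
      height_m = numeric(), dbh_cm = numeric(),
      crown_radius_m = numeric()), crs = crs)
  }

  list(cube = hyper_cube(cube_vals, wl, 0, 0, res, crs),
       chm = raster_grid(chm_vals, 0, 0, res, crs),
       crowns = crowns, trees = trees)
}

#' Sample (x, y) pairs from a noisy power law
#'
#' x ~ Uniform(x_range), y = a * x^b + Gaussian noise, truncated to stay
#' positive.  Deterministic given `seed`.
#'
#' @param a,b Power-law truth (a > 0).
#' @param noise_sd Additive Gaussian noise SD.
#' @param n Sample size (>= 3).
#' @param seed RNG seed.
#' @param x_range Range of the predictor.
#' @return Data frame with columns x, y.
#' @export
make_allometric_sample <- function(a, b, noise_sd = 0, n = 100, seed = 1,
                                   x_range = c(1, 50)) {
  stopifnot(a > 0, n >= 3)
  set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- pmax(a * x^b + stats::rnorm(n, 0, noise_sd), 1e-6)
  data.frame(x = x, y = y)
}
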