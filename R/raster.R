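# Georeferenced raster containers and text-format I/O.
#
# Grids are stored north-up with square pixels: values[1, 1] is the
# north-west pixel, map X increases with column, map Y decreases with row.
# Pixel (row, col) has its CENTER at
#   X = xmin + (col - 0.5) * res,  Y = ymax - (row - 0.5) * res.
# On-disk format is the ESRI ASCII grid (.asc) with an optional .prj sidecar
# holding the CRS string; hyperspectral cubes are one .asc per band plus a
# `band,wavelength_nm` CSV.

#' Construct a single-band georeferenced grid
#'
#' @param values Numeric matrix (rows = north to south); NA marks nodata.
#' @param xmin,ymin Map coordinates of the lower-left corner (m).
#' @param res Square pixel size (m), strictly positive.
#' @param crs CRS identifier string ("" = unspecified).
#' @param nodata Sentinel written for NA cells on disk.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, res = 1, crs = "",
                        nodata = -9999) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), res > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         crs = crs, nodata = nodata),
    class = "raster_grid")
}

grid_nrow <- function(g) nrow(g$values)
grid_ncol <- function(g) ncol(g$values)
grid_ymax <- function(g) g$ymin + grid_nrow(g) * g$res

# Map coordinates of pixel centers for (row, col) index vectors.
cell_center <- function(g, row, col) {
  cbind(x = g$xmin + (col - 0.5) * g$res,
        y = grid_ymax(g) - (row - 0.5) * g$res)
}

# (row, col) of the pixel containing map point(s); NA outside the grid.
map_to_cell <- function(g, x, y) {
  col <- floor((x - g$xmin) / g$res) + 1L
  row <- floor((grid_ymax(g) - y) / g$res) + 1L
  bad <- col < 1L | col > grid_ncol(g) | row < 1L | row > grid_nrow(g)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d px, res %g m, origin (%g, %g), crs '%s'\n",
              grid_nrow(x), grid_ncol(x), x$res, x$xmin, x$ymin, x$crs))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d nodata px\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Construct a hyperspectral cube
#'
#' @param values 3-D numeric array (rows x cols x bands); NA marks nodata.
#' @param wavelengths_nm Strictly increasing per-band center wavelengths (nm).
#' @inheritParams raster_grid
#' @return A `hyper_cube` object.
#' @export
hyper_cube <- function(values, wavelengths_nm, xmin = 0, ymin = 0, res = 1,
                       crs = "", nodata = -9999) {
  stopifnot(length(dim(values)) == 3)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (dim(values)[3] != length(wavelengths_nm))
    stop("number of bands and wavelengths differ")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(
    list(values = values, wavelengths_nm = wavelengths_nm,
         xmin = xmin, ymin = ymin, res = res, crs = crs, nodata = nodata),
    class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<hyper_cube> %d x %d px, %d bands (%g-%g nm), res %g m, crs '%s'\n",
    d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
    x$res, x$crs))
  invisible(x)
}

#' Extract one band of a cube as a raster grid
#'
#' @param cube A `hyper_cube`.
#' @param band Band index.
#' @return A `raster_grid` sharing the cube's georeferencing.
#' @export
cube_band <- function(cube, band) {
  stopifnot(band >= 1, band <= dim(cube$values)[3])
  raster_grid(cube$values[, , band], cube$xmin, cube$ymin, cube$res,
              cube$crs, cube$nodata)
}

#' Index of the band whose wavelength is nearest a target
#'
#' Ties (two bands equally distant from the target) resolve to the lower
#' wavelength, so results are deterministic on regular wavelength grids.
#'
#' @param cube A `hyper_cube`.
#' @param target_nm Target wavelength in nm.
#' @return Integer band index.
#' @export
band_nearest <- function(cube, target_nm) {
  wl <- cube$wavelengths_nm
  if (length(wl) == 0) stop("cube has no bands")
  d <- abs(wl - target_nm)
  which(d == min(d))[1]  # wavelengths increasing => first hit is the lower one
}

## ---- ESRI ASCII grid I/O ---------------------------------------------------

#' Read a georeferenced raster (ESRI ASCII grid)
#'
#' Reads `path` (.asc); if a sidecar `.prj` file exists its contents become
#' the grid's CRS string.  Cells equal to the header's NODATA_value become NA.
#'
#' @param path Path to an .asc file.
#' @return A `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("not an ESRI ASCII grid: ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- 5 + !is.null(hdr$nodata_value)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header: ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  prj <- sub("\\.asc$", ".prj", path)
  crs <- if (file.exists(prj)) paste(readLines(prj), collapse = "\n") else ""
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs, nodata)
}

#' Write a raster grid as an ESRI ASCII grid
#'
#' @param grid A `raster_grid`.
#' @param path Output .asc path; a `.prj` sidecar is written when the grid
#'   carries a CRS string.
#' @export
write_raster <- function(grid, path) {
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", grid_ncol(grid)),
    sprintf("nrows %d", grid_nrow(grid)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$res),
    sprintf("NODATA_value %.10g", grid$nodata))
  body <- apply(m, 1, function(r) paste(format(r, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  if (nzchar(grid$crs)) writeLines(grid$crs, sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' Read a hyperspectral cube from per-band rasters
#'
#' @param paths Character vector of .asc paths, one per band, in band order.
#' @param wavelengths Either a numeric vector of center wavelengths (nm) or
#'   the path of a CSV with columns `band,wavelength_nm`.
#' @return A `hyper_cube`; all bands must share shape, georeferencing and CRS.
#' @export
read_cube <- function(paths, wavelengths) {
  if (is.character(wavelengths) && length(wavelengths) == 1 &&
      file.exists(wavelengths)) {
    tab <- utils::read.csv(wavelengths)
    if (!all(c("band", "wavelength_nm") %in% names(tab)))
      stop("wavelength CSV needs columns band,wavelength_nm")
    wavelengths <- tab$wavelength_nm[order(tab$band)]
  }
  wavelengths <- as.numeric(wavelengths)
  if (length(paths) != length(wavelengths))
    stop("one path per wavelength required")
  grids <- lapply(paths, read_raster)
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (grid_nrow(g) != grid_nrow(g1) || grid_ncol(g) != grid_ncol(g1) ||
        g$xmin != g1$xmin || g$ymin != g1$ymin || g$res != g1$res)
      stop("cube bands do not share a common grid")
    if (!identical(g$crs, g1$crs))
      stop("cube bands have mismatched CRS")
  }
  arr <- array(NA_real_, c(grid_nrow(g1), grid_ncol(g1), length(grids)))
  for (i in seq_along(grids)) arr[, , i] <- grids[[i]]$values
  hyper_cube(arr, wavelengths, g1$xmin, g1$ymin, g1$res, g1$crs, g1$nodata)
}

#' Write a hyperspectral cube as per-band rasters plus a wavelength CSV
#'
#' @param cube A `hyper_cube`.
#' @param dir Output directory (created if missing); writes
#'   `band_###.asc` files and `wavelengths.csv`.
#' @return Invisibly, the band file paths.
#' @export
write_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nb <- dim(cube$values)[3]
  paths <- file.path(dir, sprintf("band_%03d.asc", seq_len(nb)))
  for (i in seq_len(nb)) write_raster(cube_band(cube, i), paths[i])
  utils::write.csv(
    data.frame(band = seq_len(nb), wavelength_nm = cube$wavelengths_nm),
    file.path(dir, "wavelengths.csv"), row.names = FALSE)
  invisible(paths)
}

# Error unless two layers carry compatible CRS strings (one may be empty).
check_crs <- function(crs_a, crs_b, what = "layers") {
  if (nzchar(crs_a) && nzchar(crs_b) && !identical(crs_a, crs_b))
    stop(sprintf("CRS mismatch between %s: '%s' vs '%s'", what, crs_a, crs_b))
  invisible(TRUE)
}

# (row, col, x, y) of pixels whose centers fall inside a polygon.
pixels_in_polygon <- function(grid, poly) {
  bb <- poly_bbox(poly)
  lo <- map_to_cell(grid, max(bb["xmin"], grid$xmin + grid$res / 2),
                    min(bb["ymax"], grid_ymax(grid) - grid$res / 2))
  hi <- map_to_cell(grid, min(bb["xmax"], grid$xmin + (grid_ncol(grid) - 0.5) * grid$res),
                    max(bb["ymin"], grid$ymin + grid$res / 2))
  if (any(is.na(lo)) || any(is.na(hi)))
    return(data.frame(row = integer(), col = integer(),
                      x = numeric(), y = numeric()))
  rows <- lo[1, "row"]:hi[1, "row"]
  cols <- lo[1, "col"]:hi[1, "col"]
  idx <- expand.grid(row = rows, col = cols)
  ctr <- cell_center(grid, idx$row, idx$col)
  keep <- points_in_polygon(ctr[, "x"], ctr[, "y"], poly)
  data.frame(row = idx$row[keep], col = idx$col[keep],
             x = ctr[keep, "x"], y = ctr[keep, "y"])
}
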