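# Crown polygon sets and field-tree tables.
#
# A crown_set is a data.frame with one row per individual tree crown (ITC):
# columns crown_id, plot_id, species, height_m, radius_m and a `geometry`
# list-column of two-column vertex matrices (open rings, map meters).
# A field_tree_set is a validated data.frame of stem records.

#' Construct a crown set
#'
#' @param geometry List of two-column vertex matrices (x, y), open rings.
#' @param crown_id Unique crown identifiers (default 1..n).
#' @param plot_id,species Optional per-crown attributes (NA when unknown).
#' @param height_m,radius_m Optional crown height and radius (m).
#' @param crs CRS identifier string shared by all crowns.
#' @return A `crown_set` data.frame.
#' @export
crown_set <- function(geometry, crown_id = seq_along(geometry),
                      plot_id = NA, species = NA_character_,
                      height_m = NA_real_, radius_m = NA_real_, crs = "") {
  geometry <- lapply(geometry, function(g) {
    g <- ring_to_matrix(as_ring(g))
    if (nrow(g) < 3) stop("crown polygons need at least 3 vertices")
    g
  })
  if (anyDuplicated(crown_id)) stop("crown_id must be unique")
  df <- data.frame(crown_id = crown_id,
                   plot_id = rep_len(plot_id, length(geometry)),
                   species = rep_len(species, length(geometry)),
                   height_m = rep_len(as.numeric(height_m), length(geometry)),
                   radius_m = rep_len(as.numeric(radius_m), length(geometry)),
                   stringsAsFactors = FALSE)
  df$geometry <- geometry
  attr(df, "crs") <- crs
  class(df) <- c("crown_set", "data.frame")
  df
}

empty_crown_set <- function(crs = "") {
  df <- data.frame(crown_id = integer(), plot_id = character(),
                   species = character(), height_m = numeric(),
                   radius_m = numeric(), stringsAsFactors = FALSE)
  df$geometry <- list()
  attr(df, "crs") <- crs
  class(df) <- c("crown_set", "data.frame")
  df
}

#' @export
print.crown_set <- function(x, ...) {
  cat(sprintf("<crown_set> %d crowns, crs '%s'\n", nrow(x),
              attr(x, "crs") %||% ""))
  if (nrow(x) > 0) {
    a <- crown_areas(x)
    cat(sprintf("  area m2: min %.2f / median %.2f / max %.2f\n",
                min(a), stats::median(a), max(a)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crown polygon areas
#'
#' @param crowns A `crown_set`.
#' @return Numeric vector of areas (m^2), one per crown.
#' @export
crown_areas <- function(crowns) {
  vapply(crowns$geometry, poly_area, numeric(1))
}

#' Crown centroids
#'
#' @param crowns A `crown_set`.
#' @return Two-column matrix (x, y) of polygon centroids.
#' @export
crown_centroids <- function(crowns) {
  t(vapply(crowns$geometry, poly_centroid, numeric(2)))
}

## ---- GeoJSON I/O -----------------------------------------------------------

#' Read crowns from a GeoJSON FeatureCollection
#'
#' Polygon features only (outer rings; holes are not supported).  Recognized
#' properties: crown_id, plot_id, species, height_m, radius_m; a CRS is taken
#' from a top-level `crs` member when present (GeoJSON defaults to none).
#'
#' @param path Path to a .geojson / .json file.
#' @return A `crown_set`.
#' @export
read_crowns <- function(path) {
  if (!file.exists(path)) stop("vector file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection: ", path)
  crs <- ""
  if (!is.null(gj$crs$properties$name)) crs <- gj$crs$properties$name
  feats <- gj$features
  if (length(feats) == 0) return(empty_crown_set(crs))
  prop_vec <- function(key, coerce, default) {
    vapply(feats, function(f) {
      v <- f$properties[[key]]
      if (is.null(v)) default else coerce(v)
    }, default)
  }
  geometry <- lapply(feats, function(f) {
    geom <- f$geometry
    if (!identical(geom$type, "Polygon"))
      stop("only Polygon geometries are supported")
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON closes rings; drop the repeated last vertex
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
  ids <- prop_vec("crown_id", as.character, NA_character_)
  if (anyNA(ids)) ids <- ifelse(is.na(ids), as.character(seq_along(feats)), ids)
  if (!anyNA(suppressWarnings(as.numeric(ids)))) ids <- as.numeric(ids)
  crown_set(
    geometry,
    crown_id = ids,
    plot_id  = prop_vec("plot_id", as.character, NA_character_),
    species  = prop_vec("species", as.character, NA_character_),
    height_m = prop_vec("height_m", as.numeric, NA_real_),
    radius_m = prop_vec("radius_m", as.numeric, NA_real_),
    crs = crs)
}

#' Write crowns to a GeoJSON FeatureCollection
#'
#' @param crowns A `crown_set`.
#' @param path Output path.
#' @export
write_crowns <- function(crowns, path) {
  feat <- lapply(seq_len(nrow(crowns)), function(i) {
    g <- crowns$geometry[[i]]
    ring <- lapply(seq_len(nrow(g) + 1), function(k) {
      k <- if (k > nrow(g)) 1 else k
      c(g[k, 1], g[k, 2])
    })
    props <- list(crown_id = crowns$crown_id[i])
    for (key in c("plot_id", "species", "height_m", "radius_m")) {
      v <- crowns[[key]][i]
      if (!is.na(v)) props[[key]] <- v
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  out <- list(type = "FeatureCollection", features = feat)
  crs <- attr(crowns, "crs") %||% ""
  if (nzchar(crs))
    out$crs <- list(type = "name", properties = list(name = crs))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

## ---- Field trees -----------------------------------------------------------

#' Construct a field-surveyed tree table
#'
#' @param df Data frame with columns stem_id, x, y, height_m, dbh_cm and
#'   optionally crown_radius_m (NA where not measured in the field).
#' @param crs CRS identifier string.
#' @return A validated `field_tree_set` data.frame.
#' @export
field_tree_set <- function(df, crs = "") {
  need <- c("stem_id", "x", "y", "height_m", "dbh_cm")
  if (!all(need %in% names(df)))
    stop("field trees need columns: ", paste(need, collapse = ", "))
  if (!"crown_radius_m" %in% names(df)) df$crown_radius_m <- NA_real_
  if (anyDuplicated(df$stem_id)) stop("stem_id must be unique")
  if (any(!is.na(df$dbh_cm) & df$dbh_cm <= 0))
    stop("stem diameters must be positive")
  if (any(!is.na(df$height_m) & df$height_m <= 0))
    stop("tree heights must be positive")
  if (any(!is.na(df$crown_radius_m) & df$crown_radius_m <= 0))
    stop("crown radii must be positive")
  attr(df, "crs") <- crs
  class(df) <- c("field_tree_set", "data.frame")
  df
}

#' Read field-surveyed trees from CSV
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping the canonical names
#'   (stem_id, x, y, height_m, dbh_cm, crown_radius_m) to the file's
#'   header names; defaults assume canonical headers.
#' @param crs CRS identifier to attach.
#' @return A `field_tree_set`.
#' @export
read_field_trees <- function(path,
                             col_map = c(stem_id = "stem_id", x = "x", y = "y",
                                         height_m = "height_m",
                                         dbh_cm = "dbh_cm",
                                         crown_radius_m = "crown_radius_m"),
                             crs = "") {
  if (!file.exists(path)) stop("tree table not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(stem_id = raw[[col_map[["stem_id"]]]],
                    x = raw[[col_map[["x"]]]],
                    y = raw[[col_map[["y"]]]],
                    height_m = raw[[col_map[["height_m"]]]],
                    dbh_cm = raw[[col_map[["dbh_cm"]]]])
  rcol <- col_map[["crown_radius_m"]]
  out$crown_radius_m <- if (rcol %in% names(raw)) raw[[rcol]] else NA_real_
  field_tree_set(out, crs = crs)
}

#' Write field trees to CSV
#'
#' @param trees A `field_tree_set`.
#' @param path Output CSV path.
#' @export
write_field_trees <- function(trees, path) {
  utils::write.csv(as.data.frame(trees)[, c("stem_id", "x", "y", "height_m",
                                            "dbh_cm", "crown_radius_m")],
                   path, row.names = FALSE)
  invisible(path)
}
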