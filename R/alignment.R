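# Crown-to-stem alignment with allometric gap-filling.
#
# Missing field crown radii are predicted from R = a * (H * D)^b and missing
# crown heights from H = a * R^b, both fitted by nonlinear least squares.
# Each delineated crown is then linked to the field tree minimizing
# D = D_pos + D_attr, the sum of the planimetric Euclidean distance and the
# Euclidean distance in (height, crown radius) space.

#' Fit a power law y = a * x^b by nonlinear least squares
#'
#' Initialized from the ordinary least squares fit of log(y) on log(x) and
#' refined by Levenberg-Marquardt NLS.  If the NLS refinement fails the
#' log-log estimate is returned with `converged = FALSE`.
#'
#' @param x,y Positive numeric vectors (>= 3 points).
#' @return A `power_law_model`: a, b, residual_sse, n_fit, converged.
#' @export
fit_power_law <- function(x, y) {
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("power-law fit needs at least 3 positive points")
  # log-log OLS start
  lf <- stats::lm.fit(cbind(1, log(x)), log(y))
  a0 <- unname(exp(lf$coefficients[1])); b0 <- unname(lf$coefficients[2])
  # constant y has zero log-log slope; keep b0 finite in all cases
  if (!is.finite(a0) || !is.finite(b0)) { a0 <- mean(y); b0 <- 0 }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * x^b, start = list(a = a0, b = b0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("nonlinear refinement failed; returning log-log estimate")
    a <- a0; b <- b0; conv <- FALSE
  } else {
    cf <- stats::coef(fit); a <- cf[["a"]]; b <- cf[["b"]]; conv <- TRUE
  }
  structure(list(a = a, b = b,
                 residual_sse = sum((y - a * x^b)^2),
                 n_fit = length(x), converged = conv),
            class = "power_law_model")
}

#' Predict from a fitted power law
#'
#' @param object A `power_law_model`.
#' @param newdata Numeric vector of x values.
#' @param ... Unused.
#' @return Predicted y.
#' @export
predict.power_law_model <- function(object, newdata, ...) {
  object$a * newdata^object$b
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("<power_law_model> y = %.6g * x^%.6g  (n = %d, SSE = %.3g%s)\n",
              x$a, x$b, x$n_fit, x$residual_sse,
              if (x$converged) "" else ", log-log fallback"))
  invisible(x)
}

#' Impute missing field crown radii from height and stem diameter
#'
#' Fits R = a * (H * D)^b on trees with measured radius, height and diameter
#' and predicts the radius where it is missing.  Measured radii are never
#' overwritten.  Heights are in m and diameters in cm as recorded; the fit
#' absorbs the mixed units into `a`.
#'
#' @param trees A `field_tree_set`.
#' @return The `field_tree_set` with crown_radius_m completed; the fitted
#'   model is attached as attribute "radius_model".
#' @export
impute_field_radius <- function(trees) {
  complete <- !is.na(trees$crown_radius_m) & !is.na(trees$height_m) &
    !is.na(trees$dbh_cm)
  missing <- is.na(trees$crown_radius_m)
  if (!any(missing)) return(trees)
  if (sum(complete) < 3)
    stop("need >= 3 trees with measured radius, height and diameter")
  mod <- fit_power_law(trees$height_m[complete] * trees$dbh_cm[complete],
                       trees$crown_radius_m[complete])
  hd <- trees$height_m[missing] * trees$dbh_cm[missing]
  trees$crown_radius_m[missing] <- predict(mod, hd)
  attr(trees, "radius_model") <- mod
  trees
}

#' Maximum canopy height inside a crown polygon
#'
#' @param crown Two-column vertex matrix of the crown polygon.
#' @param chm A `raster_grid` canopy height model.
#' @return Maximum CHM value among pixels whose centers fall inside the
#'   polygon, or NA when no valid pixel center is inside.
#' @export
itc_height_from_chm <- function(crown, chm) {
  px <- pixels_in_polygon(chm, crown)
  if (nrow(px) == 0) return(NA_real_)
  vals <- chm$values[cbind(px$row, px$col)]
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}

#' Attach CHM-derived heights and equal-area radii to crowns
#'
#' Fills `radius_m` with the radius of the equal-area circle,
#' sqrt(area / pi), and `height_m` with the in-crown CHM maximum where a CHM
#' is given.  Existing values are kept.
#'
#' @param crowns A `crown_set`.
#' @param chm Optional `raster_grid` canopy height model.
#' @return The completed `crown_set`.
#' @export
measure_crowns <- function(crowns, chm = NULL) {
  need_r <- is.na(crowns$radius_m)
  crowns$radius_m[need_r] <- sqrt(crown_areas(crowns)[need_r] / pi)
  if (!is.null(chm)) {
    check_crs(attr(crowns, "crs") %||% "", chm$crs, "crowns and CHM")
    need_h <- is.na(crowns$height_m)
    crowns$height_m[need_h] <- vapply(crowns$geometry[need_h],
                                      itc_height_from_chm, numeric(1),
                                      chm = chm)
  }
  crowns
}

#' Impute missing crown heights from crown radius
#'
#' Fits H = a * R^b on crowns with known height and radius and predicts the
#' missing heights.
#'
#' @param crowns A `crown_set` whose `radius_m` is set (see
#'   [measure_crowns()]).
#' @return The `crown_set` with height_m completed; the fitted model is
#'   attached as attribute "height_model".
#' @export
impute_itc_height <- function(crowns) {
  if (any(is.na(crowns$radius_m)))
    stop("all crowns need radius_m before height imputation")
  complete <- !is.na(crowns$height_m)
  missing <- !complete
  if (!any(missing)) return(crowns)
  if (sum(complete) < 3)
    stop("need >= 3 crowns with known height")
  mod <- fit_power_law(crowns$radius_m[complete], crowns$height_m[complete])
  crowns$height_m[missing] <- predict(mod, crowns$radius_m[missing])
  attr(crowns, "height_model") <- mod
  crowns
}

#' Match delineated crowns to field-surveyed trees
#'
#' For every crown/tree pair the distance is D = D_pos + D_attr with
#' D_pos the planimetric Euclidean distance between the crown centroid and
#' the stem, and D_attr the Euclidean distance between (height, radius)
#' pairs.  In mode "nearest" each crown takes its argmin-D tree (a tree may
#' be claimed by several crowns); in mode "one-to-one" pairs are accepted
#' greedily in ascending D with every crown and tree used at most once.
#'
#' @param itcs A `crown_set` with height_m and radius_m set.
#' @param trees A `field_tree_set` with height_m and crown_radius_m set.
#' @param mode "nearest" (default) or "one-to-one".
#' @param max_distance Optional cap: pairs with D above it are rejected
#'   (off by default).
#' @return A `match_result`: `pairs` (itc_id, stem_id, d_pos, d_attr,
#'   d_total), `unmatched_itcs`, `unmatched_trees`.
#' @export
match_crowns <- function(itcs, trees, mode = c("nearest", "one-to-one"),
                         max_distance = Inf) {
  mode <- match.arg(mode)
  if (nrow(itcs) == 0 || nrow(trees) == 0) stop("empty crowns or trees")
  if (any(is.na(itcs$height_m)) || any(is.na(itcs$radius_m)))
    stop("crowns must carry height_m and radius_m (impute first)")
  if (any(is.na(trees$height_m)) || any(is.na(trees$crown_radius_m)))
    stop("trees must carry height_m and crown_radius_m (impute first)")
  ctr <- crown_centroids(itcs)
  d_pos <- outer(ctr[, 1], trees$x, "-")^2 + outer(ctr[, 2], trees$y, "-")^2
  d_pos <- sqrt(d_pos)
  d_attr <- sqrt(outer(itcs$height_m, trees$height_m, "-")^2 +
                   outer(itcs$radius_m, trees$crown_radius_m, "-")^2)
  d <- d_pos + d_attr
  pairs <- NULL
  if (mode == "nearest") {
    j <- apply(d, 1, which.min)
    keep <- d[cbind(seq_len(nrow(itcs)), j)] <= max_distance
    pairs <- data.frame(itc_id = itcs$crown_id[keep],
                        stem_id = trees$stem_id[j[keep]],
                        d_pos = d_pos[cbind(which(keep), j[keep])],
                        d_attr = d_attr[cbind(which(keep), j[keep])],
                        d_total = d[cbind(which(keep), j[keep])])
  } else {
    ord <- order(d)  # ascending D; ties resolve in column-major index order
    used_i <- rep(FALSE, nrow(itcs)); used_j <- rep(FALSE, nrow(trees))
    rows <- list()
    for (lin in ord) {
      if (d[lin] > max_distance) break
      i <- (lin - 1) %% nrow(d) + 1
      j <- (lin - 1) %/% nrow(d) + 1
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      rows[[length(rows) + 1]] <-
        data.frame(itc_id = itcs$crown_id[i], stem_id = trees$stem_id[j],
                   d_pos = d_pos[i, j], d_attr = d_attr[i, j],
                   d_total = d[i, j])
    }
    pairs <- if (length(rows)) do.call(rbind, rows) else
      data.frame(itc_id = itcs$crown_id[0], stem_id = trees$stem_id[0],
                 d_pos = numeric(), d_attr = numeric(), d_total = numeric())
  }
  structure(list(
    pairs = pairs,
    unmatched_itcs = setdiff(itcs$crown_id, pairs$itc_id),
    unmatched_trees = setdiff(trees$stem_id, pairs$stem_id)),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs, %d unmatched crowns, %d unmatched trees\n",
              nrow(x$pairs), length(x$unmatched_itcs),
              length(x$unmatched_trees)))
  invisible(x)
}
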