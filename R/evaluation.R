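# Delineation scoring: per-crown Jaccard with best-overlap matching,
# two-level plot averaging, and the area-based overall confusion matrix.

#' Score a delineation against reference crowns
#'
#' For every reference crown the Jaccard overlap with each intersecting
#' predicted crown is computed and only the best is kept (0 when nothing
#' overlaps; a predicted crown may be the best match of several references).
#' The plot score is the mean over the plot's reference crowns and the
#' dataset score is the mean over plot scores — a two-level mean, not a flat
#' mean over crowns.
#'
#' @param reference A `crown_set` carrying plot_id.
#' @param predicted A `crown_set`.
#' @return List with `per_crown` (reference_id, plot_id, best_predicted_id,
#'   jaccard), `per_plot` (plot_id, score, n_crowns) and `dataset_score`.
#' @export
score_dataset <- function(reference, predicted) {
  check_crs(attr(reference, "crs") %||% "", attr(predicted, "crs") %||% "",
            "reference and predicted crowns")
  if (nrow(reference) == 0) stop("no reference crowns to score")
  pred_bb <- lapply(predicted$geometry, poly_bbox)
  per <- data.frame(reference_id = reference$crown_id,
                    plot_id = as.character(reference$plot_id),
                    best_predicted_id = NA,
                    jaccard = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(reference))) {
    g <- reference$geometry[[i]]
    bb <- poly_bbox(g)
    best_j <- 0; best_id <- NA
    for (j in seq_len(nrow(predicted))) {
      if (!bbox_overlaps(bb, pred_bb[[j]])) next
      jc <- jaccard(g, predicted$geometry[[j]])
      if (jc > best_j) { best_j <- jc; best_id <- predicted$crown_id[j] }
    }
    per$jaccard[i] <- best_j
    per$best_predicted_id[i] <- best_id
  }
  keep <- !is.na(per$plot_id)
  if (!all(keep))
    warning(sum(!keep), " reference crown(s) without plot_id excluded ",
            "from plot averaging")
  plots <- split(per$jaccard[keep], per$plot_id[keep])
  per_plot <- data.frame(plot_id = names(plots),
                         score = vapply(plots, mean, numeric(1)),
                         n_crowns = vapply(plots, length, integer(1)),
                         row.names = NULL, stringsAsFactors = FALSE)
  list(per_crown = per, per_plot = per_plot,
       dataset_score = mean(per_plot$score))
}

#' Area-based overall confusion matrix
#'
#' Accounts crown area in m^2 on dissolved (self-unioned) reference and
#' predicted sets: `ref_covered` is the reference area intersected by
#' predictions, `ref_missed` the reference area with no prediction cover,
#' and `pred_excess` the predicted area outside all references.  The
#' challenge's bar-chart report labels these TruePositive, FalsePositive and
#' FalseNegative respectively; those (non-standard) labels are used only in
#' report mode, the fields keep neutral names.
#'
#' @param reference,predicted `crown_set`s in the same CRS.
#' @param by_plot Also return a per-plot breakdown (reference plot_id; a
#'   predicted crown contributes to the plot of the reference it overlaps
#'   most, unassigned predictions to plot NA).
#' @return List with `ref_covered_m2`, `ref_missed_m2`, `pred_excess_m2`,
#'   `ref_area_m2`, `pred_area_m2` and, when `by_plot`, a `per_plot` data
#'   frame of the same cells.
#' @export
area_confusion <- function(reference, predicted, by_plot = FALSE) {
  check_crs(attr(reference, "crs") %||% "", attr(predicted, "crs") %||% "",
            "reference and predicted crowns")
  cells <- function(ref_geoms, pred_geoms) {
    ra <- union_area(ref_geoms)
    pa <- union_area(pred_geoms)
    tp <- union_intersection_area(ref_geoms, pred_geoms)
    c(ref_covered_m2 = tp, ref_missed_m2 = ra - tp, pred_excess_m2 = pa - tp,
      ref_area_m2 = ra, pred_area_m2 = pa)
  }
  out <- as.list(cells(reference$geometry, predicted$geometry))
  if (by_plot) {
    # assign each predicted crown to the plot of its best-overlap reference
    pred_plot <- rep(NA_character_, nrow(predicted))
    for (j in seq_len(nrow(predicted))) {
      ints <- vapply(reference$geometry, poly_intersection_area,
                     numeric(1), b = predicted$geometry[[j]])
      if (any(ints > 0))
        pred_plot[j] <- as.character(reference$plot_id[which.max(ints)])
    }
    plots <- sort(unique(as.character(reference$plot_id)))
    rows <- lapply(plots, function(p) {
      cells(reference$geometry[as.character(reference$plot_id) %in% p],
            predicted$geometry[pred_plot %in% p])
    })
    out$per_plot <- cbind(data.frame(plot_id = plots,
                                     stringsAsFactors = FALSE),
                          do.call(rbind, rows))
  }
  out
}

#' Report an area confusion matrix with challenge-style labels
#'
#' @param ac Result of [area_confusion()].
#' @return Named numeric vector using the challenge report labels
#'   (TruePositive = reference area covered, FalsePositive = reference area
#'   missed, FalseNegative = predicted excess area).
#' @export
format_area_confusion <- function(ac) {
  c(TruePositive = ac$ref_covered_m2,
    FalsePositive = ac$ref_missed_m2,
    FalseNegative = ac$pred_excess_m2)
}

#' Bar chart of the per-plot area confusion matrix
#'
#' @param ac Result of `area_confusion(..., by_plot = TRUE)`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_area_confusion <- function(ac, ...) {
  if (is.null(ac$per_plot)) stop("run area_confusion with by_plot = TRUE")
  m <- t(as.matrix(ac$per_plot[, c("ref_covered_m2", "ref_missed_m2",
                                   "pred_excess_m2")]))
  rownames(m) <- c("TruePositive", "FalsePositive", "FalseNegative")
  graphics::barplot(m, names.arg = ac$per_plot$plot_id, beside = TRUE,
                    legend.text = rownames(m), ylab = "area (m2)",
                    xlab = "plot", ...)
  invisible(m)
}

#' Mean Jaccard score by reference crown-area bin
#'
#' @param scores Result of [score_dataset()] (its `per_crown` element is
#'   used), or a data frame with columns reference_id and jaccard.
#' @param reference The `crown_set` the scores refer to.
#' @param bin_edges_m2 Increasing numeric vector of bin edges covering the
#'   observed crown areas; bins are left-closed, right-open except the last.
#' @return Data frame bin_low, bin_high, n, mean_jaccard (NA for empty bins).
#' @export
score_by_area_bins <- function(scores, reference, bin_edges_m2) {
  per <- if (is.data.frame(scores)) scores else scores$per_crown
  areas <- crown_areas(reference)[match(per$reference_id,
                                        reference$crown_id)]
  if (any(areas < min(bin_edges_m2) | areas > max(bin_edges_m2)))
    stop("bin edges do not cover the observed crown areas")
  bin <- findInterval(areas, bin_edges_m2, rightmost.closed = TRUE)
  nb <- length(bin_edges_m2) - 1
  out <- data.frame(bin_low = bin_edges_m2[-length(bin_edges_m2)],
                    bin_high = bin_edges_m2[-1],
                    n = 0L, mean_jaccard = NA_real_)
  for (b in seq_len(nb)) {
    sel <- bin == b
    out$n[b] <- sum(sel)
    if (any(sel)) out$mean_jaccard[b] <- mean(per$jaccard[sel])
  }
  out
}
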