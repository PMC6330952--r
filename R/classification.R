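# Pixel-level tree species classification with crown-level aggregation.
#
# Steps: per-pixel sum normalization of the spectra, SFFS band selection
# under the Jeffries-Matusita (JM) separability criterion, an RBF support
# vector machine on the selected bands plus the crown's canopy height, and a
# majority vote per crown.  Accuracy metrics follow standard remote-sensing
# usage: overall accuracy, Cohen's kappa, producer's/user's accuracy per
# class and the unweighted mean of producer's accuracies.

#' Classification configuration
#'
#' @param max_features Number of bands SFFS must select.
#' @param criterion "mean" (default) or "min" pairwise JM across class pairs.
#' @param cost Candidate SVM cost values for cross-validation.
#' @param gamma_scale RBF kernel widths, as multiples of 1/n_features.
#' @param folds Cross-validation folds.
#' @param seed RNG seed for fold assignment (and any stochastic SVM step).
#' @return A `classify_config` list.
#' @export
classify_config <- function(max_features = 40, criterion = c("mean", "min"),
                            cost = c(1, 10, 100),
                            gamma_scale = c(0.1, 1, 10),
                            folds = 5, seed = 1234) {
  list(max_features = max_features, criterion = match.arg(criterion),
       cost = cost, gamma_scale = gamma_scale, folds = folds, seed = seed)
}

#' Sum-normalize pixel spectra
#'
#' Divides every pixel (row) by the sum of its values across all bands, so
#' each row sums to 1 and between-image brightness differences cancel while
#' the spectral shape is preserved.  All-zero rows cannot be normalized and
#' are dropped with a warning.
#'
#' @param spectra Numeric matrix, rows = pixels, cols = bands.
#' @return The normalized matrix; attribute "dropped" lists removed rows.
#' @export
normalize_pixels <- function(spectra) {
  spectra <- as.matrix(spectra)
  s <- rowSums(spectra)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    warning(sum(bad), " all-zero/invalid pixel row(s) dropped")
    spectra <- spectra[!bad, , drop = FALSE]
    s <- s[!bad]
  }
  out <- spectra / s
  attr(out, "dropped") <- which(bad)
  out
}

#' Per-class Gaussian statistics
#'
#' @param features Numeric matrix, rows = pixels.
#' @param labels Class label per row.
#' @param min_count Classes with fewer pixels are excluded (with a warning).
#' @return A `class_stats` list: per class `mean`, `cov`, `count`.
#' @export
class_stats <- function(features, labels, min_count = 2) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  counts <- table(labels)
  small <- names(counts)[counts < min_count]
  if (length(small) > 0)
    warning("class(es) with < ", min_count, " pixels excluded: ",
            paste(small, collapse = ", "))
  keep <- setdiff(names(counts), small)
  out <- lapply(keep, function(cl) {
    x <- features[labels == cl, , drop = FALSE]
    list(mean = colMeans(x), cov = stats::cov(x), count = nrow(x))
  })
  names(out) <- keep
  structure(out, class = "class_stats")
}

# log-determinant via Cholesky; ridge keeps covariances invertible
logdet <- function(m) 2 * sum(log(diag(chol(m))))

ridge_cov <- function(m, ridge = 1e-6) m + diag(ridge, nrow(m))

#' Jeffries-Matusita distance between two Gaussian classes
#'
#' JM = 2 (1 - exp(-B)) with Bhattacharyya distance
#' B = 1/8 (mu_i - mu_j)' M^-1 (mu_i - mu_j)
#'   + 1/2 ln( |M| / sqrt(|S_i| |S_j|) ),  M = (S_i + S_j) / 2.
#' Bounded in \[0, 2\]; 0 for identical distributions, 2 in the limit of
#' complete separation.  Covariances get a 1e-6 diagonal ridge so singular
#' sample covariances stay invertible.
#'
#' @param stats_i,stats_j Entries of a [class_stats()] object (list with
#'   `mean` and `cov`).
#' @param ridge Diagonal regularization added to each covariance.
#' @return JM separability in \[0, 2\].
#' @export
jm_distance <- function(stats_i, stats_j, ridge = 1e-6) {
  si <- ridge_cov(as.matrix(stats_i$cov), ridge)
  sj <- ridge_cov(as.matrix(stats_j$cov), ridge)
  m <- (si + sj) / 2
  dm <- stats_i$mean - stats_j$mean
  b <- c(crossprod(dm, solve(m, dm))) / 8 +
    (logdet(m) - (logdet(si) + logdet(sj)) / 2) / 2
  2 * (1 - exp(-max(b, 0)))
}

# Separability criterion on a band subset: mean (or min) pairwise JM.
jm_criterion <- function(stats, subset, criterion = "mean", ridge = 1e-6) {
  cls <- names(stats)
  if (length(cls) < 2) stop("JM criterion needs >= 2 classes")
  prs <- utils::combn(length(cls), 2)
  vals <- apply(prs, 2, function(p) {
    a <- stats[[p[1]]]; b <- stats[[p[2]]]
    jm_distance(list(mean = a$mean[subset],
                     cov = a$cov[subset, subset, drop = FALSE]),
                list(mean = b$mean[subset],
                     cov = b$cov[subset, subset, drop = FALSE]),
                ridge = ridge)
  })
  if (criterion == "min") min(vals) else mean(vals)
}

#' Sequential forward floating selection of bands
#'
#' Classic SFFS: greedily add the band that maximizes the JM criterion, then
#' conditionally remove bands while a removal improves on the best known
#' criterion at the smaller size.  The criterion is the mean (or min)
#' pairwise JM over all class pairs, computed from Gaussian class statistics
#' of the candidate subset.
#'
#' @param features Numeric matrix, rows = pixels, cols = bands.
#' @param labels Class label per pixel (>= 2 classes with >= 2 pixels).
#' @param max_features Target subset size.
#' @param criterion "mean" or "min" pairwise JM.
#' @param ridge Covariance regularization.
#' @return List with `selected` (band indices, best subset of size
#'   `max_features`), and `trace`, a data frame of the best subset and
#'   criterion at every size up to `max_features`.
#' @export
sffs_select <- function(features, labels, max_features,
                        criterion = c("mean", "min"), ridge = 1e-6) {
  criterion <- match.arg(criterion)
  features <- as.matrix(features)
  nb <- ncol(features)
  max_features <- min(max_features, nb)
  stats <- class_stats(features, labels)
  if (length(stats) < 2) stop("need >= 2 classes with >= 2 pixels each")
  crit <- function(s) jm_criterion(stats, s, criterion, ridge)
  best_set <- vector("list", max_features)   # best subset found at each size
  best_val <- rep(-Inf, max_features)
  cur <- integer(0)
  guard <- 0
  while (length(cur) < max_features && (guard <- guard + 1) < 100 * nb) {
    # forward step
    cand <- setdiff(seq_len(nb), cur)
    vals <- vapply(cand, function(b) crit(c(cur, b)), numeric(1))
    cur <- c(cur, cand[which.max(vals)])
    v <- max(vals)
    k <- length(cur)
    if (v > best_val[k]) { best_val[k] <- v; best_set[[k]] <- cur }
    # conditional backward steps
    while (length(cur) > 2) {
      k <- length(cur)
      drops <- vapply(seq_along(cur), function(i) crit(cur[-i]), numeric(1))
      i <- which.max(drops)
      if (drops[i] > best_val[k - 1]) {
        cur <- cur[-i]
        best_val[k - 1] <- drops[i]
        best_set[[k - 1]] <- cur
      } else break
    }
  }
  trace <- data.frame(size = seq_len(max_features),
                      criterion = best_val[seq_len(max_features)])
  trace$bands <- best_set[seq_len(max_features)]
  list(selected = sort(best_set[[max_features]]), trace = trace)
}

# Seeded fold assignment, stratified by class where possible.
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  folds <- integer(n)
  set.seed(seed)
  counts <- table(labels)
  if (any(counts < k)) {
    if (any(counts < 2))
      warning("class with a single pixel: folds are not stratified")
    return(sample(rep_len(seq_len(k), n)))
  }
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Train an RBF SVM on pixels and predict test pixels
#'
#' Features are z-scored with training statistics; cost and kernel width are
#' chosen by seeded k-fold cross-validation on the training pixels; the best
#' pair (ties to the earlier grid entry) is refit on all training pixels.
#'
#' @param train_features,train_labels Training pixels and labels.
#' @param test_features Pixels to predict.
#' @param config A [classify_config()].
#' @return Character vector of predicted labels, one per test row, with the
#'   chosen (cost, sigma) and CV table in attribute "tuning".
#' @export
train_and_predict <- function(train_features, train_labels, test_features,
                              config = classify_config()) {
  x <- as.matrix(train_features)
  xt <- as.matrix(test_features)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  x <- sweep(sweep(x, 2, mu), 2, sd, "/")
  xt <- sweep(sweep(xt, 2, mu), 2, sd, "/")
  y <- factor(train_labels)
  if (nlevels(y) < 2) stop("need >= 2 classes to train")
  sigmas <- config$gamma_scale / ncol(x)
  grid <- expand.grid(cost = config$cost, sigma = sigmas,
                      KEEP.OUT.ATTRS = FALSE)
  folds <- make_folds(as.character(y), config$folds, config$seed)
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      set.seed(config$seed)
      m <- kernlab::ksvm(x[tr, , drop = FALSE], y[tr], type = "C-svc",
                         kernel = "rbfdot",
                         kpar = list(sigma = grid$sigma[g]),
                         C = grid$cost[g], scaled = FALSE)
      p <- kernlab::predict(m, x[!tr, , drop = FALSE])
      correct <- correct + sum(p == y[!tr])
    }
    cv_acc[g] <- correct / length(y)
  }
  best <- which.max(cv_acc)
  set.seed(config$seed)
  model <- kernlab::ksvm(x, y, type = "C-svc", kernel = "rbfdot",
                         kpar = list(sigma = grid$sigma[best]),
                         C = grid$cost[best], scaled = FALSE)
  pred <- as.character(kernlab::predict(model, xt))
  attr(pred, "tuning") <- list(best = grid[best, ],
                               table = cbind(grid, cv_accuracy = cv_acc))
  pred
}

#' Aggregate pixel labels to one species per crown
#'
#' Majority vote over a crown's pixels.  Ties resolve to the class with the
#' larger training sample (when `train_counts` is given), then
#' alphabetically.
#'
#' @param pixel_labels Predicted label per pixel.
#' @param crown_ids Crown id per pixel.
#' @param train_counts Optional named vector of training sample counts used
#'   for tie-breaking.
#' @return Data frame crown_id, species.
#' @export
aggregate_majority <- function(pixel_labels, crown_ids, train_counts = NULL) {
  stopifnot(length(pixel_labels) == length(crown_ids))
  ids <- unique(crown_ids)
  species <- vapply(ids, function(id) {
    tab <- table(pixel_labels[crown_ids == id])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1 && !is.null(train_counts)) {
      tc <- train_counts[top]
      tc[is.na(tc)] <- 0
      top <- top[tc == max(tc)]
    }
    sort(top)[1]
  }, character(1))
  data.frame(crown_id = ids, species = species, stringsAsFactors = FALSE)
}

#' Build a confusion matrix (rows = predicted, columns = reference)
#'
#' @param predicted,reference Label vectors of equal length.
#' @param classes Class ordering; default = sorted union of labels.
#' @return Square integer matrix with dimnames.
#' @export
confusion_matrix <- function(predicted, reference,
                             classes = sort(union(predicted, reference))) {
  m <- table(factor(predicted, levels = classes),
             factor(reference, levels = classes))
  out <- matrix(as.integer(m), nrow = length(classes),
                dimnames = list(predicted = classes, reference = classes))
  out
}

#' Accuracy metrics of a confusion matrix
#'
#' With rows = predicted and columns = reference: overall accuracy is the
#' diagonal fraction; producer's accuracy of a class is its diagonal count
#' over the column total (recall), user's accuracy over the row total
#' (precision); mean class accuracy is the unweighted mean of producer's
#' accuracies over classes that occur in the reference; kappa is the
#' chance-corrected agreement.  All in percent, unrounded.
#'
#' @param cm Square count matrix, rows = predicted, columns = reference.
#' @return List: overall_accuracy, kappa, mean_class_accuracy, producers,
#'   users (named per class; NaN where the denominator is zero), n.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), sum(cm) >= 1, all(cm >= 0))
  total <- sum(cm)
  diagv <- diag(cm)
  rowt <- rowSums(cm)
  colt <- colSums(cm)
  oa <- sum(diagv) / total
  pe <- sum(rowt * colt) / total^2
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else NaN
  producers <- ifelse(colt > 0, diagv / colt, NaN) * 100
  users <- ifelse(rowt > 0, diagv / rowt, NaN) * 100
  mca <- mean(producers[colt > 0])
  list(overall_accuracy = 100 * oa, kappa = 100 * kappa,
       mean_class_accuracy = mca,
       producers = stats::setNames(producers, colnames(cm)),
       users = stats::setNames(users, rownames(cm)), n = total)
}

#' Extract crown pixels from a hyperspectral cube
#'
#' @param cube A `hyper_cube`.
#' @param crowns A `crown_set`.
#' @return List with `spectra` (pixels x bands), and `info` data frame
#'   (crown_id, plot_id, species, row, col); crowns containing no pixel
#'   center are dropped with a warning.
#' @export
extract_crown_pixels <- function(cube, crowns) {
  check_crs(cube$crs, attr(crowns, "crs") %||% "", "cube and crowns")
  ref <- cube_band(cube, 1)
  rows <- list(); specs <- list()
  empty <- character(0)
  for (i in seq_len(nrow(crowns))) {
    px <- pixels_in_polygon(ref, crowns$geometry[[i]])
    if (nrow(px) == 0) {
      empty <- c(empty, as.character(crowns$crown_id[i]))
      next
    }
    sp <- t(vapply(seq_len(nrow(px)),
                   function(j) cube$values[px$row[j], px$col[j], ],
                   numeric(dim(cube$values)[3])))
    specs[[length(specs) + 1]] <- sp
    rows[[length(rows) + 1]] <- data.frame(
      crown_id = crowns$crown_id[i], plot_id = crowns$plot_id[i],
      species = crowns$species[i], row = px$row, col = px$col,
      stringsAsFactors = FALSE)
  }
  if (length(empty) > 0)
    warning("crown(s) with no pixel center inside, excluded: ",
            paste(empty, collapse = ", "))
  if (length(specs) == 0) stop("no crown contains a pixel center")
  list(spectra = do.call(rbind, specs), info = do.call(rbind, rows))
}

#' Classify crown species end to end
#'
#' Extracts pixels inside the crown polygons, sum-normalizes the spectra,
#' selects bands by SFFS + JM on the training pixels, appends the crown's
#' maximum canopy height (replicated to its pixels) when a CHM is given,
#' trains the SVM, predicts test pixels, aggregates with the majority rule
#' and, when test species are known, reports the confusion matrix and its
#' metrics.
#'
#' @param cube A `hyper_cube`.
#' @param chm Optional `raster_grid` canopy height model.
#' @param train_crowns A `crown_set` with species (>= 2 classes).
#' @param test_crowns A `crown_set` (species optional; used for scoring).
#' @param config A [classify_config()].
#' @return List: `predictions` (crown_id, species), `selected_bands`,
#'   `band_trace`, `pixel_labels`, and `confusion` + `metrics` when test
#'   species are known.
#' @export
classify_crowns <- function(cube, chm = NULL, train_crowns, test_crowns,
                            config = classify_config()) {
  if (length(unique(stats::na.omit(train_crowns$species))) < 2)
    stop("training crowns must span >= 2 species")
  tr <- extract_crown_pixels(cube, train_crowns)
  te <- extract_crown_pixels(cube, test_crowns)
  xtr <- normalize_pixels(tr$spectra)
  if (length(attr(xtr, "dropped")) > 0)
    tr$info <- tr$info[-attr(xtr, "dropped"), , drop = FALSE]
  xte <- normalize_pixels(te$spectra)
  if (length(attr(xte, "dropped")) > 0)
    te$info <- te$info[-attr(xte, "dropped"), , drop = FALSE]
  sel <- sffs_select(xtr, tr$info$species, config$max_features,
                     config$criterion)
  ftr <- xtr[, sel$selected, drop = FALSE]
  fte <- xte[, sel$selected, drop = FALSE]
  if (!is.null(chm)) {
    chm_of <- function(crowns, info) {
      h <- vapply(seq_len(nrow(crowns)), function(i)
        itc_height_from_chm(crowns$geometry[[i]], chm), numeric(1))
      h[is.na(h)] <- 0
      h[match(info$crown_id, crowns$crown_id)]
    }
    ftr <- cbind(ftr, chm = chm_of(train_crowns, tr$info))
    fte <- cbind(fte, chm = chm_of(test_crowns, te$info))
  }
  pix <- train_and_predict(ftr, tr$info$species, fte, config)
  counts <- table(tr$info$species)
  pred <- aggregate_majority(pix, te$info$crown_id,
                             stats::setNames(as.numeric(counts),
                                             names(counts)))
  out <- list(predictions = pred, selected_bands = sel$selected,
              band_trace = sel$trace, pixel_labels = pix,
              svm_tuning = attr(pix, "tuning"))
  truth <- test_crowns$species[match(pred$crown_id, test_crowns$crown_id)]
  if (!anyNA(truth)) {
    cm <- confusion_matrix(pred$species, truth)
    out$confusion <- cm
    out$metrics <- confusion_metrics(cm)
  }
  out
}
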