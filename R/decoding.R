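#' Spike-count feature matrix of a trial set
#'
#' Rate coding: the feature of afferent j in trial i is its spike count in
#' the window (`FR = spikes / delta_t` up to the constant window length,
#' which the normalization absorbs).
#'
#' @param trials A `trial_set` from [haptic_dataset()].
#' @param window Counting window `c(t0, t1)` in ms; defaults to the full
#'   trial.
#' @param types Afferent types to keep: `"SA"`, `"FA"`, or both.
#' @return A `feature_matrix`: tibble with `trial`, `object`, `fingers`,
#'   `rep`, then one integer count column per afferent (named by
#'   `afferent_id`), with the afferent-type mask as an attribute.
#' @examples
#' d <- haptic_design(repetitions = 2, trial_duration = 400, hold_duration = 300,
#'                    grasp_rise = 40, grasp_fall = 40)
#' fm <- spike_counts(haptic_dataset(d, seed = 1))
#' dim(fm)
#' @export
spike_counts <- function(trials, window = NULL, types = c("SA", "FA")) {
  stopifnot(inherits(trials, "trial_set"))
  afferents <- attr(trials, "afferents")
  duration <- attr(trials, "duration")
  if (is.null(window)) window <- c(0, duration)
  if (window[[1]] < 0 || window[[2]] > duration || window[[1]] >= window[[2]]) {
    abort("`window` must lie within the trial duration")
  }
  types <- vapply(types, match_afferent, "")
  keep <- which(afferents$type %in% types)
  if (!length(keep)) abort("no afferents match the requested types")
  counts <- t(vapply(trials$spikes, function(sp) {
    vapply(sp[keep], function(st) {
      sum(st >= window[[1]] & st <= window[[2]])
    }, 0L)
  }, integer(length(keep))))
  colnames(counts) <- afferents$afferent_id[keep]
  out <- dplyr::bind_cols(
    trials[, c("trial", "object", "fingers", "rep")],
    as_tibble(counts)
  )
  attr(out, "afferents") <- afferents[keep, ]
  attr(out, "window") <- window
  class(out) <- c("feature_matrix", class(out))
  out
}

feature_cols <- function(features) {
  setdiff(names(features), c("trial", "object", "fingers", "rep"))
}

#' Project spike-count features onto the first principal components
#'
#' Features are normalized (z-scored per column), then projected onto the
#' top-variance directions of the sample covariance. Component signs are
#' fixed by the largest-loading-positive convention so that scores are
#' deterministic. Zero-variance columns are dropped with a warning.
#'
#' @param features A `feature_matrix` (or any tibble with meta columns
#'   `trial`, `object`, `fingers`, `rep` and numeric feature columns).
#' @param n_components Number of components kept (default 3).
#' @param normalize Z-score the columns first.
#' @return Tibble with the meta columns plus `PC1..PCk`; the rotation and
#'   explained-variance fractions are attached as attributes.
#' @export
reduce_pca <- function(features, n_components = 3, normalize = TRUE) {
  cols <- feature_cols(features)
  x <- as.matrix(features[, cols])
  storage.mode(x) <- "double"
  if (nrow(x) < 4) abort("need at least 4 trials for a 3-component PCA")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance feature(s)", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = normalize)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  # largest-loading-positive sign convention
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  ctr <- scale(x, center = pc$center, scale = if (normalize) pc$scale else FALSE)
  scores <- ctr %*% rot
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(
    features[, intersect(c("trial", "object", "fingers", "rep"), names(features))],
    as_tibble(scores)
  )
  attr(out, "rotation") <- rot
  attr(out, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' k-nearest-neighbour classification with mean-distance tie-breaking
#'
#' Majority vote among the `k` Euclidean-nearest training points; ties are
#' broken in favour of the tied class with the smallest mean distance from
#' the test point to its tied neighbours.
#'
#' @param train_x,test_x Numeric matrices (rows = samples).
#' @param train_y Training labels.
#' @param k Number of neighbours (`<= nrow(train_x)`).
#' @return Character vector of predicted labels.
#' @examples
#' tr <- rbind(matrix(0, 5, 2), matrix(4, 5, 2))
#' knn_classify(tr, rep(c("a", "b"), each = 5), matrix(c(0.1, 0.1), 1))
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 5) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  if (k > nrow(train_x)) abort("`k` exceeds the training-set size")
  if (ncol(train_x) != ncol(test_x)) abort("feature dimension mismatch")
  # all-pairs squared distances: |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(drow) {
    nn <- order(drow)[seq_len(k)]
    votes <- table(train_y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    means <- vapply(top, function(cl) mean(sqrt(drow[nn][train_y[nn] == cl])), 1)
    top[[which.min(means)]]
  })
}

#' Nearest-class-mean classification of spike-train features
#'
#' The alternative readout described alongside the kNN classifier: a test
#' point is assigned to the class whose members have the smallest mean
#' distance to it.
#'
#' @inheritParams knn_classify
#' @return Character vector of predicted labels.
#' @export
nearest_mean_classify <- function(train_x, train_y, test_x) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  train_y <- as.character(train_y)
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * tcrossprod(test_x, train_x)
  d2[d2 < 0] <- 0
  classes <- unique(train_y)
  apply(d2, 1, function(drow) {
    means <- vapply(classes, function(cl) mean(sqrt(drow[train_y == cl])), 1)
    classes[[which.min(means)]]
  })
}

#' Decode object identity from the population spike counts
#'
#' The full rate-coding readout: per afferent set (`SA`, `FA`, `both`) and
#' finger condition, spike-count features are z-scored on the training part,
#' projected onto the first `n_components` principal components (fitted on
#' the training part only), and classified with kNN (`k = 5`). Accuracy is
#' estimated by stratified K-fold cross-validation (default 5 folds, i.e.
#' each fold trains on 80% of the trials and tests on the held-out 20%), and
#' reported as mean and SD across folds.
#'
#' @param trials A `trial_set`.
#' @param k_neighbors kNN neighbourhood size.
#' @param n_components Principal components kept.
#' @param cv_folds Number of stratified folds.
#' @param normalize Z-score features on the training fold.
#' @param window Counting window (ms), defaults to the full trial.
#' @param afferent_sets Subsets to evaluate.
#' @param by_fingers Evaluate each finger condition separately (the layout of
#'   the published accuracy table); set `FALSE` to pool.
#' @param classifier `"knn"` (the named classifier, default) or
#'   `"class_mean"` (nearest class mean, the alternative readout).
#' @param permute_labels Shuffle object labels before evaluation (chance
#'   control).
#' @param seed Seed for fold assignment (and permutation).
#' @return A `decoding_eval`: tibble with `afferent_set`, `fingers`,
#'   `mean_accuracy`, `sd_accuracy`, `n_trials` (accuracies as fractions).
#' @examples
#' d <- haptic_design(repetitions = 4, trial_duration = 400, hold_duration = 300,
#'                    grasp_rise = 40, grasp_fall = 40)
#' ev <- evaluate_decoding(haptic_dataset(d, seed = 1), seed = 1)
#' tidy(ev)
#' @export
evaluate_decoding <- function(trials, k_neighbors = 5, n_components = 3,
                              cv_folds = 5, normalize = TRUE, window = NULL,
                              afferent_sets = c("SA", "FA", "both"),
                              by_fingers = TRUE,
                              classifier = c("knn", "class_mean"),
                              permute_labels = FALSE,
                              seed = 1) {
  stopifnot(inherits(trials, "trial_set"))
  classifier <- match.arg(classifier)
  set.seed(seed)
  results <- list()
  for (aset in afferent_sets) {
    types <- if (tolower(aset) == "both") c("SA", "FA") else aset
    fm <- spike_counts(trials, window = window, types = types)
    if (permute_labels) fm$object <- sample(fm$object)
    groups <- if (by_fingers) sort(unique(fm$fingers)) else NA
    for (fg in groups) {
      sub <- if (is.na(fg)) fm else fm[fm$fingers == fg, ]
      acc <- cv_accuracy(sub, k_neighbors, n_components, cv_folds, normalize,
                         classifier)
      results[[length(results) + 1]] <- tibble(
        afferent_set = aset, fingers = fg,
        mean_accuracy = mean(acc), sd_accuracy = sd(acc),
        n_trials = nrow(sub)
      )
    }
  }
  out <- bind_rows(results)
  attr(out, "config") <- list(k_neighbors = k_neighbors,
                              n_components = n_components,
                              cv_folds = cv_folds, normalize = normalize,
                              permute_labels = permute_labels, seed = seed)
  class(out) <- c("decoding_eval", class(out))
  out
}

# stratified K-fold CV; re-draws a fold assignment that would lose a class
cv_accuracy <- function(features, k_neighbors, n_components, cv_folds, normalize,
                        classifier = "knn") {
  y <- features$object
  if (length(unique(y)) < 2) abort("need at least 2 classes")
  cols <- feature_cols(features)
  x <- as.matrix(features[, cols])
  storage.mode(x) <- "double"
  folds <- stratified_folds(y, cv_folds)
  vapply(seq_len(cv_folds), function(f) {
    test <- folds == f
    xtr <- x[!test, , drop = FALSE]; xte <- x[test, , drop = FALSE]
    ytr <- y[!test]; yte <- y[test]
    # normalization and PCA fitted on the training fold only
    mu <- colMeans(xtr)
    sc <- if (normalize) apply(xtr, 2, sd) else rep(1, ncol(xtr))
    keep <- sc > 0
    xtr <- sweep(sweep(xtr[, keep, drop = FALSE], 2, mu[keep]), 2, sc[keep], "/")
    xte <- sweep(sweep(xte[, keep, drop = FALSE], 2, mu[keep]), 2, sc[keep], "/")
    pc <- prcomp(xtr, center = FALSE, scale. = FALSE)
    k <- min(n_components, ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    pred <- if (classifier == "class_mean") {
      nearest_mean_classify(xtr %*% rot, ytr, xte %*% rot)
    } else {
      knn_classify(xtr %*% rot, ytr, xte %*% rot,
                   k = min(k_neighbors, nrow(xtr)))
    }
    mean(pred == yte)
  }, 1)
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  # every fold must retain every class in its training part
  for (f in seq_len(k)) {
    if (length(unique(y[folds != f])) < length(unique(y))) {
      return(stratified_folds(y, k))
    }
  }
  folds
}

#' @export
print.decoding_eval <- function(x, ...) {
  cat("<decoding_eval> kNN rate-coding readout\n")
  print(format_accuracy_table(x))
  invisible(x)
}

#' Format a decoding evaluation as the published-style accuracy table
#'
#' Rows are afferent sets (SA-I, FA-I, both), columns the finger conditions,
#' cells `mean% +/- sd%`.
#'
#' @param eval A `decoding_eval`.
#' @return A data frame of formatted cells.
#' @export
format_accuracy_table <- function(eval) {
  wide <- eval %>%
    mutate(cell = sprintf("%.0f%% ± %.0f%%", 100 * .data$mean_accuracy,
                          100 * .data$sd_accuracy)) %>%
    select("afferent_set", "fingers", "cell") %>%
    tidyr::pivot_wider(names_from = "fingers", values_from = "cell",
                       names_prefix = "fingers_")
  as.data.frame(wide)
}

#' @rdname evaluate_decoding
#' @param x A `decoding_eval`.
#' @export
tidy.decoding_eval <- function(x, ...) {
  as_tibble(x)
}

#' @rdname evaluate_decoding
#' @export
glance.decoding_eval <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(mean_accuracy = mean(x$mean_accuracy),
         min_accuracy = min(x$mean_accuracy),
         max_accuracy = max(x$mean_accuracy),
         k_neighbors = cfg$k_neighbors, n_components = cfg$n_components,
         cv_folds = cfg$cv_folds)
}
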