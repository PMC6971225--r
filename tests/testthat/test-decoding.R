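test_that("spike counts implement rate coding over the requested window", {
  ts <- fake_trial_set(n_per_class = 2, seed = 5)
  fm <- spike_counts(ts)
  expect_identical(nrow(fm), nrow(ts))
  expect_identical(length(tactspike:::feature_cols(fm)), 135L)

  # FR = spikes / delta_t: counts in a 100-ms window of a known train
  ts$spikes[[1]][[1]] <- seq(5, 95, by = 10) # 10 spikes inside [0, 100]
  fm2 <- spike_counts(ts, window = c(0, 100))
  expect_identical(fm2[[tactspike:::feature_cols(fm2)[1]]][1], 10L)
  expect_identical(10 / 0.1, 100) # 100 Hz over the 0.1-s window

  # type filtering: the glove population has 50 SA and 85 FA columns
  expect_identical(length(tactspike:::feature_cols(spike_counts(ts, types = "SA"))), 50L)
  expect_identical(length(tactspike:::feature_cols(spike_counts(ts, types = "FA"))), 85L)

  # empty rasters give all-zero rows
  ts$spikes[[2]] <- lapply(ts$spikes[[2]], function(x) numeric(0))
  fm3 <- spike_counts(ts)
  expect_true(all(as.matrix(fm3[2, tactspike:::feature_cols(fm3)]) == 0))

  expect_error(spike_counts(ts, window = c(0, 2000)), "within")
  expect_error(spike_counts(ts, types = character(0)), "afferent")
})

test_that("PCA scores match an independent covariance eigendecomposition", {
  set.seed(17)
  x <- matrix(rnorm(60), 10, 6)
  fm <- dplyr::bind_cols(
    tibble::tibble(trial = 1:10, object = rep(c("A", "B"), 5),
                   fingers = 3L, rep = 1:10),
    tibble::as_tibble(setNames(as.data.frame(x), paste0("f", 1:6)))
  )
  sc <- reduce_pca(fm, n_components = 3)

  # oracle: eigensolve the sample covariance of the z-scored data directly
  z <- scale(x)
  eig <- eigen(stats::cov(z), symmetric = TRUE)
  for (j in 1:3) {
    vec <- eig$vectors[, j]
    if (vec[which.max(abs(vec))] < 0) vec <- -vec
    oracle_scores <- z %*% vec
    expect_equal(sc[[paste0("PC", j)]], as.numeric(oracle_scores),
                 tolerance = 1e-8)
  }
  expect_equal(attr(sc, "explained"),
               (eig$values / sum(eig$values))[1:3], tolerance = 1e-8)
})

test_that("PCA handles rank deficiency and zero variance as documented", {
  # rank-1 data: PC1 carries everything
  v <- rnorm(8)
  x <- outer(v, c(1, 2, 3))
  fm <- dplyr::bind_cols(
    tibble::tibble(trial = 1:8, object = rep(c("A", "B"), 4), fingers = 3L, rep = 1:8),
    tibble::as_tibble(setNames(as.data.frame(x), paste0("f", 1:3)))
  )
  sc <- reduce_pca(fm, normalize = FALSE)
  expl <- attr(sc, "explained")
  expect_gt(expl[1], 1 - 1e-10)
  expect_lt(sum(abs(sc$PC2)) + sum(abs(sc$PC3)), 1e-8)

  # back-projection of rank-3 data through 3 components is lossless
  set.seed(2)
  basis <- matrix(rnorm(18), 6, 3)
  x3 <- matrix(rnorm(36), 12, 3) %*% t(basis)
  fm3 <- dplyr::bind_cols(
    tibble::tibble(trial = 1:12, object = rep(c("A", "B"), 6), fingers = 3L, rep = 1:12),
    tibble::as_tibble(setNames(as.data.frame(x3), paste0("f", 1:6)))
  )
  sc3 <- reduce_pca(fm3, normalize = FALSE)
  rot <- attr(sc3, "rotation")
  recon <- as.matrix(sc3[, c("PC1", "PC2", "PC3")]) %*% t(rot)
  centered <- scale(x3, scale = FALSE)
  expect_equal(recon, unname(centered), tolerance = 1e-8,
               ignore_attr = TRUE)

  # zero-variance feature is dropped with a warning
  fmz <- fm3
  fmz$f1 <- 1
  expect_warning(reduce_pca(fmz, normalize = TRUE), "zero-variance")
})

test_that("kNN matches a brute-force distance-scan oracle", {
  # unanimity and k = 1 identities
  tr <- rbind(matrix(0, 5, 2), matrix(4, 5, 2))
  y <- rep(c("a", "b"), each = 5)
  expect_identical(unname(knn_classify(tr, y, matrix(c(0.1, -0.1), 1), k = 5)), "a")
  expect_identical(unname(knn_classify(tr, y, tr[7, , drop = FALSE], k = 1)), "b")
  expect_error(knn_classify(tr, y, tr[1:2, ], k = 11), "exceeds")

  # 30 random points vs an explicit all-pairs oracle with the same tie rule
  set.seed(23)
  trx <- matrix(rnorm(60 * 3), 60, 3)
  try_ <- sample(c("A", "B", "C"), 60, replace = TRUE)
  tex <- matrix(rnorm(30 * 3), 30, 3)
  oracle <- character(30)
  for (i in 1:30) {
    d <- sqrt(colSums((t(trx) - tex[i, ])^2))
    nn <- order(d)[1:5]
    tab <- table(try_[nn])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      m <- sapply(top, function(cl) mean(d[nn][try_[nn] == cl]))
      top <- top[which.min(m)]
    }
    oracle[i] <- top
  }
  expect_identical(unname(knn_classify(trx, try_, tex, k = 5)), oracle)

  # cross-check against an established implementation where no ties arise
  if (requireNamespace("class", quietly = TRUE)) {
    got <- knn_classify(trx, try_, tex, k = 1)
    ref <- as.character(class::knn(trx, tex, factor(try_), k = 1))
    expect_identical(unname(got), ref)
  }

  # nearest-class-mean variant: closest class centroid by mean distance
  nm <- nearest_mean_classify(tr, y, matrix(c(0.5, 0.5), 1))
  expect_identical(unname(nm), "a")
})

test_that("perfectly separated objects decode at 100% with zero fold spread", {
  ts <- fake_trial_set(n_per_class = 10, separation = 40, noise_sd = 1, seed = 7)
  ev <- evaluate_decoding(ts, seed = 1)
  expect_identical(nrow(ev), 9L) # {SA, FA, both} x {3,4,5}
  expect_true(all(ev$mean_accuracy == 1))
  expect_true(all(ev$sd_accuracy == 0))
  expect_identical(dim(format_accuracy_table(ev)), c(3L, 4L))

  # reproducible per seed
  ev2 <- evaluate_decoding(ts, seed = 1)
  expect_identical(ev$mean_accuracy, ev2$mean_accuracy)
})

test_that("permuted labels decode at chance for three classes", {
  ts <- fake_trial_set(n_per_class = 10, separation = 40, noise_sd = 1, seed = 8)
  accs <- vapply(1:10, function(s) {
    ev <- evaluate_decoding(ts, by_fingers = FALSE, afferent_sets = "both",
                            permute_labels = TRUE, seed = s)
    ev$mean_accuracy
  }, 1)
  expect_lt(abs(mean(accs) - 1 / 3), 0.12)
})

test_that("accuracy is invariant to column order and common count rescaling", {
  ts <- fake_trial_set(n_per_class = 8, separation = 12, noise_sd = 6, seed = 9)
  fm <- spike_counts(ts)
  base <- tactspike:::cv_accuracy(fm, 5, 3, 5, TRUE)

  cols <- tactspike:::feature_cols(fm)
  set.seed(1)
  shuffled <- fm[, c(setdiff(names(fm), cols), sample(cols))]
  class(shuffled) <- class(fm)
  set.seed(42); a <- tactspike:::cv_accuracy(fm, 5, 3, 5, TRUE)
  set.seed(42); b <- tactspike:::cv_accuracy(shuffled, 5, 3, 5, TRUE)
  expect_identical(a, b)

  scaled <- fm
  for (cc in cols) scaled[[cc]] <- scaled[[cc]] * 7
  set.seed(42); d <- tactspike:::cv_accuracy(scaled, 5, 3, 5, TRUE)
  expect_equal(a, d, tolerance = 1e-12)
})
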