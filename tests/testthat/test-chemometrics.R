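test_that("PCA recovers exact low-rank structure and orthonormal loadings", {
  # points exactly on a line: PC1 explains everything
  x <- seq(-3, 3, length.out = 21)
  X <- cbind(x, 2 * x + 1)
  p <- fit_pca(X, n_comp = 1)
  expect_equal(p$explained_variance[1], 1.0, tolerance = 1e-12)

  set.seed(5)
  Xr <- matrix(rnorm(50), 10, 5)
  p2 <- fit_pca(Xr, n_comp = 4)
  expect_equal(crossprod(p2$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(fit_pca(X, n_comp = 2), "rank")
})

test_that("PCA matches an independent eigendecomposition of the covariance", {
  set.seed(6)
  X <- matrix(rnorm(50), 10, 5)
  p <- fit_pca(X, n_comp = 5)
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(p$explained_variance, ev$values / sum(ev$values),
               tolerance = 1e-8)
  # loadings agree up to sign
  for (k in 1:5) {
    expect_equal(abs(sum(p$loadings[, k] * ev$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  # scores = centered data projected on loadings
  Xc <- scale(X, scale = FALSE)
  expect_equal(p$scores, Xc %*% p$loadings, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("NIPALS PLS reduces to closed-form fits in the limiting cases", {
  set.seed(7)
  # univariate, 1 LV: identical to simple least squares
  x <- matrix(rnorm(15), 15, 1)
  y <- 2 * x[, 1] + rnorm(15)
  m <- fit_pls(x, y, n_lv = 1)
  slope <- cov(x[, 1], y) / var(x[, 1])
  expect_equal(predict_pls(m, x),
               mean(y) + slope * (x[, 1] - mean(x[, 1])),
               tolerance = 1e-10)

  # full rank: reproduces the least-squares fit
  X <- matrix(rnorm(20 * 6), 20, 6)
  yy <- rnorm(20)
  mf <- fit_pls(X, yy, n_lv = 6)
  expect_equal(predict_pls(mf, X),
               unname(lm.fit(cbind(1, X), yy)$fitted.values),
               tolerance = 1e-10)

  # X containing y as a column is learnt by one LV (n large enough that
  # the chance covariance of the noise columns with y is negligible)
  yl <- rnorm(500)
  Xy <- cbind(yl, matrix(rnorm(500 * 3), 500, 3))
  m1 <- fit_pls(Xy, yl, n_lv = 1)
  r2 <- 1 - sum((predict_pls(m1, Xy) - yl)^2) / sum((yl - mean(yl))^2)
  expect_gt(r2, 0.99)

  expect_error(fit_pls(X, yy, n_lv = 20), "rank")
  expect_error(fit_pls(X, rep(1, 20), 1), "zero variance")
})

test_that("PLS scores are orthogonal and B matches sequential deflation", {
  set.seed(8)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  m <- fit_pls(X, y, n_lv = 4)
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)

  # sequential prediction: pass new data through weights with deflation
  X_new <- matrix(rnorm(10 * 8), 10, 8)
  Xc <- sweep(sweep(X_new, 2, m$x_center), 2, m$x_scale, "/")
  pred <- rep(m$y_center, 10)
  for (a in seq_len(m$n_lv)) {
    t_a <- Xc %*% m$W[, a]
    pred <- pred + m$q[a] * t_a
    Xc <- Xc - t_a %*% t(m$P[, a])
  }
  expect_equal(predict_pls(m, X_new), as.numeric(pred), tolerance = 1e-10)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  suppressMessages(requireNamespace("mixOmics", quietly = TRUE))
  set.seed(9)
  for (rep in 1:3) {
    X <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- rnorm(20)
    ours <- predict_pls(fit_pls(X, y, n_lv = 3), X)
    mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
    ref <- unname(predict(mo, X)$predict[, 1, 3])
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("PLS-DA separates well-separated clouds and validates inputs", {
  d <- gauss_clouds(30, 30, delta = 5, seed = 10)
  m <- fit_plsda(d$X, d$labels, n_lv = 2, positive = "HCC")
  pred <- predict_class(m, d$X)
  expect_equal(mean(pred$class == d$labels), 1.0)

  # balanced classes: the score equals the raw prediction, so the class
  # call is predict_pls then sign
  m1 <- fit_plsda(d$X, d$labels, n_lv = 1, positive = "HCC")
  raw <- predict_pls(m1, d$X)
  expect_equal(predict_class(m1, d$X)$class,
               ifelse(raw >= 0, "HCC", "HCV"))

  expect_error(fit_plsda(d$X, rep("HCC", 60), 1), "two classes")
})

test_that("cross-validated accuracy on pure noise stays near chance", {
  accs <- vapply(1:50, function(s) {
    d <- gauss_clouds(15, 15, delta = 0, seed = 100 + s)
    sc <- kfold_cv_predict(d$X, d$labels, k = 5, n_lv = 2,
                           positive = "HCC", seed = s)
    mean(ifelse(sc >= 0, "HCC", "HCV") == d$labels)
  }, 0)
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})

test_that("k-fold assignment is stratified, balanced and id-keyed", {
  d <- gauss_clouds(40, 22, delta = 1, seed = 12)
  fold <- stratified_folds(rownames(d$X), d$labels, k = 7, seed = 3)
  sizes <- table(fold)
  expect_length(sizes, 7)
  expect_lte(max(sizes) - min(sizes), 1)

  sc <- kfold_cv_predict(d$X, d$labels, k = 7, n_lv = 2,
                         positive = "HCC", seed = 3)
  expect_length(sc, 62)
  expect_false(anyNA(sc))

  # permuting rows leaves each sample's prediction unchanged
  perm <- sample(62)
  sc2 <- kfold_cv_predict(d$X[perm, ], d$labels[perm], k = 7, n_lv = 2,
                          positive = "HCC", seed = 3)
  expect_equal(sc2[names(sc)], sc)
})

test_that("k = n cross-validation equals an explicit leave-one-out loop", {
  d <- gauss_clouds(5, 5, delta = 2, p = 3, seed = 13)
  sc <- kfold_cv_predict(d$X, d$labels, k = 10, n_lv = 2,
                         positive = "HCC", seed = 4)
  fold <- stratified_folds(rownames(d$X), d$labels, k = 10, seed = 4)
  loo <- sapply(seq_len(10), function(i) {
    hold <- fold == fold[i]  # k = n: each fold is one sample
    m <- fit_plsda(d$X[!hold, ], d$labels[!hold], n_lv = 2, positive = "HCC")
    predict_class(m, d$X[hold, , drop = FALSE])$score
  })
  expect_equal(unname(sc), unname(loo), tolerance = 1e-12)
})

test_that("fold-local scaling prevents leakage of an injected outlier", {
  d <- gauss_clouds(14, 14, delta = 1, seed = 14)
  sc <- kfold_cv_predict(d$X, d$labels, k = 4, n_lv = 2,
                         positive = "HCC", seed = 5)
  fold <- stratified_folds(rownames(d$X), d$labels, k = 4, seed = 5)
  Xo <- d$X
  Xo[1, ] <- Xo[1, ] + 1e4  # extreme outlier
  sco <- kfold_cv_predict(Xo, d$labels, k = 4, n_lv = 2,
                          positive = "HCC", seed = 5)
  same_fold <- fold == fold[1]
  # samples sharing the outlier's fold are predicted by models that never
  # saw it: their scores are unchanged; all other folds are affected
  expect_equal(sco[same_fold][-1], sc[same_fold][-1], tolerance = 1e-10)
  expect_false(any(abs(sco[!same_fold] - sc[!same_fold]) < 1e-8))
})

test_that("OSC removes y-orthogonal structure and only that", {
  # every column proportional to y: nothing orthogonal to remove
  y <- rep(c(1, -1), each = 10)
  Xp <- cbind(y, 2 * y, -0.5 * y)
  r <- osc_correct(Xp, y)
  expect_equal(r$X_corrected, Xp, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(r$filter$components[[1]]$removed_variance, 0)

  # informative column + strong structured noise orthogonal to y
  set.seed(15)
  z <- rnorm(20); z <- z - y * sum(z * y) / sum(y^2)
  X <- cbind(info = y + rnorm(20, sd = 0.1), noise = 5 * z + rnorm(20, sd = 0.1))
  X <- scale(X, scale = FALSE)
  r2 <- osc_correct(X, y, n_osc = 1)
  kept <- colSums(r2$X_corrected^2) / colSums(X^2)
  expect_lt(kept["noise"], 0.10)   # > 90 % of the noise factor removed
  expect_gt(kept["info"], 0.90)    # < 10 % of the informative factor lost

  # removed scores exactly orthogonal to y, on random problems too
  for (s in 1:5) {
    set.seed(200 + s)
    Xr <- scale(matrix(rnorm(30 * 10), 30, 10), scale = FALSE)
    yr <- rep(c(1, -1), 15)
    rr <- osc_correct(Xr, yr, n_osc = 2)
    for (cmp in rr$filter$components) {
      expect_lt(abs(sum(cmp$t * yr)),
                1e-6 * sqrt(sum(cmp$t^2)) * sqrt(sum(yr^2)) + 1e-15)
    }
  }
})

test_that("a fitted OSC filter transfers to new data through its weights", {
  set.seed(16)
  y <- rep(c(1, -1), each = 15)
  z <- rnorm(30); z <- z - y * sum(z * y) / sum(y^2)
  X <- scale(cbind(y + rnorm(30, 0.1), 5 * z + rnorm(30, 0.1),
                   rnorm(30)), scale = FALSE)
  r <- osc_correct(X, y)
  X2 <- apply_osc(r$filter, X)
  # the transferred correction removes the same structured component
  expect_lt(sum((X2 - r$X_corrected)^2) / sum(X^2), 0.05)
})

test_that("ROC/AUC equals concordant-pair counting and handles ties", {
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c("pos", "pos", "neg", "neg"),
               positive = "pos")
  expect_equal(r$auc, 1.0)
  r2 <- roc_auc(c(0.9, 0.8, 0.3, 0.2), c("pos", "neg", "pos", "neg"),
                positive = "pos")
  expect_equal(r2$auc, 0.75)
  r3 <- roc_auc(rep(1, 6), c("pos", "pos", "neg", "neg", "pos", "neg"),
                positive = "pos")
  expect_equal(r3$auc, 0.5)

  # exhaustive oracle on random datasets up to n = 12 (with ties)
  set.seed(17)
  for (n in c(4, 8, 12)) {
    for (rep in 1:10) {
      labs <- sample(c("pos", "neg"), n, replace = TRUE)
      if (length(unique(labs)) < 2) next
      sc <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      expect_equal(roc_auc(sc, labs, positive = "pos")$auc,
                   auc_by_pairs(sc, labs, "pos"))
    }
  }

  # curve geometry: starts (0,0), ends (1,1), both coordinates monotone
  set.seed(18)
  sc <- rnorm(40)
  labs <- rep(c("pos", "neg"), 20)
  rc <- roc_auc(sc, labs, positive = "pos")
  pts <- rc$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))

  expect_error(roc_auc(1:3, rep("pos", 3)), "two classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  suppressMessages(requireNamespace("pROC", quietly = TRUE))
  set.seed(19)
  sc <- rnorm(60)
  labs <- sample(c("pos", "neg"), 60, replace = TRUE)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labs, sc, levels = c("neg", "pos"),
                        direction = "<", quiet = TRUE))))
  expect_equal(roc_auc(sc, labs, positive = "pos")$auc, ref,
               tolerance = 1e-10)
})
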