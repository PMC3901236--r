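#' Principal component analysis
#'
#' Thin SVD-based PCA returning orthonormal loadings, scores and
#' explained-variance fractions.
#'
#' @param X Numeric matrix or [feature_table()] (already centered or
#'   autoscaled, or use `center = TRUE`).
#' @param n_comp Number of components (must not exceed the matrix rank).
#' @param center Center columns before decomposition? Default TRUE; set
#'   FALSE for data that is already centered.
#' @return An object of class `pca_model` with `loadings` (p x k,
#'   orthonormal), `scores` (n x k), `explained_variance` (fractions) and
#'   the stored `center`.
#' @export
fit_pca <- function(X, n_comp = 2, center = TRUE) {
  if (inherits(X, "feature_table")) X <- X$values
  X <- as.matrix(X)
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d[1], 0) * 1e-9)
  if (n_comp > rank) {
    stop("n_comp (", n_comp, ") exceeds the matrix rank (", rank, ")")
  }
  ev <- sv$d^2 / sum(sv$d^2)
  structure(
    list(loadings = sv$v[, seq_len(n_comp), drop = FALSE],
         scores = Xc %*% sv$v[, seq_len(n_comp), drop = FALSE],
         explained_variance = ev[seq_len(n_comp)],
         center = ctr, rank = rank),
    class = "pca_model"
  )
}

# internal: center/scale bookkeeping shared by fit_pls / fit_plsda
.fit_scaler <- function(X, scale) {
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  if (any(scl == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  }
  list(center = ctr, scale = scl)
}

.apply_scaler <- function(sc, X) {
  sweep(sweep(as.matrix(X), 2, sc$center), 2, sc$scale, "/")
}

#' Fit a PLS1 regression model by NIPALS
#'
#' Classic NIPALS with deflation of both `X` and `y`. Centering (and
#' optional unit-variance scaling) of `X` and centering of `y` are fitted
#' here and stored, so [predict_pls()] transforms new samples identically.
#'
#' @param X Numeric matrix (samples x features) on the raw scale.
#' @param y Numeric response (for discriminant analysis use +1/-1 coding
#'   via [fit_plsda()]).
#' @param n_lv Number of latent variables, `1 <= n_lv <= rank(X)`.
#' @param scale Unit-variance scale the columns of `X`?
#' @return An object of class `pls_model`: weights `W`, loadings `P`,
#'   scores `T`, per-LV y-loadings `q`, regression vector `B`, intercept,
#'   and the stored preprocessing parameters.
#' @export
fit_pls <- function(X, y, n_lv = 2, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::var(y) == 0) stop("y has zero variance")
  sc <- .fit_scaler(X, scale)
  Xc <- .apply_scaler(sc, X)
  y_center <- mean(y)
  yc <- y - y_center
  rank <- qr(Xc)$rank
  if (n_lv < 1 || n_lv > rank) {
    stop("n_lv must be between 1 and rank(X) = ", rank)
  }
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); q <- numeric(n_lv)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) stop("residual covariance vanished at LV ", a)
    w <- w / wn
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  B <- W %*% solve(crossprod(P, W), q)
  structure(
    list(n_lv = n_lv, W = W, P = P, T = Tm, q = q, B = as.numeric(B),
         x_center = sc$center, x_scale = sc$scale, scaled = scale,
         y_center = y_center, rank = rank,
         features = colnames(X)),
    class = "pls_model"
  )
}

#' Predict responses from a fitted PLS model
#'
#' Applies the stored centering/scaling to `X_new` and evaluates the
#' regression vector.
#'
#' @param m A [fit_pls()] / [fit_plsda()] model.
#' @param X_new Numeric matrix (raw scale) with the training columns.
#' @return Numeric vector of predicted responses.
#' @export
predict_pls <- function(m, X_new) {
  stopifnot(inherits(m, "pls_model"))
  X_new <- as.matrix(X_new)
  Xc <- .apply_scaler(list(center = m$x_center, scale = m$x_scale), X_new)
  as.numeric(m$y_center + Xc %*% m$B)
}

#' Fit a two-class PLS-DA model
#'
#' Labels are coded +1 (positive class) / -1 (negative class) and a PLS1
#' model is fitted to the coded response. The positive class is the
#' case/disease class whose detection sensitivity refers to.
#'
#' @param X Numeric matrix (samples x features), raw scale.
#' @param labels Two-class label vector.
#' @param n_lv Number of latent variables.
#' @param positive Positive-class label; defaults to the first level
#'   (factor input) or the alphabetically first label.
#' @param scale One of `"autoscale"` (unit-variance, default for targeted
#'   peak-integral tables) or `"center"` (mean-centering only, the usual
#'   choice for full-spectrum bins).
#' @return A `pls_model` with classification fields (`positive`,
#'   `negative`, `scale_mode`).
#' @export
fit_plsda <- function(X, labels, n_lv = 2, positive = NULL,
                      scale = c("autoscale", "center")) {
  scale <- match.arg(scale)
  classes <- if (is.factor(labels)) levels(droplevels(labels))
             else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  if (length(classes) != 2) {
    stop("PLS-DA needs exactly two classes, got ",
         length(classes), ": ", paste(classes, collapse = ", "))
  }
  positive <- positive %||% classes[1]
  if (!positive %in% classes) stop("positive class '", positive, "' not in labels")
  negative <- setdiff(classes, positive)
  y <- ifelse(labels == positive, 1, -1)
  m <- fit_pls(X, y, n_lv = n_lv, scale = (scale == "autoscale"))
  m$positive <- positive
  m$negative <- negative
  m$scale_mode <- scale
  m
}

#' Predict class labels (and continuous scores) from a PLS-DA model
#'
#' The discriminant score is the centered prediction
#' `s(x) = yhat(x) - mean(y_train)`, i.e. the regression prediction with
#' the class-imbalance offset of the +1/-1 coding removed; with balanced
#' training classes it equals the raw prediction. The predicted class is
#' the sign of the score relative to `threshold` (default 0, the midpoint
#' of the coding). Removing the offset keeps the classification rate of an
#' uninformative model at chance even when the cohorts differ in size.
#'
#' @param m A [fit_plsda()] model.
#' @param X_new Numeric matrix, raw scale.
#' @param threshold Decision threshold on the score.
#' @return A list with `class` (labels) and `score` (continuous values,
#'   usable for ROC analysis).
#' @export
predict_class <- function(m, X_new, threshold = 0) {
  stopifnot(inherits(m, "pls_model"), !is.null(m$positive))
  score <- predict_pls(m, X_new) - m$y_center
  list(class = ifelse(score >= threshold, m$positive, m$negative),
       score = score)
}

#' Stratified k-fold assignment keyed by sample id
#'
#' Samples are processed in sorted-id order within sorted class order, so
#' the assignment depends on ids, not row positions: permuting the rows of
#' the input leaves each sample's fold unchanged.
#'
#' @param ids Unique sample identifiers.
#' @param labels Class label per id.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold index per id (in the order of `ids`).
#' @export
stratified_folds <- function(ids, labels, k, seed) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  fold <- stats::setNames(integer(length(ids)), ids)
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(as.character(labels)))) {
      members <- sort(ids[labels == cl])
      members <- sample(members)
      idx <- ((seq_along(members) - 1L + offset) %% k) + 1L
      fold[members] <- idx
      offset <- (offset + length(members)) %% k
    }
  })
  fold[as.character(ids)]
}

#' Leakage-free k-fold cross-validated PLS-DA predictions
#'
#' Folds are assigned by seeded stratified sampling keyed on sample ids.
#' For each fold, the model (including its centering/autoscaling
#' parameters) is refitted on the remaining samples only, then predicts
#' the held-out fold; every sample is predicted exactly once. Returned
#' values are discriminant scores as defined in [predict_class()]
#' (centered predictions; sign gives the class call at threshold 0).
#'
#' @param X Numeric matrix, raw scale; row names are sample ids.
#' @param labels Two-class labels.
#' @param k Number of folds (default 7).
#' @param n_lv Latent variables.
#' @param positive,scale Passed to [fit_plsda()].
#' @param seed Integer seed for the fold assignment.
#' @return Numeric vector of continuous cross-validated predictions,
#'   named by sample id, in the row order of `X`.
#' @export
kfold_cv_predict <- function(X, labels, k = 7, n_lv = 2, positive = NULL,
                             scale = c("autoscale", "center"), seed = 1L) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  if (k < 2) stop("k must be >= 2")
  ids <- rownames(X)
  fold <- stratified_folds(ids, labels, k, seed)
  preds <- stats::setNames(rep(NA_real_, nrow(X)), ids)
  for (f in seq_len(k)) {
    test <- fold == f
    if (!any(test)) next
    if (length(unique(labels[!test])) < 2) {
      stop("a class is absent from the training split of fold ", f,
           "; use a smaller k")
    }
    m <- fit_plsda(X[!test, , drop = FALSE], labels[!test], n_lv = n_lv,
                   positive = positive, scale = scale)
    preds[test] <- predict_class(m, X[test, , drop = FALSE])$score
  }
  preds
}
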