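#' Orthogonal signal correction
#'
#' Iteratively removes from a centered data matrix the high-variance
#' component(s) whose scores are orthogonal to the class vector (Wold-style
#' OSC). Each component starts from the first principal-component score,
#' alternates (orthogonalize to `y`) -> (regress weights) -> (rebuild
#' score) to convergence, is orthogonalized against `y` a final time, and
#' is deflated from `X` via its loading.
#'
#' If `X` carries no variation orthogonal to `y` (e.g. every column is a
#' multiple of `y`) the component degenerates to zero and `X` is returned
#' unchanged for that component.
#'
#' @param X Centered numeric matrix (samples x features).
#' @param y Class vector (+1/-1 coding, or any centered numeric).
#' @param n_osc Number of components to remove (default 1).
#' @param tol Relative convergence tolerance on the score vector.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   iteration diagnostics.
#' @return A list with `X_corrected` and `filter` (class `osc_filter`,
#'   holding per-component weights `w`, loadings `p`, scores `t`, the
#'   removed variance, and the tolerances), usable on new data via
#'   [apply_osc()].
#' @export
osc_correct <- function(X, y, n_osc = 1, tol = 1e-8, max_iter = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (sum(y^2) == 0) stop("y is all zero")
  comps <- list()
  Xc <- X
  for (comp in seq_len(n_osc)) {
    sv <- svd(Xc, nu = 1, nv = 0)
    t_cur <- sv$u[, 1] * sv$d[1]
    iter <- 0L
    repeat {
      iter <- iter + 1L
      t_star <- t_cur - y * sum(y * t_cur) / sum(y^2)
      w <- crossprod(Xc, t_star)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-12 * max(1, sqrt(sum(Xc^2)))) {
        # no variation orthogonal to y left: degenerate component
        w <- NULL
        break
      }
      w <- w / wn
      t_new <- as.numeric(Xc %*% w)
      delta <- sqrt(sum((t_new - t_cur)^2)) / sqrt(sum(t_new^2))
      t_cur <- t_new
      if (delta < tol) break
      if (iter >= max_iter) {
        stop("OSC component ", comp, " did not converge in ", max_iter,
             " iterations (last relative change ", signif(delta, 3), ")")
      }
    }
    if (is.null(w)) {
      comps[[comp]] <- list(w = rep(0, ncol(Xc)), p = rep(0, ncol(Xc)),
                            t = rep(0, nrow(Xc)), removed_variance = 0,
                            iterations = iter, degenerate = TRUE)
      next
    }
    t_osc <- t_cur - y * sum(y * t_cur) / sum(y^2)  # exact orthogonality
    ss <- sum(t_osc^2)
    if (ss < 1e-24) {
      comps[[comp]] <- list(w = rep(0, ncol(Xc)), p = rep(0, ncol(Xc)),
                            t = rep(0, nrow(Xc)), removed_variance = 0,
                            iterations = iter, degenerate = TRUE)
      next
    }
    p_osc <- as.numeric(crossprod(Xc, t_osc) / ss)
    removed <- t_osc %*% t(p_osc)
    Xc <- Xc - removed
    comps[[comp]] <- list(w = as.numeric(w), p = p_osc, t = t_osc,
                          removed_variance = sum(removed^2),
                          iterations = iter, degenerate = FALSE)
  }
  filter <- structure(list(n_osc = n_osc, components = comps,
                           tol = tol, max_iter = max_iter),
                      class = "osc_filter")
  list(X_corrected = Xc, filter = filter)
}

#' Apply a fitted OSC filter to new (centered) data
#'
#' @param f An `osc_filter` from [osc_correct()].
#' @param X_new Numeric matrix, centered with the training parameters.
#' @return The corrected matrix.
#' @export
apply_osc <- function(f, X_new) {
  stopifnot(inherits(f, "osc_filter"))
  X_new <- as.matrix(X_new)
  for (cmp in f$components) {
    if (cmp$degenerate) next
    t_new <- as.numeric(X_new %*% cmp$w)
    X_new <- X_new - t_new %*% t(cmp$p)
  }
  X_new
}

#' ROC curve and AUC from continuous scores
#'
#' The AUC is the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, with ties counting one half; the curve comes from a
#' threshold sweep over the unique scores.
#'
#' @param scores Continuous classifier outputs (larger = more positive).
#' @param labels Two-class labels.
#' @param positive Positive-class label (defaults as in [fit_plsda()]).
#' @return An object of class `roc_curve`: `points` (data.frame `fpr`,
#'   `tpr`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes, got ",
                                 length(classes))
  positive <- positive %||% classes[1]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("one class is empty")
  r <- rank(scores, ties.method = "average")
  U <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  auc <- U / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(th) {
    c(fpr = sum(!pos & scores >= th) / n_neg,
      tpr = sum(pos & scores >= th) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  pts <- rbind(c(0, 0), pts)
  if (pts[nrow(pts), 1] < 1 || pts[nrow(pts), 2] < 1) pts <- rbind(pts, c(1, 1))
  structure(list(points = data.frame(fpr = pts[, 1], tpr = pts[, 2]),
                 auc = auc, positive = positive,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (positive class '%s', %d vs %d)\n",
              x$auc, x$positive, x$n_pos, x$n_neg))
  invisible(x)
}

#' Write a ROC curve as TSV
#'
#' @param roc A `roc_curve`.
#' @param path Output path.
#' @export
write_roc <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
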