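#' Confusion matrix for a two-class problem
#'
#' @param tp,fn,fp,tn Non-negative counts, with the case (e.g. HCC) as the
#'   positive class: `tp` positives called positive, `fn` positives called
#'   negative, `fp` negatives called positive, `tn` negatives called
#'   negative.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("confusion-matrix counts must be >= 0")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Tally a confusion matrix from predicted and true labels
#'
#' @param predicted,truth Label vectors of equal length.
#' @param positive Positive-class label.
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(predicted, truth, positive) {
  stopifnot(length(predicted) == length(truth))
  p <- predicted == positive
  t_ <- truth == positive
  confusion_matrix(tp = sum(p & t_), fn = sum(!p & t_),
                   fp = sum(p & !t_), tn = sum(!p & !t_))
}

#' Sensitivity and specificity of a confusion matrix
#'
#' Sensitivity = tp / (tp + fn); specificity = tn / (fp + tn).
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivity_specificity <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) stop("no positive-class predictions to score")
  if (cm$fp + cm$tn == 0) stop("no negative-class predictions to score")
  c(sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$fp + cm$tn))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(true = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
  invisible(x)
}

# one MCCV iteration: stratified 60/40 split, internal k-fold CV calls on
# the training samples + external calls on the validation samples.
# Returns the per-sample class calls (aligned with `labels`).
.mccv_iteration <- function(X, labels, train_frac, k_internal, n_lv,
                            positive, scale) {
  ids <- rownames(X)
  train <- logical(length(ids))
  for (cl in sort(unique(labels))) {
    members <- sort(ids[labels == cl])
    members <- sample(members)
    n_train <- round(train_frac * length(members))
    if (n_train < 2 || n_train > length(members) - 1) {
      stop("train_frac ", train_frac, " leaves class '", cl,
           "' without train or test samples")
    }
    train[ids %in% members[seq_len(n_train)]] <- TRUE
  }
  internal_seed <- sample.int(2147483645L, 1)
  cv_scores <- kfold_cv_predict(X[train, , drop = FALSE], labels[train],
                                k = k_internal, n_lv = n_lv,
                                positive = positive, scale = scale,
                                seed = internal_seed)
  model <- fit_plsda(X[train, , drop = FALSE], labels[train], n_lv = n_lv,
                     positive = positive, scale = scale)
  ext <- predict_class(model, X[!train, , drop = FALSE])
  calls <- character(length(ids))
  calls[train] <- ifelse(cv_scores >= 0, model$positive, model$negative)
  calls[!train] <- ext$class
  calls
}

#' Monte-Carlo cross-validation of a PLS-DA model
#'
#' Repeats `n_iter` times: (1) a seeded stratified split into a training
#' set (`train_frac`, default 60%) and a validation set; (2) PLS-DA with
#' `k_internal`-fold internal cross-validation producing a class call for
#' every training sample; (3) the model fitted on the full training set
#' predicts every validation sample. The internal-CV calls and the external
#' calls together give one class call per sample per iteration; those calls
#' accumulate into one aggregated confusion matrix (so its row totals are
#' exactly `n_pos * n_iter` and `n_neg * n_iter`), and per-iteration
#' sensitivity/specificity pairs are recorded.
#'
#' All randomness derives from `seed` through one sub-seed per iteration,
#' so any single iteration can be replayed in isolation.
#'
#' @param X Numeric matrix (samples x features), raw scale; row names are
#'   sample ids.
#' @param labels Two-class labels.
#' @param n_iter Number of Monte-Carlo iterations (default 200).
#' @param train_frac Training fraction of each class (default 0.6; class
#'   training sizes are `round(train_frac * n_class)`).
#' @param k_internal Internal cross-validation folds (default 7).
#' @param n_lv Latent variables.
#' @param positive Positive-class label.
#' @param scale `"autoscale"` or `"center"` (see [fit_plsda()]).
#' @param seed Master seed.
#' @param permute Permute the labels afresh each iteration (the
#'   permutation null)? Use [permutation_mccv()] for the documented
#'   interface.
#' @return An object of class `mccv_result`: aggregated
#'   [confusion_matrix()], `per_iteration` (n_iter x 2 matrix of
#'   sensitivity/specificity), `n_iter`, `train_frac`, `seed`,
#'   `iteration_seeds`, `positive`, and (for permutation runs)
#'   `permutations`, a matrix whose rows are the permuted label vectors.
#' @export
mccv <- function(X, labels, n_iter = 200, train_frac = 0.6, k_internal = 7,
                 n_lv = 2, positive = NULL, scale = c("autoscale", "center"),
                 seed = 1L, permute = FALSE) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes")
  positive <- positive %||% classes[1]
  iter_seeds <- derive_seeds(seed, n_iter)
  agg <- c(tp = 0, fn = 0, fp = 0, tn = 0)
  per_iter <- matrix(NA_real_, n_iter, 2,
                     dimnames = list(NULL, c("sensitivity", "specificity")))
  perms <- if (permute) matrix(NA_character_, n_iter, length(labels)) else NULL
  for (i in seq_len(n_iter)) {
    with_seed(iter_seeds[i], {
      labs_i <- if (permute) sample(labels) else labels
      if (permute) perms[i, ] <- labs_i
      calls <- .mccv_iteration(X, labs_i, train_frac, k_internal, n_lv,
                               positive, scale)
      cm_i <- confusion_from_labels(calls, labs_i, positive)
      agg <- agg + c(tp = cm_i$tp, fn = cm_i$fn, fp = cm_i$fp, tn = cm_i$tn)
      per_iter[i, ] <- sensitivity_specificity(cm_i)
    })
  }
  structure(
    list(confusion = confusion_matrix(agg["tp"], agg["fn"],
                                      agg["fp"], agg["tn"]),
         per_iteration = per_iter, n_iter = n_iter, train_frac = train_frac,
         k_internal = k_internal, n_lv = n_lv, seed = seed,
         iteration_seeds = iter_seeds, positive = positive,
         permuted = permute, permutations = perms),
    class = "mccv_result"
  )
}

#' Permutation-null Monte-Carlo cross-validation
#'
#' Each iteration draws a fresh uniform permutation of the label vector
#' (class counts preserved) and runs one full MCCV iteration against the
#' permuted labels; aggregation is identical to [mccv()]. The result
#' estimates the no-association performance level.
#'
#' @inheritParams mccv
#' @return An `mccv_result` with `permuted = TRUE` and the per-iteration
#'   permutations recorded.
#' @export
permutation_mccv <- function(X, labels, n_iter = 200, train_frac = 0.6,
                             k_internal = 7, n_lv = 2, positive = NULL,
                             scale = c("autoscale", "center"), seed = 1L) {
  mccv(X, labels, n_iter = n_iter, train_frac = train_frac,
       k_internal = k_internal, n_lv = n_lv, positive = positive,
       scale = scale, seed = seed, permute = TRUE)
}

#' @export
print.mccv_result <- function(x, ...) {
  ss <- sensitivity_specificity(x$confusion)
  cat(sprintf("<mccv_result>%s %d iterations, positive class '%s'\n",
              if (x$permuted) " (permutation null)" else "",
              x$n_iter, x$positive))
  cat(sprintf("  aggregated sensitivity %.3f, specificity %.3f\n",
              ss[1], ss[2]))
  invisible(x)
}

#' Format aggregated MCCV confusion counts as a publication-style table
#'
#' Rows are true classes, columns predicted classes; permutation counts,
#' if supplied, appear in parentheses next to the true-model counts.
#'
#' @param true_res `mccv_result` of the true-label run.
#' @param perm_res Optional `mccv_result` of the permutation run.
#' @param negative Negative-class display label.
#' @return A character matrix ready for printing / writing.
#' @export
format_confusion_table <- function(true_res, perm_res = NULL,
                                   negative = NULL) {
  cm <- true_res$confusion
  pos <- true_res$positive
  neg <- negative %||% "other"
  fmt <- function(a, b) if (is.null(b)) format(a) else sprintf("%d (%d)", a, b)
  pm <- if (is.null(perm_res)) list(tp = NULL, fn = NULL, fp = NULL, tn = NULL)
        else perm_res$confusion
  out <- matrix(c(fmt(cm$tp + cm$fn, if (is.null(perm_res)) NULL
                      else pm$tp + pm$fn),
                  fmt(cm$tp, pm$tp), fmt(cm$fn, pm$fn),
                  fmt(cm$fp + cm$tn, if (is.null(perm_res)) NULL
                      else pm$fp + pm$tn),
                  fmt(cm$fp, pm$fp), fmt(cm$tn, pm$tn)),
                nrow = 2, byrow = TRUE,
                dimnames = list(`True class` = c(pos, neg),
                                c("Total", pos, neg)))
  out
}

#' Serialize MCCV results (true + permutation) to JSON
#'
#' @param true_res,perm_res `mccv_result` objects.
#' @param path Output path.
#' @param extra Optional named list merged into the JSON root.
#' @export
write_mccv_json <- function(true_res, perm_res = NULL, path, extra = list()) {
  pack <- function(r) {
    if (is.null(r)) return(NULL)
    ss <- sensitivity_specificity(r$confusion)
    list(confusion = list(tp = r$confusion$tp, fn = r$confusion$fn,
                          fp = r$confusion$fp, tn = r$confusion$tn),
         sensitivity = unname(ss[1]), specificity = unname(ss[2]),
         n_iter = r$n_iter, train_frac = r$train_frac,
         k_internal = r$k_internal, n_lv = r$n_lv, seed = r$seed,
         per_iteration = unname(as.data.frame(r$per_iteration)))
  }
  obj <- c(list(true_model = pack(true_res), permutation = pack(perm_res)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
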