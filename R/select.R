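#' Classic (equal-variance) two-sample Student's t-test
#'
#' Pooled-variance unpaired t statistic with `df = n_a + n_b - 2` and a
#' two-sided p-value from the t distribution. Implemented from the closed
#' form (not delegated) so it can be cross-checked against a reference
#' statistics library.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return A list with `t`, `df`, `p`.
#' @export
unpaired_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) stop("pooled variance is zero")
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Signed fold change between two groups
#'
#' Ratio of raw-scale group means `r = mean(pos) / mean(neg)`, reported as
#' `+r` when the positive class is elevated (`r >= 1`) and `-1/r` when the
#' negative class is elevated, so `|fold change| >= 1` always and the sign
#' says which group is up.
#'
#' @param pos,neg Numeric vectors of raw-scale (uncentered) values.
#' @return Signed fold change.
#' @export
fold_change <- function(pos, neg) {
  mp <- mean(pos); mn <- mean(neg)
  if (mp <= 0 || mn <= 0) {
    stop("group means must be positive: fold changes need a raw-scale ",
         "(uncentered) feature table")
  }
  r <- mp / mn
  if (r >= 1) r else -1 / r
}

#' Univariate screening of a raw feature table
#'
#' Per-feature Student's t-test and signed fold change between the two
#' classes, computed on raw integrals. Features with `p < alpha` are
#' selected (uncorrected by default, mirroring a deliberately permissive
#' biomarker screen); Bonferroni or Benjamini-Hochberg adjusted p-values
#' are available via `correction`. Degenerate features (zero pooled
#' variance, non-positive means) are recorded as failed with a warning and
#' excluded, never silently dropped.
#'
#' @param t A raw [feature_table()] with labels, or a matrix plus `labels`.
#' @param labels Two-class labels (if `t` carries none).
#' @param alpha Selection threshold on the (possibly adjusted) p-value.
#' @param correction `"none"` (default), `"bonferroni"` or `"BH"`.
#' @param positive Positive-class label.
#' @return An object of class `selection_result`: `stats` (data.frame
#'   ordered by ascending p: feature, t, df, p, p_adjusted, fold_change,
#'   mean_pos, mean_neg), `selected` (feature names with p < alpha),
#'   `alpha`, `failed` (names of degenerate features).
#' @export
select_features <- function(t, labels = NULL, alpha = 0.05,
                            correction = c("none", "bonferroni", "BH"),
                            positive = NULL) {
  correction <- match.arg(correction)
  if (inherits(t, "feature_table")) {
    if (t$scaling_state != "raw") {
      stop("feature selection needs the raw-scale table, not ",
           t$scaling_state)
    }
    labels <- labels %||% t$labels
    X <- t$values
  } else {
    X <- as.matrix(t)
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("need exactly two classes")
  positive <- positive %||% classes[1]
  pos <- labels == positive
  rows <- list(); failed <- character(0)
  for (f in colnames(X)) {
    res <- tryCatch({
      tt <- unpaired_ttest(X[pos, f], X[!pos, f])
      fc <- fold_change(X[pos, f], X[!pos, f])
      data.frame(feature = f, t = tt$t, df = tt$df, p = tt$p,
                 fold_change = fc, mean_pos = mean(X[pos, f]),
                 mean_neg = mean(X[!pos, f]), stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("feature '", f, "' skipped: ", conditionMessage(res),
              call. = FALSE)
      failed <- c(failed, f)
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  stats_df <- do.call(rbind, rows)
  if (is.null(stats_df)) stop("no feature could be tested")
  stats_df$p_adjusted <- if (correction == "none") stats_df$p
                         else stats::p.adjust(stats_df$p, method = correction)
  stats_df <- stats_df[order(stats_df$p), , drop = FALSE]
  rownames(stats_df) <- NULL
  structure(
    list(stats = stats_df,
         selected = stats_df$feature[stats_df$p_adjusted < alpha],
         alpha = alpha, correction = correction, positive = positive,
         failed = failed),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d/%d features with p < %g (%s)\n",
              length(x$selected), nrow(x$stats), x$alpha, x$correction))
  print(utils::head(x$stats, 5))
  invisible(x)
}

#' Write a biomarker screen as a summary TSV
#'
#' Columns mirror a typical published marker table: metabolite, chemical
#' shift, multiplicity, p-value, fold change. Shift/multiplicity are taken
#' from the supplied library where the feature name matches.
#'
#' @param sel A `selection_result`.
#' @param path Output path.
#' @param lib Optional metabolite library for shift/multiplicity lookup.
#' @param selected_only Write only the selected features?
#' @export
write_selection_tsv <- function(sel, path, lib = NULL,
                                selected_only = FALSE) {
  df <- sel$stats
  if (selected_only) df <- df[df$feature %in% sel$selected, , drop = FALSE]
  out <- data.frame(Metabolite = df$feature,
                    `Chemical Shift (ppm)` = NA_real_,
                    Multiplicity = NA_character_,
                    `p-value` = df$p,
                    `Fold change` = df$fold_change,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(lib)) {
    first <- lib[!duplicated(lib$name), ]
    idx <- match(out$Metabolite, first$name)
    out$`Chemical Shift (ppm)` <- first$center_ppm[idx]
    out$Multiplicity <- first$multiplicity[idx]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
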