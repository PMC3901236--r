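#' Save a fitted PLS(-DA) model to JSON
#'
#' Serializes every quantity needed to transform and score new samples
#' (weights, loadings, y-loadings, regression vector, centering/scaling
#' parameters, class coding), so a reloaded model predicts identically.
#'
#' @param m A `pls_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "pls_model"))
  obj <- list(
    class = "pls_model", n_lv = m$n_lv,
    W = unname(m$W), P = unname(m$P),
    q = m$q, B = m$B,
    x_center = as.list(stats::setNames(m$x_center, m$features)),
    x_scale = as.list(stats::setNames(m$x_scale, m$features)),
    scaled = m$scaled, y_center = m$y_center,
    features = m$features,
    positive = m$positive, negative = m$negative,
    scale_mode = m$scale_mode
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a PLS(-DA) model saved by [save_model()]
#'
#' @param path JSON path.
#' @return A `pls_model`.
#' @export
load_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$class, "pls_model")) stop("not a saved pls_model: ", path)
  W <- as.matrix(o$W)
  P <- as.matrix(o$P)
  m <- structure(
    list(n_lv = o$n_lv, W = W, P = P, T = NULL, q = as.numeric(o$q),
         B = as.numeric(o$B),
         x_center = unlist(o$x_center), x_scale = unlist(o$x_scale),
         scaled = isTRUE(o$scaled), y_center = o$y_center,
         rank = NA_integer_, features = o$features,
         positive = o$positive, negative = o$negative,
         scale_mode = o$scale_mode),
    class = "pls_model"
  )
  names(m$x_center) <- o$features
  names(m$x_scale) <- o$features
  m
}
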