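#' Construct a 1D NMR spectrum
#'
#' A spectrum is a strictly descending chemical-shift axis (ppm, as spectra
#' are conventionally plotted) with one intensity per point, plus metadata.
#'
#' @param ppm Numeric vector, strictly monotone descending chemical shifts.
#' @param intensity Numeric vector, same length as `ppm`.
#' @param sample_id Character scalar identifying the sample.
#' @param meta Named list of free-form metadata (alignment shift, seeds, ...).
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(ppm, intensity, sample_id = "sample", meta = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) < 2L) stop("a spectrum needs at least two points")
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity lengths differ")
  }
  if (any(diff(ppm) >= 0)) stop("ppm axis must be strictly monotone descending")
  if (anyNA(ppm) || anyNA(intensity)) stop("NA values in spectrum")
  structure(
    list(ppm = ppm, intensity = intensity,
         sample_id = as.character(sample_id), meta = meta),
    class = "raw_spectrum"
  )
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> %s: %d points, %.3f .. %.3f ppm\n",
              x$sample_id, length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Read a spectrum from a two-column (ppm, intensity) CSV file
#'
#' @param path File path. The file must have a header with columns
#'   `ppm` and `intensity` (descending ppm).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [raw_spectrum()].
#' @export
read_spectrum_csv <- function(path, sample_id = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("ppm", "intensity") %in% names(d))) {
    stop("expected columns 'ppm' and 'intensity' in ", path)
  }
  raw_spectrum(d$ppm, d$intensity,
               sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a spectrum to a two-column CSV file
#'
#' @param s A [raw_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "raw_spectrum"))
  utils::write.csv(data.frame(ppm = s$ppm, intensity = s$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a simple JCAMP-DX 1D spectrum
#'
#' Minimal reader for uncompressed JCAMP-DX files whose data block is
#' `##XYDATA=(X++(Y..Y))` with plain (AFFN) numbers: each data line holds an
#' abscissa value followed by consecutive ordinates on an evenly spaced grid.
#' `##XFACTOR`/`##YFACTOR` are applied; compressed (SQZ/DIF/DUP) encodings
#' are not supported.
#'
#' @param path File path.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A [raw_spectrum()] (axis flipped to descending if needed).
#' @export
read_jdx <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name, default = NA_real_) {
    hit <- grep(paste0("^##", name, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", name, "="), "", hit[1]))
  }
  xfac <- ldr("XFACTOR", 1)
  yfac <- ldr("YFACTOR", 1)
  i0 <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(i0)) stop("no ##XYDATA=(X++(Y..Y)) block in ", path)
  iend <- grep("^##", lines)
  iend <- iend[iend > i0[1]]
  body <- lines[(i0[1] + 1):(if (length(iend)) iend[1] - 1 else length(lines))]
  xs <- c(); ys <- c()
  for (ln in body) {
    v <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    if (length(v) < 2 || anyNA(v)) next
    xs <- c(xs, v[1]); ys <- c(ys, list(v[-1]))
  }
  if (length(xs) < 2) stop("could not parse XYDATA block in ", path)
  # even grid step from consecutive line starts
  npl <- lengths(ys)
  step <- (xs[2] - xs[1]) / npl[1]
  ppm <- unlist(lapply(seq_along(xs), function(i) {
    xs[i] + step * (seq_len(npl[i]) - 1)
  })) * xfac
  y <- unlist(ys) * yfac
  if (ppm[1] < ppm[length(ppm)]) { ppm <- rev(ppm); y <- rev(y) }
  raw_spectrum(ppm, y, sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}
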