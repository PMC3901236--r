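#' Default serum metabolite library
#'
#' One row per resonance (a metabolite may contribute several multiplets).
#' The library lists 19 small-molecule metabolites routinely quantified in
#' CPMG serum spectra, plus the TSP chemical-shift/quantitation reference
#' singlet at 0.0 ppm. The three study biomarkers carry their literature
#' shifts and multiplicities (choline 3.20 s, valine 1.03 d,
#' creatinine 3.03 s); the remaining members are common serum metabolites
#' placed at their usual shifts, with multiplet patterns simplified where
#' needed so that the default integration regions stay pairwise disjoint.
#' Mean concentrations are in arbitrary units chosen to echo the relative
#' dynamic range of serum (glucose and lactate dominant, free choline weak).
#'
#' Columns: `name`, `center_ppm`, `multiplicity` (s/d/t/q/m), `J_hz`,
#' `linewidth_hz` (FWHM), `rel_intensity` (area weight within the
#' metabolite), `mean_conc`, `bio_cv` (between-subject coefficient of
#' variation of concentration).
#'
#' @return A `data.frame` of class `metabolite_library`.
#' @export
default_metabolite_library <- function() {
  lib <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name            center_ppm multiplicity J_hz linewidth_hz rel_intensity mean_conc bio_cv
TSP             0.000      s            0.0  1.2          1.00          1.00      0.00
isoleucine      0.930      t            7.4  1.2          1.00          0.06      0.30
leucine         0.970      d            6.8  1.2          1.00          0.13      0.30
valine          1.030      d            7.0  1.2          1.00          0.22      0.30
hydroxybutyrate 1.200      d            6.3  1.2          1.00          0.08      0.30
lactate         1.330      d            6.9  1.2          0.75          1.50      0.30
lactate         4.110      q            6.9  1.2          0.25          1.50      0.30
alanine         1.479      d            7.2  1.2          1.00          0.35      0.30
acetate         1.920      s            0.0  1.2          1.00          0.05      0.30
acetone         2.230      s            0.0  1.2          1.00          0.03      0.30
glutamate       2.350      m            0.0  2.5          1.00          0.08      0.30
glutamine       2.450      m            0.0  2.5          1.00          0.50      0.30
citrate         2.540      d           16.0  1.5          1.00          0.10      0.30
asparagine      2.870      m            0.0  2.5          1.00          0.04      0.30
creatinine      3.030      s            0.0  1.2          1.00          0.07      0.30
choline         3.200      s            0.0  1.2          1.00          0.03      0.30
glycine         3.560      s            0.0  1.2          1.00          0.25      0.30
glucose         3.720      m            0.0  3.0          0.85          5.00      0.30
glucose         4.650      d            7.9  1.2          0.15          5.00      0.30
creatine        3.930      s            0.0  1.2          1.00          0.04      0.30
histidine       7.070      s            0.0  1.5          1.00          0.08      0.30
formate         8.450      s            0.0  1.2          1.00          0.02      0.30
")
  validate_library(lib)
}

#' Validate a metabolite library table
#'
#' @param lib Data frame with the columns documented in
#'   [default_metabolite_library()].
#' @return The validated library, classed `metabolite_library`.
#' @export
validate_library <- function(lib) {
  need <- c("name", "center_ppm", "multiplicity", "J_hz", "linewidth_hz",
            "rel_intensity", "mean_conc", "bio_cv")
  miss <- setdiff(need, names(lib))
  if (length(miss)) stop("library is missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(lib$multiplicity %in% c("s", "d", "t", "q", "m"))) {
    stop("multiplicity must be one of s, d, t, q, m")
  }
  if (any(lib$linewidth_hz <= 0)) stop("linewidth_hz must be > 0")
  if (any(lib$J_hz < 0)) stop("J_hz must be >= 0")
  if (any(lib$rel_intensity <= 0)) stop("rel_intensity must be > 0")
  if (any(lib$mean_conc <= 0)) stop("mean_conc must be > 0")
  if (any(lib$bio_cv < 0 | lib$bio_cv >= 1)) stop("bio_cv must be in [0, 1)")
  # per-metabolite concentration parameters must agree across its peaks
  for (nm in unique(lib$name)) {
    rows <- lib[lib$name == nm, ]
    if (length(unique(rows$mean_conc)) > 1 || length(unique(rows$bio_cv)) > 1) {
      stop("inconsistent mean_conc/bio_cv for metabolite '", nm, "'")
    }
  }
  class(lib) <- c("metabolite_library", "data.frame")
  lib
}

#' Names of the quantified metabolites in a library
#'
#' @param lib A metabolite library.
#' @param exclude_reference Drop the TSP reference (default TRUE).
#' @return Character vector of metabolite names, in library order.
#' @export
library_metabolites <- function(lib, exclude_reference = TRUE) {
  nm <- unique(lib$name)
  if (exclude_reference) nm <- setdiff(nm, "TSP")
  nm
}

#' Read / write a metabolite library as TSV
#'
#' @param path File path.
#' @return `read_library` returns a validated library;
#'   `write_library` returns `path` invisibly.
#' @export
read_library <- function(path) {
  validate_library(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_library
#' @param lib A metabolite library.
#' @export
write_library <- function(lib, path) {
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default targeted integration regions
#'
#' One disjoint chemical-shift window per quantified metabolite of the
#' default library (19 regions), centred on the metabolite's reporter
#' multiplet and sized to hold it at the default linewidths. All windows
#' avoid the residual-water region (4.7-5.2 ppm). The exact windows of the
#' original targeted analyses are study-specific; these defaults are tied to
#' the default simulator library and are fully configurable.
#'
#' @return A `data.frame` with columns `name`, `lo`, `hi` (ppm, `lo < hi`).
#' @export
default_regions <- function() {
  r <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
name            lo     hi
isoleucine      0.905  0.955
leucine         0.956  1.000
valine          1.005  1.055
hydroxybutyrate 1.175  1.225
lactate         1.305  1.355
alanine         1.454  1.504
acetate         1.895  1.945
acetone         2.205  2.255
glutamate       2.320  2.380
glutamine       2.420  2.480
citrate         2.505  2.575
asparagine      2.840  2.900
creatinine      3.005  3.055
choline         3.175  3.225
glycine         3.535  3.585
glucose         3.650  3.790
creatine        3.905  3.955
histidine       7.045  7.095
formate         8.425  8.475
")
  validate_regions(r)
}

#' Validate a region table
#'
#' @param r Data frame with columns `name`, `lo`, `hi`.
#' @return The validated table.
#' @export
validate_regions <- function(r) {
  stopifnot(all(c("name", "lo", "hi") %in% names(r)))
  if (any(r$lo >= r$hi)) stop("regions must have lo < hi")
  if (anyDuplicated(r$name)) stop("duplicate region names")
  o <- order(r$lo)
  lo <- r$lo[o]; hi <- r$hi[o]
  if (any(lo[-1] < hi[-length(hi)])) {
    stop("regions overlap: targeted regions must be pairwise disjoint")
  }
  r
}

#' Read / write a region table as TSV
#'
#' @param path File path.
#' @return `read_regions` returns a validated region table.
#' @export
read_regions <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(r)[names(r) == "lo_ppm"] <- "lo"
  names(r)[names(r) == "hi_ppm"] <- "hi"
  validate_regions(r)
}

#' @rdname read_regions
#' @param r A region table.
#' @export
write_regions <- function(r, path) {
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
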