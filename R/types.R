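# Lightweight containers. Plain data frames / lists with a class attribute
# and validated invariants, in the style of base scientific R.

#' Relaxation decay series for one residue
#'
#' @param residue_id Integer residue number.
#' @param delays Relaxation delays, seconds (non-negative).
#' @param intensities Peak intensities, arbitrary units (same length).
#' @param replicate_id Integer replicate index.
#' @return A `relaxation_series` object.
#' @export
relaxation_series <- function(residue_id, delays, intensities,
                              replicate_id = 1L) {
  if (length(delays) != length(intensities))
    abort_field("intensities", "must match `delays` in length")
  if (any(delays < 0)) abort_field("delays", "must be non-negative")
  structure(list(residue_id = as.integer(residue_id),
                 delays = as.numeric(delays),
                 intensities = as.numeric(intensities),
                 replicate_id = as.integer(replicate_id)),
            class = "relaxation_series")
}

#' @export
print.relaxation_series <- function(x, ...) {
  cat(sprintf("<relaxation_series> residue %d, replicate %d, %d delays\n",
              x$residue_id, x$replicate_id, length(x$delays)))
  invisible(x)
}

#' Thermal-shift melt curve
#'
#' @param temperatures Strictly increasing temperatures, degC.
#' @param fluorescence Fluorescence readings, arbitrary units.
#' @param replicate_id Integer replicate index.
#' @param construct_label Construct name.
#' @return A `melt_curve` object.
#' @export
melt_curve <- function(temperatures, fluorescence, replicate_id = 1L,
                       construct_label = "construct") {
  if (length(temperatures) != length(fluorescence))
    abort_field("fluorescence", "must match `temperatures` in length")
  if (is.unsorted(temperatures, strictly = TRUE))
    abort_field("temperatures", "must be strictly increasing")
  structure(list(temperatures = as.numeric(temperatures),
                 fluorescence = as.numeric(fluorescence),
                 replicate_id = as.integer(replicate_id),
                 construct_label = construct_label),
            class = "melt_curve")
}

#' Assigned 2D peak list
#'
#' One row per assigned amide cross peak. Assignments are generated as
#' `"<residue>N-H"` when only residue numbers are given, and must be unique.
#'
#' @param residue Integer residue numbers.
#' @param w_H Proton chemical shifts, ppm.
#' @param w_N Nitrogen chemical shifts, ppm.
#' @param height Peak heights, arbitrary units.
#' @param assignment Optional assignment labels.
#' @return A data frame of class `peak_list`.
#' @export
peak_list <- function(residue, w_H, w_N, height,
                      assignment = paste0(residue, "N-H")) {
  df <- data.frame(assignment = assignment, residue = as.integer(residue),
                   w_H = w_H, w_N = w_N, height = height,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$assignment))
    abort_field("assignment", "labels must be unique within a peak list")
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Multi-model coordinate ensemble
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`, `atom`
#'   describing the (shared, ordered) atom roster.
#' @param coords Numeric array `n_atoms x 3 x n_models`.
#' @return An `ensemble` object.
#' @export
ensemble <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms),
            length(dim(coords)) == 3L,
            dim(coords)[1] == nrow(atoms), dim(coords)[2] == 3L)
  structure(list(atoms = atoms, coords = coords), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d models, %d atoms, residues %d-%d\n",
              dim(x$coords)[3], nrow(x$atoms),
              min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Number of models in an ensemble
#' @param ens An `ensemble`.
#' @return Integer model count.
#' @export
n_models <- function(ens) dim(ens$coords)[3]
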