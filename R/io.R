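# Readers and writers for the plain-text interchange formats of the
# pipeline: delay-series / melt-curve / rates CSV tables, Sparky-style
# peak lists and multi-model PDB files.

#' Write / read a relaxation delay-series table
#'
#' Long CSV with columns `residue`, `delay_s`, `intensity`, `replicate`.
#'
#' @param series_list List of [relaxation_series()] objects.
#' @param path File path.
#' @return `write_delay_csv` the path invisibly; `read_delay_csv` the table.
#' @export
write_delay_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(residue = s$residue_id, delay_s = s$delays,
               intensity = s$intensities, replicate = s$replicate_id))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_delay_csv
#' @export
read_delay_csv <- function(path) utils::read.csv(path)

#' Write / read a Sparky-style peak list
#'
#' Whitespace-separated text: assignment column first, then `w1` (15N,
#' ppm), `w2` (1H, ppm) and a height column. A header line starting with
#' `Assignment` and blank lines are skipped on read.
#'
#' @param peaks A [peak_list()].
#' @param path File path.
#' @return `write_sparky` the path invisibly; `read_sparky` a `peak_list`.
#' @export
write_sparky <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_list"))
  lines <- c(sprintf("%-12s %8s %8s %12s", "Assignment", "w1", "w2",
                     "Height"),
             sprintf("%-12s %8.3f %8.3f %12.4g", peaks$assignment,
                     peaks$w_N, peaks$w_H, peaks$height))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sparky
#' @export
read_sparky <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "Assignment")]
  f <- do.call(rbind, strsplit(lines, "\\s+"))
  res <- as.integer(sub("^[A-Za-z]*([0-9]+).*$", "\\1", f[, 1]))
  peak_list(residue = res,
            w_H = as.numeric(f[, 3]), w_N = as.numeric(f[, 2]),
            height = if (ncol(f) >= 4) as.numeric(f[, 4]) else NA_real_,
            assignment = f[, 1])
}

#' Write / read a melt-curve table
#'
#' CSV with columns `temperature_C`, `fluorescence`, `replicate`,
#' `construct` (the qPCR-export-like layout the fitters consume).
#'
#' @param curves List of [melt_curve()] objects.
#' @param path File path.
#' @return `write_melt_csv` the path invisibly; `read_melt_csv` the table.
#' @export
write_melt_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(temperature_C = cv$temperatures,
               fluorescence = cv$fluorescence,
               replicate = cv$replicate_id,
               construct = cv$construct_label))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melt_csv
#' @export
read_melt_csv <- function(path) utils::read.csv(path)

#' Write / read a per-residue rates table
#'
#' CSV with columns `residue`, `R1`, `R1_err`, `R2`, `R2_err`, `NOE`,
#' `NOE_err` -- the interchange between rate fitting and spectral density
#' mapping.
#'
#' @param rates Data frame in that layout.
#' @param path File path.
#' @return `write_rates_csv` the path invisibly; `read_rates_csv` the table.
#' @export
write_rates_csv <- function(rates, path) {
  utils::write.csv(rates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) utils::read.csv(path)

#' Read a multi-model PDB file as an ensemble
#'
#' Each MODEL block is parsed with `bio3d::read.pdb`. Alternate locations
#' are resolved to the first listed (deposited highest-occupancy) copy,
#' hydrogens are kept (selections filter them later), and the roster is
#' harmonized: atoms absent from any model are dropped with a message so
#' every model carries the identical, identically ordered atom set.
#'
#' @param path Path to a PDB file with MODEL/ENDMDL records.
#' @return An [ensemble()].
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) < 2L || length(starts) != length(ends))
    abort_field("path", "ensemble statistics need >= 2 MODEL records")
  models <- lapply(seq_along(starts), function(m) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(c(lines[(starts[m] + 1L):(ends[m] - 1L)], "END"), tf)
    at <- bio3d::read.pdb(tf, verbose = FALSE)$atom
    at <- at[at$type == "ATOM", , drop = FALSE]
    at$key <- paste(at$chain, at$resno, at$elety, sep = "|")
    at[!duplicated(at$key), , drop = FALSE]   # first alt-loc copy wins
  })
  roster <- Reduce(intersect, lapply(models, `[[`, "key"))
  n_dropped <- nrow(models[[1]]) - length(roster)
  if (n_dropped > 0L)
    message(n_dropped,
            " atom(s) missing from at least one model were dropped")
  roster <- models[[1]]$key[models[[1]]$key %in% roster]  # model-1 order
  coords <- array(NA_real_, dim = c(length(roster), 3, length(models)))
  for (m in seq_along(models)) {
    at <- models[[m]]
    i <- match(roster, at$key)
    coords[, , m] <- cbind(at$x[i], at$y[i], at$z[i])
  }
  a1 <- models[[1]][match(roster, models[[1]]$key), ]
  atoms <- data.frame(chain = a1$chain, resno = a1$resno,
                      resname = a1$resid, atom = a1$elety,
                      stringsAsFactors = FALSE)
  ensemble(atoms, coords)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Minimal fixed-width ATOM/MODEL/ENDMDL writer (sufficient for the
#' round-trip with [read_ensemble()]).
#'
#' @param ens An [ensemble()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  a <- ens$atoms
  for (m in seq_len(n_models(ens))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens$coords[, , m]
    name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                    sprintf("%-4s", a$atom))
    lines <- sprintf(
      "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(a)), name4, "", substr(a$resname, 1, 3),
      substr(a$chain, 1, 1), a$resno, "",
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
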