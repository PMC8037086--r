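# NOE distance-restraint bookkeeping: sequence-separation classification
# and the category counts reported in NMR structure-statistics tables.

#' Classify a restraint by sequence separation
#'
#' `|i - j| = 0` intra-residual, `1` sequential, `2-4` medium range,
#' `> 4` long range. Symmetric in `(i, j)`.
#'
#' @param residue_i,residue_j Integer residue numbers; vectorized.
#' @return Factor with levels `intra`, `sequential`, `medium`, `long`.
#' @examples
#' classify_restraint(50, c(50, 51, 53, 60))
#' @export
classify_restraint <- function(residue_i, residue_j) {
  sep <- abs(as.integer(residue_i) - as.integer(residue_j))
  lab <- ifelse(sep == 0, "intra",
         ifelse(sep == 1, "sequential",
         ifelse(sep <= 4, "medium", "long")))
  factor(lab, levels = c("intra", "sequential", "medium", "long"))
}

#' Count restraints per sequence-separation category
#'
#' @param records Data frame with columns `residue_i`, `residue_j`.
#' @return Named integer vector `intra`, `sequential`, `medium`, `long`,
#'   `total`; the categories partition the total exactly.
#' @export
summarize_restraints <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(c(intra = 0L, sequential = 0L, medium = 0L, long = 0L,
             total = 0L))
  cat <- classify_restraint(records$residue_i, records$residue_j)
  counts <- table(cat)
  c(intra = unname(counts[["intra"]]),
    sequential = unname(counts[["sequential"]]),
    medium = unname(counts[["medium"]]),
    long = unname(counts[["long"]]),
    total = nrow(records))
}

#' Read a tabular restraint list
#'
#' Simple CSV format: columns `residue_i`, `atom_i`, `residue_j`, `atom_j`
#' and optionally `bound` (upper distance bound, Angstrom).
#'
#' @param path File path.
#' @return Data frame with a `category` column attached.
#' @export
read_restraints_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("residue_i", "residue_j") %in% names(df)))
  df$category <- classify_restraint(df$residue_i, df$residue_j)
  df
}

#' Permissive reader for XPLOR/CYANA-style restraint text
#'
#' Extracts `(residue_i, residue_j)` pairs from `assign (resid I and ...)
#' (resid J and ...)` statements (XPLOR dialect, case-insensitive,
#' statements may span lines) or, failing that, from CYANA-style columnar
#' lines (`i resname atom j resname atom upper ...`). Ambiguous OR-group
#' restraints contribute one pair (the first); the
#' number of such restraints is reported via a message.
#'
#' @param path File path to the `.mr`-style text.
#' @return Data frame with `residue_i`, `residue_j`, `category`.
#' @export
read_restraints_mr <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*[!#]", txt)]
  joined <- paste(txt, collapse = "\n")
  pairs <- list()
  n_ambiguous <- 0L
  # XPLOR: assign (sel-i)(sel-j) bounds...; the first `resid` inside each
  # top-level parenthesis group defines the pair, so OR-groups collapse to
  # their first alternative
  top_level_groups <- function(stmt) {
    chars <- strsplit(stmt, "")[[1]]
    depth <- 0L; start <- NA_integer_; groups <- character()
    for (i in seq_along(chars)) {
      if (chars[i] == "(") {
        if (depth == 0L) start <- i
        depth <- depth + 1L
      } else if (chars[i] == ")") {
        depth <- depth - 1L
        if (depth == 0L && !is.na(start))
          groups <- c(groups, substr(stmt, start, i))
      }
    }
    groups
  }
  first_resid <- function(group) {
    m <- regmatches(group, regexpr("(?i)resid\\s+\\d+", group, perl = TRUE))
    if (length(m) == 0L) return(NA_integer_)
    as.integer(sub("(?i)resid\\s+", "", m, perl = TRUE))
  }
  starts <- gregexpr("(?i)assign", joined, perl = TRUE)[[1]]
  if (starts[1] != -1) {
    ends <- c(starts[-1], nchar(joined) + 1L)
    for (k in seq_along(starts)) {
      stmt <- substr(joined, starts[k], ends[k] - 1L)
      groups <- top_level_groups(stmt)
      if (length(groups) < 2L) next
      ids <- c(first_resid(groups[1]), first_resid(groups[2]))
      if (anyNA(ids)) next
      n_resid <- length(gregexpr("(?i)resid\\s+\\d+", stmt,
                                 perl = TRUE)[[1]])
      if (n_resid > 2L || grepl("(?i)\\bor\\b", stmt, perl = TRUE))
        n_ambiguous <- n_ambiguous + 1L
      pairs[[length(pairs) + 1L]] <- ids
    }
  } else {
    # CYANA-like: "i resname atom j resname atom upper"
    for (line in txt) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(f) >= 6 && !is.na(suppressWarnings(as.integer(f[1]))) &&
          !is.na(suppressWarnings(as.integer(f[4])))) {
        pairs[[length(pairs) + 1L]] <- c(as.integer(f[1]), as.integer(f[4]))
      }
    }
  }
  if (length(pairs) == 0L)
    return(data.frame(residue_i = integer(), residue_j = integer(),
                      category = classify_restraint(integer(), integer())))
  if (n_ambiguous > 0L)
    message(n_ambiguous,
            " ambiguous (OR-group) restraint(s) counted once by first pair")
  df <- as.data.frame(do.call(rbind, pairs))
  names(df) <- c("residue_i", "residue_j")
  df$category <- classify_restraint(df$residue_i, df$residue_j)
  df
}
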