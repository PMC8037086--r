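# Ensemble precision statistics: rigid-body superposition, iterative
# mean-structure RMSD, and atom selections matching the conventions of
# NMR structure tables.

#' Atom selection for ensemble statistics
#'
#' `"backbone"` selects atoms named N, CA, C (the common NMR-ensemble
#' convention; carbonyl O can be included with `include_O = TRUE`);
#' `"heavy"` selects all non-hydrogen atoms (names not starting with H,
#' nor digit-prefixed hydrogens such as `1HB`).
#'
#' @param mode `"backbone"` or `"heavy"`.
#' @param residue_range Inclusive residue range `c(first, last)` or `NULL`
#'   for all residues.
#' @param include_O Include carbonyl O in the backbone set.
#' @return An `atom_selection` object.
#' @export
atom_selection <- function(mode = c("backbone", "heavy"),
                           residue_range = NULL, include_O = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, residue_range = residue_range,
                 include_O = include_O),
            class = "atom_selection")
}

is_hydrogen <- function(atom) grepl("^[0-9]?H", atom)

#' Indices of atoms matching a selection
#'
#' @param ens An [ensemble()].
#' @param selection An [atom_selection()].
#' @return Integer atom indices into the ensemble roster.
#' @export
select_atoms <- function(ens, selection) {
  stopifnot(inherits(ens, "ensemble"), inherits(selection, "atom_selection"))
  a <- ens$atoms
  keep <- if (selection$mode == "backbone") {
    set <- c("N", "CA", "C", if (selection$include_O) "O")
    a$atom %in% set
  } else {
    !is_hydrogen(a$atom)
  }
  if (!is.null(selection$residue_range)) {
    keep <- keep & a$resno >= selection$residue_range[1] &
                   a$resno <= selection$residue_range[2]
  }
  which(keep)
}

# Kabsch superposition: proper rotation (det +1) minimizing RMSD of
# `mobile` onto `reference` (both n x 3), plus the translation.
kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, center_mobile = cm, center_reference = cr)
}

apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2, tr$center_mobile) %*% t(tr$rotation), 2,
        tr$center_reference, "+")
}

#' Superpose one model onto a reference
#'
#' Least-squares rigid-body superposition (Kabsch, proper rotation with
#' determinant +1) computed over the selected atoms and applied to all
#' atoms of the model.
#'
#' @param model Numeric `n_atoms x 3` coordinate matrix.
#' @param reference Matrix of the same shape.
#' @param sel_idx Integer indices of the atoms defining the fit (>= 3,
#'   non-degenerate geometry).
#' @return List with `coords` (transformed model), `rotation`,
#'   `translation` and `rmsd` (over the selection, after fitting).
#' @export
superpose <- function(model, reference, sel_idx = seq_len(nrow(model))) {
  stopifnot(nrow(model) == nrow(reference))
  if (length(sel_idx) < 3L)
    abort_field("sel_idx", "at least 3 atoms are required")
  P <- model[sel_idx, , drop = FALSE]
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2)
    abort_field("sel_idx", "selected atoms are geometrically degenerate")
  tr <- kabsch(P, reference[sel_idx, , drop = FALSE])
  out <- apply_transform(model, tr)
  rmsd <- sqrt(mean(rowSums((out[sel_idx, , drop = FALSE] -
                             reference[sel_idx, , drop = FALSE])^2)))
  list(coords = out, rotation = tr$rotation,
       translation = tr$center_reference -
         as.vector(tr$center_mobile %*% t(tr$rotation)),
       rmsd = rmsd)
}

#' RMSD of each model from the iteratively converged mean structure
#'
#' All models are superposed on model 1 over the selection, averaged, then
#' repeatedly re-superposed on the running mean until the mean moves by no
#' more than `tol` (RMS over selected coordinates; default 1e-6 Angstrom,
#' at most `max_iter` iterations). Reported per-model RMSDs are to the
#' converged mean over the selected atoms.
#'
#' @param ens An [ensemble()] with >= 2 models.
#' @param selection An [atom_selection()].
#' @param tol Convergence tolerance on the mean structure, Angstrom.
#' @param max_iter Iteration cap (error if exceeded).
#' @return An `rmsd_report`: list with `selection`, `per_model_rmsd`,
#'   `mean`, `sd`, `n_atoms`, `iterations`.
#' @examples
#' ens <- simulate_ensemble(synthetic_template_structure(10), 5, 0.3,
#'                          noise_spec(seed = 1))
#' rmsd_from_mean(ens, atom_selection("backbone"))
#' @export
rmsd_from_mean <- function(ens, selection = atom_selection("backbone"),
                           tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(ens, "ensemble"))
  nm <- n_models(ens)
  if (nm < 2L) abort_field("ens", "need >= 2 models for RMSD statistics")
  idx <- select_atoms(ens, selection)
  if (length(idx) < 3L) abort_field("selection", "selects fewer than 3 atoms")
  models <- lapply(seq_len(nm), function(m) ens$coords[, , m])
  ref <- models[[1]]
  models <- lapply(models, function(x) superpose(x, ref, idx)$coords)
  mean_xyz <- Reduce(`+`, models) / nm
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter)
      stop("mean structure failed to converge in ", max_iter, " iterations")
    models <- lapply(models, function(x) superpose(x, mean_xyz, idx)$coords)
    new_mean <- Reduce(`+`, models) / nm
    shift <- sqrt(mean((new_mean[idx, ] - mean_xyz[idx, ])^2))
    mean_xyz <- new_mean
    if (shift <= tol) break
  }
  per_model <- vapply(models, function(x)
    sqrt(mean(rowSums((x[idx, , drop = FALSE] -
                       mean_xyz[idx, , drop = FALSE])^2))), numeric(1))
  structure(list(selection = selection, per_model_rmsd = per_model,
                 mean = mean(per_model), sd = stats::sd(per_model),
                 n_atoms = length(idx), iterations = it),
            class = "rmsd_report")
}

#' @export
print.rmsd_report <- function(x, ...) {
  rng <- if (is.null(x$selection$residue_range)) "all residues"
         else paste(x$selection$residue_range, collapse = "-")
  cat(sprintf("<rmsd_report> %s atoms, residues %s: %.2f +/- %.2f A (%d atoms, %d models)\n",
              x$selection$mode, rng, x$mean, x$sd, x$n_atoms,
              length(x$per_model_rmsd)))
  invisible(x)
}
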