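# Rigid-body superposition, iterative mean-structure RMSD and restraint
# classification.

test_that("atom selections follow the backbone/heavy conventions", {
  tmpl <- synthetic_template_structure(5)
  bb <- select_atoms(tmpl, atom_selection("backbone"))
  expect_equal(sort(unique(tmpl$atoms$atom[bb])), c("C", "CA", "N"))
  expect_equal(length(bb), 15)
  bbo <- select_atoms(tmpl, atom_selection("backbone", include_O = TRUE))
  expect_equal(length(bbo), 20)
  hv <- select_atoms(tmpl, atom_selection("heavy"))
  expect_false(any(tmpl$atoms$atom[hv] == "H"))
  expect_equal(length(hv), 25)
  rng <- select_atoms(tmpl, atom_selection("heavy", residue_range = c(2, 3)))
  expect_setequal(unique(tmpl$atoms$resno[rng]), 2:3)
})

test_that("superposition inverts a constructed rigid motion", {
  tmpl <- synthetic_template_structure(6)
  ref <- tmpl$coords[, , 1]
  idf <- superpose(ref, ref)
  expect_equal(idf$rmsd, 0, tolerance = 1e-10)
  expect_equal(idf$rotation, diag(3), tolerance = 1e-10)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(ref %*% t(Rz), 2, c(1, 2, 3), "+")
  fit <- superpose(moved, ref)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$coords, ref, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # degenerate geometry (collinear points) is rejected
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("superposed RMSD matches the brute-force rotation-search oracle", {
  withr::with_seed(19, {
    for (k in 1:3) {
      A <- matrix(stats::rnorm(30, sd = 3), ncol = 3)
      B <- matrix(stats::rnorm(30, sd = 3), ncol = 3)
      fit <- superpose(A, B)
      oracle <- oracle_superpose_rmsd(A, B)
      expect_lt(abs(fit$rmsd - oracle), 1e-3)
      # second independent route: bio3d's fitted RMSD
      expect_equal(fit$rmsd,
                   bio3d::rmsd(as.vector(t(B)), as.vector(t(A)), fit = TRUE),
                   tolerance = 1e-4)
      # fitting never exceeds the unsuperposed deviation
      raw <- sqrt(mean(rowSums((A - B)^2)))
      expect_lte(fit$rmsd, raw + 1e-12)
    }
  })
})

test_that("identical models give zero RMSD from the mean", {
  tmpl <- synthetic_template_structure(8)
  ens <- simulate_ensemble(tmpl, 5, coord_sd = 0,
                           noise = noise_spec(seed = 21))
  rep <- rmsd_from_mean(ens, atom_selection("backbone"))
  expect_equal(rep$mean, 0, tolerance = 1e-9)
  expect_equal(rep$sd, 0, tolerance = 1e-9)
})

test_that("two-model toy matches the hand-computed RMSD to the mean", {
  # two identical 4-atom models except one atom displaced by 0.6 A in x;
  # the mean sits halfway, so each model is 0.3 A from the mean at that
  # atom and the per-model RMSD is sqrt(0.3^2 / n_sel)
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
  m2 <- base; m2[1, 1] <- m2[1, 1] + 0.6
  atoms <- data.frame(chain = "A", resno = 1:4, resname = "ALA",
                      atom = c("N", "CA", "C", "CB"))
  coords <- array(c(base, m2), dim = c(4, 3, 2))
  ens <- ensemble(atoms, coords)
  sel <- atom_selection("heavy")
  rep <- rmsd_from_mean(ens, sel)
  hand <- sqrt(0.3^2 / 4)
  # superposition re-distributes a little of the displacement, so the
  # converged value can only be <= the superposition-free hand value
  expect_lte(rep$mean, hand + 1e-9)
  expect_equal(rep$mean, hand, tolerance = 0.15)
  expect_equal(rep$per_model_rmsd[1], rep$per_model_rmsd[2],
               tolerance = 1e-6)
})

test_that("rigid-body motion of one model leaves the report unchanged", {
  tmpl <- synthetic_template_structure(10)
  ens <- simulate_ensemble(tmpl, 6, 0.4, noise_spec(seed = 23))
  rep1 <- rmsd_from_mean(ens, atom_selection("backbone"))
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ens2 <- ens
  ens2$coords[, , 3] <- sweep(ens2$coords[, , 3] %*% t(Rz), 2,
                              c(5, -2, 8), "+")
  rep2 <- rmsd_from_mean(ens2, atom_selection("backbone"))
  expect_equal(rep2$per_model_rmsd, rep1$per_model_rmsd, tolerance = 1e-6)
})

test_that("RMSD report matches the no-rotation brute-force oracle", {
  tmpl <- synthetic_template_structure(15)
  ns <- noise_spec(seed = 25)
  ens <- simulate_ensemble(tmpl, 20, coord_sd = 0.5, noise = ns)
  plain <- simulate_ensemble(tmpl, 20, coord_sd = 0.5, noise = ns,
                             rigid_motion = FALSE)
  sel <- atom_selection("backbone")
  idx <- select_atoms(tmpl, sel)
  oracle <- oracle_rmsd_no_superposition(plain$coords, idx)
  rep <- rmsd_from_mean(ens, sel)
  expect_equal(rep$mean, mean(oracle), tolerance = 0.15)
  # closed-form expectation for isotropic scatter: E[rmsd^2] per atom is
  # 3 sd^2 (1 - 1/n_models)
  expect_equal(mean(rep$per_model_rmsd^2), 3 * 0.5^2 * (1 - 1 / 20),
               tolerance = 0.2)
})

test_that("restraint classification follows the |i-j| categories", {
  expect_equal(as.character(classify_restraint(50, 50)), "intra")
  expect_equal(as.character(classify_restraint(50, 51)), "sequential")
  expect_equal(as.character(classify_restraint(50, 53)), "medium")
  expect_equal(as.character(classify_restraint(50, 54)), "medium")
  expect_equal(as.character(classify_restraint(50, 55)), "long")
  expect_equal(as.character(classify_restraint(50, 60)), "long")
  # symmetry
  expect_equal(classify_restraint(3, 10), classify_restraint(10, 3))
})

test_that("restraint summaries partition the total", {
  expect_equal(summarize_restraints(NULL)[["total"]], 0L)
  rec <- data.frame(
    residue_i = c(5, 9, 12, 20, 30, 21, 33, 52, 40, 41),
    residue_j = c(5, 9, 13, 21, 31, 23, 30, 49, 50, 60))
  s <- summarize_restraints(rec)
  expect_equal(unname(s[c("intra", "sequential", "medium", "long")]),
               c(2L, 3L, 3L, 2L))
  expect_equal(sum(s[1:4]), s[["total"]])
})

test_that("XPLOR-style restraint text parses into residue pairs", {
  mr <- c(
    "! test restraints",
    "assign (resid 12 and name HN)(resid 15 and name HA) 4.0 2.2 1.0",
    "assign (resid 30 and name HB#)",
    "       (resid 80 and name HG1) 5.0 3.2 1.5",
    "assign ((resid 40 and name HD1) or (resid 41 and name HD2))",
    "       (resid 90 and name HN) 6.0 4.2 2.0")
  p <- withr::local_tempfile(fileext = ".mr")
  writeLines(mr, p)
  expect_message(df <- read_restraints_mr(p), "ambiguous")
  expect_equal(df$residue_i, c(12, 30, 40))
  expect_equal(df$residue_j, c(15, 80, 90))
  expect_equal(as.character(df$category), c("medium", "long", "long"))

  # tabular reader
  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(residue_i = c(1, 2), atom_i = c("HN", "HA"),
                              residue_j = c(1, 9), atom_j = c("HA", "HB"),
                              bound = c(3.5, 5)), csv, row.names = FALSE)
  tab <- read_restraints_csv(csv)
  expect_equal(as.character(tab$category), c("intra", "long"))
})

test_that("reader harmonizes rosters and drops hydrogens on selection", {
  ens <- simulate_ensemble(synthetic_template_structure(5), 3, 0.2,
                           noise_spec(seed = 29))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, p)
  back <- read_ensemble(p)
  hv <- select_atoms(back, atom_selection("heavy"))
  expect_false(any(back$atoms$atom[hv] == "H"))
  expect_equal(length(hv), 25)

  # an atom missing from one model is dropped from every model, with a log
  lines <- readLines(p)
  m2 <- grep("^MODEL", lines)[2]
  cb <- grep(" CB ", lines)
  lines <- lines[-cb[cb > m2][1]]
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, p2)
  expect_message(back2 <- read_ensemble(p2), "dropped")
  expect_equal(nrow(back2$atoms), nrow(back$atoms) - 1L)
  expect_equal(dim(back2$coords)[1], nrow(back$atoms) - 1L)
  expect_false(any(!is.finite(back2$coords)))
})
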