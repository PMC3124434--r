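cis_fix <- function(cutoff = 8) {
  s <- build_peptide(build_spec(cis_bonds = 8))
  bond <- check_structure(s)$peptide_bonds[8, ]
  flipped <- flip_peptide_bond(s, bond, "O")
  target <- restraint_spec(
    "dihedral",
    c(bond$row_CA_i, bond$row_C_i, bond$row_N_j, bond$row_CA_j) - 1L,
    force_constant = 200, reference_angle = 180)
  fixed <- suppressWarnings(
    regularize_local(flipped, bond, cutoff = cutoff, target = target))
  list(s0 = s, flipped = flipped, fixed = fixed, bond = bond)
}

d_fix <- function(cutoff = 8) {
  s <- build_peptide(build_spec(d_residues = 8))
  ctr <- check_structure(s)$chiral_centers[8, ]
  flipped <- flip_chirality(s, ctr)
  target <- restraint_spec(
    "improper",
    c(ctr$row_s1, ctr$row_c, ctr$row_s2, ctr$row_s3) - 1L,
    force_constant = 200, reference_angle = -ctr$improper)
  fixed <- suppressWarnings(
    regularize_local(flipped, ctr, cutoff = cutoff, target = target))
  list(s0 = s, flipped = flipped, fixed = fixed, ctr = ctr)
}

test_that("reflecting O toggles the cis verdict on ideal planar input", {
  s <- build_peptide(build_spec(cis_bonds = 8))
  bond <- check_structure(s)$peptide_bonds[8, ]
  s2 <- flip_peptide_bond(s, bond, "O")
  rec <- classify_peptide_bond(s2, enumerate_peptide_bonds(s2)[8, ])
  expect_false(rec$is_cis)
  # only the O atom moved, to its exact point reflection through C
  moved <- which(stereocheck:::.xyz_matrix(s) != stereocheck:::.xyz_matrix(s2),
                 arr.ind = TRUE)
  expect_equal(unique(moved[, 1]), bond$row_O_i)
  expect_equal(stereocheck:::.atom_xyz(s2, bond$row_O_i),
               point_reflect(stereocheck:::.atom_xyz(s, bond$row_O_i),
                             stereocheck:::.atom_xyz(s, bond$row_C_i)))
})

test_that("reflecting H lands at exactly 2 r_N - r_H", {
  s <- build_peptide(build_spec(cis_bonds = 8))
  bond <- check_structure(s)$peptide_bonds[8, ]
  h_row <- stereocheck:::.atom_row(s, "A:9:_", "H")
  h_old <- stereocheck:::.atom_xyz(s, h_row)
  s2 <- flip_peptide_bond(s, bond, "H")
  expect_equal(stereocheck:::.atom_xyz(s2, h_row),
               2 * stereocheck:::.atom_xyz(s, bond$row_N_j) - h_old)
})

test_that("moving a C-alpha or an absent atom is refused", {
  s <- build_peptide(build_spec(cis_bonds = 8))
  bond <- check_structure(s)$peptide_bonds[8, ]
  expect_error(flip_peptide_bond(s, bond, "CA"))
  # hydrogen-free model, as from X-ray: only O available
  s_noh <- s
  s_noh$atoms <- s_noh$atoms[s_noh$atoms$element != "H", ]
  bond2 <- check_structure(s_noh)$peptide_bonds[8, ]
  expect_error(flip_peptide_bond(s_noh, bond2, "H"), "amide hydrogen")
  # Xaa-Pro has no amide hydrogen
  sp <- build_peptide(build_spec("AAPA"))
  bondp <- check_structure(sp)$peptide_bonds[2, ]
  expect_error(flip_peptide_bond(sp, bondp, "H"), "Pro")
})

test_that("cis correction round-trips to a clean report", {
  r <- cis_fix()
  rep <- check_structure(r$fixed)
  expect_equal(rep$counts$cis_count, 0L)
  expect_equal(rep$counts$chirality_error_count, 0L)
  expect_equal(rep$counts$unevaluable_bonds, 0L)
  om <- rep$peptide_bonds$omega[8]
  expect_lt(abs(stereocheck:::.wrap180(om - 180)), 10)
})

test_that("chirality correction round-trips to a clean report", {
  r <- d_fix()
  rep <- check_structure(r$fixed)
  expect_equal(rep$counts$chirality_error_count, 0L)
  expect_equal(rep$counts$cis_count, 0L)
  expect_gt(rep$chiral_centers$improper[8], 0)
})

test_that("chirality flip requires the center hydrogen", {
  s <- build_peptide(build_spec(d_residues = 8, include_hydrogens = FALSE))
  ctr <- check_structure(s)$chiral_centers[8, ]
  expect_error(flip_chirality(s, ctr), "add hydrogens")
})

test_that("regularization restores ideal bond geometry", {
  r <- cis_fix()
  top <- stereocheck:::.structure_topology(r$fixed)
  X <- stereocheck:::.xyz_matrix(r$fixed)
  lens <- sqrt(rowSums((X[top$bonds[, 1], ] - X[top$bonds[, 2], ])^2))
  expect_lt(max(abs(lens - top$bond_r0)), 0.05)
  # the corrected carbonyl specifically
  co <- stereocheck:::.atom_row(r$fixed, "A:8:_", "C")
  oo <- stereocheck:::.atom_row(r$fixed, "A:8:_", "O")
  d <- sqrt(sum((stereocheck:::.atom_xyz(r$fixed, co) -
                   stereocheck:::.atom_xyz(r$fixed, oo))^2))
  expect_lt(abs(d - 1.231), 0.05)
})

test_that("atoms beyond the cutoff are bit-identical after regularization", {
  r <- cis_fix(cutoff = 5)
  mobile <- attr(r$fixed, "mobile_atoms")
  fixed_rows <- setdiff(seq_len(nrow(r$s0$atoms)), mobile)
  expect_gt(length(fixed_rows), 0L)
  expect_identical(stereocheck:::.xyz_matrix(r$flipped)[fixed_rows, ],
                   stereocheck:::.xyz_matrix(r$fixed)[fixed_rows, ])
})

test_that("an already-ideal structure barely moves under regularization", {
  s <- build_peptide(build_spec())
  s2 <- suppressWarnings(regularize_local(s, "A:8", cutoff = 8))
  expect_lt(max(abs(stereocheck:::.xyz_matrix(s2) -
                      stereocheck:::.xyz_matrix(s))), 1e-3)
})

test_that("generated restraints cover every bond and center with correct references", {
  s <- build_peptide(build_spec())
  rs <- generate_restraints(s)
  expect_equal(sum(rs$kind == "dihedral"), 14L)
  expect_equal(sum(rs$kind == "improper"), 15L)
  expect_true(all(rs$reference_angle[rs$kind == "dihedral"] == 180))
  expect_true(all(rs$reference_angle[rs$kind == "improper"] > 0))
  # a genuine cis bond kept by the user gets reference 0
  s2 <- build_peptide(build_spec(cis_bonds = 8))
  rs2 <- generate_restraints(s2)
  refs <- rs2$reference_angle[rs2$kind == "dihedral"]
  expect_equal(refs[8], 0)
  expect_true(all(refs[-8] == 180))
  # indices are 0-based, distinct, in range
  expect_true(all(rs$i >= 0 & rs$l < nrow(s$atoms)))
})

test_that("minimizing a clean helix under its own restraints changes no classification", {
  s <- build_peptide(build_spec())
  rep0 <- check_structure(s)
  rs <- generate_restraints(s, rep0)
  s2 <- suppressWarnings(regularize_local(s, "A:8", cutoff = 30,
                                          target = rs))
  rep1 <- check_structure(s2)
  expect_equal(rep1$peptide_bonds$is_cis, rep0$peptide_bonds$is_cis)
  expect_equal(rep1$chiral_centers$flagged, rep0$chiral_centers$flagged)
})

test_that("the extra-bonds format round-trips losslessly", {
  s <- build_peptide(build_spec(cis_bonds = 8))
  rs <- generate_restraints(s)
  lines <- write_extrabonds(rs)
  expect_equal(length(lines), nrow(rs))
  expect_match(lines[rs$kind == "dihedral"][1],
               "^dihedral( \\d+){4} 200\\.0 (180\\.0|0\\.0)$")
  back <- read_extrabonds(lines)
  expect_equal(as.data.frame(back), as.data.frame(rs), tolerance = 1e-9)
  # line order is preserved for mixed collections
  expect_equal(back$kind, rs$kind)
  # file round trip too
  f <- tempfile()
  write_extrabonds(rs, f)
  expect_equal(as.data.frame(read_extrabonds(f)), as.data.frame(rs),
               tolerance = 1e-9)
})

test_that("restraint_spec validates its indices", {
  expect_error(restraint_spec("dihedral", c(0, 1, 2)), "four")
  expect_error(restraint_spec("dihedral", c(0, 1, 2, 2)), "distinct")
  expect_error(restraint_spec("dihedral", c(-1, 1, 2, 3)), "non-negative")
  expect_error(restraint_spec("bend", 0:3))
})
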