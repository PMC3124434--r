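test_that("a 15-residue helix yields 14 evaluable peptide-bond candidates", {
  s <- build_peptide(build_spec())
  bonds <- enumerate_peptide_bonds(s)
  expect_equal(nrow(bonds), 14L)
  expect_true(all(bonds$evaluable))
})

test_that("a chain break is excluded by the C-N distance rule", {
  s <- build_peptide(build_spec())
  shift <- s$atoms$res_seq == 8L
  s$atoms[shift, c("x", "y", "z")] <- s$atoms[shift, c("x", "y", "z")] + 50
  bonds <- enumerate_peptide_bonds(s)
  expect_equal(nrow(bonds), 12L)
  expect_false(any(bonds$res_seq_i %in% c(7L, 8L)))
})

test_that("a missing carbonyl O makes its bond unevaluable with the atom named", {
  s <- build_peptide(build_spec())
  s$atoms <- s$atoms[!(s$atoms$res_seq == 8L & s$atoms$name == "O"), ]
  bonds <- enumerate_peptide_bonds(s)
  expect_equal(nrow(bonds), 14L)
  bad <- bonds[!bonds$evaluable, ]
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$res_seq_i, 8L)
  expect_match(bad$reason_unevaluable, "missing O")
})

test_that("ideal trans and cis bonds classify by |omega'|", {
  s <- make_bond_structure(omega_prime = 0, omega = 180)
  bond <- classify_peptide_bond(s, enumerate_peptide_bonds(s)[1, ])
  expect_false(bond$is_cis)
  expect_equal(bond$omega_prime, 0, tolerance = 1e-6)
  expect_equal(abs(bond$omega), 180, tolerance = 1e-6)
  s <- make_bond_structure(omega_prime = 180, omega = 0)
  bond <- classify_peptide_bond(s, enumerate_peptide_bonds(s)[1, ])
  expect_true(bond$is_cis)
  expect_equal(abs(bond$omega_prime), 180, tolerance = 1e-6)
})

test_that("the 85-degree threshold is a strict inequality on |omega'|", {
  verdicts <- vapply(c(84, 85, 86, -84, -85, -86), function(op) {
    s <- make_bond_structure(omega_prime = op)
    classify_peptide_bond(s, enumerate_peptide_bonds(s)[1, ])$is_cis
  }, logical(1))
  expect_equal(verdicts, c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
})

test_that("pre-proline bonds are annotated", {
  s <- build_peptide(build_spec("AAPA"))
  rep <- check_structure(s)
  expect_equal(rep$peptide_bonds$pre_proline, c(FALSE, TRUE, FALSE))
})

test_that("chiral-center enumeration follows the template table", {
  s <- build_peptide(build_spec())
  cc <- enumerate_chiral_centers(s)
  expect_equal(nrow(cc), 15L)
  expect_true(all(cc$center == "CA"))
  # glycine has no center; Thr and Ile add a C-beta center
  s2 <- build_peptide(build_spec("AGTI"))
  cc2 <- enumerate_chiral_centers(s2)
  expect_false(any(cc2$res_name == "GLY"))
  expect_equal(sum(cc2$center == "CA"), 3L)
  expect_equal(sort(cc2$res_name[cc2$center == "CB"]), c("ILE", "THR"))
})

test_that("nucleotide sugar centers enumerate C1'/C3'/C4' plus C2' for RNA", {
  fake_nt <- function(res_name, atom_names) {
    n <- length(atom_names)
    stereocheck:::new_structure(data.frame(
      serial = seq_len(n), name = atom_names, alt_loc = "",
      res_name = res_name, chain = "A", res_seq = 1L, i_code = "",
      x = stats::rnorm(n), y = stats::rnorm(n), z = stats::rnorm(n),
      occupancy = 1, b_factor = 0, element = substr(atom_names, 1, 1),
      is_hetero = FALSE, stringsAsFactors = FALSE))
  }
  rna <- fake_nt("A", c("C1'", "C2'", "C3'", "C4'", "C5'", "O2'", "O3'",
                        "O4'", "N9"))
  cc <- enumerate_chiral_centers(rna)
  expect_setequal(cc$center, c("C1'", "C2'", "C3'", "C4'"))
  dna <- fake_nt("DA", c("C1'", "C2'", "C3'", "C4'", "C5'", "O3'", "O4'",
                         "N9"))
  cc2 <- enumerate_chiral_centers(dna)
  expect_setequal(cc2$center, c("C1'", "C3'", "C4'"))
  expect_equal(nrow(cc2), 3L)
})

test_that("L centers give positive impropers; mirroring flags them", {
  s <- build_peptide(build_spec("ATIQ"))
  rep <- check_structure(s)
  expect_true(all(rep$chiral_centers$improper > 0))
  expect_false(any(rep$chiral_centers$flagged))
  m <- check_structure(mirror_structure(s))
  expect_true(all(m$chiral_centers$flagged))
  expect_equal(m$chiral_centers$improper, -rep$chiral_centers$improper,
               tolerance = 1e-9)
})

test_that("an injected D-center is flagged exactly at its site", {
  s <- build_peptide(build_spec(d_residues = 8))
  rep <- check_structure(s)
  flagged <- rep$chiral_centers[rep$chiral_centers$flagged, ]
  expect_equal(nrow(flagged), 1L)
  expect_equal(flagged$res_seq, 8L)
  expect_equal(flagged$res_name, "GLN")
  expect_lt(flagged$improper, 0)
})

test_that("missing template atoms mark a center unevaluable", {
  s <- build_peptide(build_spec())
  s$atoms <- s$atoms[!(s$atoms$res_seq == 5L & s$atoms$name == "CB"), ]
  rep <- check_structure(s)
  bad <- rep$chiral_centers[!rep$chiral_centers$evaluable, ]
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$res_seq, 5L)
  expect_match(bad$reason_unevaluable, "missing CB")
  expect_equal(rep$counts$unevaluable_centers, 1L)
})

test_that("improper verdicts agree with the signed-triple-product oracle", {
  set.seed(42)
  n_agree <- 0L
  n <- 1000L
  for (i in seq_len(n)) {
    arr <- random_chiral_arrangement()
    imp <- signed_improper(list(arr$subs[[1]], arr$ctr, arr$subs[[2]],
                                arr$subs[[3]]))
    flagged <- imp < 0
    # natural configurations have negative triple product in template
    # order, so a positive product is the oracle's flag
    oracle_flag <- oracle_triple_product(arr$subs[[1]], arr$ctr,
                                         arr$subs[[2]], arr$subs[[3]]) > 0
    if (flagged == oracle_flag) n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, n)
})

test_that("check_structure reports exact counts for injected anomalies", {
  clean <- check_structure(build_peptide(build_spec()))
  expect_equal(clean$counts$cis_count, 0L)
  expect_equal(clean$counts$chirality_error_count, 0L)
  expect_equal(clean$residues_checked, 15L)
  expect_equal(clean$residues_total, 15L)

  both <- check_structure(build_peptide(build_spec(cis_bonds = 8,
                                                   d_residues = 8)))
  expect_equal(both$counts$cis_count, 1L)
  expect_equal(both$counts$chirality_error_count, 1L)
  cis <- both$peptide_bonds[both$peptide_bonds$is_cis, ]
  expect_equal(cis$res_seq_i, 8L)
  expect_equal(cis$res_name_i, "GLN")
  expect_equal(cis$res_name_j, "ALA")
  expect_equal(both$chiral_centers$res_seq[both$chiral_centers$flagged], 8L)
})

test_that("reports are deterministic for identical input text", {
  txt <- write_structure(build_peptide(build_spec(cis_bonds = 3,
                                                  d_residues = 11)))
  r1 <- check_structure(read_structure(txt))
  r2 <- check_structure(read_structure(txt))
  expect_identical(r1$peptide_bonds, r2$peptide_bonds)
  expect_identical(r1$chiral_centers, r2$chiral_centers)
})

test_that("HETATM residues are checked only under standard names", {
  s <- build_peptide(build_spec("AAA"))
  s$atoms$is_hetero[s$atoms$res_seq == 2L] <- TRUE
  expect_equal(nrow(enumerate_peptide_bonds(s)), 2L)
  s$atoms$res_name[s$atoms$res_seq == 2L] <- "LIG"
  expect_equal(nrow(enumerate_peptide_bonds(s)), 0L)
  expect_equal(nrow(enumerate_chiral_centers(s)), 2L)
})

test_that("report serialization writes both formats", {
  rep <- check_structure(build_peptide(build_spec(cis_bonds = 8)))
  tsv <- write_report(rep)
  expect_match(tsv[1], "record_type")
  expect_equal(length(tsv), 1L + 14L + 15L)
  js <- jsonlite::fromJSON(write_report(rep, format = "json"))
  expect_equal(js$counts$cis_count, 1L)
  expect_equal(nrow(js$peptide_bonds), 14L)
})
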