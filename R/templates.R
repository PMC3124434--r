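# Residue chemistry tables shared by detection, correction and the
# peptide builder.

# Standard residue vocabularies.  HETATM residues are only checked when
# their residue name appears here.
.STD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "MSE")
.STD_DNA <- c("DA", "DG", "DC", "DT", "DI")
.STD_RNA <- c("A", "G", "C", "U", "I")
.PURINES <- c("A", "G", "I", "DA", "DG", "DI")

.AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

is_protein_residue <- function(res_name) res_name %in% .STD_AA
is_nucleic_residue <- function(res_name) res_name %in% c(.STD_DNA, .STD_RNA)

#' Chiral-center template table
#'
#' One row per (residue name, center atom) pair checked by the chirality
#' scan: C-alpha of every standard amino acid except glycine, C-beta of
#' threonine and isoleucine, the sugar carbons C1'/C3'/C4' of DNA and RNA
#' nucleotides and additionally C2' for RNA.  The improper angle of a
#' center is `dihedral_angle(s1, center, s2, s3)`; the substituent
#' orderings are fixed (calibrated once against ideal residue geometry) so
#' that every naturally occurring configuration gives a positive improper,
#' making a negative value the flag for an unusual chirality.  `h_name` is
#' the hydrogen reflected by [flip_chirality()].
#'
#' @return A data.frame with columns `res_name`, `center`, `s1`, `s2`,
#'   `s3`, `h_name`.
#' @export
chiral_templates <- function() {
  aa <- setdiff(.STD_AA, "GLY")
  rows <- data.frame(res_name = aa, center = "CA",
                     s1 = "N", s2 = "CB", s3 = "C", h_name = "HA",
                     stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(
    res_name = c("THR", "ILE"), center = "CB",
    s1 = c("OG1", "CG1"), s2 = "CA", s3 = "CG2", h_name = "HB",
    stringsAsFactors = FALSE))
  for (nt in c(.STD_DNA, .STD_RNA)) {
    base_n <- if (nt %in% .PURINES) "N9" else "N1"
    ctrs <- data.frame(
      res_name = nt,
      center = c("C1'", "C3'", "C4'"),
      s1 = c("O4'", "O3'", "O4'"),
      s2 = c(base_n, "C2'", "C3'"),
      s3 = c("C2'", "C4'", "C5'"),
      h_name = c("H1'", "H3'", "H4'"),
      stringsAsFactors = FALSE)
    if (nt %in% .STD_RNA)
      ctrs <- rbind(ctrs, data.frame(
        res_name = nt, center = "C2'", s1 = "O2'", s2 = "C1'", s3 = "C3'",
        h_name = "H2'", stringsAsFactors = FALSE))
    rows <- rbind(rows, ctrs)
  }
  rownames(rows) <- NULL
  rows
}

# --- internal-coordinate building templates --------------------------------

# Ideal backbone geometry (Engh-Huber-style values, Angstrom / degrees).
.BB_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_N_H = 1.000, b_C_H = 1.090,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.8, a_C_N_H = 119.3)

# Side-chain / branch placement templates, applied after the backbone
# N/CA/C/O of a residue exist.  Each row: atom to place, frame atoms
# (a, b, c; the new atom bonds to c), bond length, angle at c, torsion
# a-b-c-new.  Branch torsions in the (C, N, CA) frame are negated to build
# a D-configuration at C-alpha.
.SIDE_TEMPLATES <- list(
  ALA = list(
    c("CB", "C", "N", "CA", "1.530", "109.5", "-120"),
    c("HA", "C", "N", "CA", "1.090", "109.5", "120")),
  GLY = list(
    c("HA2", "C", "N", "CA", "1.090", "109.5", "120"),
    c("HA3", "C", "N", "CA", "1.090", "109.5", "-120")),
  GLN = list(
    c("CB",  "C", "N", "CA",   "1.530", "109.5", "-120"),
    c("HA",  "C", "N", "CA",   "1.090", "109.5", "120"),
    c("CG",  "N", "CA", "CB",  "1.530", "111.0", "-60"),
    c("CD",  "CA", "CB", "CG", "1.525", "111.0", "180"),
    c("OE1", "CB", "CG", "CD", "1.231", "120.5", "-90"),
    c("NE2", "CB", "CG", "CD", "1.328", "116.5", "90")),
  THR = list(
    c("CB",  "C", "N", "CA",  "1.540", "109.5", "-120"),
    c("HA",  "C", "N", "CA",  "1.090", "109.5", "120"),
    c("OG1", "N", "CA", "CB", "1.417", "109.5", "60"),
    c("CG2", "N", "CA", "CB", "1.521", "109.5", "-60"),
    c("HB",  "N", "CA", "CB", "1.090", "109.5", "180")),
  ILE = list(
    c("CB",  "C", "N", "CA",   "1.540", "109.5", "-120"),
    c("HA",  "C", "N", "CA",   "1.090", "109.5", "120"),
    c("CG1", "N", "CA", "CB",  "1.530", "109.5", "-60"),
    c("CG2", "N", "CA", "CB",  "1.521", "109.5", "180"),
    c("HB",  "N", "CA", "CB",  "1.090", "109.5", "60"),
    c("CD1", "CA", "CB", "CG1", "1.513", "111.0", "180")),
  SER = list(
    c("CB", "C", "N", "CA",  "1.530", "109.5", "-120"),
    c("HA", "C", "N", "CA",  "1.090", "109.5", "120"),
    c("OG", "N", "CA", "CB", "1.417", "109.5", "-60")),
  VAL = list(
    c("CB",  "C", "N", "CA",  "1.540", "109.5", "-120"),
    c("HA",  "C", "N", "CA",  "1.090", "109.5", "120"),
    c("CG1", "N", "CA", "CB", "1.521", "109.5", "-60"),
    c("CG2", "N", "CA", "CB", "1.521", "109.5", "180"),
    c("HB",  "N", "CA", "CB", "1.090", "109.5", "60")),
  PRO = list(
    c("CB", "C", "N", "CA",   "1.530", "104.0", "-120"),
    c("HA", "C", "N", "CA",   "1.090", "110.5", "120"),
    c("CG", "N", "CA", "CB",  "1.530", "104.5", "30"),
    c("CD", "CA", "CB", "CG", "1.530", "106.0", "-35")))

.SUPPORTED_BUILD_AA <- names(.SIDE_TEMPLATES)

.element_from_name <- function(name) {
  stripped <- sub("^[0-9']+", "", name)
  first <- substr(stripped, 1L, 1L)
  ifelse(first == "H", "H", first)
}

.is_hydrogen <- function(name, element = NULL) {
  if (is.null(element)) element <- rep("", length(name))
  el <- toupper(trimws(element))
  out <- el %in% c("H", "D")
  need <- !nzchar(el)
  if (any(need))
    out[need] <- .element_from_name(name[need]) == "H"
  out
}
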