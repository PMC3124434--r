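# Synthetic test-bed structures: ideal peptides built from internal
# coordinates, with injectable stereochemical perturbations (cis bonds,
# D-centers), mirroring, and a standard fixture battery.

#' Specification for a synthetic peptide
#'
#' Describes an ideal peptide to be built from internal coordinates.  The
#' default is the 15-residue alanine/glutamine alpha-helix AAQAAAAQAAAAQAA
#' with helical backbone dihedrals, the system used to illustrate how a
#' single chirality or isomerization error disrupts secondary structure.
#'
#' @param sequence One-letter amino-acid string; supported letters are
#'   `r paste(names(.AA1TO3)[.AA1TO3 %in% .SUPPORTED_BUILD_AA], collapse = ", ")`.
#' @param phi,psi Backbone dihedrals in degrees, recycled along the
#'   sequence; defaults -57/-47 (ideal alpha helix).
#' @param omega Peptide-bond dihedrals in degrees for the `n - 1` bonds,
#'   recycled; default 180 (all-trans).
#' @param cis_bonds Integer indices (1-based; bond `i` joins residues `i`
#'   and `i + 1`) whose omega is set to 0.
#' @param d_residues Integer residue indices built as D-configurations at
#'   C-alpha (hydrogen and side-chain branch placements swapped about the
#'   backbone plane; glycine cannot be listed).
#' @param include_hydrogens Build amide and C-alpha (and, on chiral
#'   C-beta, beta) hydrogens; side chains otherwise carry no hydrogens.
#' @param caps Add an acetyl (ACE) N-terminal and amide (NH2) C-terminal
#'   capping group.
#' @param chain Chain identifier for the built residues.
#' @return A validated list of class `build_spec`.
#' @export
build_spec <- function(sequence = "AAQAAAAQAAAAQAA", phi = -57, psi = -47,
                       omega = 180, cis_bonds = integer(),
                       d_residues = integer(), include_hydrogens = TRUE,
                       caps = FALSE, chain = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(letters1)
  if (n < 2L) stop("'sequence' must contain at least two residues",
                   call. = FALSE)
  bad <- setdiff(letters1, names(.AA1TO3)[.AA1TO3 %in% .SUPPORTED_BUILD_AA])
  if (length(bad) > 0L)
    stop(sprintf("unsupported residue letter(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  cis_bonds <- as.integer(cis_bonds)
  d_residues <- as.integer(d_residues)
  if (length(cis_bonds) > 0L &&
      (any(cis_bonds < 1L) || any(cis_bonds > n - 1L)))
    stop(sprintf("'cis_bonds' indices must lie in [1, %d]", n - 1L),
         call. = FALSE)
  if (length(d_residues) > 0L &&
      (any(d_residues < 1L) || any(d_residues > n)))
    stop(sprintf("'d_residues' indices must lie in [1, %d]", n),
         call. = FALSE)
  if (any(letters1[d_residues] == "G"))
    stop("glycine has no C-alpha chiral center and cannot be built as D",
         call. = FALSE)
  omega_vec <- rep_len(omega, n - 1L)
  omega_vec[cis_bonds] <- 0
  structure(list(sequence = letters1, res_names = unname(.AA1TO3[letters1]),
                 phi = rep_len(phi, n), psi = rep_len(psi, n),
                 omega = omega_vec, cis_bonds = sort(unique(cis_bonds)),
                 d_residues = sort(unique(d_residues)),
                 include_hydrogens = isTRUE(include_hydrogens),
                 caps = isTRUE(caps), chain = chain),
            class = "build_spec")
}

#' Build an ideal peptide from internal coordinates
#'
#' Places the backbone atom by atom with [place_atom()] using ideal bond
#' lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231
#' Angstrom) and the spec's phi/psi/omega, then attaches side chains and
#' hydrogens from per-residue internal-coordinate templates.  Residues
#' listed in `d_residues` have their C-alpha branch torsions negated,
#' which inverts the center without distorting the backbone.  The build is
#' deterministic: identical specs give identical structures.
#'
#' @param spec A [build_spec()] (or a sequence string, converted with
#'   defaults).
#' @return A `stereo_structure`.
#' @export
build_peptide <- function(spec = build_spec()) {
  if (is.character(spec)) spec <- build_spec(spec)
  stopifnot(inherits(spec, "build_spec"))
  g <- .BB_GEOM
  n <- length(spec$res_names)

  atoms <- list()   # per residue: named list of coordinates
  meta <- list()
  add_res <- function(res_name, seq_num, coords) {
    atoms[[length(atoms) + 1L]] <<- coords
    meta[[length(meta) + 1L]] <<- list(res_name = res_name,
                                       seq_num = seq_num)
  }

  # bootstrap first backbone triad in the xy-plane
  prev <- NULL  # list(CA=, C=, O=) of the previous peptide unit
  seq0 <- 1L
  if (spec$caps) {
    ace <- list(CH3 = c(0, 0, 0), C = c(1.520, 0, 0))
    # carbonyl O of the cap, in-plane
    ace$O <- place_atom(c(0, 1, 0), ace$CH3, ace$C, g$b_C_O, g$a_CA_C_O, 0)
    add_res("ACE", 0L, ace)
    # the cap acts as the previous peptide unit; the next N is placed
    # anti to the cap oxygen
    prev <- list(CA = ace$CH3, C = ace$C, O = ace$O, N_prev = ace$O,
                 psi = 180, omega_next = 180)
  }

  for (i in seq_len(n)) {
    rn <- spec$res_names[i]
    co <- list()
    if (is.null(prev)) {
      co$N <- c(0, 0, 0)
      co$CA <- c(g$b_N_CA, 0, 0)
      th <- pi - g$a_N_CA_C * pi / 180
      co$C <- co$CA + g$b_CA_C * c(cos(th), sin(th), 0)
    } else {
      om <- prev$omega_next
      co$N <- place_atom(prev$N_prev, prev$CA, prev$C, g$b_C_N,
                         g$a_CA_C_N, prev$psi)
      co$CA <- place_atom(prev$CA, prev$C, co$N, g$b_N_CA, g$a_C_N_CA, om)
      co$C <- place_atom(prev$C, co$N, co$CA, g$b_CA_C, g$a_N_CA_C,
                         spec$phi[i])
      if (spec$include_hydrogens && rn != "PRO")
        co$H <- place_atom(prev$CA, prev$C, co$N, g$b_N_H, g$a_C_N_H,
                           om - 180)
    }
    # carbonyl O anti to the next amide nitrogen: torsion psi + 180
    co$O <- place_atom(co$N, co$CA, co$C, g$b_C_O, g$a_CA_C_O,
                       spec$psi[i] + 180)
    # side chain and C-alpha hydrogens from the residue template
    d_here <- i %in% spec$d_residues
    for (t in .SIDE_TEMPLATES[[rn]]) {
      nm <- t[1L]
      if (!spec$include_hydrogens && .is_hydrogen(nm)) next
      tor <- as.numeric(t[7L])
      if (d_here && identical(t[2L:4L], c("C", "N", "CA"))) tor <- -tor
      co[[nm]] <- place_atom(co[[t[2L]]], co[[t[3L]]], co[[t[4L]]],
                             as.numeric(t[5L]), as.numeric(t[6L]), tor)
    }
    if (is.null(prev) && spec$include_hydrogens && !spec$caps &&
        rn != "PRO")
      co$H1 <- place_atom(co$C, co$CA, co$N, g$b_N_H, 109.5, 180)
    add_res(rn, i, co)
    prev <- list(CA = co$CA, C = co$C, O = co$O, N_prev = co$N,
                 psi = spec$psi[i],
                 omega_next = if (i < n) spec$omega[i] else 180)
  }

  if (spec$caps) {
    nh2 <- list(N = place_atom(prev$N_prev, prev$CA, prev$C, g$b_C_N,
                               g$a_CA_C_N, prev$psi))
    if (spec$include_hydrogens)
      nh2$HN1 <- place_atom(prev$CA, prev$C, nh2$N, g$b_N_H, g$a_C_N_H, 0)
    add_res("NH2", n + 1L, nh2)
  }

  # assemble the atom table, conventional order: backbone, side, hydrogens
  order_names <- function(nms) {
    pref <- c("N", "CA", "C", "O")
    heavy <- setdiff(nms[!.is_hydrogen(nms)], pref)
    hyd <- nms[.is_hydrogen(nms)]
    c(intersect(pref, nms), heavy, hyd)
  }
  rows <- list()
  for (k in seq_along(atoms)) {
    co <- atoms[[k]]
    for (nm in order_names(names(co))) {
      p <- co[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        serial = length(rows) + 1L, name = nm, alt_loc = "",
        res_name = meta[[k]]$res_name, chain = spec$chain,
        res_seq = meta[[k]]$seq_num, i_code = "",
        x = p[1L], y = p[2L], z = p[3L],
        occupancy = 1, b_factor = 0,
        element = .element_from_name(nm),
        is_hetero = meta[[k]]$res_name %in% c("ACE", "NH2"),
        stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows))
}

#' Mirror a structure
#'
#' Negates every z coordinate, producing the enantiomeric structure with
#' unchanged topology.  Mirroring negates every signed improper (so every
#' evaluable chiral center of an all-natural structure becomes flagged)
#' while leaving `|omega_prime|`, and hence every cis/trans verdict,
#' unchanged.
#'
#' @param s A `stereo_structure`.
#' @return The mirrored `stereo_structure`.
#' @export
mirror_structure <- function(s) {
  stopifnot(inherits(s, "stereo_structure"))
  s$atoms$z <- -s$atoms$z
  s
}

#' Write the standard fixture battery
#'
#' Emits a deterministic set of eight PDB files derived from the default
#' 15-residue helix: clean; one cis bond at residues 8-9; one D-center at
#' residue 8; both combined; a chain break (residue 8 translated +50
#' Angstrom); a missing carbonyl O at residue 8; the one-cis variant with
#' a matching CISPEP header record; and an all-trans variant with a false
#' CISPEP record.  A TSV of expected detection outcomes per file, computed
#' at generation time, is written alongside.
#'
#' @param dir Output directory (created if needed).
#' @param sequence Sequence for the battery.
#' @return Invisibly, a data.frame of the expected outcomes per file.
#' @export
write_fixture_set <- function(dir, sequence = "AAQAAAAQAAAAQAA") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  xray <- "EXPDTA    X-RAY DIFFRACTION"
  n <- nchar(sequence)
  mid_bond <- min(8L, n - 1L)
  mid_res <- min(8L, n)
  res3 <- unname(.AA1TO3[strsplit(toupper(sequence), "")[[1L]]])
  cis_rec <- format_cispep_record(1L, res3[mid_bond], "A", mid_bond,
                                  res3[mid_bond + 1L], "A", mid_bond + 1L,
                                  0)

  variants <- list(
    clean = list(s = build_peptide(build_spec(sequence)), header = xray),
    one_cis = list(s = build_peptide(build_spec(sequence,
                                                cis_bonds = mid_bond)),
                   header = xray),
    one_d = list(s = build_peptide(build_spec(sequence,
                                              d_residues = mid_res)),
                 header = xray),
    combined = list(s = build_peptide(build_spec(sequence,
                                                 cis_bonds = mid_bond,
                                                 d_residues = mid_res)),
                    header = xray),
    chain_break = local({
      s <- build_peptide(build_spec(sequence))
      shift <- s$atoms$res_seq == mid_res
      s$atoms[shift, c("x", "y", "z")] <-
        s$atoms[shift, c("x", "y", "z")] + 50
      list(s = s, header = xray)
    }),
    missing_atom = local({
      s <- build_peptide(build_spec(sequence))
      drop <- s$atoms$res_seq == mid_res & s$atoms$name == "O"
      s$atoms <- s$atoms[!drop, , drop = FALSE]
      list(s = s, header = xray)
    }),
    with_cispep = list(s = build_peptide(build_spec(sequence,
                                                    cis_bonds = mid_bond)),
                       header = c(xray, cis_rec)),
    false_cispep = list(s = build_peptide(build_spec(sequence)),
                        header = c(xray, cis_rec)))

  expected <- do.call(rbind, lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    path <- file.path(dir, paste0(nm, ".pdb"))
    write_structure(v$s, file = path, header = v$header)
    rep <- check_structure(v$s)
    data.frame(file = basename(path),
               cis_count = rep$counts$cis_count,
               chirality_error_count = rep$counts$chirality_error_count,
               unevaluable_bonds = rep$counts$unevaluable_bonds,
               unevaluable_centers = rep$counts$unevaluable_centers,
               residues_checked = rep$residues_checked,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(expected, file.path(dir, "expected_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expected)
}
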