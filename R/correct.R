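# Correction moves (steps 3-4 of the protocol): reflection of the chosen
# atom, local regularization under a harmonic bonded-term model with a
# target-state restraint, and generation of preventive restraints.

.wrap180 <- function(x) {
  x <- (x + 180) %% 360 - 180
  ifelse(x <= -180, x + 180 * 2, x)
}

# --- connectivity ----------------------------------------------------------

# Heavy-atom side-chain bonds by standard PDB atom names.
.SIDECHAIN_BONDS <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","NE"),
             c("NE","CZ"), c("CZ","NH1"), c("CZ","NH2")),
  ASN = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = list(c("CA","CB"), c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = list(c("CA","CB"), c("CB","SG")),
  GLN = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","NE2")),
  GLU = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","OE1"),
             c("CD","OE2")),
  GLY = list(),
  HIS = list(c("CA","CB"), c("CB","CG"), c("CG","ND1"), c("CG","CD2"),
             c("ND1","CE1"), c("CD2","NE2"), c("CE1","NE2")),
  ILE = list(c("CA","CB"), c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","CE"),
             c("CE","NZ")),
  MET = list(c("CA","CB"), c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = list(c("CA","CB"), c("CB","CG"), c("CG","CD"), c("CD","N")),
  SER = list(c("CA","CB"), c("CB","OG")),
  THR = list(c("CA","CB"), c("CB","OG1"), c("CB","CG2")),
  TRP = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","NE1"), c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"),
             c("CE2","CZ2"), c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = list(c("CA","CB"), c("CB","CG"), c("CG","CD1"), c("CG","CD2"),
             c("CD1","CE1"), c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"),
             c("CZ","OH")))

# hydrogen attachment by name, for the hydrogens the builder emits
.H_PARENT <- c(H = "N", H1 = "N", H2 = "N", H3 = "N", HN = "N",
               HA = "CA", HA2 = "CA", HA3 = "CA", HB = "CB")

# fallback ideal bond lengths by element pair (Angstrom)
.ELEMENT_BONDS <- c("C|C" = 1.526, "C|N" = 1.470, "C|O" = 1.420,
                    "C|S" = 1.810, "C|H" = 1.090, "N|H" = 1.000,
                    "O|H" = 0.960, "S|H" = 1.340, "O|P" = 1.600,
                    "C|P" = 1.800)

.element_pair_r0 <- function(e1, e2) {
  key <- paste(sort(c(toupper(e1), toupper(e2))), collapse = "|")
  if (!is.na(.ELEMENT_BONDS[key])) return(unname(.ELEMENT_BONDS[key]))
  1.5
}

# Reference ideal geometry, measured once per residue type from a
# template-built tripeptide so that the regularizer's minimum coincides
# exactly with the builder's ideal geometry.
.stereocheck_cache <- new.env(parent = emptyenv())

.ideal_geometry_tables <- function() {
  if (!is.null(.stereocheck_cache$ideal)) return(.stereocheck_cache$ideal)
  bonds <- new.env(parent = emptyenv())
  angles <- new.env(parent = emptyenv())
  one <- names(.AA1TO3)[.AA1TO3 %in% .SUPPORTED_BUILD_AA]
  for (x in one) {
    s <- build_peptide(build_spec(paste0("A", x, "A")))
    top <- .structure_topology(s, use_ideal = FALSE)
    a <- s$atoms
    X <- .xyz_matrix(s)
    key_of <- function(r) sprintf("%s:%s", a$res_name[r], a$name[r])
    for (b in seq_len(nrow(top$bonds))) {
      i <- top$bonds[b, 1L]; j <- top$bonds[b, 2L]
      if (a$res_seq[i] != a$res_seq[j]) next
      if (a$res_seq[i] != 2L && x != "A") next
      key <- paste(sort(c(key_of(i), key_of(j))), collapse = "|")
      if (is.null(bonds[[key]]))
        bonds[[key]] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
    for (t in seq_len(nrow(top$angles))) {
      i <- top$angles[t, 1L]; j <- top$angles[t, 2L]; k <- top$angles[t, 3L]
      same <- a$res_seq[i] == a$res_seq[j] && a$res_seq[j] == a$res_seq[k]
      key <- if (same) {
        paste(a$res_name[j], a$name[i], a$name[j], a$name[k], sep = "|")
      } else {
        # inter-residue triple, keyed by names plus residue offsets
        paste("PEP", a$name[i], a$res_seq[i] - a$res_seq[j],
              a$name[j], a$name[k], a$res_seq[k] - a$res_seq[j],
              if (any(a$res_name[c(i, j, k)] == "PRO")) "PRO" else "",
              sep = "|")
      }
      if (is.null(angles[[key]]))
        angles[[key]] <- bond_angle(X[i, ], X[j, ], X[k, ])
    }
  }
  .stereocheck_cache$ideal <- list(bonds = bonds, angles = angles)
  .stereocheck_cache$ideal
}

# Bond graph and term lists for a structure; when use_ideal, reference
# values come from the measured-ideal tables with element-pair and
# hybridization fallbacks.
.structure_topology <- function(s, use_ideal = TRUE) {
  a <- s$atoms
  n <- nrow(a)
  uid <- .res_uid(a$chain, a$res_seq, a$i_code)
  res <- residues(s)
  row_of <- function(u, nm) {
    hit <- which(uid == u & a$name == nm)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }

  bonds <- list()
  add_bond <- function(i, j) {
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1L]] <<- c(i, j)
  }
  for (r in seq_len(nrow(res))) {
    u <- res$uid[r]
    rn <- res$res_name[r]
    in_res <- which(uid == u)
    if (is_protein_residue(rn)) {
      add_bond(row_of(u, "N"), row_of(u, "CA"))
      add_bond(row_of(u, "CA"), row_of(u, "C"))
      add_bond(row_of(u, "C"), row_of(u, "O"))
      sc <- .SIDECHAIN_BONDS[[rn]]
      if (!is.null(sc))
        for (b in sc) add_bond(row_of(u, b[1L]), row_of(u, b[2L]))
      for (i in in_res[.is_hydrogen(a$name[in_res], a$element[in_res])]) {
        parent <- .H_PARENT[a$name[i]]
        if (!is.na(parent)) add_bond(i, row_of(u, parent))
        else {
          # nearest heavy atom within bonding distance
          heavy <- in_res[!.is_hydrogen(a$name[in_res], a$element[in_res])]
          d <- sqrt(colSums((t(.xyz_matrix(s)[heavy, , drop = FALSE]) -
                               .atom_xyz(s, i))^2))
          if (length(d) > 0L && min(d) < 1.3) add_bond(i, heavy[which.min(d)])
        }
      }
    } else {
      # generic distance-based perception within the residue
      X <- .xyz_matrix(s)[in_res, , drop = FALSE]
      if (length(in_res) > 1L) {
        D <- as.matrix(stats::dist(X))
        hyd <- .is_hydrogen(a$name[in_res], a$element[in_res])
        for (p in seq_along(in_res))
          for (q in seq_len(p - 1L)) {
            lim <- if (hyd[p] || hyd[q]) 1.25
            else if (any(a$element[in_res[c(p, q)]] %in% c("S", "P"))) 2.1
            else 1.85
            if (D[p, q] < lim && !(hyd[p] && hyd[q]))
              add_bond(in_res[p], in_res[q])
          }
      }
    }
  }
  # inter-residue peptide bonds C(n)-N(n+1)
  pep <- list()
  if (nrow(res) >= 2L)
    for (r in seq_len(nrow(res) - 1L)) {
      if (res$chain[r] != res$chain[r + 1L]) next
      ci <- row_of(res$uid[r], "C"); nj <- row_of(res$uid[r + 1L], "N")
      if (is.na(ci) || is.na(nj)) next
      d <- sqrt(sum((.atom_xyz(s, ci) - .atom_xyz(s, nj))^2))
      if (d <= 2.0) {
        add_bond(ci, nj)
        pep[[length(pep) + 1L]] <- list(
          i = r, j = r + 1L,
          CA_i = row_of(res$uid[r], "CA"), C_i = ci, O_i = row_of(res$uid[r], "O"),
          N_j = nj, CA_j = row_of(res$uid[r + 1L], "CA"),
          H_j = {
            h <- row_of(res$uid[r + 1L], "H")
            if (is.na(h)) row_of(res$uid[r + 1L], "HN") else h
          })
      }
    }
  bonds <- unique(lapply(bonds, function(b) sort(b)))
  bmat <- if (length(bonds) > 0L) do.call(rbind, bonds) else
    matrix(integer(), ncol = 2L)

  # angles from the bond graph
  nbr <- vector("list", n)
  for (b in seq_len(nrow(bmat))) {
    nbr[[bmat[b, 1L]]] <- c(nbr[[bmat[b, 1L]]], bmat[b, 2L])
    nbr[[bmat[b, 2L]]] <- c(nbr[[bmat[b, 2L]]], bmat[b, 1L])
  }
  angs <- list()
  for (j in seq_len(n)) {
    nb <- nbr[[j]]
    if (length(nb) < 2L) next
    for (p in seq_along(nb))
      for (q in seq_len(p - 1L))
        angs[[length(angs) + 1L]] <- c(nb[p], j, nb[q])
  }
  amat <- if (length(angs) > 0L) do.call(rbind, angs) else
    matrix(integer(), ncol = 3L)

  top <- list(bonds = bmat, angles = amat, peptide = pep, nbr = nbr)
  if (!use_ideal) return(top)

  ideal <- .ideal_geometry_tables()
  key_of <- function(r) sprintf("%s:%s", a$res_name[r], a$name[r])
  top$bond_r0 <- vapply(seq_len(nrow(bmat)), function(b) {
    i <- bmat[b, 1L]; j <- bmat[b, 2L]
    if (a$name[i] == "C" && a$name[j] == "N" || a$name[i] == "N" &&
        a$name[j] == "C")
      if (uid[i] != uid[j]) return(.BB_GEOM$b_C_N)
    key <- paste(sort(c(key_of(i), key_of(j))), collapse = "|")
    v <- ideal$bonds[[key]]
    if (!is.null(v)) v else .element_pair_r0(a$element[i], a$element[j])
  }, numeric(1))
  top$angle_th0 <- vapply(seq_len(nrow(amat)), function(t) {
    i <- amat[t, 1L]; j <- amat[t, 2L]; k <- amat[t, 3L]
    same <- uid[i] == uid[j] && uid[j] == uid[k]
    lookup <- function(ii, kk) {
      key <- if (same)
        paste(a$res_name[j], a$name[ii], a$name[j], a$name[kk], sep = "|")
      else
        paste("PEP", a$name[ii], a$res_seq[ii] - a$res_seq[j],
              a$name[j], a$name[kk], a$res_seq[kk] - a$res_seq[j],
              if (any(a$res_name[c(ii, j, kk)] == "PRO")) "PRO" else "",
              sep = "|")
      ideal$angles[[key]]
    }
    v <- lookup(i, k)
    if (is.null(v)) v <- lookup(k, i)
    if (!is.null(v)) return(v)
    # hybridization fallback: carbonyl carbon / amide nitrogen are sp2
    deg <- length(top$nbr[[j]])
    el <- a$element[j]
    if (el == "C" && deg == 3L && any(a$element[top$nbr[[j]]] == "O")) 120
    else if (el == "N" && a$name[j] == "N") 120
    else if (el %in% c("C", "N") && deg == 3L) 120
    else 109.5
  }, numeric(1))
  top
}

# --- bonded-term energy model ---------------------------------------------

.dihedral_phi_grad <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
  nb2 <- .vnorm(b2)
  n1sq <- sum(n1 * n1); n2sq <- sum(n2 * n2)
  if (nb2 < 1e-8 || n1sq < 1e-16 || n2sq < 1e-16)
    return(NULL)
  phi <- atan2(sum(.cross(n1, n2) * (b2 / nb2)), sum(n1 * n2))
  g1 <- -(nb2 / n1sq) * n1
  g4 <- (nb2 / n2sq) * n2
  f <- sum(b1 * b2) / (nb2 * nb2)
  h <- sum(b3 * b2) / (nb2 * nb2)
  g2 <- -(1 + f) * g1 + h * g4
  g3 <- f * g1 - (1 + h) * g4
  list(phi = phi, g = rbind(g1, g2, g3, g4))
}

# Evaluate total energy and per-atom gradient of the bonded model.
# torsion term types: "harmonic" (k * wrap(phi - ref)^2),
# "planar" (harmonic about the nearer of 0/180), "twofold" (k * (1 - cos 2 phi)).
.bonded_energy <- function(X, terms) {
  E <- 0
  G <- matrix(0, nrow(X), 3L)
  deg <- pi / 180
  if (nrow(terms$bonds) > 0L) {
    i <- terms$bonds[, 1L]; j <- terms$bonds[, 2L]
    d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    r <- sqrt(rowSums(d * d))
    dr <- r - terms$bond_r0
    E <- E + sum(terms$k_bond * dr * dr)
    f <- 2 * terms$k_bond * dr / pmax(r, 1e-8)
    gi <- f * d
    for (c3 in 1:3) {
      G[, c3] <- G[, c3] + unname(tapply(c(gi[, c3], -gi[, c3]),
                                         factor(c(i, j), levels = seq_len(nrow(X))),
                                         sum, default = 0))
    }
  }
  if (nrow(terms$angles) > 0L) {
    i <- terms$angles[, 1L]; j <- terms$angles[, 2L]; k <- terms$angles[, 3L]
    u <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    v <- X[k, , drop = FALSE] - X[j, , drop = FALSE]
    nu <- sqrt(rowSums(u * u)); nv <- sqrt(rowSums(v * v))
    cth <- pmin(1 - 1e-10, pmax(-1 + 1e-10,
                                rowSums(u * v) / (nu * nv)))
    th <- acos(cth)
    sth <- sqrt(1 - cth * cth)
    dth <- th - terms$angle_th0 * deg
    E <- E + sum(terms$k_angle * dth * dth)
    pref <- 2 * terms$k_angle * dth
    uh <- u / nu; vh <- v / nv
    gi <- pref / (nu * sth) * (cth * uh - vh)
    gk <- pref / (nv * sth) * (cth * vh - uh)
    gj <- -(gi + gk)
    idx <- factor(c(i, j, k), levels = seq_len(nrow(X)))
    for (c3 in 1:3)
      G[, c3] <- G[, c3] + unname(tapply(c(gi[, c3], gj[, c3], gk[, c3]),
                                         idx, sum, default = 0))
  }
  if (length(terms$torsions) > 0L) {
    for (t in terms$torsions) {
      dg <- .dihedral_phi_grad(X[t$idx[1L], ], X[t$idx[2L], ],
                               X[t$idx[3L], ], X[t$idx[4L], ])
      if (is.null(dg)) next
      phi <- dg$phi
      if (t$type == "twofold") {
        E <- E + t$k * (1 - cos(2 * phi))
        dEdphi <- 2 * t$k * sin(2 * phi)
      } else {
        ref <- if (t$type == "planar") {
          if (abs(.wrap180(phi / deg)) <= 90) 0 else 180
        } else t$ref
        dphi <- .wrap180(phi / deg - ref) * deg
        E <- E + t$k * dphi * dphi
        dEdphi <- 2 * t$k * dphi
      }
      G[t$idx, ] <- G[t$idx, ] + dEdphi * dg$g
    }
  }
  list(E = E, G = G)
}

.rotation_about_axis <- function(origin, axis, angle_deg) {
  u <- axis / .vnorm(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
  function(P) sweep(sweep(P, 2L, origin) %*% t(R), 2L, origin, `+`)
}

.parse_site <- function(site) {
  if (is.data.frame(site)) {
    seqs <- if ("res_seq" %in% names(site)) site$res_seq else
      c(site$res_seq_i, site$res_seq_j)
    ics <- if ("i_code" %in% names(site)) site$i_code else
      c(site$i_code_i, site$i_code_j)
    return(data.frame(chain = rep(site$chain, length.out = length(seqs)),
                      res_seq = seqs, i_code = ics,
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(as.character(site), ":", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) {
    if (length(p) < 2L)
      stop("site must be given as 'chain:res_seq[:i_code]'", call. = FALSE)
    data.frame(chain = p[1L], res_seq = as.integer(p[2L]),
               i_code = if (length(p) >= 3L) p[3L] else "",
               stringsAsFactors = FALSE)
  }))
}

#' Locally regularize geometry around a site
#'
#' Energy-minimizes a harmonic bonded-term model (bonds, angles, peptide
#' planarity impropers and a two-fold peptide torsion that keeps omega at
#' one of its two isomeric values, plus an optional target restraint) over
#' the atoms of every residue having any atom within `cutoff` of the site
#' residues.  Atoms outside this mobile set are left bit-identical to the
#' input, which keeps the correction local.  When the target is a dihedral
#' restraint far from its reference, an initial guess is generated by
#' rigidly rotating the mobile downstream segment about the dihedral axis
#' onto the target isomer before minimization.
#'
#' @param s A `stereo_structure`.
#' @param site Residue identifier(s): `"chain:res_seq"` strings or a
#'   data.frame with `chain`, `res_seq` (optionally `i_code`) columns --
#'   e.g. a record from a detection report.
#' @param cutoff Mobility radius in Angstrom (default 8).
#' @param target Optional one-row restraint (see [restraint_spec()])
#'   enforcing the desired isomer or configuration.
#' @param k_bond,k_angle,k_planarity Force constants of the model, in
#'   kcal/mol/A^2 and kcal/mol/rad^2.
#' @param k_peptide_torsion Barrier parameter (kcal/mol) of the two-fold
#'   peptide torsion; the cis/trans barrier of the model is twice this.
#' @param max_iter Iteration budget of the L-BFGS minimizer.
#' @param grad_tol Convergence threshold on the largest gradient component
#'   (kcal/mol/A); non-convergence yields a warning and the best-found
#'   coordinates, with `attr(result, "converged")` set to `FALSE`.
#' @return The structure with regularized coordinates.
#' @export
regularize_local <- function(s, site, cutoff = 8, target = NULL,
                             k_bond = 300, k_angle = 50, k_planarity = 40,
                             k_peptide_torsion = 10,
                             max_iter = 2000, grad_tol = 0.1) {
  stopifnot(inherits(s, "stereo_structure"), cutoff > 0)
  a <- s$atoms
  uid <- .res_uid(a$chain, a$res_seq, a$i_code)
  sites <- .parse_site(site)
  site_uids <- .res_uid(sites$chain, sites$res_seq, sites$i_code)
  if (!any(uid %in% site_uids))
    stop("site residue not found in structure", call. = FALSE)

  X <- .xyz_matrix(s)
  site_rows <- which(uid %in% site_uids)
  d2 <- rep(Inf, nrow(X))
  for (r in site_rows) {
    dd <- rowSums(sweep(X, 2L, X[r, ])^2)
    d2 <- pmin(d2, dd)
  }
  near_res <- unique(uid[d2 <= cutoff^2])
  mobile <- which(uid %in% near_res)
  if (length(mobile) == 0L) return(s)

  top <- .structure_topology(s)
  touch <- function(idx) any(idx %in% mobile)
  keep_b <- vapply(seq_len(nrow(top$bonds)), function(b)
    touch(top$bonds[b, ]), logical(1))
  keep_a <- vapply(seq_len(nrow(top$angles)), function(t)
    touch(top$angles[t, ]), logical(1))
  torsions <- list()
  for (p in top$peptide) {
    idx4 <- c(p$CA_i, p$C_i, p$N_j, p$CA_j)
    if (anyNA(idx4) || !touch(idx4)) next
    torsions[[length(torsions) + 1L]] <-
      list(idx = idx4, type = "twofold", k = k_peptide_torsion)
    # the O and amide-H impropers are 180 degrees in either isomer, so a
    # harmonic about 180 keeps the peptide group planar without biasing
    # cis vs trans, and pulls a reflected atom onto the consistent side
    if (!is.na(p$O_i))
      torsions[[length(torsions) + 1L]] <-
        list(idx = c(p$CA_i, p$C_i, p$N_j, p$O_i), type = "harmonic",
             k = k_planarity, ref = 180)
    if (!is.na(p$H_j))
      torsions[[length(torsions) + 1L]] <-
        list(idx = c(p$CA_j, p$N_j, p$C_i, p$H_j), type = "harmonic",
             k = k_planarity, ref = 180)
  }
  if (!is.null(target)) {
    stopifnot(is.data.frame(target), nrow(target) >= 1L)
    for (r in seq_len(nrow(target))) {
      torsions[[length(torsions) + 1L]] <- list(
        idx = c(target$i[r], target$j[r], target$k[r], target$l[r]) + 1L,
        type = "harmonic", k = target$force_constant[r],
        ref = target$reference_angle[r])
    }
  }
  terms <- list(bonds = top$bonds[keep_b, , drop = FALSE],
                bond_r0 = top$bond_r0[keep_b],
                k_bond = k_bond,
                angles = top$angles[keep_a, , drop = FALSE],
                angle_th0 = top$angle_th0[keep_a],
                k_angle = k_angle,
                torsions = torsions)

  # initial guess for a large improper change (chirality inversion):
  # mirror the s2 branch through the plane of (s1, center, s3), then
  # re-idealize hydrogens on the center; bonds and angles are preserved
  # exactly while the improper changes sign
  if (!is.null(target)) {
    nbr <- top$nbr
    for (r in seq_len(nrow(target))) {
      if (target$kind[r] != "improper") next
      idx4 <- c(target$i[r], target$j[r], target$k[r], target$l[r]) + 1L
      dg <- .dihedral_phi_grad(X[idx4[1L], ], X[idx4[2L], ],
                               X[idx4[3L], ], X[idx4[4L], ])
      if (is.null(dg)) next
      if (abs(.wrap180(dg$phi * 180 / pi - target$reference_angle[r])) <= 90)
        next
      ctr <- idx4[2L]; s1 <- idx4[1L]; s2 <- idx4[3L]; s3 <- idx4[4L]
      # branch = atoms reachable from s2 without passing through the center
      comp <- s2; frontier <- s2
      while (length(frontier) > 0L) {
        nxt <- setdiff(unique(unlist(nbr[frontier])), c(comp, ctr))
        comp <- c(comp, nxt)
        frontier <- nxt
      }
      if (any(c(s1, s3) %in% comp) || !all(comp %in% mobile) ||
          length(comp) > 60L)
        next
      nrm <- .cross(X[s1, ] - X[ctr, ], X[s3, ] - X[ctr, ])
      if (.vnorm(nrm) < 1e-8) next
      nrm <- nrm / .vnorm(nrm)
      rel <- sweep(X[comp, , drop = FALSE], 2L, X[ctr, ])
      X[comp, ] <- sweep(rel - 2 * (rel %*% nrm) %*% t(nrm), 2L,
                         X[ctr, ], `+`)
      # tetrahedral completion for hydrogens bonded to the center
      h_on_ctr <- intersect(nbr[[ctr]],
                            which(.is_hydrogen(a$name, a$element)))
      for (h in intersect(h_on_ctr, mobile)) {
        u <- -(
          (X[s1, ] - X[ctr, ]) / .vnorm(X[s1, ] - X[ctr, ]) +
            (X[s2, ] - X[ctr, ]) / .vnorm(X[s2, ] - X[ctr, ]) +
            (X[s3, ] - X[ctr, ]) / .vnorm(X[s3, ] - X[ctr, ]))
        u <- u / .vnorm(u)
        X[h, ] <- X[ctr, ] + .vnorm(X[h, ] - X[ctr, ]) * u
      }
    }
  }

  # initial guess for a large dihedral change: rigid rotation of the
  # mobile downstream segment about the bond axis
  if (!is.null(target)) {
    for (r in seq_len(nrow(target))) {
      if (target$kind[r] != "dihedral") next
      idx4 <- c(target$i[r], target$j[r], target$k[r], target$l[r]) + 1L
      dg <- .dihedral_phi_grad(X[idx4[1L], ], X[idx4[2L], ],
                               X[idx4[3L], ], X[idx4[4L], ])
      if (is.null(dg)) next
      delta <- .wrap180(target$reference_angle[r] - dg$phi * 180 / pi)
      if (abs(delta) <= 30) next
      axis_from <- X[idx4[2L], ]; axis_to <- X[idx4[3L], ]
      res_order <- residues(s)
      pivot_uid <- uid[idx4[3L]]
      pivot_pos <- match(pivot_uid, res_order$uid)
      down_uids <- res_order$uid[res_order$chain == res_order$chain[pivot_pos] &
                                   seq_len(nrow(res_order)) >= pivot_pos]
      rot_rows <- intersect(which(uid %in% down_uids), mobile)
      rot_rows <- setdiff(rot_rows, idx4[3L])  # axis atom stays put anyway
      if (length(rot_rows) == 0L) next
      rot <- .rotation_about_axis(axis_from, axis_to - axis_from, delta)
      X[rot_rows, ] <- rot(X[rot_rows, , drop = FALSE])
    }
    # make the guess self-consistent: a peptide O or amide H left on the
    # wrong side of its (always-180) planarity improper is reflected
    # through its bonded heavy atom
    for (p in top$peptide) {
      fix_side <- function(idx4, atom_row, heavy_row) {
        if (anyNA(idx4) || !atom_row %in% mobile) return()
        dg <- .dihedral_phi_grad(X[idx4[1L], ], X[idx4[2L], ],
                                 X[idx4[3L], ], X[idx4[4L], ])
        if (is.null(dg)) return()
        if (abs(.wrap180(dg$phi * 180 / pi - 180)) > 90)
          X[atom_row, ] <<- point_reflect(X[atom_row, ], X[heavy_row, ])
      }
      if (!is.na(p$O_i))
        fix_side(c(p$CA_i, p$C_i, p$N_j, p$O_i), p$O_i, p$C_i)
      if (!is.na(p$H_j))
        fix_side(c(p$CA_j, p$N_j, p$C_i, p$H_j), p$H_j, p$N_j)
    }
  }

  par0 <- as.vector(X[mobile, , drop = FALSE])
  eval_env <- new.env()
  evaluate <- function(par) {
    if (!is.null(eval_env$par) && identical(par, eval_env$par))
      return(eval_env$res)
    Xc <- X
    Xc[mobile, ] <- matrix(par, ncol = 3L)
    res <- .bonded_energy(Xc, terms)
    eval_env$par <- par
    eval_env$res <- res
    res
  }
  fn <- function(par) evaluate(par)$E
  gr <- function(par) as.vector(evaluate(par)$G[mobile, , drop = FALSE])
  # L-BFGS with a few jittered restarts: the line search can stall in the
  # stiff, nearly singular valleys of the bonded model
  par <- par0
  max_grad <- Inf
  for (round in 1:4) {
    opt <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1e3))
    par <- opt$par
    # polish with a second solver: the L-BFGS line search can stall in
    # the stiff, nearly singular valleys of the bonded model
    pol <- stats::nlminb(par, fn, gr,
                         control = list(iter.max = max_iter,
                                        eval.max = 2L * max_iter))
    if (pol$objective <= opt$value) par <- pol$par
    max_grad <- max(abs(evaluate(par)$G[mobile, ]))
    if (max_grad <= grad_tol) break
    # deterministic jitter to escape saddles, so runs stay reproducible
    par <- par + 2e-3 * sin(seq_along(par) * 7919 * round)
  }
  converged <- max_grad <= grad_tol
  if (!converged)
    warning(sprintf(
      "local regularization did not reach gradient tolerance (max |g| = %.3g); returning best-found coordinates",
      max_grad), call. = FALSE)
  X[mobile, ] <- matrix(opt$par, ncol = 3L)
  s <- .set_xyz(s, mobile, X[mobile, , drop = FALSE])
  attr(s, "converged") <- converged
  attr(s, "max_gradient") <- max_grad
  attr(s, "mobile_atoms") <- mobile
  s
}

# --- reflection moves ------------------------------------------------------

.find_bond <- function(s, bond, cfg = detection_config()) {
  if (is.data.frame(bond) && "row_C_i" %in% names(bond)) return(bond)
  site <- .parse_site(bond)[1L, ]
  cands <- enumerate_peptide_bonds(s, cfg)
  hit <- which(cands$chain == site$chain & cands$res_seq_i == site$res_seq &
                 cands$i_code_i == site$i_code)
  if (length(hit) == 0L)
    stop(sprintf("no peptide bond starts at residue %s:%d",
                 site$chain, site$res_seq), call. = FALSE)
  cands[hit[1L], ]
}

#' Flip a peptide bond by reflecting its oxygen or amide hydrogen
#'
#' Reflects the chosen atom through its bonded heavy partner: the carbonyl
#' oxygen through the peptide carbon, or the amide hydrogen through the
#' peptide nitrogen.  C-alpha atoms are never moved, which minimizes the
#' structural impact; which of the two atoms to move depends on the local
#' hydrogen-bonding environment and is the caller's decision.  On ideal
#' planar input the reflection toggles the bond's cis/trans verdict; a
#' subsequent [regularize_local()] with a dihedral restraint completes the
#' isomerization.
#'
#' @param s A `stereo_structure`.
#' @param bond A bond record from [enumerate_peptide_bonds()] /
#'   [check_structure()], or a `"chain:res_seq"` site naming residue n of
#'   the bond.
#' @param move `"O"` or `"H"`.  Hydrogens are absent from most X-ray
#'   models, and Xaa-Pro bonds have no amide hydrogen; in both cases only
#'   `"O"` is available.
#' @return The structure with the atom reflected.
#' @export
flip_peptide_bond <- function(s, bond, move = c("O", "H")) {
  move <- match.arg(move)
  bond <- .find_bond(s, bond)
  stopifnot(nrow(bond) == 1L)
  if (move == "O") {
    if (is.na(bond$row_O_i) || is.na(bond$row_C_i))
      stop(sprintf("cannot move O of %s:%d: missing %s", bond$chain,
                   bond$res_seq_i,
                   if (is.na(bond$row_O_i)) "O" else "C"), call. = FALSE)
    p <- point_reflect(.atom_xyz(s, bond$row_O_i),
                       .atom_xyz(s, bond$row_C_i))
    s <- .set_xyz(s, bond$row_O_i, matrix(p, 1L))
  } else {
    if (bond$res_name_j == "PRO")
      stop("Xaa-Pro bonds have no amide hydrogen; move O instead",
           call. = FALSE)
    uid_j <- .res_uid(bond$chain, bond$res_seq_j, bond$i_code_j)
    h <- .atom_row(s, uid_j, "H")
    if (is.na(h)) h <- .atom_row(s, uid_j, "HN")
    if (is.na(h))
      stop(sprintf(
        "no amide hydrogen on residue %s:%d (typical of X-ray models); move O instead",
        bond$chain, bond$res_seq_j), call. = FALSE)
    if (is.na(bond$row_N_j))
      stop("missing peptide nitrogen", call. = FALSE)
    p <- point_reflect(.atom_xyz(s, h), .atom_xyz(s, bond$row_N_j))
    s <- .set_xyz(s, h, matrix(p, 1L))
  }
  s
}

#' Flip a chiral center by reflecting its hydrogen
#'
#' Reflects the center's hydrogen (the smallest substituent, so the least
#' perturbing choice) through the chiral atom.  The move alone does not
#' invert the heavy-atom improper; a subsequent [regularize_local()] with
#' an improper restraint at the mirrored reference completes the
#' inversion.
#'
#' @param s A `stereo_structure`.
#' @param center A center record from [enumerate_chiral_centers()] /
#'   [check_structure()], or a `"chain:res_seq"` site (C-alpha center
#'   assumed).
#' @return The structure with the hydrogen reflected.
#' @export
flip_chirality <- function(s, center) {
  if (!is.data.frame(center) || !"row_c" %in% names(center)) {
    site <- .parse_site(center)[1L, ]
    cands <- enumerate_chiral_centers(s)
    hit <- which(cands$chain == site$chain &
                   cands$res_seq == site$res_seq &
                   cands$i_code == site$i_code)
    if (length(hit) == 0L)
      stop(sprintf("no chiral center at residue %s:%d", site$chain,
                   site$res_seq), call. = FALSE)
    center <- cands[hit[1L], ]
  }
  stopifnot(nrow(center) == 1L)
  uid <- .res_uid(center$chain, center$res_seq, center$i_code)
  h <- .atom_row(s, uid, center$h_name)
  if (is.na(h))
    stop(sprintf(
      "residue %s:%d has no %s hydrogen; add hydrogens before correcting chirality",
      center$chain, center$res_seq, center$h_name), call. = FALSE)
  p <- point_reflect(.atom_xyz(s, h), .atom_xyz(s, center$row_c))
  .set_xyz(s, h, matrix(p, 1L))
}

# --- restraints ------------------------------------------------------------

#' Construct a harmonic restraint specification
#'
#' @param kind `"dihedral"` or `"improper"`.
#' @param atoms Four distinct 0-based atom indices into the structure's
#'   serialized atom order.
#' @param force_constant Force constant in kcal/mol/rad^2.
#' @param reference_angle Reference angle in degrees.
#' @return A one-row data.frame of class `restraint_spec`.
#' @export
restraint_spec <- function(kind, atoms, force_constant = 200,
                           reference_angle = 180) {
  kind <- match.arg(kind, c("dihedral", "improper"))
  atoms <- as.integer(atoms)
  if (length(atoms) != 4L || anyNA(atoms) || any(atoms < 0L) ||
      anyDuplicated(atoms))
    stop("'atoms' must be four distinct non-negative 0-based indices",
         call. = FALSE)
  out <- data.frame(kind = kind, i = atoms[1L], j = atoms[2L],
                    k = atoms[3L], l = atoms[4L],
                    force_constant = force_constant,
                    reference_angle = reference_angle,
                    stringsAsFactors = FALSE)
  class(out) <- c("restraint_spec", "data.frame")
  out
}

#' Generate restraints preserving the current stereochemistry
#'
#' Builds one harmonic dihedral restraint per evaluable peptide bond
#' (reference 180 degrees for trans bonds, 0 for cis, on the omega atoms
#' CA, C, N', CA') and one harmonic improper restraint per evaluable
#' chiral center (reference equal to its current improper).  Applied
#' during relaxation steps these prevent changes in isomerization state
#' and chirality; they should be removed before production equilibrium
#' simulations, where they would be an unnecessary modification of the
#' force field.
#'
#' @param s A `stereo_structure`.
#' @param report A `detection_report` produced from `s`.
#' @param force_constant Force constant in kcal/mol/rad^2 (default 200).
#' @return A `restraint_spec` data.frame, one row per restraint; atom
#'   indices are 0-based into the structure's serialized atom order.
#' @export
generate_restraints <- function(s, report = check_structure(s),
                                force_constant = 200) {
  stopifnot(inherits(report, "detection_report"))
  rows <- list()
  b <- report$peptide_bonds
  for (i in seq_len(nrow(b))) {
    if (!b$evaluable[i]) next
    rows[[length(rows) + 1L]] <- restraint_spec(
      "dihedral",
      c(b$row_CA_i[i], b$row_C_i[i], b$row_N_j[i], b$row_CA_j[i]) - 1L,
      force_constant,
      if (b$is_cis[i]) 0 else 180)
  }
  cc <- report$chiral_centers
  for (i in seq_len(nrow(cc))) {
    if (!cc$evaluable[i]) next
    rows[[length(rows) + 1L]] <- restraint_spec(
      "improper",
      c(cc$row_s1[i], cc$row_c[i], cc$row_s2[i], cc$row_s3[i]) - 1L,
      force_constant,
      cc$improper[i])
  }
  if (length(rows) == 0L) {
    out <- restraint_spec("dihedral", 0:3)[0L, ]
    class(out) <- c("restraint_spec", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("restraint_spec", "data.frame")
  out
}

.fmt_num <- function(v) {
  vapply(v, function(x) {
    s1 <- sprintf("%.1f", x)
    if (as.numeric(s1) == x) s1 else sprintf("%.10g", x)
  }, character(1))
}

#' Write restraints in the extra-bonds text format
#'
#' One line per restraint: keyword (`dihedral` or `improper`), four
#' 0-based atom indices, force constant (kcal/mol/rad^2) and reference
#' angle (degrees) -- the side-file dialect consumed by the NAMD
#' extraBonds facility.
#'
#' @param rs A `restraint_spec` data.frame.
#' @param file Optional output path.
#' @return Invisibly, the character vector of lines.
#' @export
write_extrabonds <- function(rs, file = NULL) {
  stopifnot(is.data.frame(rs))
  lines <- if (nrow(rs) == 0L) character(0) else
    sprintf("%s %d %d %d %d %s %s", rs$kind, rs$i, rs$j, rs$k, rs$l,
            .fmt_num(rs$force_constant), .fmt_num(rs$reference_angle))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Read an extra-bonds restraint file
#'
#' @param x A file path or the text itself.
#' @return A `restraint_spec` data.frame.
#' @export
read_extrabonds <- function(x) {
  lines <- .as_pdb_lines(x)$lines
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    out <- restraint_spec("dihedral", 0:3)[0L, ]
    class(out) <- c("restraint_spec", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\\s+")
  out <- do.call(rbind, lapply(parts, function(p) {
    if (length(p) != 7L)
      stop("malformed extra-bonds line: ", paste(p, collapse = " "),
           call. = FALSE)
    restraint_spec(p[1L], as.integer(p[2:5]), as.numeric(p[6L]),
                   as.numeric(p[7L]))
  }))
  class(out) <- c("restraint_spec", "data.frame")
  out
}
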