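# Shared helpers: independent geometric oracles and crafted structures.

# Brute-force rotation oracle for the torsion sign convention: find the
# right-handed rotation of p4 about the p2->p3 axis that brings it
# coplanar-cis with p1; the torsion is minus that rotation.
oracle_dihedral <- function(p1, p2, p3, p4, step = 0.02) {
  axis <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  proj <- function(v) v - sum(v * axis) * axis
  u <- proj(p1 - p2); u <- u / sqrt(sum(u^2))
  w0 <- p4 - p3
  thetas <- seq(-180, 180 - step, by = step)
  mis <- vapply(thetas, function(th) {
    thr <- th * pi / 180
    K <- rbind(c(0, -axis[3], axis[2]),
               c(axis[3], 0, -axis[1]),
               c(-axis[2], axis[1], 0))
    R <- diag(3) * cos(thr) + sin(thr) * K +
      (1 - cos(thr)) * (axis %o% axis)
    w <- proj(as.vector(R %*% w0))
    w <- w / sqrt(sum(w^2))
    sum((w - u)^2)
  }, numeric(1))
  theta_cis <- thetas[which.min(mis)]
  ang <- -theta_cis
  if (ang <= -180) ang <- ang + 360
  if (ang > 180) ang <- ang - 360
  ang
}

# Signed triple product of the template substituents about the center;
# natural configurations give a negative value under the calibrated
# template orderings (the improper is minus-signed relative to this).
oracle_triple_product <- function(s1, ctr, s2, s3) {
  det(cbind(s1 - ctr, s2 - ctr, s3 - ctr))
}

random_rigid_motion <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- stats::rnorm(3, sd = 10)
  function(p) as.vector(R %*% p) + t
}

apply_rigid_to_structure <- function(s, motion) {
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  Xn <- t(apply(X, 1, motion))
  s$atoms[, c("x", "y", "z")] <- Xn
  s
}

# Minimal hand-crafted peptide unit whose omega-prime is exactly the
# requested value; residue n = GLN 8, residue n+1 = ALA 9.
make_bond_structure <- function(omega_prime, omega = omega_prime - 180) {
  C <- c(0, 0, 0)
  N <- c(1.329, 0, 0)
  CA_j <- place_atom(c(0, 1, 0), C, N, 1.458, 121.7, 20)
  O <- place_atom(CA_j, N, C, 1.231, 123.0, omega_prime)
  CA_i <- place_atom(CA_j, N, C, 1.525, 116.2, omega)
  atoms <- data.frame(
    serial = 1:5,
    name = c("CA", "C", "O", "N", "CA"),
    alt_loc = "",
    res_name = c("GLN", "GLN", "GLN", "ALA", "ALA"),
    chain = "A",
    res_seq = c(8L, 8L, 8L, 9L, 9L),
    i_code = "",
    x = c(CA_i[1], C[1], O[1], N[1], CA_j[1]),
    y = c(CA_i[2], C[2], O[2], N[2], CA_j[2]),
    z = c(CA_i[3], C[3], O[3], N[3], CA_j[3]),
    occupancy = 1, b_factor = 0,
    element = c("C", "C", "O", "N", "C"),
    is_hetero = FALSE,
    stringsAsFactors = FALSE)
  stereocheck:::new_structure(atoms)
}

# Random tetrahedral-ish arrangement of a center and three substituents.
random_chiral_arrangement <- function() {
  repeat {
    ctr <- stats::rnorm(3)
    subs <- replicate(3, ctr + stats::rnorm(3), simplify = FALSE)
    vol <- abs(oracle_triple_product(subs[[1]], ctr, subs[[2]], subs[[3]]))
    if (vol > 1e-3) return(list(ctr = ctr, subs = subs))
  }
}

# A random but valid build spec for property tests.
random_build_spec <- function() {
  letters_ok <- c("A", "G", "Q", "T", "I", "S", "V")
  n <- sample(4:10, 1)
  seqn <- paste(sample(letters_ok, n, replace = TRUE), collapse = "")
  non_gly <- which(strsplit(seqn, "")[[1]] != "G")
  build_spec(seqn,
             phi = stats::runif(1, -150, -50),
             psi = stats::runif(1, -60, 150),
             cis_bonds = if (stats::runif(1) < 0.3) sample(n - 1, 1)
             else integer(),
             d_residues = if (stats::runif(1) < 0.3 && length(non_gly) > 0)
               sample(non_gly, 1) else integer())
}

battery_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "stereocheck-battery")
      write_fixture_set(dir)
    }
    dir
  }
})
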