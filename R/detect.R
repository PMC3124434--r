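# Step (1) of the correction protocol: enumerate peptide bonds and chiral
# centers, classify each, and assemble a detection report.

#' Detection configuration
#'
#' @param omega_prime_threshold Degrees; a peptide bond is flagged as cis
#'   when the magnitude of its omega-prime dihedral (O, C, N', CA')
#'   strictly exceeds this value.  Default 85, chosen to avoid false
#'   positives while keeping sensitivity.
#' @param peptide_bond_max_cn_distance Angstrom; consecutive residues whose
#'   C--N distance exceeds this are treated as a chain break, not a bond.
#' @param check_proteins,check_nucleic Enable the protein (peptide bond +
#'   amino-acid chirality) and nucleic-acid (sugar chirality) scans.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(omega_prime_threshold = 85,
                             peptide_bond_max_cn_distance = 2.0,
                             check_proteins = TRUE,
                             check_nucleic = TRUE) {
  if (!is.numeric(omega_prime_threshold) || omega_prime_threshold <= 0 ||
      omega_prime_threshold >= 180)
    stop("'omega_prime_threshold' must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  if (!is.numeric(peptide_bond_max_cn_distance) ||
      peptide_bond_max_cn_distance <= 0)
    stop("'peptide_bond_max_cn_distance' must be positive", call. = FALSE)
  structure(list(omega_prime_threshold = omega_prime_threshold,
                 peptide_bond_max_cn_distance = peptide_bond_max_cn_distance,
                 check_proteins = isTRUE(check_proteins),
                 check_nucleic = isTRUE(check_nucleic)),
            class = "detection_config")
}

.PEPTIDE_ATOMS <- c("CA_i", "C_i", "O_i", "N_j", "CA_j")

#' Enumerate candidate peptide bonds
#'
#' One candidate per pair of consecutive standard amino-acid residues
#' within a chain whose C(n)--N(n+1) distance is at most the configured
#' cutoff.  Candidates missing any of the five required heavy atoms
#' (CA, C, O of residue n; N, CA of residue n+1) are returned marked
#' unevaluable with the missing atom named.  Non-standard residue names
#' (including capping groups) are skipped as non-peptide neighbors.
#'
#' @param s A `stereo_structure`.
#' @param cfg A [detection_config()].
#' @return A data.frame of candidates with residue identifiers of both
#'   partners, `evaluable` and `reason_unevaluable`, plus hidden atom-row
#'   columns used by [classify_peptide_bond()].
#' @export
enumerate_peptide_bonds <- function(s, cfg = detection_config()) {
  res <- residues(s)
  res <- res[is_protein_residue(res$res_name), , drop = FALSE]
  out <- list()
  if (nrow(res) >= 2L && cfg$check_proteins) {
    for (k in seq_len(nrow(res) - 1L)) {
      ri <- res[k, ]; rj <- res[k + 1L, ]
      if (ri$chain != rj$chain) next
      rows <- c(CA_i = .atom_row(s, ri$uid, "CA"),
                C_i = .atom_row(s, ri$uid, "C"),
                O_i = .atom_row(s, ri$uid, "O"),
                N_j = .atom_row(s, rj$uid, "N"),
                CA_j = .atom_row(s, rj$uid, "CA"))
      # chain-break rule needs both C and N
      if (!is.na(rows["C_i"]) && !is.na(rows["N_j"])) {
        d <- sqrt(sum((.atom_xyz(s, rows["C_i"]) -
                         .atom_xyz(s, rows["N_j"]))^2))
        if (d > cfg$peptide_bond_max_cn_distance) next
      }
      missing <- .PEPTIDE_ATOMS[is.na(rows)]
      reason <- if (length(missing) > 0L)
        paste("missing",
              paste(sub("_i$|_j$", "", missing), collapse = ", "))
      else ""
      out[[length(out) + 1L]] <- data.frame(
        chain = ri$chain, res_seq_i = ri$res_seq, i_code_i = ri$i_code,
        res_name_i = ri$res_name, res_seq_j = rj$res_seq,
        i_code_j = rj$i_code, res_name_j = rj$res_name,
        evaluable = length(missing) == 0L, reason_unevaluable = reason,
        row_CA_i = rows[["CA_i"]], row_C_i = rows[["C_i"]],
        row_O_i = rows[["O_i"]], row_N_j = rows[["N_j"]],
        row_CA_j = rows[["CA_j"]], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chain = character(), res_seq_i = integer(),
                      i_code_i = character(), res_name_i = character(),
                      res_seq_j = integer(), i_code_j = character(),
                      res_name_j = character(), evaluable = logical(),
                      reason_unevaluable = character(),
                      row_CA_i = integer(), row_C_i = integer(),
                      row_O_i = integer(), row_N_j = integer(),
                      row_CA_j = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify one peptide-bond candidate
#'
#' Computes the backbone omega dihedral (CA, C, N', CA') and the detection
#' dihedral omega-prime (O, C, N', CA'); the bond is flagged cis when
#' `|omega_prime|` strictly exceeds the configured threshold (85 degrees
#' by default).  Omega-prime is approximately 0 for a trans bond and
#' approximately 180 for a cis bond; its magnitude is used so the verdict
#' does not depend on the torsion sign convention.  Pre-proline bonds
#' (the common genuine cis case) are annotated via `pre_proline`.
#'
#' @param s A `stereo_structure`.
#' @param bond A one-row data.frame from [enumerate_peptide_bonds()].
#' @param cfg A [detection_config()].
#' @return The row augmented with `omega`, `omega_prime`, `is_cis`,
#'   `pre_proline`; degenerate geometry marks the record unevaluable
#'   instead of raising.
#' @export
classify_peptide_bond <- function(s, bond, cfg = detection_config()) {
  stopifnot(nrow(bond) == 1L)
  bond$omega <- NA_real_
  bond$omega_prime <- NA_real_
  bond$is_cis <- FALSE
  bond$pre_proline <- bond$res_name_j == "PRO"
  if (!bond$evaluable) return(bond)
  ang <- tryCatch({
    c(omega = dihedral_angle(.atom_xyz(s, bond$row_CA_i),
                             .atom_xyz(s, bond$row_C_i),
                             .atom_xyz(s, bond$row_N_j),
                             .atom_xyz(s, bond$row_CA_j)),
      omega_prime = dihedral_angle(.atom_xyz(s, bond$row_O_i),
                                   .atom_xyz(s, bond$row_C_i),
                                   .atom_xyz(s, bond$row_N_j),
                                   .atom_xyz(s, bond$row_CA_j)))
  }, error = function(e) e)
  if (inherits(ang, "error")) {
    bond$evaluable <- FALSE
    bond$reason_unevaluable <- conditionMessage(ang)
    return(bond)
  }
  bond$omega <- unname(ang["omega"])
  bond$omega_prime <- unname(ang["omega_prime"])
  bond$is_cis <- abs(bond$omega_prime) > cfg$omega_prime_threshold
  bond
}

#' Enumerate candidate chiral centers
#'
#' One candidate per (residue, center) pair of the template table:
#' C-alpha of every standard amino acid except glycine, C-beta of Thr and
#' Ile, and the sugar carbons C1'/C3'/C4' of nucleotides (plus C2' for
#' RNA).  Candidates with any template atom missing are marked
#' unevaluable.
#'
#' @param s A `stereo_structure`.
#' @param templates A template table as from [chiral_templates()].
#' @param cfg A [detection_config()].
#' @return A data.frame of candidates with residue identifier, center
#'   name, `evaluable`, `reason_unevaluable` and hidden atom-row columns.
#' @export
enumerate_chiral_centers <- function(s, templates = chiral_templates(),
                                     cfg = detection_config()) {
  res <- residues(s)
  keep <- (is_protein_residue(res$res_name) & cfg$check_proteins) |
    (is_nucleic_residue(res$res_name) & cfg$check_nucleic)
  res <- res[keep, , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(res))) {
    r <- res[k, ]
    tpl <- templates[templates$res_name == r$res_name, , drop = FALSE]
    if (nrow(tpl) == 0L) next
    for (t in seq_len(nrow(tpl))) {
      nm <- c(tpl$s1[t], tpl$center[t], tpl$s2[t], tpl$s3[t])
      rows <- vapply(nm, function(n) .atom_row(s, r$uid, n), integer(1))
      missing <- nm[is.na(rows)]
      out[[length(out) + 1L]] <- data.frame(
        chain = r$chain, res_seq = r$res_seq, i_code = r$i_code,
        res_name = r$res_name, center = tpl$center[t],
        h_name = tpl$h_name[t],
        evaluable = length(missing) == 0L,
        reason_unevaluable = if (length(missing) > 0L)
          paste("missing", paste(missing, collapse = ", ")) else "",
        row_s1 = rows[[1L]], row_c = rows[[2L]], row_s2 = rows[[3L]],
        row_s3 = rows[[4L]], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chain = character(), res_seq = integer(),
                      i_code = character(), res_name = character(),
                      center = character(), h_name = character(),
                      evaluable = logical(),
                      reason_unevaluable = character(),
                      row_s1 = integer(), row_c = integer(),
                      row_s2 = integer(), row_s3 = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Evaluate one chiral-center candidate
#'
#' The center's signed improper dihedral is computed over the template's
#' ordered substituent quadruple; a negative value flags an unusual
#' chirality (the orderings are calibrated so every naturally occurring
#' configuration is positive).
#'
#' @param s A `stereo_structure`.
#' @param center A one-row data.frame from [enumerate_chiral_centers()].
#' @return The row augmented with `improper` and `flagged`.
#' @export
evaluate_chiral_center <- function(s, center) {
  stopifnot(nrow(center) == 1L)
  center$improper <- NA_real_
  center$flagged <- FALSE
  if (!center$evaluable) return(center)
  imp <- tryCatch(
    signed_improper(list(.atom_xyz(s, center$row_s1),
                         .atom_xyz(s, center$row_c),
                         .atom_xyz(s, center$row_s2),
                         .atom_xyz(s, center$row_s3))),
    error = function(e) e)
  if (inherits(imp, "error")) {
    center$evaluable <- FALSE
    center$reason_unevaluable <- conditionMessage(imp)
    return(center)
  }
  center$improper <- imp
  center$flagged <- imp < 0
  center
}

#' Scan a structure for stereochemical anomalies
#'
#' Runs the peptide-bond and chiral-center enumerations and
#' classifications and assembles a detection report.  Detected anomalies
#' are reported, never auto-corrected: D-amino acids and cis bonds
#' (especially pre-proline ones) do occur naturally, so whether to correct
#' is a separate, user-driven decision.
#'
#' @param s A `stereo_structure`.
#' @param cfg A [detection_config()].
#' @return An object of class `detection_report`: list with
#'   `peptide_bonds` and `chiral_centers` data.frames, `residues_checked`
#'   (residues contributing at least one evaluable candidate),
#'   `residues_total`, and a `counts` list (`cis_count`,
#'   `chirality_error_count`, `unevaluable_bonds`, `unevaluable_centers`).
#' @export
check_structure <- function(s, cfg = detection_config()) {
  stopifnot(inherits(s, "stereo_structure"))
  bonds <- enumerate_peptide_bonds(s, cfg)
  if (nrow(bonds) > 0L)
    bonds <- do.call(rbind, lapply(seq_len(nrow(bonds)), function(i)
      classify_peptide_bond(s, bonds[i, ], cfg)))
  else {
    bonds$omega <- numeric(); bonds$omega_prime <- numeric()
    bonds$is_cis <- logical(); bonds$pre_proline <- logical()
  }
  centers <- enumerate_chiral_centers(s, cfg = cfg)
  if (nrow(centers) > 0L)
    centers <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
      evaluate_chiral_center(s, centers[i, ])))
  else {
    centers$improper <- numeric(); centers$flagged <- logical()
  }

  res <- residues(s)
  checked <- character(0)
  if (nrow(bonds) > 0L) {
    ev <- bonds$evaluable
    checked <- c(checked,
                 .res_uid(bonds$chain[ev], bonds$res_seq_i[ev],
                          bonds$i_code_i[ev]),
                 .res_uid(bonds$chain[ev], bonds$res_seq_j[ev],
                          bonds$i_code_j[ev]))
  }
  if (nrow(centers) > 0L) {
    ev <- centers$evaluable
    checked <- c(checked, .res_uid(centers$chain[ev], centers$res_seq[ev],
                                   centers$i_code[ev]))
  }

  structure(list(
    peptide_bonds = bonds,
    chiral_centers = centers,
    residues_checked = length(unique(checked)),
    residues_total = nrow(res),
    counts = list(
      cis_count = sum(bonds$is_cis),
      chirality_error_count = sum(centers$flagged),
      unevaluable_bonds = sum(!bonds$evaluable),
      unevaluable_centers = sum(!centers$evaluable)),
    config = cfg), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> %d peptide bond(s), %d chiral center(s), %d residue(s) checked (%d total)\n",
    nrow(x$peptide_bonds), nrow(x$chiral_centers), x$residues_checked,
    x$residues_total))
  cat(sprintf("  cis bonds: %d  chirality flags: %d  unevaluable: %d bond(s), %d center(s)\n",
              x$counts$cis_count, x$counts$chirality_error_count,
              x$counts$unevaluable_bonds, x$counts$unevaluable_centers))
  b <- x$peptide_bonds
  for (i in which(b$is_cis))
    cat(sprintf("  cis peptide bond %s %s%d%s - %s %s%d%s (omega' = %.2f)%s\n",
                b$res_name_i[i], b$chain[i], b$res_seq_i[i], b$i_code_i[i],
                b$res_name_j[i], b$chain[i], b$res_seq_j[i], b$i_code_j[i],
                b$omega_prime[i],
                if (b$pre_proline[i]) " [pre-proline]" else ""))
  cc <- x$chiral_centers
  for (i in which(cc$flagged))
    cat(sprintf("  chirality flag at %s %s%d%s %s (improper = %.2f)\n",
                cc$res_name[i], cc$chain[i], cc$res_seq[i], cc$i_code[i],
                cc$center[i], cc$improper[i]))
  invisible(x)
}

# public record columns (hidden atom-row indices removed)
.report_bond_cols <- c("chain", "res_seq_i", "i_code_i", "res_name_i",
                       "res_seq_j", "i_code_j", "res_name_j", "omega",
                       "omega_prime", "is_cis", "pre_proline", "evaluable",
                       "reason_unevaluable")
.report_center_cols <- c("chain", "res_seq", "i_code", "res_name", "center",
                         "improper", "flagged", "evaluable",
                         "reason_unevaluable")

#' Serialize a detection report
#'
#' Writes the per-record tables either as a single tab-separated file
#' (with a `record_type` column distinguishing peptide bonds from chiral
#' centers, angles at 0.01-degree precision) or as JSON.
#'
#' @param report A `detection_report`.
#' @param file Output path; when `NULL` the text is returned invisibly.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the serialized text.
#' @export
write_report <- function(report, file = NULL, format = c("tsv", "json")) {
  stopifnot(inherits(report, "detection_report"))
  format <- match.arg(format)
  b <- report$peptide_bonds[, .report_bond_cols, drop = FALSE]
  cc <- report$chiral_centers[, .report_center_cols, drop = FALSE]
  b$omega <- round(b$omega, 2L)
  b$omega_prime <- round(b$omega_prime, 2L)
  cc$improper <- round(cc$improper, 2L)
  if (format == "json") {
    txt <- jsonlite::toJSON(list(
      peptide_bonds = b, chiral_centers = cc,
      residues_checked = report$residues_checked,
      residues_total = report$residues_total,
      counts = report$counts), auto_unbox = TRUE, pretty = TRUE,
      na = "null")
    if (!is.null(file)) writeLines(txt, file)
    return(invisible(txt))
  }
  all_cols <- union(c("record_type", names(b)), names(cc))
  pad <- function(df, type) {
    if (nrow(df) == 0L) return(NULL)
    df$record_type <- type
    for (col in setdiff(all_cols, names(df))) df[[col]] <- NA
    df[, all_cols, drop = FALSE]
  }
  combined <- rbind(pad(b, "peptide_bond"), pad(cc, "chiral_center"))
  if (is.null(combined)) combined <- data.frame(record_type = character())
  txt <- c(paste(names(combined), collapse = "\t"),
           if (nrow(combined) > 0L)
             apply(combined, 1L, function(r)
               paste(ifelse(is.na(r), "", trimws(as.character(r))),
                     collapse = "\t")))
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
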