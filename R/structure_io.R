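# Fixed-column PDB reading and writing, plus parsing of the header
# records used for cross-validation (CISPEP, CAVEAT, REMARK 500, EXPDTA).
#
# Survey policy: only the first model is read, and for alternate
# locations only the first-encountered altLoc identifier per residue is
# retained.

.as_pdb_lines <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x))
    return(list(lines = readLines(x, warn = FALSE), path = x))
  list(lines = unlist(strsplit(as.character(x), "\n", fixed = TRUE)),
       path = NA_character_)
}

.pad80 <- function(lines) formatC(lines, width = -80L)

.num_field <- function(lines, from, to) {
  suppressWarnings(as.numeric(substr(lines, from, to)))
}

#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records from fixed columns.  When several models are
#' present (MODEL/ENDMDL, typical of NMR entries) only the first model is
#' kept; when a residue has alternate conformations (altLoc) only the
#' first-encountered altLoc identifier of that residue is kept, alongside
#' blank-altLoc atoms.  Records whose fixed-column numeric fields fail to
#' parse are skipped with a warning; the number skipped is available as
#' `attr(s, "n_skipped")`.
#'
#' @param x A file path, or PDB text (a single string with newlines or a
#'   character vector of lines).
#' @return A `stereo_structure`.
#' @seealso [write_structure()], [parse_header_annotations()]
#' @export
read_structure <- function(x) {
  src <- .as_pdb_lines(x)
  lines <- .pad80(src$lines)
  rec <- substr(lines, 1L, 6L)
  is_coord <- rec %in% c("ATOM  ", "HETATM")

  # first-model window
  model_id <- 1L
  model_at <- which(rec == "MODEL ")
  endmdl_at <- which(rec == "ENDMDL")
  if (length(model_at) > 0L) {
    first <- model_at[1L]
    mid <- suppressWarnings(as.integer(substr(lines[first], 11L, 14L)))
    if (!is.na(mid)) model_id <- mid
    stop_at <- if (length(endmdl_at) > 0L) endmdl_at[1L] else
      if (length(model_at) > 1L) model_at[2L] else length(lines) + 1L
    is_coord <- is_coord & seq_along(lines) > first & seq_along(lines) < stop_at
  }
  al <- lines[is_coord]
  if (length(al) == 0L)
    stop("no ATOM/HETATM coordinate records found", call. = FALSE)

  atoms <- data.frame(
    serial = as.integer(.num_field(al, 7L, 11L)),
    name = trimws(substr(al, 13L, 16L)),
    alt_loc = trimws(substr(al, 17L, 17L)),
    res_name = trimws(substr(al, 18L, 20L)),
    chain = substr(al, 22L, 22L),
    res_seq = as.integer(.num_field(al, 23L, 26L)),
    i_code = trimws(substr(al, 27L, 27L)),
    x = .num_field(al, 31L, 38L),
    y = .num_field(al, 39L, 46L),
    z = .num_field(al, 47L, 54L),
    occupancy = .num_field(al, 55L, 60L),
    b_factor = .num_field(al, 61L, 66L),
    element = trimws(substr(al, 77L, 78L)),
    is_hetero = substr(al, 1L, 6L) == "HETATM",
    stringsAsFactors = FALSE)

  bad <- is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z) |
    is.na(atoms$res_seq) | atoms$name == ""
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d malformed coordinate record(s): %s",
                    n_skipped,
                    paste(utils::head(trimws(al[bad]), 3L), collapse = "; ")),
            call. = FALSE)
    atoms <- atoms[!bad, , drop = FALSE]
  }
  if (nrow(atoms) == 0L)
    stop("no parseable ATOM/HETATM coordinate records found", call. = FALSE)
  atoms$serial[is.na(atoms$serial)] <- seq_len(nrow(atoms))[is.na(atoms$serial)]
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$b_factor[is.na(atoms$b_factor)] <- 0
  no_el <- atoms$element == ""
  atoms$element[no_el] <- .element_from_name(atoms$name[no_el])

  # first-conformation policy: per residue, keep blank altLoc plus the
  # first altLoc identifier encountered in file order
  uid <- .res_uid(atoms$chain, atoms$res_seq, atoms$i_code)
  keep <- rep(TRUE, nrow(atoms))
  has_alt <- atoms$alt_loc != ""
  if (any(has_alt)) {
    first_alt <- tapply(atoms$alt_loc[has_alt], uid[has_alt], `[`, 1L)
    keep[has_alt] <- atoms$alt_loc[has_alt] ==
      unname(first_alt[uid[has_alt]])
    atoms <- atoms[keep, , drop = FALSE]
    uid <- uid[keep]
  }

  # duplicate atom names within a residue (after altLoc choice): first wins
  dup <- duplicated(paste(uid, atoms$name))
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate atom name(s) within residues",
                    sum(dup)), call. = FALSE)
    atoms <- atoms[!dup, , drop = FALSE]
  }

  s <- new_structure(atoms, model_id = model_id, source_path = src$path)
  attr(s, "n_skipped") <- n_skipped
  s
}

#' Parse PDB header annotations
#'
#' Extracts the header records used to cross-validate stereochemical
#' detections: CISPEP entries (reported cis peptide bonds with their
#' omega angles), CAVEAT presence and text, REMARK 500 lines with
#' chirality phrasing, and the EXPDTA experimental method mapped to the
#' categories used for per-method aggregation.
#'
#' @param x A file path or PDB text (as in [read_structure()]).
#' @return An object of class `header_annotations`: a list with
#'   `cispep_entries` (data.frame), `caveat_present`, `caveat_text`,
#'   `remark500_chirality_lines`, `experimental_method` and
#'   `unparsed_lines`.
#' @export
parse_header_annotations <- function(x) {
  lines <- .pad80(.as_pdb_lines(x)$lines)
  rec <- substr(lines, 1L, 6L)

  cis_lines <- lines[rec == "CISPEP"]
  unparsed <- character()
  cis <- data.frame(res_name_1 = character(), chain_1 = character(),
                    seq_1 = integer(), i_code_1 = character(),
                    res_name_2 = character(), chain_2 = character(),
                    seq_2 = integer(), i_code_2 = character(),
                    angle = numeric(), stringsAsFactors = FALSE)
  for (ln in cis_lines) {
    entry <- data.frame(
      res_name_1 = trimws(substr(ln, 12L, 14L)),
      chain_1 = substr(ln, 16L, 16L),
      seq_1 = suppressWarnings(as.integer(substr(ln, 18L, 21L))),
      i_code_1 = trimws(substr(ln, 22L, 22L)),
      res_name_2 = trimws(substr(ln, 26L, 28L)),
      chain_2 = substr(ln, 30L, 30L),
      seq_2 = suppressWarnings(as.integer(substr(ln, 32L, 35L))),
      i_code_2 = trimws(substr(ln, 36L, 36L)),
      angle = suppressWarnings(as.numeric(substr(ln, 54L, 59L))),
      stringsAsFactors = FALSE)
    if (is.na(entry$seq_1) || is.na(entry$seq_2) ||
        entry$res_name_1 == "" || entry$res_name_2 == "") {
      warning("retaining unparseable CISPEP record as raw text",
              call. = FALSE)
      unparsed <- c(unparsed, trimws(ln))
    } else {
      cis <- rbind(cis, entry)
    }
  }

  caveat_lines <- lines[rec == "CAVEAT"]
  caveat_text <- paste(trimws(substr(caveat_lines, 20L, 79L)),
                       collapse = " ")

  r500 <- lines[rec == "REMARK" &
                  trimws(substr(lines, 8L, 10L)) == "500"]
  chir <- grepl("CHIRAL|IMPROPER|D-AMINO|HANDEDNESS", r500,
                ignore.case = TRUE)

  exp_lines <- lines[rec == "EXPDTA"]
  method <- "other"
  if (length(exp_lines) > 0L) {
    txt <- toupper(paste(trimws(substr(exp_lines, 11L, 79L)),
                         collapse = "; "))
    method <- if (grepl("X-RAY DIFFRACTION", txt)) "X-ray diffraction"
    else if (grepl("SOLUTION NMR", txt)) "Solution NMR"
    else if (grepl("ELECTRON MICROSCOPY", txt)) "Electron microscopy"
    else "other"
  }

  structure(list(cispep_entries = cis,
                 caveat_present = length(caveat_lines) > 0L,
                 caveat_text = caveat_text,
                 remark500_chirality_lines = trimws(r500[chir]),
                 experimental_method = method,
                 unparsed_lines = unparsed),
            class = "header_annotations")
}

#' @export
print.header_annotations <- function(x, ...) {
  cat(sprintf(
    "<header_annotations> method: %s; CISPEP: %d; CAVEAT: %s; REMARK 500 chirality lines: %d\n",
    x$experimental_method, nrow(x$cispep_entries),
    if (x$caveat_present) "yes" else "no",
    length(x$remark500_chirality_lines)))
  invisible(x)
}

.format_atom_line <- function(rec, serial, name, alt, res_name, chain,
                              res_seq, i_code, x, y, z, occ, b, element) {
  if (nchar(name) > 4L)
    stop(sprintf("atom name '%s' does not fit PDB fixed columns", name),
         call. = FALSE)
  if (nchar(res_name) > 3L)
    stop(sprintf("residue name '%s' does not fit PDB fixed columns",
                 res_name), call. = FALSE)
  if (serial > 99999L)
    stop(sprintf("atom serial %d does not fit PDB fixed columns", serial),
         call. = FALSE)
  if (res_seq > 9999L || res_seq < -999L)
    stop(sprintf("residue number %d does not fit PDB fixed columns",
                 res_seq), call. = FALSE)
  if (any(abs(c(x, y, z)) >= 10000))
    stop(sprintf("coordinates of atom %d do not fit PDB fixed columns",
                 serial), call. = FALSE)
  # single-letter-element names start in column 14
  name_f <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name_f, substr(alt, 1L, 1L), res_name, chain,
          res_seq, substr(i_code, 1L, 1L), x, y, z, occ, b,
          toupper(substr(element, 1L, 2L)))
}

#' Write a structure as PDB text
#'
#' Serializes the atom table back to fixed-column ATOM/HETATM records
#' (coordinates as %8.3f, so the read/write round trip is lossless to
#' 0.001 Angstrom), with a TER line after each chain.  Atom serial numbers
#' are renumbered 1..n in table order; this is the serialized atom order
#' that restraint specifications index into.
#'
#' @param s A `stereo_structure`.
#' @param file Optional path; when given the text is written there.
#' @param header Optional character vector of header lines (e.g. EXPDTA or
#'   CISPEP records) emitted before the coordinates.
#' @return Invisibly, the character vector of PDB lines.
#' @export
write_structure <- function(s, file = NULL, header = NULL) {
  stopifnot(inherits(s, "stereo_structure"))
  a <- s$atoms
  out <- character(0)
  if (nrow(a) > 0L) {
    out <- vapply(seq_len(nrow(a)), function(i) {
      .format_atom_line(if (a$is_hetero[i]) "HETATM" else "ATOM",
                        i, a$name[i], a$alt_loc[i], a$res_name[i],
                        a$chain[i], a$res_seq[i], a$i_code[i],
                        a$x[i], a$y[i], a$z[i],
                        a$occupancy[i], a$b_factor[i], a$element[i])
    }, character(1))
    # TER after the last atom of each chain block
    chain_end <- cumsum(rle(a$chain)$lengths)
    out <- unlist(lapply(seq_along(chain_end), function(k) {
      from <- if (k == 1L) 1L else chain_end[k - 1L] + 1L
      c(out[from:chain_end[k]], "TER")
    }))
  }
  out <- c(header, out, "END")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

# Fixed-column CISPEP record (used when fixtures emit annotated files).
format_cispep_record <- function(ser, res_name_1, chain_1, seq_1,
                                 res_name_2, chain_2, seq_2,
                                 angle, i_code_1 = "", i_code_2 = "",
                                 mod_num = 0L) {
  sprintf("CISPEP %3d %3s %1s %4d%1s   %3s %1s %4d%1s       %3d       %6.2f",
          ser, res_name_1, chain_1, seq_1, substr(i_code_1, 1L, 1L),
          res_name_2, chain_2, seq_2, substr(i_code_2, 1L, 1L),
          mod_num, angle)
}
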