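# The coordinate container: a flat atom table plus model metadata.
# Atoms are kept in file order; a residue is identified by
# (chain, res_seq, i_code).

.ATOM_COLS <- c("serial", "name", "alt_loc", "res_name", "chain",
                "res_seq", "i_code", "x", "y", "z", "occupancy",
                "b_factor", "element", "is_hetero")

new_structure <- function(atoms, model_id = 1L, source_path = NA_character_) {
  stopifnot(is.data.frame(atoms), all(.ATOM_COLS %in% names(atoms)))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model_id = as.integer(model_id),
                 source_path = source_path),
            class = "stereo_structure")
}

#' @export
print.stereo_structure <- function(x, ...) {
  res <- residues(x)
  cat(sprintf("<stereo_structure> %d atoms, %d residues, %d chain(s), model %d\n",
              nrow(x$atoms), nrow(res), length(unique(x$atoms$chain)),
              x$model_id))
  if (!is.na(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

# Unique residue key, stable across the package.
.res_uid <- function(chain, res_seq, i_code) {
  paste(chain, res_seq, ifelse(is.na(i_code) | i_code == "", "_", i_code),
        sep = ":")
}

#' Residue table of a structure
#'
#' @param s A `stereo_structure`.
#' @return A data.frame with one row per residue, in file order: `chain`,
#'   `res_seq`, `i_code`, `res_name`, `is_hetero` and the internal key
#'   `uid`.
#' @export
residues <- function(s) {
  a <- s$atoms
  uid <- .res_uid(a$chain, a$res_seq, a$i_code)
  keep <- !duplicated(uid)
  data.frame(chain = a$chain[keep], res_seq = a$res_seq[keep],
             i_code = a$i_code[keep], res_name = a$res_name[keep],
             is_hetero = a$is_hetero[keep], uid = uid[keep],
             stringsAsFactors = FALSE)
}

# Row index of a named atom in a residue (NA when absent; first wins).
.atom_row <- function(s, uid, name) {
  a <- s$atoms
  hit <- which(.res_uid(a$chain, a$res_seq, a$i_code) == uid & a$name == name)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

.atom_xyz <- function(s, row) {
  if (is.na(row)) return(NULL)
  as.numeric(s$atoms[row, c("x", "y", "z")])
}

.xyz_matrix <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

.set_xyz <- function(s, rows, xyz) {
  s$atoms[rows, c("x", "y", "z")] <- xyz
  s
}
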