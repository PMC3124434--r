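# Batch scanning of many structure files, cross-validation against header
# annotations, and per-method aggregation of error rates.

#' Cross-validate a detection report against header annotations
#'
#' Each detected cis peptide bond is matched against the CISPEP records on
#' the (chain, sequence number, insertion code) of both residues:
#' detections without a matching record are `unreported_cis`, records
#' without a matching detection are `header_only_cis`.  Chirality is
#' compared at structure level only -- CAVEAT records are free text and
#' chirality outliers are often documented inconsistently in REMARK 500 --
#' giving `unreported_chirality` / `header_only_chirality` items.
#'
#' @param report A `detection_report`.
#' @param hdr A `header_annotations` object from the same file.
#' @return A data.frame of discrepancies: `category`, `site`, `detail`.
#' @export
compare_with_header <- function(report, hdr) {
  stopifnot(inherits(report, "detection_report"),
            inherits(hdr, "header_annotations"))
  items <- list()
  add <- function(category, site, detail)
    items[[length(items) + 1L]] <<- data.frame(
      category = category, site = site, detail = detail,
      stringsAsFactors = FALSE)

  b <- report$peptide_bonds
  det_keys <- character(0)
  if (nrow(b) > 0L) {
    det <- b[b$is_cis, , drop = FALSE]
    det_keys <- paste(det$chain, det$res_seq_i, det$i_code_i,
                      det$chain, det$res_seq_j, det$i_code_j)
    hdr_keys <- with(hdr$cispep_entries,
                     paste(chain_1, seq_1, i_code_1, chain_2, seq_2,
                           i_code_2))
    for (i in seq_len(nrow(det)))
      if (!det_keys[i] %in% hdr_keys)
        add("unreported_cis",
            sprintf("%s:%d-%s:%d", det$chain[i], det$res_seq_i[i],
                    det$chain[i], det$res_seq_j[i]),
            sprintf("detected cis bond (omega' = %.2f) absent from CISPEP records",
                    det$omega_prime[i]))
    for (i in seq_len(nrow(hdr$cispep_entries)))
      if (!hdr_keys[i] %in% det_keys)
        add("header_only_cis",
            sprintf("%s:%d-%s:%d", hdr$cispep_entries$chain_1[i],
                    hdr$cispep_entries$seq_1[i],
                    hdr$cispep_entries$chain_2[i],
                    hdr$cispep_entries$seq_2[i]),
            "CISPEP record without a detected cis bond")
  }

  flagged <- report$counts$chirality_error_count > 0L
  evidence <- hdr$caveat_present ||
    length(hdr$remark500_chirality_lines) > 0L
  if (flagged && !evidence)
    add("unreported_chirality", "structure",
        sprintf("%d chirality flag(s) without CAVEAT/REMARK 500 annotation",
                report$counts$chirality_error_count))
  if (evidence && !flagged)
    add("header_only_chirality", "structure",
        "CAVEAT/REMARK 500 chirality annotation without a detected flag")

  if (length(items) == 0L)
    return(data.frame(category = character(), site = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, items)
}

.empty_survey_row <- function(source) {
  row <- data.frame(source = "", experimental_method = "other",
                    residues_checked = 0L, residues_total = 0L,
                    cis_count = 0L, chirality_error_count = 0L,
                    unevaluable_bonds = 0L, unevaluable_centers = 0L,
                    n_discrepancies = 0L, parse_failed = TRUE,
                    stringsAsFactors = FALSE)
  row <- row[rep(1L, length(source)), , drop = FALSE]
  row$source <- source
  rownames(row) <- NULL
  row
}

#' Batch-scan structure files
#'
#' Runs detection and header cross-validation over a set of PDB files.
#' Files are processed independently (results do not depend on order);
#' parse failures are recorded per file, never fatal.  When a cache path
#' is given, per-file results are stored as JSON lines keyed by file
#' checksum, so an interrupted survey resumes where it stopped.
#'
#' @param paths Character vector of PDB file paths.
#' @param cfg A [detection_config()].
#' @param cache Optional path of a JSON-lines cache file.
#' @param verbose Log progress to stderr.
#' @return A data.frame of class `survey_results`, one row per file, with
#'   per-file discrepancy tables in `attr(, "discrepancies")`.
#' @export
survey_structures <- function(paths, cfg = detection_config(),
                              cache = NULL, verbose = FALSE) {
  cached <- list()
  if (!is.null(cache) && file.exists(cache)) {
    for (ln in readLines(cache, warn = FALSE)) {
      rec <- jsonlite::fromJSON(ln)
      cached[[rec$checksum]] <- rec
    }
  }
  rows <- vector("list", length(paths))
  discrepancies <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    path <- paths[k]
    if (verbose) message("surveying ", path)
    checksum <- tryCatch(unname(tools::md5sum(path)),
                         error = function(e) NA_character_)
    if (!is.na(checksum) && !is.null(cached[[checksum]])) {
      rec <- cached[[checksum]]
      rows[[k]] <- as.data.frame(rec$row, stringsAsFactors = FALSE)
      rows[[k]]$source <- path
      discrepancies[[k]] <- as.data.frame(rec$discrepancies)
      next
    }
    result <- tryCatch({
      s <- suppressWarnings(read_structure(path))
      hdr <- parse_header_annotations(path)
      rep <- check_structure(s, cfg)
      disc <- compare_with_header(rep, hdr)
      list(row = data.frame(
        source = path, experimental_method = hdr$experimental_method,
        residues_checked = rep$residues_checked,
        residues_total = rep$residues_total,
        cis_count = rep$counts$cis_count,
        chirality_error_count = rep$counts$chirality_error_count,
        unevaluable_bonds = rep$counts$unevaluable_bonds,
        unevaluable_centers = rep$counts$unevaluable_centers,
        n_discrepancies = nrow(disc), parse_failed = FALSE,
        stringsAsFactors = FALSE), disc = disc)
    }, error = function(e) {
      if (verbose) message("  parse failed: ", conditionMessage(e))
      list(row = .empty_survey_row(path),
           disc = compare_with_header(
             structure(list(peptide_bonds = data.frame(),
                            chiral_centers = data.frame(),
                            residues_checked = 0L, residues_total = 0L,
                            counts = list(cis_count = 0L,
                                          chirality_error_count = 0L,
                                          unevaluable_bonds = 0L,
                                          unevaluable_centers = 0L)),
                       class = "detection_report"),
             tryCatch(parse_header_annotations(path), error = function(e2)
               structure(list(cispep_entries = data.frame(),
                              caveat_present = FALSE, caveat_text = "",
                              remark500_chirality_lines = character(),
                              experimental_method = "other"),
                         class = "header_annotations"))))
    })
    rows[[k]] <- result$row
    discrepancies[[k]] <- result$disc
    if (!is.null(cache) && !is.na(checksum)) {
      line <- jsonlite::toJSON(list(checksum = checksum, row = result$row,
                                    discrepancies = result$disc),
                               dataframe = "columns", auto_unbox = TRUE)
      cat(line, "\n", sep = "", file = cache, append = TRUE)
    }
  }
  out <- if (length(rows) == 0L) .empty_survey_row(character(0))[0L, ]
  else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "discrepancies") <- discrepancies
  class(out) <- c("survey_results", "data.frame")
  out
}

#' Aggregate survey results by experimental method
#'
#' Produces one row per experimental method present plus an "All" row.
#' `total_errors` sums the requested error kind(s); `residues_per_error`
#' is total residues checked divided by total errors, rounded to integer
#' (absent when there are no errors); the percentage of structures with
#' errors is rounded to integer percent.
#'
#' @param results A `survey_results` data.frame (parse failures are
#'   excluded from the denominators).
#' @param kind Which errors to count: `"all"` (chirality + cis),
#'   `"chirality"` or `"cis"`.
#' @return A data.frame with columns `method`, `total_errors`,
#'   `residues_per_error`, `structures_analyzed`, `structures_with_errors`
#'   and `pct_with_errors`.
#' @export
aggregate_by_method <- function(results, kind = c("all", "chirality", "cis")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(results))
  res <- results[!results$parse_failed, , drop = FALSE]
  errors <- switch(kind,
                   all = res$chirality_error_count + res$cis_count,
                   chirality = res$chirality_error_count,
                   cis = res$cis_count)
  one_row <- function(label, idx) {
    tot <- sum(errors[idx])
    nres <- sum(res$residues_checked[idx])
    data.frame(
      method = label,
      total_errors = tot,
      residues_per_error = if (tot > 0L) as.integer(round(nres / tot))
      else NA_integer_,
      structures_analyzed = length(idx),
      structures_with_errors = sum(errors[idx] > 0L),
      pct_with_errors = if (length(idx) > 0L)
        as.integer(round(100 * sum(errors[idx] > 0L) / length(idx)))
      else NA_integer_,
      stringsAsFactors = FALSE)
  }
  methods <- sort(unique(res$experimental_method))
  rows <- lapply(methods, function(m)
    one_row(m, which(res$experimental_method == m)))
  out <- rbind(one_row("All", seq_len(nrow(res))), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Write survey outputs as TSV
#'
#' @param results A `survey_results` data.frame.
#' @param dir Output directory; writes `survey_results.tsv` (per file),
#'   `survey_by_method.tsv` (aggregate in the layout of a per-method
#'   summary table) and `discrepancies.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_survey <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "survey_results.tsv")
  utils::write.table(as.data.frame(results), p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  agg <- rbind(cbind(kind = "chirality",
                     aggregate_by_method(results, "chirality")),
               cbind(kind = "cis", aggregate_by_method(results, "cis")))
  p2 <- file.path(dir, "survey_by_method.tsv")
  utils::write.table(agg, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  disc <- attr(results, "discrepancies")
  dd <- do.call(rbind, lapply(seq_along(disc), function(k) {
    d <- disc[[k]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    cbind(source = results$source[k], d)
  }))
  p3 <- file.path(dir, "discrepancies.tsv")
  if (is.null(dd))
    dd <- data.frame(source = character(), category = character(),
                     site = character(), detail = character())
  utils::write.table(dd, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
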