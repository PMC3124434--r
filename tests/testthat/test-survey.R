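test_that("surveying the battery reproduces the per-file expected counts", {
  dir <- battery_dir()
  expected <- utils::read.delim(file.path(dir, "expected_counts.tsv"))
  res <- survey_structures(file.path(dir, expected$file))
  expect_equal(res$cis_count, expected$cis_count)
  expect_equal(res$chirality_error_count, expected$chirality_error_count)
  expect_false(any(res$parse_failed))
  expect_true(all(res$experimental_method == "X-ray diffraction"))
})

test_that("an unreadable file is recorded as a parse failure, others unaffected", {
  dir <- battery_dir()
  bad <- tempfile(fileext = ".pdb")
  writeLines("HEADER    NOTHING HERE", bad)
  res <- survey_structures(c(file.path(dir, "clean.pdb"), bad,
                             file.path(dir, "one_cis.pdb")))
  expect_equal(res$parse_failed, c(FALSE, TRUE, FALSE))
  expect_equal(res$cis_count, c(0L, 0L, 1L))
  expect_equal(nrow(survey_structures(character(0))), 0L)
})

test_that("header cross-validation separates matching, missing and false records", {
  dir <- battery_dir()
  with_rec <- file.path(dir, "with_cispep.pdb")
  d_match <- compare_with_header(
    check_structure(suppressWarnings(read_structure(with_rec))),
    parse_header_annotations(with_rec))
  expect_equal(nrow(d_match), 0L)

  stripped <- file.path(dir, "one_cis.pdb")
  d_unrep <- compare_with_header(
    check_structure(read_structure(stripped)),
    parse_header_annotations(stripped))
  expect_equal(d_unrep$category, "unreported_cis")
  expect_match(d_unrep$site, "A:8")

  false_rec <- file.path(dir, "false_cispep.pdb")
  d_false <- compare_with_header(
    check_structure(read_structure(false_rec)),
    parse_header_annotations(false_rec))
  expect_equal(d_false$category, "header_only_cis")
})

test_that("chirality discrepancies compare at structure level", {
  dir <- battery_dir()
  one_d <- file.path(dir, "one_d.pdb")
  rep <- check_structure(read_structure(one_d))
  d1 <- compare_with_header(rep, parse_header_annotations(one_d))
  expect_equal(d1$category, "unreported_chirality")
  annotated <- parse_header_annotations(
    c("CAVEAT     XXXX    CHIRALITY ERROR AT GLN 8", readLines(one_d)))
  expect_equal(nrow(compare_with_header(rep, annotated)), 0L)
  clean_rep <- check_structure(read_structure(file.path(dir, "clean.pdb")))
  d2 <- compare_with_header(clean_rep, annotated)
  expect_equal(d2$category, "header_only_chirality")
})

test_that("aggregation arithmetic matches the worked example", {
  mock <- data.frame(
    source = c("a", "b"), experimental_method = "X-ray diffraction",
    residues_checked = c(1000L, 500L), residues_total = c(1000L, 500L),
    cis_count = c(2L, 1L), chirality_error_count = 0L,
    unevaluable_bonds = 0L, unevaluable_centers = 0L,
    n_discrepancies = 0L, parse_failed = FALSE,
    stringsAsFactors = FALSE)
  agg <- aggregate_by_method(mock, kind = "cis")
  xrow <- agg[agg$method == "X-ray diffraction", ]
  expect_equal(xrow$total_errors, 3L)
  expect_equal(xrow$residues_per_error, 500L)
  expect_equal(xrow$structures_analyzed, 2L)
  expect_equal(xrow$structures_with_errors, 2L)
  expect_equal(xrow$pct_with_errors, 100L)
})

test_that("the All row conserves every column across methods", {
  set.seed(7)
  mock <- data.frame(
    source = sprintf("s%02d", 1:12),
    experimental_method = rep(c("X-ray diffraction", "Electron microscopy",
                                "Solution NMR"), each = 4),
    residues_checked = sample(100:2000, 12),
    residues_total = 2000L,
    cis_count = sample(0:3, 12, replace = TRUE),
    chirality_error_count = sample(0:2, 12, replace = TRUE),
    unevaluable_bonds = 0L, unevaluable_centers = 0L,
    n_discrepancies = 0L, parse_failed = FALSE,
    stringsAsFactors = FALSE)
  for (kind in c("all", "chirality", "cis")) {
    agg <- aggregate_by_method(mock, kind = kind)
    all_row <- agg[agg$method == "All", ]
    rest <- agg[agg$method != "All", ]
    expect_equal(all_row$total_errors, sum(rest$total_errors))
    expect_equal(all_row$structures_analyzed,
                 sum(rest$structures_analyzed))
    expect_equal(all_row$structures_with_errors,
                 sum(rest$structures_with_errors))
    # residues-per-error ratio inverts back to the residue total
    with_err <- agg[!is.na(agg$residues_per_error), ]
    for (r in seq_len(nrow(with_err))) {
      idx <- if (with_err$method[r] == "All") seq_len(nrow(mock)) else
        which(mock$experimental_method == with_err$method[r])
      expect_lt(abs(with_err$residues_per_error[r] *
                      with_err$total_errors[r] -
                      sum(mock$residues_checked[idx])),
                with_err$total_errors[r])
    }
  }
})

test_that("aggregation of an empty survey yields a zero All row", {
  empty <- survey_structures(character(0))
  agg <- aggregate_by_method(empty)
  expect_equal(agg$method, "All")
  expect_equal(agg$total_errors, 0L)
  expect_true(is.na(agg$residues_per_error))
})

test_that("survey results are order-invariant", {
  dir <- battery_dir()
  files <- file.path(dir, c("clean.pdb", "one_cis.pdb", "one_d.pdb",
                            "combined.pdb"))
  r1 <- survey_structures(files)
  r2 <- survey_structures(rev(files))
  expect_equal(aggregate_by_method(r1), aggregate_by_method(r2))
  key1 <- r1[order(r1$source), ]
  key2 <- r2[order(r2$source), ]
  rownames(key1) <- rownames(key2) <- NULL
  attr(key1, "discrepancies") <- attr(key2, "discrepancies") <- NULL
  expect_equal(as.data.frame(key1), as.data.frame(key2))
})

test_that("the JSON-lines cache makes surveys resumable", {
  dir <- battery_dir()
  files <- file.path(dir, c("clean.pdb", "one_cis.pdb"))
  cache <- tempfile(fileext = ".jsonl")
  r1 <- survey_structures(files, cache = cache)
  expect_equal(length(readLines(cache)), 2L)
  r2 <- survey_structures(file.path(dir, c("clean.pdb", "one_cis.pdb",
                                           "one_d.pdb")), cache = cache)
  expect_equal(length(readLines(cache)), 3L)
  expect_equal(r2$cis_count, c(0L, 1L, 0L))
  expect_equal(r2$chirality_error_count, c(0L, 0L, 1L))
})

test_that("write_survey emits the three TSV outputs", {
  dir <- battery_dir()
  res <- survey_structures(file.path(dir, c("clean.pdb", "one_cis.pdb")))
  out <- tempfile()
  paths <- write_survey(res, out)
  expect_true(all(file.exists(paths)))
  agg <- utils::read.delim(file.path(out, "survey_by_method.tsv"))
  expect_setequal(unique(agg$kind), c("chirality", "cis"))
})
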