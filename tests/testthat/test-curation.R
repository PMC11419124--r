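# unit tests for the five-stage curation cascade

make_records <- function(...) {
  rows <- list(...)
  defaults <- list(record_id = NA_character_, uniprot_id = "P00519",
                   target_id = "CHEMBL1862", compound_id = "CMPD1",
                   smiles = "CCO", activity_type = "Ki", value = 1,
                   units = "nM", document_id = "DOC1", year = 2010L,
                   authors = "smith a|jones b")
  df <- do.call(rbind, lapply(rows, function(row) {
    filled <- utils::modifyList(defaults, row)
    as.data.frame(filled[names(defaults)], stringsAsFactors = FALSE)
  }))
  if (all(is.na(df$record_id))) {
    df$record_id <- sprintf("R%03d", seq_len(nrow(df)))
  }
  df[affinityforge:::ACTIVITY_RECORD_COLUMNS]
}

test_that("unit standardization is exact on the p-scale", {
  expect_equal(standardize_activity(1, "nM", "Ki")$p_value, 9.0)
  expect_equal(standardize_activity(1000, "nM", "IC50")$p_value, 6.0)
  expect_equal(standardize_activity(1, "uM", "IC50")$p_value, 6.0)
  expect_equal(standardize_activity(1, "µM", "IC50")$p_value, 6.0)
  expect_equal(standardize_activity(1, "M", "Kd")$p_value, 0.0)
  expect_equal(standardize_activity(1, "fM", "Kd")$p_value, 15.0)
  expect_identical(standardize_activity(1, "nM", "Ki")$mtype, "pKi")
  expect_identical(standardize_activity(1, "nM", "Kd")$mtype, "pKd")
  expect_identical(standardize_activity(1, "nM", "IC50")$mtype, "pIC50")
})

test_that("unclear units and nonpositive values are flagged, not computed", {
  std <- standardize_activity(c(5, -1, 2), c("mg/mL", "nM", "NM"),
                              c("Ki", "Ki", "Ki"))
  expect_identical(std$drop_reason,
                   c("unclear units", "nonpositive value", NA))
  expect_true(is.na(std$p_value[1]))
  expect_error(standardize_activity(1, "nM", "EC50"), "EC50")
})

test_that("dummy-target removal drops exactly the flagged identifiers", {
  recs <- make_records(
    list(target_id = "CHEMBL1862"), list(target_id = "CHEMBL612545"),
    list(target_id = "CHEMBL1862"), list(target_id = "CHEMBL1862"),
    list(target_id = "CHEMBL1862")
  )
  out <- remove_dummy_targets(recs)
  expect_identical(nrow(out), 4L)
  expect_identical(attr(out, "drops")$record_id, "R002")

  expect_identical(nrow(remove_dummy_targets(recs, character(0))), 5L)
  all_gone <- remove_dummy_targets(recs, unique(recs$target_id))
  expect_identical(nrow(all_gone), 0L)
  expect_identical(nrow(attr(all_gone, "drops")), 5L)
})

test_that("extreme filter is strict at both printed boundaries", {
  recs <- make_records(
    list(value = 11, units = "mM"),    # > 10 mM        -> dropped
    list(value = 10, units = "mM"),    # exactly 10 mM  -> retained (p = 2)
    list(value = 1, units = "pM"),     # p = 12         -> retained
    list(value = 1, units = "fM"),     # exactly 1 fM   -> retained (p = 15)
    list(value = 0.5, units = "fM")    # < 1 fM         -> dropped
  )
  std <- standardize_activity(recs$value, recs$units, recs$activity_type)
  recs$p_value <- std$p_value
  out <- filter_extremes(recs)
  expect_identical(out$record_id, c("R002", "R003", "R004"))
  drops <- attr(out, "drops")
  expect_setequal(drops$record_id, c("R001", "R005"))
  expect_setequal(drops$reason, c("extreme concentration > 10 mM",
                                  "extreme concentration < 1 fM"))
})

test_that("within-publication collapse keeps the highest value, ties by index", {
  recs <- make_records(
    list(value = 10^(9 - 6.1)), list(value = 10^(9 - 7.3)),
    list(document_id = "DOC2", value = 1)
  )
  recs$.idx <- seq_len(nrow(recs))
  std <- standardize_activity(recs$value, recs$units, recs$activity_type)
  recs$p_value <- std$p_value
  recs$system_key <- "S"
  out <- collapse_within_document(recs)
  expect_setequal(out$record_id, c("R002", "R003"))
  expect_equal(out$p_value[out$record_id == "R002"], 7.3)

  # exact tie: exactly one survivor, the earlier-ingested row
  tie <- make_records(list(value = 1), list(value = 1))
  tie$.idx <- 1:2
  tie$p_value <- c(7, 7)
  tie$system_key <- "S"
  kept <- collapse_within_document(tie)
  expect_identical(kept$record_id, "R001")
})

test_that("citation dedup keeps the earliest-year document of an identical value", {
  recs <- make_records(
    list(document_id = "A", year = 2010L, value = 10^(9 - 7.3)),
    list(document_id = "B", year = 2015L, value = 10^(9 - 7.3)),
    list(document_id = "C", year = 2012L, value = 10^(9 - 7.31))
  )
  recs$.idx <- seq_len(nrow(recs))
  recs$p_value <- standardize_activity(recs$value, recs$units,
                                       recs$activity_type)$p_value
  recs$system_key <- "S"
  out <- remove_cited_duplicates(recs)
  # 7.30 vs 7.31 differ beyond tolerance: both kept; B is a citation of A
  expect_setequal(out$record_id, c("R001", "R003"))

  # three documents, identical value, earliest year survives
  chain <- make_records(
    list(document_id = "A", year = 2015L),
    list(document_id = "B", year = 2010L),
    list(document_id = "C", year = 2012L)
  )
  chain$.idx <- 1:3
  chain$p_value <- rep(9, 3)
  chain$system_key <- "S"
  kept <- remove_cited_duplicates(chain)
  expect_identical(kept$record_id, "R002")

  # missing year is never the kept original
  noyr <- make_records(
    list(document_id = "A", year = NA_integer_),
    list(document_id = "B", year = 2018L)
  )
  noyr$.idx <- 1:2
  noyr$p_value <- c(8, 8)
  noyr$system_key <- "S"
  expect_identical(remove_cited_duplicates(noyr)$record_id, "R002")
})

test_that("author-overlap dedup keeps one record per connected component", {
  recs <- make_records(
    list(document_id = "A", year = 2015L, authors = "x x|y y",
         value = 10^(9 - 6)),
    list(document_id = "B", year = 2018L, authors = "y y|z z",
         value = 10^(9 - 7))
  )
  recs$.idx <- 1:2
  recs$p_value <- c(6, 7)
  recs$system_key <- "S"
  expect_identical(remove_author_overlap(recs)$record_id, "R001")

  # disjoint author sets: both kept
  recs$authors <- c("x x", "y y")
  expect_identical(nrow(remove_author_overlap(recs)), 2L)

  # chain A-B, B-C with A,C disjoint still collapses to one record
  chain <- make_records(
    list(document_id = "A", year = 2012L, authors = "a a|b b", value = 1),
    list(document_id = "B", year = 2014L, authors = "b b|c c", value = 2),
    list(document_id = "C", year = 2016L, authors = "c c|d d", value = 3)
  )
  chain$.idx <- 1:3
  chain$p_value <- c(9, 8.7, 8.4)
  chain$system_key <- "S"
  expect_identical(remove_author_overlap(chain)$record_id, "R001")

  # author matching is normalized (case, whitespace)
  norm <- make_records(
    list(document_id = "A", year = 2012L, authors = "Smith  A", value = 1),
    list(document_id = "B", year = 2014L, authors = "smith a", value = 2)
  )
  norm$.idx <- 1:2
  norm$p_value <- c(9, 8)
  norm$system_key <- "S"
  expect_identical(nrow(remove_author_overlap(norm)), 1L)
})

test_that("run_cascade reproduces planted fixture ground truth", {
  fx <- generate_curation_fixture(fixture_spec(n_records = 200, seed = 1))
  res <- run_cascade(fx$records)
  expect_identical(res$report$stages, fx$ground_truth$stages)
  expect_identical(sort(res$records$record_id),
                   fx$ground_truth$survivor_ids)
  # measurements carry p-scale values and verbatim provenance
  m <- res$measurements[[1]]
  expect_true(m$mtype %in% c("pKd", "pKi", "pIC50"))
  expect_false(is.na(m$metadata$original_units))
})

test_that("cascade handles empty input and is idempotent", {
  fx <- generate_curation_fixture(fixture_spec(n_records = 80, seed = 5))
  empty <- fx$records[0, ]
  res0 <- run_cascade(empty)
  expect_length(res0$measurements, 0L)
  expect_true(all(res0$report$stages$records_in == 0L))
  expect_true(all(res0$report$stages$records_out == 0L))

  once <- run_cascade(fx$records)
  twice <- run_cascade(once$records)
  expect_identical(sort(twice$records$record_id),
                   sort(once$records$record_id))
  expect_identical(twice$report$stages$records_in,
                   rep(nrow(once$records), 5L))
})

test_that("a fixture with nothing planted passes through unchanged", {
  spec <- fixture_spec(n_records = 40, seed = 3, n_dummy_targets = 0,
                       n_extreme_high = 0, n_extreme_low = 0,
                       n_unclear_units = 0,
                       n_within_doc_duplicate_groups = 0,
                       n_citation_chains = 0,
                       n_author_overlap_components = 0)
  fx <- generate_curation_fixture(spec)
  res <- run_cascade(fx$records)
  expect_true(all(res$report$stages$records_out == 40L))
})

test_that("record counts never increase and reports chain across stages", {
  fx <- generate_curation_fixture(fixture_spec(n_records = 150, seed = 9))
  st <- run_cascade(fx$records)$report$stages
  expect_true(all(st$records_out <= st$records_in))
  expect_identical(st$records_in[-1], st$records_out[-5])
  expect_error(
    CurationReport(data.frame(stage = c("a", "b"),
                              records_in = c(10L, 9L),
                              records_out = c(8L, 7L)),
                   list(NULL, NULL)),
    "chain"
  )
})

test_that("permuting input rows changes no report counts", {
  fx <- generate_curation_fixture(fixture_spec(n_records = 100, seed = 13))
  res1 <- run_cascade(fx$records)
  perm <- affinityforge:::with_seed(99,
    fx$records[sample.int(nrow(fx$records)), , drop = FALSE])
  res2 <- run_cascade(perm)
  expect_identical(res1$report$stages, res2$report$stages)
  expect_identical(sort(res1$records$record_id),
                   sort(res2$records$record_id))
})

test_that("grouped stages agree with the brute-force pairwise oracle", {
  for (seed in c(2, 4, 6)) {
    spec <- random_fixture_spec(seed, n_max = 50)
    fx <- generate_curation_fixture(spec)
    prepared <- oracle_prepare_records(fx$records)
    o3 <- oracle_collapse_within_document(prepared)
    o4 <- oracle_remove_cited_duplicates(o3)
    o5 <- oracle_remove_author_overlap(o4)
    res <- run_cascade(fx$records)
    expect_identical(sort(res$records$record_id), sort(o5$record_id))
  }
})

test_that("missing required columns abort with the column named", {
  fx <- generate_curation_fixture(fixture_spec(n_records = 60, seed = 2))
  broken <- fx$records
  broken$units <- NULL
  expect_error(run_cascade(broken), "units")
})

test_that("curation reports serialize to JSON with the stage schema", {
  fx <- generate_curation_fixture(fixture_spec(n_records = 60, seed = 21))
  res <- run_cascade(fx$records)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_curation_report(res$report, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(parsed$stages, 5L)
  expect_identical(parsed$stages[[1]]$stage, "group_and_remove_dummy")
  expect_identical(parsed$stages[[1]]$records_in, 60L)
})
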