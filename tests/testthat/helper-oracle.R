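# Test helpers: independent brute-force oracles and the Python/RDKit
# reference fingerprint.

# Child Rscript processes (CLI tests) must resolve the package from the
# same library tree as this session, wherever it is installed.
Sys.setenv(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))

# --- brute-force curation oracle -----------------------------------------
# Exhaustive pairwise reimplementation of cascade stages 3-5, written
# independently of the package's grouped/graph-based implementation.
# Records must carry system_key, p_value, document_id, year, authors and an
# ingestion index .idx.

oracle_collapse_within_document <- function(records) {
  keep <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    for (j in seq_len(nrow(records))) {
      if (i == j) next
      same_group <- records$system_key[i] == records$system_key[j] &&
        records$document_id[i] == records$document_id[j]
      if (!same_group) next
      beats <- records$p_value[j] > records$p_value[i] ||
        (records$p_value[j] == records$p_value[i] &&
           records$.idx[j] < records$.idx[i])
      if (beats) keep[i] <- FALSE
    }
  }
  records[keep, , drop = FALSE]
}

# transitive closure of a pairwise relation, then keep the earliest-year
# (missing year = latest; ties by .idx) member of each equivalence class
.oracle_components_keep <- function(records, related) {
  n <- nrow(records)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && related(i, j) && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  year <- ifelse(is.na(records$year), Inf, records$year)
  keep <- logical(n)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    best <- members[order(year[members], records$.idx[members])][1]
    keep[best] <- TRUE
  }
  records[keep, , drop = FALSE]
}

oracle_remove_cited_duplicates <- function(records, tol = 1e-6) {
  .oracle_components_keep(records, function(i, j) {
    records$system_key[i] == records$system_key[j] &&
      abs(records$p_value[i] - records$p_value[j]) <= tol
  })
}

oracle_remove_author_overlap <- function(records) {
  sets <- lapply(records$authors, affinityforge:::parse_authors)
  .oracle_components_keep(records, function(i, j) {
    records$system_key[i] == records$system_key[j] &&
      length(intersect(sets[[i]], sets[[j]])) > 0L
  })
}

# prepare raw fixture records for the stage-3..5 oracles: canonical system
# key, p-scale value, ingestion index (mirrors cascade stages 1-2)
oracle_prepare_records <- function(records,
                                   dummy_ids = "CHEMBL612545") {
  records$.idx <- seq_len(nrow(records))
  records <- records[!(records$target_id %in% dummy_ids), , drop = FALSE]
  canon <- vapply(records$smiles, canonical_smiles, character(1))
  records$system_key <- paste(records$uniprot_id, canon, sep = "::")
  std <- standardize_activity(records$value, records$units,
                              records$activity_type)
  records$p_value <- std$p_value
  records <- records[is.na(std$drop_reason), , drop = FALSE]
  records[records$p_value >= 2 & records$p_value <= 15, , drop = FALSE]
}

# --- Python / RDKit fingerprint oracle -----------------------------------

oracle_py_path <- function() {
  testthat::test_path("oracle_fp.py")
}

# send one request line per element, return one response line per element
oracle_fp_query <- function(lines) {
  out <- system2("python", shQuote(oracle_py_path()), input = lines,
                 stdout = TRUE, stderr = FALSE)
  stopifnot(length(out) == length(lines))
  out
}

# on-bit positions (0-based) from the reference implementation
oracle_fingerprint_bits <- function(smiles, radius, n_bits) {
  res <- oracle_fp_query(paste("fp", smiles, radius, n_bits))
  lapply(strsplit(res, ","), as.integer)
}

# deterministic random SMILES respellings of one molecule
oracle_respellings <- function(smiles, n, seed) {
  res <- oracle_fp_query(paste("respell", smiles, n, seed))
  strsplit(res, " ")[[1]]
}

# bit positions (0-based) of a package fingerprint tensor
fp_on_bits <- function(tensor) as.integer(which(tensor$values == 1) - 1L)
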