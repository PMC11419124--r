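# The five-stage curation cascade: raw activity rows in, deduplicated
# unit-harmonized measurements out, with a per-stage audit report.
#
# Activity records are plain data.frames in the ChEMBL dialect:
#   record_id, uniprot_id, target_id, compound_id, smiles, activity_type
#   (Kd | Ki | IC50), value, units, document_id, year, authors
# with authors as a "|"-separated string. The cascade runs, in order:
#   1. group by system (protein key + canonical ligand SMILES), remove the
#      database's dummy validation target
#   2. convert activities to the p-scale, drop unclear units and extreme
#      concentrations (> 10 mM or < 1 fM, strict)
#   3. within each (system, publication), keep only the highest p-value
#   4. remove later republications of an identical value (citations)
#   5. remove non-independent measurements from author-overlapping
#      publications, keeping the earliest

ACTIVITY_RECORD_COLUMNS <- c(
  "record_id", "uniprot_id", "target_id", "compound_id", "smiles",
  "activity_type", "value", "units", "document_id", "year", "authors"
)

RAW_ACTIVITY_TYPES <- c(Kd = "pKd", Ki = "pKi", IC50 = "pIC50")

# molar multiplier per recognized unit, micro-sign tolerant, case-insensitive
UNIT_FACTORS <- c(
  fm = 1e-15, pm = 1e-12, nm = 1e-9,
  um = 1e-6, "µm" = 1e-6, "μm" = 1e-6,
  mm = 1e-3, m = 1
)

#' Default configuration for the curation cascade
#'
#' @param dummy_ids Target identifiers to purge in stage 1. Defaults to the
#'   ChEMBL dummy target `CHEMBL612545` used to verify unchecked analyses.
#' @param identical_tol Absolute p-scale tolerance within which two reported
#'   values count as identical for citation deduplication.
#' @param source Source label recorded in the provenance metadata of the
#'   emitted measurements.
#' @return A named list of configuration values.
#' @export
curation_config <- function(dummy_ids = "CHEMBL612545",
                            identical_tol = 1e-6,
                            source = "activity_csv") {
  list(dummy_ids = dummy_ids, identical_tol = identical_tol, source = source)
}

#' Standardize raw activities to the p-scale
#'
#' Converts a concentration-type activity (Kd, Ki or IC50 with a molar-style
#' unit) to its negative base-10 logarithm in molar units: 1 nM Ki becomes
#' pKi 9, 1 uM IC50 becomes pIC50 6. Unrecognized units and non-positive
#' values cannot be standardized and are flagged for dropping.
#'
#' @param value Numeric vector of raw activity values.
#' @param units Character vector of unit strings (fM, pM, nM, uM/µM, mM, M;
#'   case-insensitive).
#' @param rtype Character vector of raw activity types (`Kd`, `Ki`, `IC50`).
#' @return A data.frame with columns `p_value` (numeric, `NA` when not
#'   standardizable), `mtype` (`pKd`/`pKi`/`pIC50`), and `drop_reason`
#'   (`NA` or `"unclear units"` / `"nonpositive value"`).
#' @export
#' @examples
#' standardize_activity(1, "nM", "Ki")$p_value     # 9
#' standardize_activity(1000, "nM", "IC50")$p_value  # 6
standardize_activity <- function(value, units, rtype) {
  n <- max(length(value), length(units), length(rtype))
  value <- rep_len(as.numeric(value), n)
  units <- rep_len(as.character(units), n)
  rtype <- rep_len(as.character(rtype), n)

  bad_type <- !(rtype %in% names(RAW_ACTIVITY_TYPES))
  if (any(bad_type)) {
    stop("unknown raw activity type: ",
         paste(unique(rtype[bad_type]), collapse = ", "))
  }
  factor <- unname(UNIT_FACTORS[tolower(trimws(units))])
  reason <- rep(NA_character_, n)
  reason[is.na(factor)] <- "unclear units"
  reason[is.na(reason) & (!is.finite(value) | value <= 0)] <-
    "nonpositive value"
  p <- rep(NA_real_, n)
  ok <- is.na(reason)
  p[ok] <- -log10(value[ok] * factor[ok])
  data.frame(
    p_value = p,
    mtype = unname(RAW_ACTIVITY_TYPES[rtype]),
    drop_reason = reason,
    stringsAsFactors = FALSE
  )
}

# attach/merge a drops attribute: data.frame(record_id, reason)
.with_drops <- function(records, dropped_ids, reason) {
  drops <- attr(records, "drops") %||%
    data.frame(record_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  if (length(dropped_ids) > 0L) {
    drops <- rbind(drops, data.frame(record_id = dropped_ids,
                                     reason = reason,
                                     stringsAsFactors = FALSE))
  }
  attr(records, "drops") <- drops
  records
}

#' Remove records measured against a dummy target
#'
#' Activity databases carry placeholder targets used to validate unchecked
#' analyses; measurements against them are meaningless and are purged first.
#'
#' @param records Activity-record data.frame.
#' @param dummy_ids Character vector of target identifiers to purge.
#' @return The filtered data.frame; dropped record ids are recorded in the
#'   `"drops"` attribute.
#' @export
remove_dummy_targets <- function(records, dummy_ids = "CHEMBL612545") {
  is_dummy <- records$target_id %in% dummy_ids
  out <- records[!is_dummy, , drop = FALSE]
  .with_drops(out, records$record_id[is_dummy], "dummy target")
}

#' Remove extreme affinity values
#'
#' Drops records whose concentration is strictly greater than 10 mM
#' (p-value < 2) or strictly less than 1 fM (p-value > 15); the boundary
#' concentrations themselves are retained.
#'
#' @param records Activity-record data.frame carrying a `p_value` column.
#' @return Filtered data.frame with drop bookkeeping in the `"drops"`
#'   attribute.
#' @export
filter_extremes <- function(records) {
  stopifnot("p_value" %in% names(records))
  high <- records$p_value < 2    # concentration above 10 mM
  low <- records$p_value > 15    # concentration below 1 fM
  out <- records[!(high | low), , drop = FALSE]
  attr(out, "drops") <- attr(records, "drops")
  out <- .with_drops(out, records$record_id[high],
                     "extreme concentration > 10 mM")
  .with_drops(out, records$record_id[low], "extreme concentration < 1 fM")
}

#' Collapse multiple measurements within one publication
#'
#' Where a system has several measurements in the same publication, only the
#' highest p-value (strongest reported affinity) is retained; ties are
#' broken deterministically by lowest ingestion index.
#'
#' @param records Activity-record data.frame with `system_key`, `p_value`,
#'   `document_id` and `.idx` columns.
#' @return Filtered data.frame, one row per (system, document).
#' @export
collapse_within_document <- function(records) {
  stopifnot(all(c("system_key", "p_value", "document_id") %in%
                  names(records)))
  if (is.null(records$.idx)) records$.idx <- seq_len(nrow(records))
  if (nrow(records) == 0L) return(.with_drops(records, character(), ""))
  grp <- paste(records$system_key, records$document_id, sep = "\r")
  ord <- order(grp, -records$p_value, records$.idx)
  sorted <- records[ord, , drop = FALSE]
  keep_first <- !duplicated(grp[ord])
  out <- sorted[keep_first, , drop = FALSE]
  out <- out[order(out$.idx), , drop = FALSE]
  attr(out, "drops") <- attr(records, "drops")
  dropped <- setdiff(records$record_id, out$record_id)
  .with_drops(out, dropped, "lower value within publication")
}

# normalized author-name sets from a "|"-separated string
parse_authors <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(character())
  parts <- strsplit(s, "[|;]")[[1]]
  parts <- tolower(gsub("\\s+", " ", trimws(parts)))
  unique(parts[nzchar(parts)])
}

# Within one system, keep the earliest-year document of each connected
# component of `edges` (pairs of row indices); missing years sort last, ties
# broken by ingestion index. Returns the row indices to keep.
.keep_component_originals <- function(sub, edges) {
  n <- nrow(sub)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  year <- ifelse(is.na(sub$year), Inf, sub$year)
  keep <- integer(0)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    best <- members[order(year[members], sub$.idx[members])][1]
    keep <- c(keep, best)
  }
  sort(keep)
}

#' Remove republished (cited) duplicate values
#'
#' Within each system, documents reporting an identical value (within
#' `identical_tol` on the p-scale) are treated as citations of the same
#' original experiment; only the earliest-year document's record survives.
#' Records with a missing year are never treated as the original.
#'
#' @param records One record per (system, document), with `system_key`,
#'   `p_value`, `year` columns.
#' @param identical_tol Absolute p-scale tolerance for value identity.
#' @return Filtered data.frame.
#' @export
remove_cited_duplicates <- function(records, identical_tol = 1e-6) {
  if (is.null(records$.idx)) records$.idx <- seq_len(nrow(records))
  keep_ids <- character(0)
  for (key in unique(records$system_key)) {
    sub <- records[records$system_key == key, , drop = FALSE]
    n <- nrow(sub)
    edges <- matrix(integer(0), ncol = 2)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          if (abs(sub$p_value[i] - sub$p_value[j]) <= identical_tol) {
            edges <- rbind(edges, c(i, j))
          }
        }
      }
    }
    keep_ids <- c(keep_ids,
                  sub$record_id[.keep_component_originals(sub, edges)])
  }
  out <- records[records$record_id %in% keep_ids, , drop = FALSE]
  attr(out, "drops") <- attr(records, "drops")
  .with_drops(out, setdiff(records$record_id, keep_ids), "cited duplicate")
}

#' Remove author-overlapping measurements of the same system
#'
#' Within each system, documents whose (normalized) author sets intersect
#' are not independent; from each connected component of the author-overlap
#' graph only the earliest-year document's record is kept. Documents with an
#' empty author list form their own component.
#'
#' @param records One record per (system, document), with `system_key`,
#'   `authors`, `year` columns.
#' @return Filtered data.frame.
#' @export
remove_author_overlap <- function(records) {
  if (is.null(records$.idx)) records$.idx <- seq_len(nrow(records))
  keep_ids <- character(0)
  for (key in unique(records$system_key)) {
    sub <- records[records$system_key == key, , drop = FALSE]
    n <- nrow(sub)
    sets <- lapply(sub$authors, parse_authors)
    edges <- matrix(integer(0), ncol = 2)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
          if (length(intersect(sets[[i]], sets[[j]])) > 0L) {
            edges <- rbind(edges, c(i, j))
          }
        }
      }
    }
    keep_ids <- c(keep_ids,
                  sub$record_id[.keep_component_originals(sub, edges)])
  }
  out <- records[records$record_id %in% keep_ids, , drop = FALSE]
  attr(out, "drops") <- attr(records, "drops")
  .with_drops(out, setdiff(records$record_id, keep_ids), "author overlap")
}

# summarize drops of one stage as named counts
.reason_counts <- function(drops) {
  if (is.null(drops) || nrow(drops) == 0L) return(integer(0))
  tab <- table(drops$reason)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a CurationReport from per-stage counts
#'
#' @param stages data.frame with columns `stage`, `records_in`,
#'   `records_out`.
#' @param drop_reasons Named list (one element per stage) of named integer
#'   vectors of drop reasons.
#' @return An object of class `CurationReport`.
#' @export
CurationReport <- function(stages, drop_reasons) {
  stopifnot(is.data.frame(stages),
            all(c("stage", "records_in", "records_out") %in% names(stages)))
  if (any(stages$records_out > stages$records_in)) {
    stop("records_out must never exceed records_in")
  }
  if (nrow(stages) > 1L) {
    chained <- stages$records_out[-nrow(stages)] == stages$records_in[-1]
    if (!all(chained)) {
      stop("stage counts must chain: records_out of stage k must equal ",
           "records_in of stage k+1")
    }
  }
  structure(list(stages = stages, drop_reasons = drop_reasons),
            class = "CurationReport")
}

#' @export
print.CurationReport <- function(x, ...) {
  cat("<CurationReport>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %d. %-28s %6d -> %6d\n", i, x$stages$stage[i],
                x$stages$records_in[i], x$stages$records_out[i]))
    reasons <- x$drop_reasons[[i]]
    for (r in names(reasons)) {
      cat(sprintf("       - %s: %d\n", r, reasons[[r]]))
    }
  }
  invisible(x)
}

#' Write a CurationReport to JSON
#'
#' @param report A `CurationReport`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curation_report <- function(report, path) {
  stopifnot(inherits(report, "CurationReport"))
  stages <- lapply(seq_len(nrow(report$stages)), function(i) {
    reasons <- report$drop_reasons[[i]]
    list(
      stage = report$stages$stage[i],
      records_in = report$stages$records_in[i],
      records_out = report$stages$records_out[i],
      drop_reasons = if (length(reasons) == 0L) {
        stats::setNames(list(), character(0))
      } else {
        as.list(reasons)
      }
    )
  })
  jsonlite::write_json(list(stages = stages), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the full five-stage curation cascade
#'
#' Executes, in order: system grouping with dummy-target removal; p-scale
#' standardization with unclear-unit and extreme-value filtering;
#' within-publication collapse to the highest value; citation
#' deduplication; author-overlap deduplication. Returns the surviving
#' records as `Measurement` objects together with a chained per-stage
#' report.
#'
#' @param records Activity-record data.frame (see
#'   [ACTIVITY_RECORD_COLUMNS]).
#' @param config Configuration list from [curation_config()].
#' @return A list with elements `measurements` (list of `Measurement`),
#'   `report` (a `CurationReport`), and `records` (the surviving rows of the
#'   input data.frame, raw columns intact).
#' @export
run_cascade <- function(records, config = curation_config()) {
  missing_cols <- setdiff(ACTIVITY_RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- records
  records$.idx <- seq_len(nrow(records))

  stage_names <- c("group_and_remove_dummy", "standardize_and_filter_extremes",
                   "collapse_within_document", "remove_cited_duplicates",
                   "remove_author_overlap")
  counts_in <- integer(5)
  counts_out <- integer(5)
  reasons <- vector("list", 5)

  # Stage 1: group by system (canonical ligand + protein key), drop dummy
  counts_in[1] <- nrow(records)
  canon <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    canon[i] <- tryCatch(canonical_smiles(records$smiles[i]),
                         error = function(e) NA_character_)
  }
  bad <- is.na(canon)
  step <- records[!bad, , drop = FALSE]
  step$system_key <- paste(step$uniprot_id, canon[!bad], sep = "::")
  step <- .with_drops(step, records$record_id[bad], "invalid SMILES")
  step <- remove_dummy_targets(step, config$dummy_ids)
  counts_out[1] <- nrow(step)
  reasons[[1]] <- .reason_counts(attr(step, "drops"))
  attr(step, "drops") <- NULL

  # Stage 2: standardize units to the p-scale, drop extremes
  counts_in[2] <- nrow(step)
  std <- standardize_activity(step$value, step$units, step$activity_type)
  step$p_value <- std$p_value
  step$mtype <- std$mtype
  unclear <- !is.na(std$drop_reason)
  kept <- step[!unclear, , drop = FALSE]
  for (r in unique(std$drop_reason[unclear])) {
    kept <- .with_drops(kept,
                        step$record_id[unclear & std$drop_reason == r], r)
  }
  step <- filter_extremes(kept)
  counts_out[2] <- nrow(step)
  reasons[[2]] <- .reason_counts(attr(step, "drops"))
  attr(step, "drops") <- NULL

  # Stage 3: within-publication collapse
  counts_in[3] <- nrow(step)
  step <- collapse_within_document(step)
  counts_out[3] <- nrow(step)
  reasons[[3]] <- .reason_counts(attr(step, "drops"))
  attr(step, "drops") <- NULL

  # Stage 4: citation dedup
  counts_in[4] <- nrow(step)
  step <- remove_cited_duplicates(step, config$identical_tol)
  counts_out[4] <- nrow(step)
  reasons[[4]] <- .reason_counts(attr(step, "drops"))
  attr(step, "drops") <- NULL

  # Stage 5: author-overlap dedup
  counts_in[5] <- nrow(step)
  step <- remove_author_overlap(step)
  counts_out[5] <- nrow(step)
  reasons[[5]] <- .reason_counts(attr(step, "drops"))
  attr(step, "drops") <- NULL

  report <- CurationReport(
    data.frame(stage = stage_names, records_in = counts_in,
               records_out = counts_out, stringsAsFactors = FALSE),
    reasons
  )

  measurements <- lapply(seq_len(nrow(step)), function(i) {
    row <- step[i, ]
    Measurement(
      system = System(list(
        Protein(uniprot_id = row$uniprot_id),
        Ligand(row$smiles, name = row$compound_id,
               identifiers = list(compound_id = row$compound_id))
      )),
      mtype = row$mtype,
      values = row$p_value,
      conditions = AssayConditions(pH = 7),
      metadata = Metadata(
        source = config$source,
        document_id = row$document_id,
        year = if (is.na(row$year)) NA_integer_ else as.integer(row$year),
        authors = parse_authors(row$authors),
        original_value = row$value,
        original_units = row$units
      )
    )
  })

  survivors <- raw[raw$record_id %in% step$record_id, , drop = FALSE]
  rownames(survivors) <- NULL
  list(measurements = measurements, report = report, records = survivors)
}
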