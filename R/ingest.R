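# Dataset providers: parse ChEMBL-dialect and PKIS2-dialect activity tables
# into DatasetProvider objects, and merge kinase-definition snapshots into a
# UniProt-keyed roster.

#' Default column map for the ChEMBL CSV dialect
#'
#' Maps the canonical activity-record fields to the column headers expected
#' in the input CSV; override entries to adapt to a different export layout.
#'
#' @return Named character vector (field -> column header).
#' @export
chembl_column_map <- function() {
  c(record_id = "record_id", uniprot_id = "uniprot_id",
    target_id = "target_id", compound_id = "compound_id", smiles = "smiles",
    activity_type = "activity_type", value = "value", units = "units",
    document_id = "document_id", year = "year", authors = "authors")
}

# read a csv and rename columns by map; error naming missing columns
.read_mapped_csv <- function(path, column_map) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  missing_cols <- setdiff(unname(column_map), names(df))
  if (length(missing_cols) > 0L) {
    stop("input CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- df[unname(column_map)]
  names(out) <- names(column_map)
  out
}

#' Read a ChEMBL-dialect activity CSV into a DatasetProvider
#'
#' Rows are optionally filtered by target accession and measurement type
#' (after standardization of Kd/Ki/IC50 to pKd/pKi/pIC50), then uniformly
#' subsampled to exactly `sample_size` rows under the given seed. Rows whose
#' units cannot be standardized are excluded and counted in the provenance.
#' The original value and unit strings are preserved verbatim in each
#' measurement's metadata.
#'
#' @param path Path to the CSV file.
#' @param uniprot_ids Optional character vector of accessions to keep.
#' @param mtypes Optional subset of `c("pIC50", "pKi", "pKd")` to keep.
#' @param sample_size Optional number of rows to subsample (exact, without
#'   replacement); must not exceed the rows available after filtering.
#' @param seed Integer seed for the subsample (Mersenne-Twister via
#'   `sample.int`); recorded in the provenance.
#' @param column_map Column map, see [chembl_column_map()].
#' @return A [DatasetProvider].
#' @export
read_chembl_csv <- function(path, uniprot_ids = NULL, mtypes = NULL,
                            sample_size = NULL, seed = 1L,
                            column_map = chembl_column_map()) {
  df <- .read_mapped_csv(path, column_map)
  df$value <- as.numeric(df$value)
  df$year <- suppressWarnings(as.integer(df$year))
  n_read <- nrow(df)

  if (!is.null(uniprot_ids)) {
    df <- df[df$uniprot_id %in% uniprot_ids, , drop = FALSE]
  }
  std <- standardize_activity(df$value, df$units, df$activity_type)
  df$p_value <- std$p_value
  df$mtype <- std$mtype
  n_unclear <- sum(!is.na(std$drop_reason))
  df <- df[is.na(std$drop_reason), , drop = FALSE]
  if (!is.null(mtypes)) {
    bad <- setdiff(mtypes, c("pIC50", "pKi", "pKd"))
    if (length(bad) > 0L) {
      stop("unknown measurement type(s): ", paste(bad, collapse = ", "))
    }
    df <- df[df$mtype %in% mtypes, , drop = FALSE]
  }
  if (!is.null(sample_size)) {
    if (sample_size > nrow(df)) {
      stop("sample_size (", sample_size, ") exceeds the ", nrow(df),
           " rows available after filtering")
    }
    idx <- with_seed(seed, sample.int(nrow(df), size = sample_size))
    df <- df[sort(idx), , drop = FALSE]
  }

  measurements <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    Measurement(
      system = System(list(
        Protein(uniprot_id = row$uniprot_id, name = row$target_id),
        Ligand(row$smiles, name = row$compound_id,
               identifiers = list(compound_id = row$compound_id))
      )),
      mtype = row$mtype,
      values = row$p_value,
      conditions = AssayConditions(pH = 7),
      metadata = Metadata(
        source = "chembl_dialect_csv", document_id = row$document_id,
        year = row$year, authors = parse_authors(row$authors),
        original_value = row$value, original_units = row$units
      )
    )
  })

  DatasetProvider(
    measurements,
    provenance = list(
      source = path, dialect = "chembl",
      uniprot_ids = uniprot_ids, mtypes = mtypes,
      sample_size = sample_size, seed = as.integer(seed),
      rng = "Mersenne-Twister (R sample.int)",
      n_read = n_read, n_unclear_units = n_unclear
    )
  )
}

#' Read a PKIS2-dialect percent-displacement table
#'
#' PKIS2 reports a single measurement type (percent displacement of a probe
#' at one concentration) against kinases identified by display name; the
#' `name_to_uniprot` table resolves display names to UniProt accessions.
#' Unresolvable names either abort (strict) or are collected into a rejects
#' report attached to the provenance (lenient) — never silently dropped.
#'
#' @param path Path to a CSV with columns `smiles`, `compound_name`,
#'   `kinase_name`, `percent_displacement`.
#' @param name_to_uniprot data.frame with columns `name`, `uniprot_id`.
#' @param strict If `TRUE` (default), an unresolved kinase name is an error
#'   listing the offending names.
#' @param probe_concentration Optional molar probe concentration to record
#'   in the assay conditions (the displacement link function requires it;
#'   it is never defaulted).
#' @return A [DatasetProvider]; in lenient mode its provenance carries a
#'   `rejects` data.frame of unresolved rows.
#' @export
read_pkis2_table <- function(path, name_to_uniprot, strict = TRUE,
                             probe_concentration = NULL) {
  if (missing(name_to_uniprot) || is.null(name_to_uniprot)) {
    stop("a kinase name -> UniProt mapping table is required")
  }
  stopifnot(is.data.frame(name_to_uniprot),
            all(c("name", "uniprot_id") %in% names(name_to_uniprot)))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("smiles", "compound_name", "kinase_name",
                "percent_displacement")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("PKIS2 table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$uniprot_id <- name_to_uniprot$uniprot_id[
    match(df$kinase_name, name_to_uniprot$name)]
  unresolved <- is.na(df$uniprot_id)
  if (any(unresolved) && strict) {
    stop("unresolved kinase name(s): ",
         paste(unique(df$kinase_name[unresolved]), collapse = ", "))
  }
  rejects <- df[unresolved, , drop = FALSE]
  df <- df[!unresolved, , drop = FALSE]

  conditions <- AssayConditions(pH = 7,
                                probe_concentration = probe_concentration)
  measurements <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    Measurement(
      system = System(list(
        Protein(uniprot_id = row$uniprot_id, name = row$kinase_name),
        Ligand(row$smiles, name = row$compound_name,
               identifiers = list(supplier = row$compound_name))
      )),
      mtype = "percent_displacement",
      values = as.numeric(row$percent_displacement),
      conditions = conditions,
      metadata = Metadata(
        source = "pkis2_dialect_csv", document_id = "PKIS2",
        original_value = as.numeric(row$percent_displacement),
        original_units = "%"
      )
    )
  })

  DatasetProvider(
    measurements,
    provenance = list(source = path, dialect = "pkis2", strict = strict,
                      rejects = rejects)
  )
}

#' Merge kinase-definition snapshots into a unified roster
#'
#' Different kinase-centric resources define overlapping but non-identical
#' kinase sets under different nomenclatures; the roster unions them on the
#' UniProt accession, keeping a per-source membership flag and display name.
#'
#' @param tables Named list of data.frames, each with columns `uniprot_id`
#'   and `display_name`, one per source.
#' @return A data.frame of class `KinaseRoster`: one row per accession,
#'   logical columns `in_<source>`, character columns `name_<source>`.
#' @export
merge_kinase_lists <- function(tables) {
  stopifnot(is.list(tables), length(tables) > 0L)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (one name per source)")
  }
  for (src in names(tables)) {
    tab <- tables[[src]]
    stopifnot(is.data.frame(tab),
              all(c("uniprot_id", "display_name") %in% names(tab)))
    dup <- tab$uniprot_id[duplicated(tab$uniprot_id)]
    if (length(dup) > 0L) {
      stop("source '", src, "' contains duplicate accession(s): ",
           paste(unique(dup), collapse = ", "))
    }
  }
  accessions <- sort(unique(unlist(
    lapply(tables, function(t) t$uniprot_id))))
  roster <- data.frame(uniprot_id = accessions, stringsAsFactors = FALSE)
  for (src in names(tables)) {
    tab <- tables[[src]]
    roster[[paste0("in_", src)]] <- accessions %in% tab$uniprot_id
    roster[[paste0("name_", src)]] <-
      tab$display_name[match(accessions, tab$uniprot_id)]
  }
  class(roster) <- c("KinaseRoster", class(roster))
  roster
}

#' Number of kinases present in every source of a roster
#'
#' @param roster A `KinaseRoster` from [merge_kinase_lists()].
#' @return Integer size of the intersection across all sources.
#' @export
count_in_all <- function(roster) {
  flags <- roster[, grepl("^in_", names(roster)), drop = FALSE]
  sum(Reduce(`&`, flags))
}
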