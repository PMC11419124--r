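# Durable columnar serialization of (possibly ragged) feature tensors with
# per-record metadata. Each feature is stored as a pair of nested list
# columns — flattened row-major values plus the original shape — so records
# with heterogeneously shaped tensors coexist in one file without padding.

TENSORSTORE_SCHEMA_VERSION <- "1.0"

#' Construct a FeatureRecord
#'
#' The (x, y) pair of one training example: named feature tensors (shapes
#' may differ across records), the observed measurement value and type, and
#' free-form string metadata.
#'
#' @param record_id Unique identifier within a store.
#' @param features Named list of [FeatureTensor]s (plain numeric
#'   vectors/matrices are coerced to float tensors). A feature may be
#'   `NULL` to mark it explicitly absent for this record.
#' @param y_value Observed measurement value (single number).
#' @param y_type Measurement type string.
#' @param metadata Named list of string metadata (provenance, conditions).
#' @return An object of class `FeatureRecord`.
#' @export
FeatureRecord <- function(record_id, features, y_value = NA_real_,
                          y_type = NA_character_, metadata = list()) {
  stopifnot(is_string(record_id), is.list(features))
  if (length(features) > 0L &&
      (is.null(names(features)) || any(!nzchar(names(features))))) {
    stop("features must be a named list")
  }
  features <- lapply(names(features), function(nm) {
    f <- features[[nm]]
    if (is.null(f)) return(NULL)
    if (inherits(f, "FeatureTensor")) return(f)
    if (is.numeric(f)) return(FeatureTensor(nm, f, dtype = "float"))
    stop("feature '", nm, "' is neither a FeatureTensor nor numeric")
  }) |> stats::setNames(names(features))
  structure(
    list(record_id = record_id, features = features,
         y_value = as.numeric(y_value), y_type = y_type,
         metadata = metadata),
    class = "FeatureRecord"
  )
}

#' Write feature records to a Parquet store
#'
#' Ragged tensors are encoded as nested list columns (`feat.<name>` holding
#' row-major flattened values, `feat.<name>.shape` holding the dimensions);
#' metadata keys become `meta.<key>` string columns; the schema version,
#' per-feature dtypes and the supplied provenance are embedded in the file
#' metadata. Output bytes are deterministic for identical records and
#' provenance.
#'
#' @param records List of [FeatureRecord]s (may be empty).
#' @param path Output `.parquet` path.
#' @param provenance Named list (tool version, config hash, seed, ...)
#'   stored as JSON in the file metadata.
#' @return The path, invisibly.
#' @export
write_store <- function(records, path, provenance = list()) {
  stopifnot(is.list(records))
  ok <- vapply(records, inherits, logical(1), what = "FeatureRecord")
  if (!all(ok)) stop("all records must be FeatureRecord objects")
  ids <- vapply(records, function(r) r$record_id, character(1))
  if (anyDuplicated(ids)) {
    stop("record_id values must be unique within a store; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  feat_names <- unique(unlist(lapply(records, function(r) {
    names(r$features)
  })))
  meta_keys <- unique(unlist(lapply(records, function(r) {
    names(r$metadata)
  })))
  n <- length(records)

  df <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  if (n == 0L) df <- data.frame(record_id = character(0))
  df[["y.value"]] <- vapply(records, function(r) r$y_value, numeric(1)) |>
    (\(v) if (n == 0L) numeric(0) else v)()
  df[["y.type"]] <- vapply(records, function(r) r$y_type, character(1)) |>
    (\(v) if (n == 0L) character(0) else v)()

  dtypes <- list()
  for (nm in feat_names) {
    vals <- vector("list", n)
    shapes <- vector("list", n)
    for (i in seq_len(n)) {
      f <- records[[i]]$features[[nm]]
      if (is.null(f)) {
        vals[i] <- list(NULL)
        shapes[i] <- list(NULL)
      } else {
        if (!is.numeric(f$values)) {
          stop("feature '", nm, "' has an unserializable dtype")
        }
        vals[[i]] <- flatten_tensor(f)
        shapes[[i]] <- as.integer(
          if (is.matrix(f$values)) dim(f$values) else length(f$values))
        if (is.null(dtypes[[nm]])) dtypes[[nm]] <- f$dtype
      }
    }
    df[[paste0("feat.", nm)]] <- vals
    df[[paste0("feat.", nm, ".shape")]] <- shapes
  }
  for (key in meta_keys) {
    col <- vapply(records, function(r) {
      v <- r$metadata[[key]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
    df[[paste0("meta.", key)]] <- if (n == 0L) character(0) else col
  }

  tb <- arrow::arrow_table(df)
  tb <- tb$ReplaceSchemaMetadata(list(
    schema_version = TENSORSTORE_SCHEMA_VERSION,
    tool = paste0("affinityforge ",
                  as.character(utils::packageVersion("affinityforge"))),
    feature_dtypes = jsonlite::toJSON(dtypes, auto_unbox = TRUE),
    provenance = jsonlite::toJSON(provenance, auto_unbox = TRUE,
                                  digits = NA)
  ))
  arrow::write_parquet(tb, path)
  invisible(path)
}

#' Read feature records back from a Parquet store
#'
#' Exact inverse of [write_store()]: values, shapes, dtypes and metadata
#' round-trip bit-exactly. Files written under a different schema major
#' version are refused, naming both versions.
#'
#' @param path Path to a store written by [write_store()].
#' @return List of [FeatureRecord]s, in the stored order. The store-level
#'   provenance is attached as the `"provenance"` attribute.
#' @export
read_store <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- tryCatch(
    arrow::read_parquet(path, as_data_frame = FALSE),
    error = function(e) {
      stop("could not read tensor store '", path, "': ",
           conditionMessage(e))
    }
  )
  meta <- tb$metadata
  version <- meta$schema_version
  if (is.null(version)) {
    stop("file carries no tensor-store schema version; refusing to read")
  }
  major <- sub("\\..*$", "", version)
  our_major <- sub("\\..*$", "", TENSORSTORE_SCHEMA_VERSION)
  if (!identical(major, our_major)) {
    stop("tensor-store schema version mismatch: file is ", version,
         ", reader supports ", TENSORSTORE_SCHEMA_VERSION)
  }
  dtypes <- jsonlite::fromJSON(meta$feature_dtypes %||% "{}")
  df <- as.data.frame(tb)
  cols <- names(df)
  feat_cols <- grep("^feat\\.", cols, value = TRUE)
  feat_names <- unique(sub("\\.shape$", "",
                           sub("^feat\\.", "", feat_cols)))
  meta_cols <- grep("^meta\\.", cols, value = TRUE)

  records <- lapply(seq_len(nrow(df)), function(i) {
    features <- list()
    for (nm in feat_names) {
      vals <- df[[paste0("feat.", nm)]][[i]]
      if (is.null(vals)) {
        features[nm] <- list(NULL)
        next
      }
      shape <- df[[paste0("feat.", nm, ".shape")]][[i]]
      dtype <- dtypes[[nm]] %||% "float"
      values <- if (length(shape) == 2L) {
        matrix(vals, nrow = shape[1], ncol = shape[2], byrow = TRUE)
      } else {
        as.numeric(vals)
      }
      features[[nm]] <- FeatureTensor(nm, values, dtype = dtype)
    }
    md <- list()
    for (col in meta_cols) {
      v <- df[[col]][i]
      if (!is.na(v)) md[[sub("^meta\\.", "", col)]] <- v
    }
    FeatureRecord(df$record_id[i], features,
                  y_value = df[["y.value"]][i],
                  y_type = df[["y.type"]][i], metadata = md)
  })
  attr(records, "provenance") <-
    jsonlite::fromJSON(meta$provenance %||% "{}")
  records
}
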