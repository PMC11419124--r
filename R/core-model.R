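# The domain object model: Ligand, Protein, System, AssayConditions,
# Metadata, Measurement, DatasetProvider. Plain S3 with strict validators;
# every other module consumes these types.

MEASUREMENT_TYPES <- c("pIC50", "pKi", "pKd", "percent_displacement")

# 20 canonical amino acids plus 'X' for unknown residues
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a Ligand from a SMILES string
#'
#' The stored SMILES is the canonical form; the string as supplied is
#' retained under the `"input_smiles"` identifier namespace so provenance is
#' never lost.
#'
#' @param smiles SMILES string (any valid spelling).
#' @param name Free-text label; defaults to the input SMILES.
#' @param identifiers Named list mapping identifier namespaces (e.g.
#'   `"chembl"`, `"supplier"`) to identifier strings.
#' @return An object of class `Ligand` with fields `smiles`, `name`,
#'   `identifiers`.
#' @export
#' @examples
#' lig <- Ligand("OCC", name = "ethanol")
#' lig$smiles  # canonical form, identical to Ligand("CCO")$smiles
Ligand <- function(smiles, name = smiles, identifiers = list()) {
  canon <- canonical_smiles(smiles)
  identifiers$input_smiles <- smiles
  structure(
    list(smiles = canon, name = name, identifiers = identifiers),
    class = "Ligand"
  )
}

#' Construct a Protein from identifiers and/or sequence
#'
#' At least one of `uniprot_id`, `ncbi_id` or `sequence` must be given. The
#' sequence, when present, must use the one-letter amino-acid alphabet
#' (20 canonical residues plus `X`).
#'
#' @param uniprot_id UniProt accession (preferred primary key).
#' @param ncbi_id NCBI accession.
#' @param name Display name.
#' @param sequence One-letter amino-acid string.
#' @return An object of class `Protein`.
#' @export
Protein <- function(uniprot_id = NULL, ncbi_id = NULL, name = NULL,
                    sequence = NULL) {
  if (is.null(uniprot_id) && is.null(ncbi_id) && is.null(sequence)) {
    stop("a Protein needs at least one of uniprot_id, ncbi_id or sequence")
  }
  if (!is.null(sequence)) {
    chars <- strsplit(toupper(sequence), "")[[1]]
    bad <- setdiff(unique(chars), AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("sequence contains letters outside the amino-acid alphabet: ",
           paste(bad, collapse = ", "))
    }
    sequence <- paste(chars, collapse = "")
  }
  structure(
    list(uniprot_id = uniprot_id, ncbi_id = ncbi_id, name = name,
         sequence = sequence),
    class = "Protein"
  )
}

#' Primary key of a protein
#'
#' UniProt accession when present, else the NCBI accession, else a hash of
#' the sequence. Used for grouping systems during curation.
#'
#' @param protein A `Protein`.
#' @return A single string.
#' @export
protein_key <- function(protein) {
  stopifnot(inherits(protein, "Protein"))
  if (!is.null(protein$uniprot_id)) return(protein$uniprot_id)
  if (!is.null(protein$ncbi_id)) return(protein$ncbi_id)
  paste0("seq:", format_id(fnv1a32(protein$sequence)))
}

#' Compose molecular components into a System
#'
#' A system is a typed composition of at most one `Ligand` and at most one
#' `Protein`; its `kind` is derived from the composition: `ligand_only`,
#' `protein_only`, or `protein_ligand_complex`.
#'
#' @param components List of `Ligand`/`Protein` objects (1 or 2 components,
#'   at most one of each role).
#' @return An object of class `System` with fields `components` and `kind`.
#' @export
#' @examples
#' sys <- System(list(Protein(uniprot_id = "P00519"), Ligand("CCO")))
#' sys$kind  # "protein_ligand_complex"
System <- function(components) {
  if (!is.list(components) || length(components) < 1L ||
      length(components) > 2L) {
    stop("components must be a list of 1 or 2 Ligand/Protein objects")
  }
  is_lig <- vapply(components, inherits, logical(1), what = "Ligand")
  is_prot <- vapply(components, inherits, logical(1), what = "Protein")
  if (!all(is_lig | is_prot)) {
    stop("components must be Ligand or Protein objects")
  }
  n_lig <- sum(is_lig); n_prot <- sum(is_prot)
  if (n_lig > 1L) stop("a System can hold at most one Ligand")
  if (n_prot > 1L) stop("a System can hold at most one Protein")
  kind <- if (n_lig == 1L && n_prot == 1L) {
    "protein_ligand_complex"
  } else if (n_lig == 1L) {
    "ligand_only"
  } else {
    "protein_only"
  }
  structure(list(components = components, kind = kind), class = "System")
}

#' Extract the Ligand / Protein component of a system
#'
#' @param system A `System`.
#' @return The component, or `NULL` if the system has none of that role.
#' @export
system_ligand <- function(system) {
  stopifnot(inherits(system, "System"))
  for (comp in system$components) if (inherits(comp, "Ligand")) return(comp)
  NULL
}

#' @rdname system_ligand
#' @export
system_protein <- function(system) {
  stopifnot(inherits(system, "System"))
  for (comp in system$components) if (inherits(comp, "Protein")) return(comp)
  NULL
}

#' Structural identity key of a system
#'
#' The pair (protein primary key, ligand canonical SMILES), rendered as a
#' single string. Two systems built from identical canonical components have
#' equal keys; curation groups measurements by this key.
#'
#' @param system A `System`.
#' @return A single string.
#' @export
system_key <- function(system) {
  stopifnot(inherits(system, "System"))
  prot <- system_protein(system)
  lig <- system_ligand(system)
  paste(
    if (is.null(prot)) "-" else protein_key(prot),
    if (is.null(lig)) "-" else lig$smiles,
    sep = "::"
  )
}

#' Assay conditions attached to a measurement
#'
#' @param pH Unitless acidity, in `[0, 14]`; default 7 (the condition under
#'   which the supported activity databases ran their assays).
#' @param temperature Kelvin, `> 0`; default 298.15.
#' @param probe_concentration Molar probe concentration of a
#'   single-concentration displacement assay; `NULL` for other assay types.
#' @return An object of class `AssayConditions`.
#' @export
AssayConditions <- function(pH = 7, temperature = 298.15,
                            probe_concentration = NULL) {
  stopifnot(is.numeric(pH), length(pH) == 1L, pH >= 0, pH <= 14)
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  if (!is.null(probe_concentration)) {
    stopifnot(is.numeric(probe_concentration),
              length(probe_concentration) == 1L, probe_concentration > 0)
  }
  structure(
    list(pH = pH, temperature = temperature,
         probe_concentration = probe_concentration),
    class = "AssayConditions"
  )
}

#' Provenance metadata attached to a measurement
#'
#' `original_value` and `original_units` record the activity exactly as
#' ingested, before any unit standardization.
#'
#' @param source Data-source name and version string.
#' @param document_id Publication / source-document identifier.
#' @param year Publication year (integer or `NA`).
#' @param authors Character vector of author names.
#' @param original_value Numeric value as ingested.
#' @param original_units Unit string as ingested, verbatim.
#' @return An object of class `Metadata`.
#' @export
Metadata <- function(source = NA_character_, document_id = NA_character_,
                     year = NA_integer_, authors = character(),
                     original_value = NA_real_,
                     original_units = NA_character_) {
  structure(
    list(source = source, document_id = document_id,
         year = if (is.na(year)) NA_integer_ else as.integer(year),
         authors = as.character(authors),
         original_value = original_value,
         original_units = original_units),
    class = "Metadata"
  )
}

#' A typed activity observation
#'
#' @param system The `System` the observation refers to.
#' @param mtype One of `"pIC50"`, `"pKi"`, `"pKd"`, `"percent_displacement"`.
#' @param values Numeric vector of one or more observed values (replicates),
#'   on the p-scale for the p-types or the percent scale for displacement.
#'   Percent values must lie in `[-10, 110]` (assay noise tolerance).
#' @param conditions An `AssayConditions`; default pH 7, 298.15 K.
#' @param metadata A `Metadata`.
#' @return An object of class `Measurement`.
#' @export
Measurement <- function(system, mtype, values,
                        conditions = AssayConditions(),
                        metadata = Metadata()) {
  stopifnot(inherits(system, "System"))
  if (!is_string(mtype) || !(mtype %in% MEASUREMENT_TYPES)) {
    stop("mtype must be one of: ", paste(MEASUREMENT_TYPES, collapse = ", "))
  }
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("values must be a non-empty vector of finite numbers")
  }
  if (mtype == "percent_displacement" &&
      any(values < -10 | values > 110)) {
    stop("percent_displacement values must lie in [-10, 110]")
  }
  stopifnot(inherits(conditions, "AssayConditions"),
            inherits(metadata, "Metadata"))
  structure(
    list(system = system, mtype = mtype, values = values,
         conditions = conditions, metadata = metadata),
    class = "Measurement"
  )
}

#' A stable, provenance-tagged collection of measurements
#'
#' @param measurements List of `Measurement` objects; iteration order is
#'   preserved.
#' @param provenance Named list describing where and how the measurements
#'   were obtained (source path, filters, subsampling seed, ...).
#' @return An object of class `DatasetProvider`.
#' @export
DatasetProvider <- function(measurements, provenance = list()) {
  stopifnot(is.list(measurements))
  ok <- vapply(measurements, inherits, logical(1), what = "Measurement")
  if (!all(ok)) stop("all elements must be Measurement objects")
  structure(
    list(measurements = measurements, provenance = provenance),
    class = "DatasetProvider"
  )
}

#' @export
length.DatasetProvider <- function(x) length(x$measurements)

#' @export
print.DatasetProvider <- function(x, ...) {
  types <- vapply(x$measurements, function(m) m$mtype, character(1))
  cat("<DatasetProvider> ", length(x$measurements), " measurements\n",
      sep = "")
  if (length(types) > 0L) {
    tab <- table(types)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  if (!is.null(x$provenance$source)) {
    cat("  source: ", x$provenance$source, "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.System <- function(x, ...) {
  cat("<System kind=", x$kind, ">\n", sep = "")
  for (comp in x$components) {
    if (inherits(comp, "Ligand")) {
      cat("  Ligand: ", comp$smiles, "\n", sep = "")
    } else {
      cat("  Protein: ", protein_key(comp), "\n", sep = "")
    }
  }
  invisible(x)
}
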