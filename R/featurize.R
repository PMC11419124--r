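# Featurizers: circular fingerprints, one-hot encodings, Tanimoto
# similarity, fingerprint-based template selection, and composable
# pipelines that turn Systems into named numeric tensors.

#' Construct a FeatureTensor
#'
#' A named numeric tensor (vector or matrix) with a declared dtype. Bit
#' tensors may contain only 0/1; all entries must be finite.
#'
#' @param name Featurizer label.
#' @param values Numeric vector or matrix.
#' @param dtype `"bit"` or `"float"`.
#' @return An object of class `FeatureTensor` with fields `name`, `values`,
#'   `dtype`.
#' @export
FeatureTensor <- function(name, values, dtype = c("float", "bit")) {
  dtype <- match.arg(dtype)
  stopifnot(is_string(name), is.numeric(values))
  storage.mode(values) <- "double"  # one numeric type on disk and in memory
  if (any(!is.finite(values))) stop("FeatureTensor entries must be finite")
  if (dtype == "bit" && length(values) > 0L && !all(values %in% c(0, 1))) {
    stop("bit FeatureTensor entries must be 0 or 1")
  }
  structure(list(name = name, values = values, dtype = dtype),
            class = "FeatureTensor")
}

# --- circular fingerprint -------------------------------------------------

# One hashing round of the circular-fingerprint update rule. Identifiers
# are 32-bit FNV-1a hashes of canonical strings:
#   round 0:  "<element>|<degree>|<charge>|<nH>|<in_ring>"
#   round r:  "<r>|<own id at r-1>|<sorted neighbor ids at r-1, comma-sep>"
# Neighbor bond orders are deliberately not hashed: the atom invariants
# already carry degree and ring membership, and omitting bond orders keeps
# the fingerprint independent of aromaticity/kekulization conventions.
.fp_identifiers <- function(graph, radius) {
  n <- length(graph$elements)
  nbrs <- vector("list", n)
  if (nrow(graph$edges) > 0L) {
    for (k in seq_len(nrow(graph$edges))) {
      a <- graph$edges[k, 1]; b <- graph$edges[k, 2]
      nbrs[[a]] <- c(nbrs[[a]], b)
      nbrs[[b]] <- c(nbrs[[b]], a)
    }
  }
  ids <- vapply(seq_len(n), function(i) {
    fnv1a32(paste(graph$elements[i], graph$degree[i], graph$charges[i],
                  graph$n_h[i], as.integer(graph$in_ring[i]), sep = "|"))
  }, numeric(1))
  all_ids <- ids
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      ids <- vapply(seq_len(n), function(i) {
        nb <- sort(ids[nbrs[[i]]])
        fnv1a32(paste(r, format_id(ids[i]),
                      paste(vapply(nb, format_id, character(1)),
                            collapse = ","),
                      sep = "|"))
      }, numeric(1))
      all_ids <- c(all_ids, ids)
    }
  }
  all_ids
}

#' Circular (ECFP-style) fingerprint of a ligand
#'
#' Builds per-atom initial invariants (element, heavy-atom degree, formal
#' charge, attached hydrogen count, ring membership), iteratively hashes
#' each atom's invariant together with its sorted neighbor identifiers for
#' `radius` rounds, and folds every identifier from every round modulo
#' `n_bits` into a fixed-length bit vector. Invariant under any valid
#' SMILES respelling of the same molecule.
#'
#' @param ligand A [Ligand] (or a SMILES string).
#' @param radius Non-negative neighborhood radius; default 2 (ECFP4-like).
#' @param n_bits Positive fingerprint length; default 2048.
#' @return A bit [FeatureTensor] of length `n_bits` named
#'   `"morgan"`.
#' @export
#' @examples
#' fp <- morgan_fingerprint(Ligand("CCO"), radius = 2, n_bits = 1024)
#' sum(fp$values)  # number of on bits
morgan_fingerprint <- function(ligand, radius = 2L, n_bits = 2048L) {
  if (inherits(ligand, "Ligand")) ligand <- ligand$smiles
  if (!is.numeric(n_bits) || length(n_bits) != 1L || n_bits <= 0) {
    stop("n_bits must be a positive integer")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0) {
    stop("radius must be a non-negative integer")
  }
  graph <- mol_graph(ligand)
  ids <- .fp_identifiers(graph, as.integer(radius))
  bits <- numeric(n_bits)
  bits[unique(ids %% n_bits) + 1] <- 1
  FeatureTensor("morgan", bits, dtype = "bit")
}

#' Tanimoto similarity of two bit tensors
#'
#' `|a AND b| / |a OR b|`; two all-zero vectors are defined as identical
#' (similarity 1).
#'
#' @param a,b Bit [FeatureTensor]s (or plain 0/1 vectors) of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "FeatureTensor")) a <- a$values
  if (inherits(b, "FeatureTensor")) b <- b$values
  if (length(a) != length(b)) {
    stop("fingerprints have different lengths (", length(a), " vs ",
         length(b), ")")
  }
  union_n <- sum(a > 0 | b > 0)
  if (union_n == 0L) return(1.0)
  sum(a > 0 & b > 0) / union_n
}

# --- one-hot encodings ----------------------------------------------------

#' Default character alphabet for canonical SMILES one-hot encoding
#'
#' Covers the organic-subset element letters (upper and aromatic lowercase),
#' `l`/`r` as the second characters of Cl/Br, ring-closure digits, and the
#' structural symbols of the SMILES grammar. Configurable wherever it is
#' consumed.
#'
#' @return Character vector of single characters.
#' @export
default_smiles_alphabet <- function() {
  c("B", "C", "N", "O", "P", "S", "F", "I", "H",
    "b", "c", "n", "o", "p", "s", "l", "r",
    as.character(0:9),
    "(", ")", "[", "]", "=", "#", "+", "-", "@", "/", "\\", ":", ".", "%")
}

.one_hot_encode <- function(chars, alphabet, max_length, what) {
  if (length(chars) > max_length) {
    stop(what, " of length ", length(chars),
         " exceeds max_length ", max_length)
  }
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    stop("character(s) outside the alphabet in ", what, ": '",
         paste(unique(chars[is.na(idx)]), collapse = "', '"), "'")
  }
  m <- matrix(0, nrow = max_length, ncol = length(alphabet))
  if (length(chars) > 0L) m[cbind(seq_along(chars), idx)] <- 1
  m
}

#' One-hot encode a ligand's canonical SMILES
#'
#' Row `i` of the result is one-hot at the alphabet index of character `i`
#' of the canonical SMILES; rows beyond the string length are all-zero
#' padding, so [decode_one_hot()] reconstructs the string exactly.
#'
#' @param ligand A [Ligand] (or SMILES string; it is canonicalized first).
#' @param alphabet Ordered character set; default
#'   [default_smiles_alphabet()].
#' @param max_length Number of rows of the encoding; must be at least the
#'   canonical SMILES length.
#' @return A bit [FeatureTensor] with a `max_length` x `length(alphabet)`
#'   matrix, named `"one_hot_smiles"`.
#' @export
one_hot_smiles <- function(ligand, alphabet = default_smiles_alphabet(),
                           max_length = 256L) {
  smiles <- if (inherits(ligand, "Ligand")) ligand$smiles else
    canonical_smiles(ligand)
  chars <- strsplit(smiles, "")[[1]]
  m <- .one_hot_encode(chars, alphabet, max_length,
                       paste0("SMILES '", smiles, "'"))
  FeatureTensor("one_hot_smiles", m, dtype = "bit")
}

#' One-hot encode a protein sequence
#'
#' Same contract as [one_hot_smiles()] over the amino-acid alphabet (20
#' canonical residues plus `X`). With `lenient = TRUE`, ambiguous residue
#' codes (B, Z, J, U, O) are mapped to `X` instead of erroring.
#'
#' @param protein A [Protein] with a sequence (or a sequence string).
#' @param alphabet Ordered residue alphabet; default the 20 canonical amino
#'   acids plus `X`.
#' @param max_length Number of rows of the encoding.
#' @param lenient Map ambiguous residue codes to `X`.
#' @return A bit [FeatureTensor] named `"one_hot_sequence"`.
#' @export
one_hot_sequence <- function(protein, alphabet = AA_ALPHABET,
                             max_length = 512L, lenient = FALSE) {
  seq_str <- if (inherits(protein, "Protein")) protein$sequence else protein
  if (is.null(seq_str) || is.na(seq_str)) {
    stop("protein has no sequence; one-hot sequence encoding needs one")
  }
  chars <- strsplit(toupper(seq_str), "")[[1]]
  if (lenient) chars[chars %in% c("B", "Z", "J", "U", "O")] <- "X"
  m <- .one_hot_encode(chars, alphabet, max_length, "sequence")
  FeatureTensor("one_hot_sequence", m, dtype = "bit")
}

#' Decode a one-hot matrix back to its string
#'
#' @param tensor A [FeatureTensor] holding a one-hot matrix (or the matrix
#'   itself).
#' @param alphabet The character set used for encoding.
#' @return The decoded string.
#' @export
decode_one_hot <- function(tensor, alphabet) {
  m <- if (inherits(tensor, "FeatureTensor")) tensor$values else tensor
  stopifnot(is.matrix(m), ncol(m) == length(alphabet))
  out <- character(0)
  for (i in seq_len(nrow(m))) {
    if (all(m[i, ] == 0)) break
    out <- c(out, alphabet[which.max(m[i, ])])
  }
  paste(out, collapse = "")
}

# --- template selection ---------------------------------------------------

#' Select the structural template with the most similar co-ligand
#'
#' For template-guided pose prediction, the best structure to dock into is
#' the one whose co-crystallized ligand is most similar to the query
#' compound. Similarity is the Tanimoto coefficient on circular
#' fingerprints; ties are broken by lexicographically smallest structure
#' identifier.
#'
#' @param ligand Query [Ligand] (or SMILES string).
#' @param candidates data.frame with columns `structure_id` and `smiles`
#'   (the co-crystallized ligand of each structure).
#' @param radius,n_bits Fingerprint parameters; defaults radius 2,
#'   2048 bits.
#' @return A list with `structure_id` and `similarity`.
#' @export
select_template <- function(ligand, candidates, radius = 2L,
                            n_bits = 2048L) {
  stopifnot(is.data.frame(candidates),
            all(c("structure_id", "smiles") %in% names(candidates)))
  if (nrow(candidates) == 0L) stop("candidate table is empty")
  query_fp <- morgan_fingerprint(ligand, radius = radius, n_bits = n_bits)
  sims <- vapply(candidates$smiles, function(s) {
    tanimoto(query_fp, morgan_fingerprint(s, radius = radius,
                                          n_bits = n_bits))
  }, numeric(1), USE.NAMES = FALSE)
  ord <- order(-sims, candidates$structure_id)
  best <- ord[1]
  list(structure_id = candidates$structure_id[best],
       similarity = sims[best])
}

# --- pipelines ------------------------------------------------------------

# registry: name -> function(system, params) returning a FeatureTensor
.featurizer_registry <- list(
  morgan = function(system, params) {
    lig <- system_ligand(system)
    if (is.null(lig)) stop("morgan fingerprint needs a Ligand component")
    morgan_fingerprint(lig, radius = params$radius %||% 2L,
                       n_bits = params$n_bits %||% 2048L)
  },
  one_hot_smiles = function(system, params) {
    lig <- system_ligand(system)
    if (is.null(lig)) stop("one_hot_smiles needs a Ligand component")
    one_hot_smiles(lig,
                   alphabet = params$alphabet %||% default_smiles_alphabet(),
                   max_length = params$max_length %||% 256L)
  },
  one_hot_sequence = function(system, params) {
    prot <- system_protein(system)
    if (is.null(prot)) stop("one_hot_sequence needs a Protein component")
    one_hot_sequence(prot,
                     alphabet = params$alphabet %||% AA_ALPHABET,
                     max_length = params$max_length %||% 512L,
                     lenient = isTRUE(params$lenient))
  },
  template = function(system, params) {
    lig <- system_ligand(system)
    if (is.null(lig)) stop("template selection needs a Ligand component")
    if (is.null(params$candidates)) {
      stop("template selection needs a 'candidates' table parameter")
    }
    hit <- select_template(lig, params$candidates,
                           radius = params$radius %||% 2L,
                           n_bits = params$n_bits %||% 2048L)
    FeatureTensor("template", hit$similarity, dtype = "float")
  }
)

#' Define a featurization pipeline
#'
#' A pipeline is an ordered list of featurizer steps applied to each system
#' in turn; per-step outputs are concatenated (flattened row-major) into a
#' combined `"concat"` feature, or only the final step's tensor is kept
#' when `retain_last_only` is set (to bound memory when archiving).
#'
#' @param steps List of steps, each a list with `name` (one of `"morgan"`,
#'   `"one_hot_smiles"`, `"one_hot_sequence"`, `"template"`) and an optional
#'   `params` list.
#' @param retain_last_only Keep only the final step's tensor.
#' @return An object of class `FeaturizationPipeline`.
#' @export
FeaturizationPipeline <- function(steps, retain_last_only = FALSE) {
  stopifnot(is.list(steps), length(steps) > 0L)
  for (s in steps) {
    if (!is.list(s) || !is_string(s$name)) {
      stop("each step must be a list with a 'name' entry")
    }
    if (!(s$name %in% names(.featurizer_registry))) {
      stop("unknown featurizer: '", s$name, "'; available: ",
           paste(names(.featurizer_registry), collapse = ", "))
    }
  }
  structure(list(steps = steps,
                 retain_last_only = isTRUE(retain_last_only)),
            class = "FeaturizationPipeline")
}

# flatten a FeatureTensor row-major (matrices are stored column-major in R,
# so transpose before unravelling)
flatten_tensor <- function(tensor) {
  v <- tensor$values
  if (is.matrix(v)) as.vector(t(v)) else as.vector(v)
}

#' Run a featurization pipeline over a list of systems
#'
#' Steps run in order for every system. A step failure (e.g., a ligand
#' featurizer applied to a protein-only system) skips that system and
#' records the error, rather than aborting the batch.
#'
#' @param pipeline A [FeaturizationPipeline].
#' @param systems List of [System] objects.
#' @return A list with one entry per successfully featurized system, each a
#'   list with `system`, `index` (position in the input list), and
#'   `features` (named list of [FeatureTensor]s, including `"concat"`
#'   unless `retain_last_only` was set). Failures are reported in the
#'   `"failures"` attribute as a data.frame of (index, error).
#' @export
run_pipeline <- function(pipeline, systems) {
  stopifnot(inherits(pipeline, "FeaturizationPipeline"), is.list(systems))
  results <- list()
  failures <- data.frame(index = integer(), error = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_along(systems)) {
    sys <- systems[[i]]
    feats <- tryCatch({
      tensors <- list()
      for (s in pipeline$steps) {
        fn <- .featurizer_registry[[s$name]]
        tensors[[length(tensors) + 1L]] <- fn(sys, s$params %||% list())
      }
      if (pipeline$retain_last_only) {
        last <- tensors[[length(tensors)]]
        stats::setNames(list(last), last$name)
      } else {
        flat <- unlist(lapply(tensors, flatten_tensor))
        dtype <- if (all(vapply(tensors, function(t) t$dtype,
                                character(1)) == "bit")) "bit" else "float"
        out <- stats::setNames(tensors,
                               vapply(tensors, function(t) t$name,
                                      character(1)))
        out$concat <- FeatureTensor("concat", flat, dtype = dtype)
        out
      }
    }, error = function(e) e)
    if (inherits(feats, "error")) {
      failures <- rbind(failures,
                        data.frame(index = i,
                                   error = conditionMessage(feats),
                                   stringsAsFactors = FALSE))
    } else {
      results[[length(results) + 1L]] <-
        list(system = sys, index = i, features = feats)
    }
  }
  attr(results, "failures") <- failures
  results
}
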