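#' @importFrom ChemmineR read.SDFset atomblock bondblock
NULL

# Memoization for OpenBabel round trips: the same SMILES recurs constantly
# during curation grouping and batch featurization.
.chem_cache <- new.env(parent = emptyenv())

#' Canonical SMILES of a molecule
#'
#' Converts any valid SMILES spelling to the canonical form produced by the
#' OpenBabel canonicalization algorithm, so that two spellings of the same
#' molecule map to the same string. Canonicalization is idempotent:
#' `canonical_smiles(canonical_smiles(s)) == canonical_smiles(s)`.
#'
#' @param smiles A single non-empty SMILES string.
#' @return The canonical SMILES string.
#' @export
#' @examples
#' canonical_smiles("OCC") == canonical_smiles("CCO")
canonical_smiles <- function(smiles) {
  if (!is_string(smiles) || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string")
  }
  key <- paste0("can::", smiles)
  hit <- get0(key, envir = .chem_cache)
  if (!is.null(hit)) return(hit)
  out <- ChemmineOB::convertFormat("SMI", "CAN", source = smiles)
  out <- sub("[ \t\r\n].*$", "", trimws(out))
  if (!nzchar(out)) {
    stop("SMILES string could not be parsed: '", smiles, "'")
  }
  assign(key, out, envir = .chem_cache)
  out
}

# Heavy-atom molecular graph of a SMILES string, extracted from an
# explicit-hydrogen SDF block written by OpenBabel and parsed by ChemmineR.
#
# Returns a list with, per heavy atom: element symbol, formal charge,
# heavy-atom degree, attached hydrogen count, ring membership; plus the
# heavy-atom bond list (two-column index matrix). Ring membership is
# computed on the heavy-atom graph: an atom is in a ring iff it has an
# incident edge that is not a bridge.
mol_graph <- function(smiles) {
  if (!is_string(smiles) || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string")
  }
  key <- paste0("graph::", smiles)
  hit <- get0(key, envir = .chem_cache)
  if (!is.null(hit)) return(hit)

  sdf_txt <- ChemmineOB::convertFormat(
    "SMI", "SDF", source = smiles,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  )
  if (!nzchar(trimws(sdf_txt))) {
    stop("SMILES string could not be parsed: '", smiles, "'")
  }
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf_txt, tf)
  sdf <- ChemmineR::read.SDFset(tf)[[1]]

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n_atoms <- length(elements)

  # MDL V2000 charge codes (atom block field "C6"; ChemmineR keeps the
  # field names of the format): 0 none, 1..3 = +3..+1, 4 radical,
  # 5..7 = -1..-3
  chg_code <- if ("C6" %in% colnames(ab)) {
    as.integer(ab[, "C6"])
  } else {
    integer(n_atoms)
  }
  chg_map <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
               `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)
  charges <- unname(chg_map[as.character(chg_code)])
  charges[is.na(charges)] <- 0L

  if (is.null(bb) || nrow(bb) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  } else {
    edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }

  heavy <- which(elements != "H")
  heavy_idx <- match(seq_len(n_atoms), heavy)  # old index -> heavy index or NA

  n_h <- integer(length(heavy))
  heavy_edges <- matrix(integer(0), ncol = 2)
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      a_h <- elements[a] == "H"; b_h <- elements[b] == "H"
      if (a_h && !b_h) {
        n_h[heavy_idx[b]] <- n_h[heavy_idx[b]] + 1L
      } else if (b_h && !a_h) {
        n_h[heavy_idx[a]] <- n_h[heavy_idx[a]] + 1L
      } else if (!a_h && !b_h) {
        heavy_edges <- rbind(heavy_edges, c(heavy_idx[a], heavy_idx[b]))
      }
    }
  }

  degree <- integer(length(heavy))
  in_ring <- logical(length(heavy))
  if (nrow(heavy_edges) > 0L) {
    g <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
    g <- igraph::add_edges(g, t(heavy_edges))
    degree <- igraph::degree(g)
    br <- igraph::bridges(g)
    cyclic <- setdiff(seq_len(igraph::ecount(g)), br)
    if (length(cyclic) > 0L) {
      ends <- igraph::ends(g, cyclic)
      in_ring[unique(as.vector(ends))] <- TRUE
    }
  }

  res <- list(
    elements = elements[heavy],
    charges = charges[heavy],
    degree = as.integer(degree),
    n_h = n_h,
    in_ring = in_ring,
    edges = heavy_edges
  )
  assign(key, res, envir = .chem_cache)
  res
}
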