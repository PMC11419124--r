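# Synthetic-data generators: every input dialect the package consumes, with
# planted, self-documented ground truth, so the whole pipeline is testable
# without network access. The curation fixture plants each drop class
# (dummy targets, extremes, unclear units, within-publication duplicates,
# citation chains, author-overlap components) in its own dedicated system,
# so per-stage drop counts are exact by construction.

#' Packaged pool of valid drug-like SMILES
#'
#' A fixed set of known small-molecule drugs and drug-like compounds (all
#' parse and canonicalize), used by the generators for chemically diverse
#' ligand sampling.
#'
#' @return Named character vector of SMILES.
#' @export
drug_like_smiles_pool <- function() {
  c(
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
    ethanol = "CCO",
    benzene = "c1ccccc1",
    toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1",
    aniline = "Nc1ccccc1",
    pyridine = "c1ccncc1",
    imidazole = "c1cnc[nH]1",
    indole = "c1ccc2[nH]ccc2c1",
    quinoline = "c1ccc2ncccc2c1",
    morpholine = "C1COCCN1",
    piperazine = "C1CNCCN1",
    cyclohexane = "C1CCCCC1",
    adenine = "Nc1ncnc2[nH]cnc12",
    nicotinamide = "NC(=O)c1cccnc1",
    benzamide = "NC(=O)c1ccccc1",
    salicylamide = "NC(=O)c1ccccc1O",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    diazepam = "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
    imatinib_frag = "Cc1ccc(cc1)C(=O)Nc1ccc(CN2CCN(C)CC2)cc1",
    erlotinib_core = "COCCOc1cc2ncnc(Nc3cccc(c3)C#C)c2cc1OCCOC",
    gefitinib_core = "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1",
    sulfanilamide = "Nc1ccc(cc1)S(N)(=O)=O",
    metformin = "CN(C)C(=N)NC(=N)N",
    ibandronate_frag = "CCCCCN(C)CCO",
    valproate = "CCCC(CCC)C(=O)O",
    chlorzoxazone = "Oc1nc2cc(Cl)ccc2o1",  # benzoxazolone-like
    theophylline = "Cn1c2[nH]cnc2c(=O)n(C)c1=O",
    benzoate = "O=C([O-])c1ccccc1",
    anilinium = "[NH3+]c1ccccc1",
    furan = "c1ccoc1",
    thiophene = "c1ccsc1",
    pyrrole = "c1cc[nH]c1",
    naphthalene = "c1ccc2ccccc2c1",
    biphenyl = "c1ccc(cc1)-c2ccccc2",
    styrene = "C=Cc1ccccc1",
    acetophenone = "CC(=O)c1ccccc1",
    benzonitrile = "N#Cc1ccccc1",
    nitrobenzene = "O=[N+]([O-])c1ccccc1",
    chlorobenzene = "Clc1ccccc1",
    bromobenzene = "Brc1ccccc1",
    fluorouracil_core = "O=c1[nH]cc(F)c(=O)[nH]1",
    tryptamine = "NCCc1c[nH]c2ccccc12",
    histamine = "NCCc1cnc[nH]1",
    serotonin = "NCCc1c[nH]c2ccc(O)cc12",
    dopamine = "NCCc1ccc(O)c(O)c1",
    tyramine = "NCCc1ccc(O)cc1",
    melatonin = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    benzocaine = "CCOC(=O)c1ccc(N)cc1",
    isoniazid = "NNC(=O)c1ccncc1",
    pyrazinamide = "NC(=O)c1cnccn1",
    coumarin = "O=c1ccc2ccccc2o1",
    chromone = "O=c1ccoc2ccccc12",
    uracil = "O=c1cc[nH]c(=O)[nH]1",
    thymine = "Cc1c[nH]c(=O)[nH]c1=O",
    cytosine = "Nc1cc[nH]c(=O)n1"
  )
}

#' Sample a set of valid, diverse ligand SMILES
#'
#' @param n Number of SMILES to draw.
#' @param seed RNG seed.
#' @param replace Sample with replacement; without replacement `n` may not
#'   exceed the pool size.
#' @return Character vector of `n` SMILES, all of which parse and
#'   canonicalize.
#' @export
generate_ligand_set <- function(n, seed = 1L, replace = FALSE) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  pool <- drug_like_smiles_pool()
  if (!replace && n > length(pool)) {
    stop("n (", n, ") exceeds the pool size (", length(pool),
         ") under no-replacement sampling")
  }
  with_seed(seed, unname(sample(pool, size = n, replace = replace)))
}

#' Generate random protein sequences
#'
#' @param n Number of proteins.
#' @param seed RNG seed.
#' @param length_range Sequence length range (uniform draw).
#' @return Character vector of amino-acid sequences over the 20 canonical
#'   residues.
#' @export
generate_protein_set <- function(n, seed = 1L, length_range = c(50L, 120L)) {
  aa <- setdiff(AA_ALPHABET, "X")
  with_seed(seed, vapply(seq_len(n), function(i) {
    len <- sample(seq(length_range[1], length_range[2]), 1)
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1)))
}

#' Specify a curation fixture
#'
#' The planted counts fix exactly how many records each cascade stage must
#' drop; every planted structure lives in its own dedicated system so
#' stages cannot interact. Within-publication duplicate groups have size 2;
#' citation chains and author-overlap components have size 3.
#'
#' @param n_records Total number of raw rows.
#' @param seed RNG seed; the same (spec, seed) always yields identical
#'   bytes.
#' @param n_dummy_targets Rows against the dummy validation target.
#' @param n_extreme_high Rows with concentration above 10 mM.
#' @param n_extreme_low Rows with concentration below 1 fM.
#' @param n_unclear_units Rows with non-molar unit strings.
#' @param n_within_doc_duplicate_groups Size-2 same-publication duplicate
#'   groups (one row dropped per group).
#' @param n_citation_chains Length-3 identical-value citation chains across
#'   publications (two rows dropped per chain).
#' @param n_author_overlap_components Size-3 author-overlap components
#'   (two rows dropped per component).
#' @param ligand_pool,protein_pool Pool sizes for distinct ligands and
#'   proteins.
#' @return An object of class `FixtureSpec`.
#' @export
fixture_spec <- function(n_records = 200L, seed = 1L,
                         n_dummy_targets = 5L,
                         n_extreme_high = 5L, n_extreme_low = 3L,
                         n_unclear_units = 4L,
                         n_within_doc_duplicate_groups = 6L,
                         n_citation_chains = 4L,
                         n_author_overlap_components = 4L,
                         ligand_pool = 20L, protein_pool = 10L) {
  spec <- list(
    n_records = as.integer(n_records), seed = as.integer(seed),
    n_dummy_targets = as.integer(n_dummy_targets),
    n_extreme_high = as.integer(n_extreme_high),
    n_extreme_low = as.integer(n_extreme_low),
    n_unclear_units = as.integer(n_unclear_units),
    n_within_doc_duplicate_groups =
      as.integer(n_within_doc_duplicate_groups),
    n_citation_chains = as.integer(n_citation_chains),
    n_author_overlap_components = as.integer(n_author_overlap_components),
    ligand_pool = as.integer(ligand_pool),
    protein_pool = as.integer(protein_pool)
  )
  if (any(vapply(spec, function(x) x < 0L, logical(1)))) {
    stop("all FixtureSpec counts must be non-negative")
  }
  planted_rows <- spec$n_dummy_targets + spec$n_extreme_high +
    spec$n_extreme_low + spec$n_unclear_units +
    2L * spec$n_within_doc_duplicate_groups +
    3L * spec$n_citation_chains + 3L * spec$n_author_overlap_components
  if (planted_rows > spec$n_records) {
    stop("infeasible FixtureSpec: planted structures need ", planted_rows,
         " rows but n_records is ", spec$n_records)
  }
  spec$n_base <- spec$n_records - planted_rows
  n_systems_needed <- spec$n_base + spec$n_dummy_targets +
    spec$n_extreme_high + spec$n_extreme_low + spec$n_unclear_units +
    spec$n_within_doc_duplicate_groups + spec$n_citation_chains +
    spec$n_author_overlap_components
  if (n_systems_needed > spec$ligand_pool * spec$protein_pool) {
    stop("infeasible FixtureSpec: ", n_systems_needed,
         " dedicated systems needed but the ligand x protein pool offers ",
         spec$ligand_pool * spec$protein_pool)
  }
  if (spec$ligand_pool > length(drug_like_smiles_pool())) {
    stop("ligand_pool exceeds the packaged SMILES pool")
  }
  structure(spec, class = "FixtureSpec")
}

#' Draw a random feasible FixtureSpec
#'
#' @param seed RNG seed; also seeds the generated fixture.
#' @param n_max Upper bound on `n_records`.
#' @return A `FixtureSpec`.
#' @export
random_fixture_spec <- function(seed, n_max = 500L) {
  with_seed(seed, {
    cap <- max(0L, n_max %/% 25L)  # keep planted structures feasible
    draw <- function(k) sample(0:min(k, cap), 1)
    n_dummy <- draw(5)
    n_eh <- draw(5)
    n_el <- draw(4)
    n_uu <- draw(4)
    n_wd <- draw(8)
    n_cc <- draw(6)
    n_ao <- draw(6)
    planted <- n_dummy + n_eh + n_el + n_uu + 2 * n_wd + 3 * n_cc + 3 * n_ao
    n_records <- planted + sample(5:max(5, n_max - planted), 1)
    n_records <- min(n_records, n_max)
    fixture_spec(
      n_records = n_records, seed = seed, n_dummy_targets = n_dummy,
      n_extreme_high = n_eh, n_extreme_low = n_el, n_unclear_units = n_uu,
      n_within_doc_duplicate_groups = n_wd, n_citation_chains = n_cc,
      n_author_overlap_components = n_ao,
      ligand_pool = min(40L, length(drug_like_smiles_pool())),
      protein_pool = 15L
    )
  })
}

#' Generate a curation fixture with planted ground truth
#'
#' Emits a raw activity table in the ChEMBL dialect together with the exact
#' expected per-stage record counts and the surviving record ids of the
#' five-stage cascade. The ground truth is authoritative:
#' [run_cascade()] on the generated table must reproduce it exactly.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `records` (the raw data.frame, rows in seeded random
#'   order), `ground_truth` (list with `stages` count data.frame and
#'   `survivor_ids`), and `spec`.
#' @export
generate_curation_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    ligands <- generate_ligand_set(spec$ligand_pool,
                                   seed = sample.int(1e6, 1))
    proteins <- sprintf("P%05d", 10000 + seq_len(spec$protein_pool))

    # dedicated system per planted structure, drawn without replacement
    all_systems <- expand.grid(lig = seq_len(spec$ligand_pool),
                               prot = seq_len(spec$protein_pool))
    sys_order <- sample.int(nrow(all_systems))
    sys_cursor <- 0L
    next_system <- function() {
      sys_cursor <<- sys_cursor + 1L
      row <- all_systems[sys_order[sys_cursor], ]
      list(smiles = ligands[row$lig], uniprot = proteins[row$prot],
           target_id = sprintf("CHEMBL_T%03d", row$prot),
           compound_id = sprintf("CMPD%03d", row$lig))
    }
    author_counter <- 0L
    fresh_authors <- function(k) {
      ids <- author_counter + seq_len(k)
      author_counter <<- author_counter + k
      sprintf("author_%04d", ids)
    }
    doc_counter <- 0L
    fresh_doc <- function() {
      doc_counter <<- doc_counter + 1L
      sprintf("DOC%04d", doc_counter)
    }
    rows <- list()
    survivors <- character(0)  # temporary tags
    tag_counter <- 0L
    add_row <- function(sys, value, units, doc, year, authors,
                        target_id = sys$target_id, survives = FALSE) {
      tag_counter <<- tag_counter + 1L
      tag <- sprintf("tag%05d", tag_counter)
      rows[[length(rows) + 1L]] <<- data.frame(
        tag = tag, uniprot_id = sys$uniprot, target_id = target_id,
        compound_id = sys$compound_id, smiles = sys$smiles,
        activity_type = sample(c("Kd", "Ki", "IC50"), 1),
        value = value, units = units, document_id = doc,
        year = year, authors = paste(authors, collapse = "|"),
        stringsAsFactors = FALSE
      )
      if (survives) survivors <<- c(survivors, tag)
      invisible(tag)
    }
    clean_value <- function() {
      p <- stats::runif(1, 4, 10)
      10^(9 - p)  # nM
    }
    rand_year <- function() sample(1995:2020, 1)

    # base clean rows: unique system and publication each, survive all stages
    for (i in seq_len(spec$n_base)) {
      add_row(next_system(), clean_value(), "nM", fresh_doc(), rand_year(),
              fresh_authors(2), survives = TRUE)
    }
    # dummy-target rows (stage 1 drops)
    for (i in seq_len(spec$n_dummy_targets)) {
      add_row(next_system(), clean_value(), "nM", fresh_doc(), rand_year(),
              fresh_authors(2), target_id = "CHEMBL612545")
    }
    # extreme concentrations (stage 2 drops)
    for (i in seq_len(spec$n_extreme_high)) {
      add_row(next_system(), stats::runif(1, 11, 100), "mM", fresh_doc(),
              rand_year(), fresh_authors(2))
    }
    for (i in seq_len(spec$n_extreme_low)) {
      add_row(next_system(), stats::runif(1, 0.01, 0.9), "fM", fresh_doc(),
              rand_year(), fresh_authors(2))
    }
    # unclear units (stage 2 drops)
    for (i in seq_len(spec$n_unclear_units)) {
      add_row(next_system(), clean_value(),
              sample(c("mg/mL", "ug/uL", "percent"), 1), fresh_doc(),
              rand_year(), fresh_authors(2))
    }
    # within-publication duplicate pairs (stage 3 drops one of each)
    for (i in seq_len(spec$n_within_doc_duplicate_groups)) {
      sys <- next_system(); doc <- fresh_doc(); yr <- rand_year()
      auth <- fresh_authors(2)
      p_lo <- stats::runif(1, 4, 8)
      p_hi <- p_lo + stats::runif(1, 0.3, 1.5)
      # the higher p (lower concentration) survives
      add_row(sys, 10^(9 - p_hi), "nM", doc, yr, auth, survives = TRUE)
      add_row(sys, 10^(9 - p_lo), "nM", doc, yr, auth)
    }
    # citation chains: 3 publications, identical value, earliest survives
    for (i in seq_len(spec$n_citation_chains)) {
      sys <- next_system()
      value <- clean_value()
      years <- sort(sample(1995:2020, 3))
      add_row(sys, value, "nM", fresh_doc(), years[1], fresh_authors(2),
              survives = TRUE)
      add_row(sys, value, "nM", fresh_doc(), years[2], fresh_authors(2))
      add_row(sys, value, "nM", fresh_doc(), years[3], fresh_authors(2))
    }
    # author-overlap components: 3 publications chained by shared authors,
    # distinct values, earliest survives
    for (i in seq_len(spec$n_author_overlap_components)) {
      sys <- next_system()
      years <- sort(sample(1995:2020, 3))
      names4 <- fresh_authors(4)  # a b c d -> {a,b}, {b,c}, {c,d}
      p0 <- stats::runif(1, 4, 7)
      add_row(sys, 10^(9 - p0), "nM", fresh_doc(), years[1],
              names4[1:2], survives = TRUE)
      add_row(sys, 10^(9 - (p0 + 0.7)), "nM", fresh_doc(), years[2],
              names4[2:3])
      add_row(sys, 10^(9 - (p0 + 1.4)), "nM", fresh_doc(), years[3],
              names4[3:4])
    }

    records <- do.call(rbind, rows)
    shuffle <- sample.int(nrow(records))
    records <- records[shuffle, , drop = FALSE]
    records$record_id <- sprintf("R%05d", seq_len(nrow(records)))
    survivor_ids <- records$record_id[match(survivors, records$tag)]
    records$tag <- NULL
    records <- records[, ACTIVITY_RECORD_COLUMNS]
    rownames(records) <- NULL

    n0 <- spec$n_records
    n1 <- n0 - spec$n_dummy_targets
    n2 <- n1 - spec$n_extreme_high - spec$n_extreme_low -
      spec$n_unclear_units
    n3 <- n2 - spec$n_within_doc_duplicate_groups
    n4 <- n3 - 2L * spec$n_citation_chains
    n5 <- n4 - 2L * spec$n_author_overlap_components
    stages <- data.frame(
      stage = c("group_and_remove_dummy", "standardize_and_filter_extremes",
                "collapse_within_document", "remove_cited_duplicates",
                "remove_author_overlap"),
      records_in = c(n0, n1, n2, n3, n4),
      records_out = c(n1, n2, n3, n4, n5),
      stringsAsFactors = FALSE
    )
    list(records = records,
         ground_truth = list(stages = stages,
                             survivor_ids = sort(survivor_ids)),
         spec = spec)
  })
}

#' Write fixture records as a ChEMBL-dialect CSV
#'
#' Byte-deterministic for identical records.
#'
#' @param records Fixture records data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_fixture_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate a PKIS2-dialect fixture
#'
#' @param n_compounds,n_kinases Grid dimensions; the table has one row per
#'   compound x kinase pair.
#' @param n_unmapped Number of kinases deliberately left out of the
#'   name-to-UniProt mapping (to exercise strict/lenient handling).
#' @param seed RNG seed.
#' @return List with `table` (columns `smiles`, `compound_name`,
#'   `kinase_name`, `percent_displacement`) and `mapping` (columns `name`,
#'   `uniprot_id`).
#' @export
generate_pkis2_fixture <- function(n_compounds = 3L, n_kinases = 2L,
                                   n_unmapped = 0L, seed = 1L) {
  stopifnot(n_unmapped <= n_kinases)
  with_seed(seed, {
    smiles <- generate_ligand_set(n_compounds, seed = sample.int(1e6, 1))
    kinases <- sprintf("KIN%02d", seq_len(n_kinases))
    grid <- expand.grid(ci = seq_len(n_compounds), ki = seq_len(n_kinases))
    table <- data.frame(
      smiles = smiles[grid$ci],
      compound_name = sprintf("GW%04d", grid$ci),
      kinase_name = kinases[grid$ki],
      percent_displacement = round(stats::runif(nrow(grid), 0, 100), 1),
      stringsAsFactors = FALSE
    )
    mapped <- if (n_unmapped > 0L) {
      kinases[seq_len(n_kinases - n_unmapped)]
    } else {
      kinases
    }
    mapping <- data.frame(
      name = mapped,
      uniprot_id = sprintf("P%05d", 20000 + seq_along(mapped)),
      stringsAsFactors = FALSE
    )
    list(table = table, mapping = mapping)
  })
}

#' Generate kinase-definition snapshot tables with a known intersection
#'
#' @param n_sources Number of sources.
#' @param n_common Accessions present in every source (the planted
#'   intersection).
#' @param n_extra_per_source Accessions unique to each source.
#' @param seed RNG seed.
#' @return Named list of data.frames (`uniprot_id`, `display_name`), one
#'   per source; the intersection across all sources is exactly
#'   `n_common`.
#' @export
generate_kinase_lists <- function(n_sources = 5L, n_common = 7L,
                                  n_extra_per_source = 3L, seed = 1L) {
  with_seed(seed, {
    common <- sprintf("P%05d", 30000 + seq_len(n_common))
    out <- list()
    extra_counter <- 0L
    for (s in seq_len(n_sources)) {
      extras <- sprintf("P%05d",
                        40000 + extra_counter + seq_len(n_extra_per_source))
      extra_counter <- extra_counter + n_extra_per_source
      acc <- c(common, extras)
      out[[sprintf("source%02d", s)]] <- data.frame(
        uniprot_id = acc,
        display_name = sprintf("KIN_%s_%d", acc, s),
        stringsAsFactors = FALSE
      )
    }
    out
  })
}

#' Simulate a mixed-type observation study with known free energies
#'
#' Draws one true binding free energy per system, assigns each system a
#' measurement class, and emits noisy replicate observations through the
#' corresponding link function: Gaussian noise with standard deviation
#' `sigma_p` on the p-scale and `sigma_pct` on the percent scale (percent
#' draws clamped to the measurement validity window `[-10, 110]`).
#'
#' @param n_systems Number of simulated systems.
#' @param seed RNG seed.
#' @param replicates Observations per system.
#' @param dg_range Range of true free energies, kcal/mol (uniform draw).
#' @param sigma_p Observation noise on the p-scale.
#' @param sigma_pct Observation noise on the percent scale.
#' @param probe_concentration Molar probe concentration of the simulated
#'   displacement assays.
#' @return A list with one element per system: `dg_true`, `mtype`, and a
#'   [Measurement] carrying the replicate values.
#' @export
generate_observation_study <- function(n_systems = 500L, seed = 1L,
                                       replicates = 3L,
                                       dg_range = c(-14, -6),
                                       sigma_p = 0.2, sigma_pct = 3,
                                       probe_concentration = 1e-6) {
  lig <- Ligand("CCO")
  with_seed(seed, lapply(seq_len(n_systems), function(i) {
    dg_true <- stats::runif(1, dg_range[1], dg_range[2])
    mtype <- sample(MEASUREMENT_TYPES, 1)
    conditions <- AssayConditions(
      probe_concentration = if (mtype == "percent_displacement") {
        probe_concentration
      } else {
        NULL
      }
    )
    ctx <- context_from_conditions(conditions)
    clean <- predict_observable(dg_true, mtype, ctx)$value
    sigma <- if (mtype == "percent_displacement") sigma_pct else sigma_p
    obs <- clean + stats::rnorm(replicates, 0, sigma)
    if (mtype == "percent_displacement") {
      obs <- pmin(pmax(obs, -10), 110)
    }
    sys <- System(list(Protein(uniprot_id = sprintf("P%05d", i)), lig))
    list(dg_true = dg_true, mtype = mtype, sigma = sigma,
         measurement = Measurement(sys, mtype, obs,
                                   conditions = conditions))
  }))
}

#' Generate a template candidate table
#'
#' @param n Number of candidate structures.
#' @param seed RNG seed.
#' @param include_smiles Optional SMILES guaranteed to appear among the
#'   candidates (e.g., to plant a similarity-1 hit).
#' @return data.frame with columns `structure_id`, `smiles`.
#' @export
generate_template_table <- function(n = 5L, seed = 1L,
                                    include_smiles = NULL) {
  with_seed(seed, {
    smiles <- generate_ligand_set(n, seed = sample.int(1e6, 1))
    if (!is.null(include_smiles)) smiles[1] <- include_smiles
    df <- data.frame(
      structure_id = sprintf("TPL%03d", sample.int(900, n)),
      smiles = smiles,
      stringsAsFactors = FALSE
    )
    df[order(df$structure_id), , drop = FALSE]
  })
}
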