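# affinityforge

Kinase-inhibitor activity data arrives as a patchwork: concentration
assays reported as K<sub>d</sub>, K<sub>i</sub> or IC<sub>50</sub> in
half a dozen units, single-concentration percent-displacement screens,
duplicated values republished across papers, placeholder database
targets, and implausible extremes. Machine-learning models trained on
such tables inherit every one of those artifacts. **affinityforge** is an
R toolkit for turning that patchwork into clean, provenance-tagged,
ML-ready tensors:

- **Object model** — `Ligand` (canonical SMILES), `Protein` (UniProt /
  NCBI / sequence), `System` (ligand-only, protein-only, or
  protein:ligand complex), `Measurement` (typed values with
  `AssayConditions` and `Metadata`), `DatasetProvider`.
- **Ingest** — readers for ChEMBL-dialect activity CSVs (with accession,
  measurement-type and seeded-subsample filters) and PKIS2-dialect
  percent-displacement tables (with a kinase-name → UniProt mapping and
  a strict/lenient rejects policy), plus `merge_kinase_lists()` to union
  kinase-definition snapshots into one UniProt-keyed roster.
- **Curation** — a five-stage cascade with a chained audit report:
  (1) group by system and purge the dummy validation target
  (CHEMBL612545); (2) standardize activities to the p-scale
  (pX = −log₁₀ of the molar concentration) and drop unclear units and
  extremes (concentration > 10 mM or < 1 fM, strictly); (3) keep only
  the highest affinity per system and publication; (4) remove later
  republications of an identical value; (5) keep one measurement per
  author-overlap component so surviving measurements are independent.
- **Featurization** — circular (ECFP-style) fingerprints, one-hot
  SMILES/sequence encodings, Tanimoto similarity, most-similar-co-ligand
  template selection, and composable pipelines with per-stage
  concatenation or last-only retention.
- **Assay model** — differentiable link functions from a latent binding
  free energy ΔG (kcal/mol) to each readout: pK_d = −ΔG/(RT ln 10) at
  standard state, single-site occupancy 100·L/(L + K_d) for percent
  displacement at probe concentration L, and a squared-error
  `observation_loss()` with analytic gradients so heterogeneous
  measurement types can train one latent quantity.
- **Tensor store** — bit-exact, byte-deterministic Parquet serialization
  of ragged feature tensors with per-record metadata and schema-versioned
  provenance.
- **Fixtures** — synthetic generators for every input dialect with
  planted, self-documented ground truth, so the whole pipeline is
  testable offline.

## Worked example

```r
library(affinityforge)

fx  <- generate_curation_fixture(fixture_spec(n_records = 200, seed = 1))
res <- run_cascade(fx$records)
print(res$report)
#> <CurationReport>
#>   1. group_and_remove_dummy          200 ->    195
#>        - dummy target: 5
#>   2. standardize_and_filter_extremes    195 ->    183
#>        - extreme concentration < 1 fM: 3
#>        - extreme concentration > 10 mM: 5
#>        - unclear units: 4
#>   3. collapse_within_document        183 ->    177
#>        - lower value within publication: 6
#>   4. remove_cited_duplicates         177 ->    169
#>        - cited duplicate: 8
#>   5. remove_author_overlap           169 ->    161
#>        - author overlap: 8
```

Each stage reports how many records entered, how many survived, and why
the rest were dropped; the 161 survivors match the generator's planted
ground truth exactly. Survivors are typed measurements:

```r
m <- res$measurements[[1]]
m$mtype; round(m$values, 3); system_key(m$system)
#> "pKi"   4.011   "P10008::[O-][N+](=O)c1ccccc1"
round(dg_from_pkd(m$values[1]), 2)   # latent free energy, kcal/mol
#> -5.47
fp <- morgan_fingerprint(system_ligand(m$system), radius = 2, n_bits = 2048)
sum(fp$values)                        # on-bits of the circular fingerprint
#> 18
```

A pKi of 4.011 is a weak binder (98 µM); its implied binding free energy
at 298.15 K is −5.47 kcal/mol. The fingerprint, one-hot encodings and
pipeline outputs can be archived with `write_store()` and read back
bit-exactly with `read_store()`.

The same operations are scriptable:

```sh
Rscript inst/cli/affinity-forge.R fixtures  --spec spec.yaml --out data/
Rscript inst/cli/affinity-forge.R curate    --input data/raw.csv \
        --output curated.csv --report report.json
Rscript inst/cli/affinity-forge.R featurize --config feats.yaml \
        --input curated.csv --output features.parquet
```

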