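---
title: "affinityforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{affinityforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and design decisions
behind affinityforge: what each component assumes, which knobs matter,
and what the synthetic-fixture tests do and do not demonstrate about
real data.

# The curation cascade

Raw activity tables mix measurement classes, units, republished values
and database artifacts. The cascade converts a table with columns
`record_id, uniprot_id, target_id, compound_id, smiles, activity_type
(Kd|Ki|IC50), value, units, document_id, year, authors` into
independent, unit-harmonized measurements in five ordered stages:

1. **Grouping and dummy removal.** Records are keyed by *system* — the
   pair (protein key, canonical ligand SMILES). The protein key is the
   UniProt accession when present, else the NCBI accession, else a hash
   of the sequence; UniProt is preferred because it is the one universal
   join key across kinase resources. Grouping only assigns keys — values
   are never aggregated here, that happens in stage 3. Records against
   the placeholder target `CHEMBL612545` (used by the source database to
   validate unchecked analyses) are purged, as are records whose SMILES
   does not parse.
2. **Standardization and extreme filtering.** Concentration activities
   are converted to the p-scale, `p = -log10(concentration in molar)`;
   Kd, Ki and IC50 become pKd, pKi, pIC50. Recognized units are fM, pM,
   nM, µM (micro-sign or `u`), mM and M, case-insensitively; anything
   else (mass-per-volume, percents, blanks) is flagged *unclear units*
   and dropped — there is no defensible automatic conversion without a
   molecular weight and assay context. Non-positive values cannot be
   log-transformed and are dropped likewise. Extremes are then removed
   with *strict* boundaries: concentration > 10 mM (p < 2) or < 1 fM
   (p > 15). The boundary values themselves — exactly 10 mM or 1 fM —
   are retained, matching the strict inequalities of the rule as stated;
   this boundary decision is deliberate and tested.
3. **Within-publication collapse.** Where one system has several values
   in the same document, only the highest p-value (strongest affinity)
   survives. This removes assay-optimization series and ambiguous
   stereoisomer annotations. Exact ties are broken by the lowest
   ingestion index, so the result is deterministic for a fixed row
   order; permuting input rows can change which tied row survives but
   never the count.
4. **Citation deduplication.** Within a system, documents reporting an
   *identical* value are treated as one experiment republished; only the
   earliest-year document survives. "Identical" is |Δp| ≤ 1e-6 by
   default (exposed in `curation_config()`): the rule's source says
   "identical" without precision, and 1e-6 on the p-scale is far below
   any experimental resolution while tolerating float round-trips
   through CSV. Identity is closed transitively (components of the
   identity graph). A record with a missing year is never kept as the
   original.
5. **Author-overlap deduplication.** Within a system, documents whose
   author sets intersect are not independent replications. Author names
   are normalized by case-folding and whitespace-collapsing only; fuzzy
   name matching (initials, transliteration) is explicitly out of scope
   — it would silently merge distinct people. From each connected
   component of the overlap graph the earliest-year record survives.
   Documents with no authors form singleton components.

In both deduplication stages the survivor is the *earliest* publication:
the intent is to remove citations of previously published values, so the
original is the one to keep. The stage order is fixed; citation
deduplication compares values *after* the within-document collapse.

The `CurationReport` chains counts (`records_out` of stage k equals
`records_in` of stage k+1, enforced by its constructor) and itemizes
drop reasons. The cascade is idempotent: running it on its own survivors
drops nothing.

# Dataset providers

`read_chembl_csv()` filters by accession, then by standardized
measurement type, then takes a uniform random subsample of exactly
`sample_size` rows. Subsampling uses R's Mersenne-Twister via
`sample.int` under an explicit seed that is recorded in the provider's
provenance, so a (path, filters, seed) triple always reproduces the same
provider. `read_pkis2_table()` emits percent-displacement measurements;
kinase display names must resolve through a user-supplied name → UniProt
table, and unresolved names either abort (strict) or are returned as a
rejects table (lenient) — never silently dropped. Readers operate only
on local snapshot files, never live APIs: versioned local copies are the
only way to make ingestion immutable and reproducible.

# Featurization

**Circular fingerprint.** `morgan_fingerprint()` implements an
ECFP-style fingerprint with a fully documented hash scheme:

- round-0 identifier per heavy atom: FNV-1a 32-bit hash of the string
  `element|degree|charge|nH|ring` (heavy-atom degree, formal charge,
  attached hydrogen count, ring membership);
- round r: hash of `r|<own id at r-1>|<sorted neighbor ids at r-1,
  comma-separated>`;
- all identifiers from rounds 0..radius are folded modulo `n_bits` into
  a bit vector.

Defaults are radius 2 and 2048 bits — the community convention for
ECFP4-class fingerprints. Bond orders are deliberately *not* hashed:
the atom invariants already carry degree and ring membership, and
omitting bond orders makes the fingerprint independent of
aromaticity/kekulization conventions, which differ across
cheminformatics toolkits. Because the scheme is deterministic and fully
specified, the test suite verifies it against an independent
reimplementation (different language, different SMILES parser, different
hash code) bit-for-bit, and verifies invariance under randomized-atom-order
SMILES respellings. An atom is "in a ring" iff it has an incident edge
that is not a bridge of the heavy-atom graph — equivalent to lying on
some cycle.

**One-hot encodings.** `one_hot_smiles()` encodes the *canonical* SMILES
over a configurable alphabet; the default covers the organic-subset
element letters (upper case and aromatic lower case), `l`/`r` as the
second characters of Cl/Br, ring-closure digits and the structural
symbols of the SMILES grammar. Rows beyond the string are all-zero
padding, so decoding (argmax per row until the first zero row) is exact.
`one_hot_sequence()` uses the 20 canonical amino acids plus `X`; a
lenient flag maps the ambiguity codes B, Z, J, U, O to `X` instead of
erroring. Over-length strings and out-of-alphabet characters are
rejected naming the offender — truncation would silently corrupt the
feature.

**Template selection.** `select_template()` returns the candidate
structure whose co-crystallized ligand maximizes the Tanimoto
coefficient on circular fingerprints, the standard prelude to
template-guided docking. Only the fingerprint metric is implemented
(maximum-common-substructure and shape metrics are out of scope). Ties
are broken by lexicographically smallest structure identifier. The
Tanimoto of two all-zero fingerprints is defined as 1 — two molecules
with no hashed environment at this bit width are indistinguishable,
and returning 0 would rank them below genuinely dissimilar pairs.

**Pipelines.** A `FeaturizationPipeline` runs its steps in order per
system; per-step tensors are flattened *row-major* (a documented choice
— R stores matrices column-major, so flattening transposes first; the
first `ncol` entries of a flattened one-hot matrix are its first row)
and concatenated into a `concat` feature. With `retain_last_only` only
the final step's tensor is kept, bounding memory when archiving large
batches. A step failure (e.g. a ligand featurizer on a protein-only
system) skips that system and records the error rather than aborting
the batch; batch featurization of thousands of systems must not die on
one malformed entry.

# The assay observation model

Different assays read out the same underlying binding event on
different scales. Rather than converting all data to one measurement
type up front, the package keeps each observation on its native scale
and maps a latent Gibbs free energy ΔG (kcal/mol) through a
deterministic, differentiable link per measurement class:

- `Kd = c0 * exp(ΔG / RT)` with the standard state `c0 = 1 M`, so
  `pKd = -ΔG/(RT ln 10)`; R is fixed at 1.987204259e-3 kcal/(mol·K) and
  T defaults to 298.15 K (taken from each measurement's
  `AssayConditions`; the supported databases do not report assay
  temperature, so the laboratory standard is the documented default).
- pKi and pIC50 share the pKd link by default. An exact Cheng–Prusoff
  correction needs the substrate concentration and Km, which activity
  exports do not carry; an additive per-assay `offset` hook is exposed
  for users who have them.
- Percent displacement uses single-site competitive occupancy,
  `100 * L / (L + Kd)` at probe concentration L — the standard
  approximation for single-concentration competition binding. The probe
  concentration is a required input and is *never* defaulted: it is
  assay-specific and not published with the datasets.

Every link returns its analytic derivative with respect to ΔG, so any
gradient-based trainer can backpropagate through the conversion without
symbolic differentiation. `observation_loss()` is the mean squared error
over a measurement's replicate values on the native scale (replicates
are treated as repeated observations of the same quantity), with the
chain-rule gradient. Squared error on the native scale is the simplest
loss family consistent with per-class adaptation; nothing in the design
precludes swapping it.

`evaluate_dg_recovery()` checks the whole chain by simulation: 500
systems with true ΔG uniform on [-14, -6] kcal/mol (spanning tight
nanomolar binders to weak millimolar ones), each assigned one
measurement class at random, observed with Gaussian noise of σ = 0.2 on
the p-scale or σ = 3 on the percent scale, 3 replicates per system, and
a probe concentration of 1 µM for the displacement assays (a typical
single-concentration screening dose). Percent draws are clamped to the
measurement validity window [-10, 110]; at saturation this is a ~4e-4
per-draw tail event with negligible bias. Recovery is by bounded scalar
minimization (`stats::optimize` on [-25, 5], tolerance 1e-7), and
success means |ΔG_hat − ΔG_true| within three standard errors, with the
observation noise propagated to the ΔG scale through the local link
slope. Near-saturated displacement observations are genuinely
uninformative (the link is flat there), which the slope-based tolerance
reflects honestly rather than hiding.

# Tensor serialization

Feature tensors are ragged: fingerprints, one-hot matrices and
similarity scalars differ in shape across records and featurizers.
Padding to a homogeneous array wastes space and corrupts shape
semantics, so `write_store()` encodes each feature as two nested list
columns in Parquet — `feat.<name>` (row-major flattened values) and
`feat.<name>.shape` (dimensions) — alongside `record_id`, `y.value`,
`y.type` and `meta.<key>` string columns. A feature may be explicitly
null for a record, which is distinct from a zero-length tensor and
round-trips as such. File-level metadata carries a schema version
(readers refuse a different major version, naming both), per-feature
dtypes, and caller-supplied provenance (config hash, seed). Output
bytes are deterministic for identical input, so stores can be
content-hashed for provenance. Values round-trip bit-exactly, including
zero-length rows.

# The fixture generator

`generate_curation_fixture()` plants each drop class in its own
dedicated system — every planted structure (dummy-target row, extreme,
unclear unit, within-document duplicate pair, length-3 citation chain,
size-3 author-overlap component) gets a fresh system and fresh author
names, and every clean base row its own (system, publication) pair.
This isolation makes the per-stage ground truth exact by construction:
stage counts follow arithmetically from the planted counts, and the
surviving record ids are known before the cascade runs. Duplicate
values in citation chains are copied exactly (not re-noised) so the
identity criterion is unambiguous; author components realize the
requested connectivity from a synthetic name pool with controlled
overlap; planted values keep ≥ 0.2 p-units of separation and distinct
years where ties would otherwise make survivors ambiguous. Ligands come
from a packaged pool of 64 valid drug-like SMILES.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic structure–activity correlation
between ligand and affinity; overlapping drop classes (one record that
is simultaneously a dummy-target row *and* extreme); near-identical
values straddling the citation tolerance; author-name variants
(initials, accents, ordering); mixed dialects within one file; and the
sheer unit chaos of production exports. The cascade stages are
additionally cross-checked against an independent brute-force pairwise
oracle on small fixtures, which covers arbitrary (non-isolated)
interactions among stages 3–5.

The observation-study generator (`generate_observation_study()`) fixes
the simulation conditions listed in the previous section as its
defaults; they were chosen once as field-realistic values and are not
tuned.

# Numerical choices and degenerate inputs

- Exact 32-bit FNV-1a in plain R: the multiply is split into 16-bit
  halves so all intermediates stay below 2^53.
- Citation-identity tolerance 1e-6 (p-scale), exposed in configuration.
- Extreme filter: strict inequalities, boundaries retained.
- Ties: lowest ingestion index (within-document collapse), earliest
  year then lowest ingestion index (deduplication survivors),
  lexicographically smallest structure id (template selection).
- Missing year: treated as latest — never the kept original.
- Empty inputs: an empty record table yields an all-zero report; an
  empty system list yields an empty featurization batch; an empty
  record list yields a valid empty store.
- `optimize` on [-25, 5] with tolerance 1e-7 for scalar ΔG recovery;
  the interval comfortably brackets the simulated range.

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run at sizes chosen to
exercise every property while staying quick on a single CPU: 100 random
curation fixtures of up to 500 records (closure), brute-force oracle
comparisons at ≤ 50 records, 500 simulated systems for ΔG recovery,
20 respellings for each of 10 ligands for fingerprint invariance, and
1,000 ragged records for store round-trips. All randomness is seeded;
the acceptance script derives every seed from its `--seed` argument.

# Known limitations

- Stereochemistry is preserved as written but racemates are not
  enumerated; two stereo-spellings of the same racemic compound are
  distinct systems.
- Unit standardization covers molar-style concentration units only.
- pKi/pIC50 share the pKd link unless an offset is supplied; systematic
  assay-class shifts are otherwise absorbed into the latent ΔG.
- Author matching is exact after normalization; shared rare surnames
  with different initials count as overlap, spelled variants do not.
- The tensor store reads eagerly; out-of-core access and sharding are
  out of scope.
- 3D structure handling (docking, pocket annotations, structure
  preparation) is out of scope; template selection stops at ranking
  candidate structures by co-ligand similarity.
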