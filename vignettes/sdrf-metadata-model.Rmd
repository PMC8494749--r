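---
title: "The SDRF/IDF sample-metadata model in sdrftab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SDRF/IDF sample-metadata model in sdrftab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrftab)
```

## The data model

A proteomics study is described by two tab-delimited files. The **IDF**
(Investigation Description Format) is a key/value document: the first cell
of each line is a property key (`Investigation Title`,
`Experiment Description`, `Person Last Name`, ...) and the remaining cells
are its values. Person keys are multi-valued and column-aligned: the i-th
value of every person key describes the same submitter. The **SDRF**
(Sample and Data Relationship Format) is a matrix in which *each row is one
relationship between a sample and a data file*. Sample properties carry the
`characteristics[...]` prefix, data-file properties the `comment[...]`
prefix, and the variables under study the `factor value[...]` prefix; the
`source name` and `assay name` columns hold the sample and acquisition
identifiers.

Two proteomics-specific patterns break the one-sample-one-file relationship
of transcriptomics metadata and drive the row semantics:

* **Fractionation** — one sample is measured as several files; the sample
  information is repeated for each file and `comment[fraction identifier]`
  (a positive integer) distinguishes them.
* **Multiplexing** (TMT, SILAC) — several labeled samples share one file;
  the file information is repeated for each channel and `comment[label]`
  (e.g. `TMT128N`) distinguishes them.

A design combining both, three multiplexed samples with three fractions,
therefore yields nine rows over three files. Because each row is
self-contained, rows can be processed independently, tables from different
datasets can be concatenated (`merge_sdrf()`), and a table can be
partitioned by any property (`split_sdrf()`).

## Cell micro-syntax

Complex values are encoded as ordered `KEY=value` pairs separated by `;`.
The package understands `NT` (name), `AC` (accession), `MT` (modification
type), `TA` (target residues), `PP` (position), `MM` (monoisotopic mass,
Da), `CF` (chemical formula) and `CS` (cleavage-site regular expression);
unrecognized keys are preserved verbatim and surfaced by the validator at
info level, so the vocabulary can grow without breaking readers. Three
choices here were genuinely open and are fixed as follows:

* A cell with no `=` is shorthand for a name-only value (`NT`), and `MT`
  defaults to *variable* — together these keep plain `Oxidation` usable as
  a modification cell.
* Mass tolerances use the smallest unambiguous grammar,
  `<number><unit>` with unit `ppm` or `Da` (case-insensitive); values must
  be strictly positive.
* Cleavage agents use `NT`/`AC` plus `CS` for the cleavage-site pattern;
  no richer enzyme grammar is attempted.

## Validation

`validate()` concatenates three rule families and orders findings by rule
code, then row, then column, so identical inputs give byte-identical
reports. Severities grade actionability: ERROR means the table cannot be
interpreted unambiguously, WARNING means reanalysis will likely be
impaired, INFO is advisory.

* **Structural rules (S1–S14).** Identifier columns, the universal
  mandatory property set (organism, organism part, biological replicate;
  fraction identifier, technical replicate, data file, label), no empty
  cells in required columns, integer fraction identifiers, and the row
  semantics: rows sharing a source name must agree on every characteristic
  (the biological replicate is a property of the sample), rows sharing a
  data file must agree on fraction identifier, technical replicate and
  instrument (the technical replicate is a property of the file), and one
  (data file, label) pair identifies one sample. Recommended
  search-parameter columns (instrument, cleavage agent, tolerances,
  modifications) and unknown label names are warnings; duplicate rows are
  warnings (readers never drop data silently); a constant factor column is
  info.
* **Template rules.** Templates are shipped as structured text files so a
  repository can tighten policy without code changes. The `human` template
  requires `characteristics[disease]` (ERROR), recommends
  `characteristics[ancestry]` (WARNING), pins the organism to
  `Homo sapiens` (ERROR) and notes (INFO) when no sample is labeled
  `normal`, the conventional value for control samples. The `cell-line`
  template requires `characteristics[cell line]`; its severity is ERROR
  when the template is requested explicitly and WARNING otherwise, which
  mirrors its "recommended metadata" status.
* **Vocabulary rules.** Cells carrying an `AC` accession are checked
  against an offline term store: unknown accessions and label/accession
  mismatches are warnings. Free text is always legal — ontology annotation
  is encouraged, not enforced.

Two deliberate conventions: `comment[label]` is required for *all*
experiments, with the sentinel `"label free sample"` for unlabeled runs, so
that every row has the same (file, label) assay identity; and the
missing-value token emitted is `not available` (with `not applicable` also
recognized on read), the de facto convention of this format family.

## The controlled-vocabulary snapshots

Live ontology-lookup queries are an annotation-time aid, not a format
requirement, so validation runs against bundled snapshot files
(3-column TSV: accession, label, prefix) covering the term classes that
recur in SDRF annotation: organisms, organs, diseases, cell lines,
instruments, cleavage agents and modifications. The set is a small curated
subset — widely used accessions such as `UNIMOD:35` (Oxidation),
`NCBITaxon:9606` (Homo sapiens) or `MS:1001251` (Trypsin) are genuine, but
the snapshot is not an authoritative ontology export, carries no term
hierarchy, and validation against it shows conformance to *a* vocabulary,
not current term accuracy. User-supplied snapshot directories are accepted
on the command line (`--cv`). The store maintains a bijection between
accessions and (prefix, case-folded label) pairs; the bundled set is tested
for it.

## The design generator

`generate_design()` is the package's synthetic-data source: it expands a
compact specification into a complete SDRF table. Its defaults describe a
small, realistic human study (organism `Homo sapiens`, organism part
`liver`, factor `phenotype` with levels `normal`/`disease`, instrument
`Q Exactive` with its accession) — values chosen once as typical of the
annotated public corpus, not tuned afterwards. Expansion semantics:

* Samples are packed into mixtures of at most the plex size (1 for
  label-free); SILAC designs must fill every channel, so the sample count
  must divide evenly — partial TMT plexes are allowed because partially
  used TMT kits are common, partially labeled SILAC cultures are not.
* One file per (mixture, technical replicate, fraction), named
  `{prefix}_{mixture}_{t}_{f}.raw`; each file carries one row per sample of
  its mixture.
* Channel assignment is deterministic channel-list order and technical
  re-injections reuse the sample-to-channel map; the `seed` field is
  reserved for future randomized layouts. Deterministic output keeps
  fixtures stable and makes the generator usable as its own oracle target.
* Factor levels are assigned to biological replicates round-robin, and the
  factor appears both as a `characteristics` column and as the
  `factor value` column, as annotated tables do in practice.

The generator emulates the *structure* of real designs — replication,
fractionation, multiplexing, channel bookkeeping — and none of their
*content* noise: no missing or inconsistent cells, no free-text dialects,
no instrument drift across files, one organism per table. Passing the
generator-based suites therefore demonstrates that the tools implement the
format's row semantics correctly, not that they are robust to every
hand-curated table in the wild; the dialect tolerance that is tested
(header case and spacing variants, missing tokens) is exercised by separate
randomized header corpora.

## Numerical and formatting choices

* Headers are matched case-insensitively with whitespace tolerance around
  the bracket, and written in one canonical lower-case form; repeated
  headers are distinguished by a 1-based occurrence index assigned left to
  right.
* The writer orders columns into the canonical three-section layout
  (sample metadata, then `assay name` and file comments, then factor
  values), stably within sections; the reader accepts any order. Round-trip
  identity is therefore stated over canonicalized tables.
* Cells are verbatim: the reader performs no trimming or type coercion,
  and the writer refuses cells embedding tabs or newlines rather than
  escaping them — the format has no escaping convention.
* Degenerate inputs: an empty file is a parse error (the header is
  mandatory); a header-only table is a valid zero-row table; ragged rows
  report the first offending 1-based line number.
* `assay name` repeats across the channel rows of one multiplexed file;
  the (data file, label) pair is the row-level assay identity.

## Problem sizes

The test suite and the acceptance script exercise 100 randomized design
specifications per property (replicates and fractions up to 5, all six
quantification methods, giving tables up to a few hundred rows), 1000
random header dialects and 200 random key/value and modification cases —
sizes at which the combinatorics of the format (plex packing, occurrence
indexing, partitioning) are fully exercised while the whole suite stays
fast.

## Known limitations

* No streaming reader: tables are held in memory (SDRF files are small).
* The converter emits a neutral YAML parameter document and a flat
  annotation CSV; it does not write any search engine's native
  configuration dialect.
* IDF support covers the key/value layer used by proteomics submissions,
  not the protocol-reference and term-source machinery of classic
  transcriptomics MAGE-TAB.
* `Comment[Instrument]` and `Software` are emitted by
  `idf_from_description()` beyond the fixed mapped key list so the record
  round-trips; consumers expecting only the minimal key set can ignore
  them.
* Chemical formulas (`CF`) are carried but not parsed, and accession/mass
  consistency for modifications is not cross-checked against a modification
  database.
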