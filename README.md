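# sdrftab

Machine-checkable sample metadata for proteomics experiments.

Public proteomics datasets are routinely deposited with RAW files and a
free-text description but without a standardized record of *which sample
went into which file*, which makes quantitative reanalysis difficult or
impossible. `sdrftab` implements the tabular sample-metadata representation
used to close that gap: the **SDRF** (Sample and Data Relationship Format)
table, in which every row records one relationship between a sample and a
data file, and the companion **IDF** (Investigation Description Format)
key/value study description. It is aimed at data submitters preparing
annotations, repository curators validating them, and reanalysis pipelines
consuming them.

## What the package does

* **Parse and write** SDRF (`read_sdrf()`, `write_sdrf()`) and IDF
  (`read_idf()`, `write_idf()`, `idf_from_description()`) files, plus the
  key/value micro-syntax used inside cells — e.g. methionine oxidation is
  encoded as

  ```
  AC=UNIMOD:35;NT=Oxidation;MT=Variable;TA=M
  ```

  (`parse_modification()`, `parse_enzyme()`, `parse_tolerance()`).

* **Validate** tables (`validate()`) against a graded rule registry:
  structural rules (one `source name` and one `assay name` column; mandatory
  `characteristics[organism]`, `characteristics[organism part]`,
  `characteristics[biological replicate]`; per-file
  `comment[fraction identifier]`, `comment[technical replicate]`,
  `comment[label]`, `comment[data file]`; agreement of sample properties
  within a source name and file properties within a data file),
  experiment-type templates (`default`, `human`, `cell-line`) and offline
  controlled-vocabulary snapshots (`default_cv_store()`). Findings are
  ERROR / WARNING / INFO with stable rule codes and row/column coordinates.

* **Generate** complete valid designs from a compact specification
  (`design_spec()`, `generate_design()`): label-free, TMT 6/10/11-plex and
  SILAC designs with replication and fractionation. Row semantics follow the
  format: with fractionation the sample information is repeated for each
  data file, and in multiplexed runs the data-file information is repeated
  for each labeling channel, so a design with three multiplexed samples and
  three fractions yields 3 × 3 = 9 rows over 3 files.

* **Merge and split** tables for meta-analysis (`merge_sdrf()`,
  `split_sdrf()`), and **convert** validated tables into downstream analysis
  inputs: per-file search-parameter documents (`extract_search_params()`,
  `write_search_params()`) and a flat per-row annotation table
  (`to_annotation_table()`) with
  `run,fraction,label,bio_replicate,tech_replicate,condition` columns.

* A **command line** (`sdrf_cli()`, or the `inst/exec/sdrftab` script) with
  `validate`, `generate`, `convert`, `merge`, `split` and `idf build`
  subcommands; exit status 0 = valid, 1 = validation errors, 2 = usage/I-O
  error.

## Worked example

A TMT experiment with three multiplexed samples and three fractions:

```r
library(sdrftab)

spec <- design_spec("TMT6", n_biological = 3, n_fractions = 3)
tab <- generate_design(spec)
tab
#> <sdrf_table> 9 rows x 12 columns
#>   source name | characteristics[organism] | characteristics[organism part] | ...

validate(tab)
#> VALID: 0 error(s), 4 warning(s), 0 info
#>   WARNING [S10] (column 'comment[cleavage agent]') recommended 'comment[cleavage agent]' column is missing
#>   ...
```

Nine rows (one per sample–file relationship) over three data files: samples
repeat across fractions, file properties repeat across the TMT channels.
The warnings note that the recommended search-parameter columns (cleavage
agent, tolerances, modifications) were not filled in. Flattening for a
quantification tool:

```r
to_annotation_table(tab)
#> # A tibble: 9 × 6
#>   run        fraction label  bio_replicate tech_replicate condition
#> 1 file_1_1_1        1 TMT126 1             1              normal
#> 2 file_1_1_1        1 TMT127 2             1              disease
#> 3 file_1_1_1        1 TMT128 3             1              normal
#> 4 file_1_1_2        2 TMT126 1             1              normal
#> # i 5 more rows
```

Each annotation row carries the run, its fraction, the channel, the
replicate structure and the study condition taken from the
`factor value[...]` columns. The same pipeline from a shell:

```sh
sdrftab generate design.txt -o study.sdrf.tsv
sdrftab validate study.sdrf.tsv --template human --json report.json
sdrftab convert study.sdrf.tsv --annotation annotation.csv --params params/
```

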