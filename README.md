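# cdeinventory

Ranked common-data-element (CDE) inventories from clinical-trial case report
forms, and coverage of those elements in hospital EHR systems.

## The problem

Setting up electronic data capture for a clinical trial, and re-using
routinely collected electronic health record (EHR) data to pre-populate it,
both hinge on knowing *which data elements trials ask for most often* and
*which of them hospitals can actually supply*. Multi-sponsor CRF corpora ask
for the same clinical facts under wildly inconsistent labels
(`<b>Heart Rate</b> (bpm)`, `heart rate`, `HEART RATE`), so building that
inventory is a record-linkage problem before it is a counting problem.

`cdeinventory` is an R package for the whole workflow:

1. **Ingest** CDISC ODM 1.3 metadata and tabular CRF exports into one
   trial-master model (`parse_odm()`, `parse_table()`, `study_set()`).
2. **Normalize** labels — strip markup, style, units — and merge variants
   into canonical elements by single-linkage clustering over a conjunction
   of string metrics, with CDISC variable names as hard keys and expert
   overrides as the final word (`clean_label()`, `cluster_labels()`,
   `apply_overrides()`).
3. **Categorize** forms into 14 SDTM-style topic domains via a keyword
   dictionary plus overrides (`assign_domains()`, `domain_table()`).
4. **Rank**: drop singleton domains, then score each element as the sum of
   planned enrollments of the distinct trials containing it
   (`filter_domains()`, `rank_elements()`), attach semantic codes
   (`annotate()`) and compare against a prior inventory
   (`compare_inventories()`).
5. **Coverage**: turn per-site EHR exports into availability /
   frequency-of-documentation heat maps (`compute_frequency()`,
   `classify_cells()`, `build_heatmap()`), with the serious-adverse-event
   subset emitted separately.

The fuzzy-matching rule is: two cleaned labels denote the same element when
`jaro_winkler(a, b) >= 0.90` **and**
`levenshtein(a, b) <= min(3, floor(0.25 * max(|a|, |b|)))`
(optionally also requiring equal Metaphone codes); equal CDISC variable
names match outright and unequal ones veto. The documentation frequency of
an element at a site is

```
frequency (%) = round_half_up(100 * n_values / n_patients, 1)
```

over a reference year — values above 100% are legitimate (labs are measured
repeatedly). The element score used for ranking is
`sum(planned_enrollment(t))` over the distinct trials `t` containing the
element in a domain.

Because real multi-sponsor CRFs are confidential, the package includes a
synthetic-corpus generator with complete ground truth
(`generate_studyset()`, `generate_exports()`): 23 trials across 7 disease
areas, 1086 forms, noisy labels drawn from a shipped 208-element vocabulary,
and per-site exports with known counts — every pipeline stage is testable
end to end.

## Worked example

```r
library(cdeinventory)
res <- run_cde_pipeline(seed = 1, out_dir = "cde_out")

res$corpus_table
#>     disease_area n_trials n_forms
#> 1 cardiovascular        3     158
#> 2       diabetes        3     172
#> 3     infectious        2      60
#> 4   neuroscience        1      64
#> 5       oncology        3     192
#> 6    psychiatric        1      69
#> 7    respiratory       10     371
#> 8            Sum       23    1086

head(res$inventory[, c("canonical_label", "domain_key", "n_trials",
                       "weighted_score", "rank")], 4)
#>            canonical_label      domain_key n_trials weighted_score rank
#> 1   Adverse event end date   adverse_event       23         143919    1
#> 2    Adverse event ongoing   adverse_event       23         143919    2
#> 3 Adverse event start date   adverse_event       23         143919    3
#> 4       Adverse event term   adverse_event       23         143919    4

res$heatmap$matrix[rownames(res$heatmap$matrix) == "Bilirubin, total", ]
#>     S1     S2     S3     S4     S5     S6     S7
#> "30.4"    "A" "44.4" "54.4" "78.6"    "A"    "A"
```

The corpus table counts trials and forms per disease area with an exact
`Sum` row. Inventory rows are (element, domain) pairs ranked by
enrollment-weighted frequency — here the ubiquitous adverse-event fields
occur in all 23 trials, so their score is the total planned enrollment
(143,919 subjects) and ties break alphabetically. The heat-map row shows one
element's coverage across seven sites: a computed documentation frequency
(`30.4` = 9574 entered values / 31,493 patients), `A` for available without
counts, `N/A` for not available.

A thin command-line front end over the same functions ships in
`inst/scripts/cde-pipeline.R` with subcommands `synth`, `ingest`,
`normalize`, `domains`, `inventory` and `coverage`.

## Scope

Domains are inventory labels, not SDTM submission datasets; semantic codes
come from static mapping tables, not live terminology services; free-text
labels are not parsed with NLP. The methods vignette
(`vignettes/cde-inventory-methods.Rmd`) documents the model, the default
thresholds and why, what the synthetic corpus does and does not emulate, and
known limitations.
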