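---
title: "Building common-data-element inventories from case report forms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building common-data-element inventories from case report forms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdeinventory)
```

## The problem

Clinical trials capture subject data on case report forms (CRFs). Across
sponsors, the same clinical fact — a heart rate, a total bilirubin, the
seriousness of an adverse event — is asked for under dozens of superficially
different labels: markup-decorated, unit-suffixed, recased, misspelled, or
renamed outright. Before routinely collected electronic health record (EHR)
data can pre-populate trial databases, someone has to answer two questions:
*which data elements do trials actually ask for most often*, and *which of
those can hospital systems actually supply, and how completely?*

`cdeinventory` implements that workflow end to end: ingest heterogeneous CRF
metadata into one trial-master model, normalize and deduplicate element
labels, classify forms into topic domains, rank the deduplicated elements by
enrollment-weighted frequency, and score each element's availability and
frequency of documentation against per-site EHR exports. Because real
multi-sponsor CRF corpora are confidential, the package also ships a
synthetic-corpus generator with complete ground truth, so the whole pipeline
is testable without access to proprietary data.

## Ingestion model

The trial-master model (`study_set`) is three tables: trials (with disease
area, planned enrollment, site count), forms, and items. Two readers populate
it: `parse_odm()` for CDISC ODM 1.3 metadata and `parse_table()` for
delimited exports driven by a column-mapping dialect. Both produce identical
fragments for identical content, which is tested directly.

Design choices a reader should know about:

* **Label precedence in ODM.** An item's label is its translated question
  text in the preferred language (default English), then any question text,
  then the item `Name`. ODM files do not mark which field a sponsor used as
  the visible label, so the reader prefers the most human-facing one.
* **Repeating and unscheduled forms** ingest once, flagged `repeating = TRUE`.
  Form repetition is a data-collection schedule, not evidence that an element
  is more common, so repetition never multiplies element counts.
* **Trials without a planned enrollment are rejected at ingestion.**
  Enrollment is the ranking weight; silently defaulting it would corrupt the
  inventory, so the error surfaces at the door.
* Encodings other than UTF-8 must be declared in the dialect configuration.

## Label normalization

Cleaning (`clean_label()`) removes markup tags and style fragments, decodes
common HTML entities, strips required-field asterisks and trailing colons,
collapses whitespace, and peels a trailing parenthesized/bracketed token into
`removed_units` when it matches a unit lexicon (a UCUM-flavoured list ships
with the package and is extensible). Case is preserved — folding happens
inside matching — so canonical labels keep their original capitalization.

Matching (`is_match()`) applies a strict decision order:

1. equal CDISC variable names (case-insensitive) match outright;
2. *unequal* non-missing variable names veto any match — `SYSBP` and `DIABP`
   stay apart no matter how similar their labels;
3. case-folded equal texts match;
4. otherwise a fuzzy rule fires when the Jaro-Winkler similarity reaches
   `jw_threshold` **and** the Levenshtein distance is at most
   `min(lev_max, floor(lev_len_ratio * max(nchar)))`, optionally also
   requiring equal Metaphone codes.

The defaults — `jw_threshold = 0.90`, `lev_max = 3`, `lev_len_ratio = 0.25`,
`require_phonetic_agreement = FALSE`, prefix weight 0.1 — are the package's
own calibration; no published threshold exists for this combination of
measures. The conjunction matters: Jaro-Winkler alone would merge long labels
that share a prefix and differ in one word ("Adverse event start date" /
"Adverse event end date" score ≈ 0.96), but their edit distance (4) exceeds
the cap; conversely Levenshtein alone would merge short lookalikes whose
Jaro-Winkler similarity stays below 0.90 ("Height" / "Weight", distance 1,
similarity 0.89). Every clustering result records its configuration.

Clustering (`cluster_labels()`) is single-linkage agglomeration over
`is_match()`. Items are sorted into a canonical order (case-folded text,
trial, form, item), deduplicated into label nodes, and merged in three
passes: exact equality, shared variable names (a cross-block pass, since a
hard key should join labels regardless of phonetics), and fuzzy matching
within blocks keyed by the first character of the Metaphone code. Blocking
makes the pass near-linear in practice but is a completeness trade-off:
fuzzy pairs whose initial phonemes differ (e.g. a typo in the first letter)
are not compared. Within single linkage, two components that carry distinct
non-missing variable names are never merged, so the hard-key veto holds at
cluster level, not just pairwise.

The canonical label is the modal variant's cleaned text, ties broken by
shortest then lexicographically smallest — a deterministic surrogate for the
expert's choice of preferred name. Expert review itself is consumed as an
override table (`apply_overrides()`: merge, split, rename, remove,
recategorize), applied in file order with every touched cluster locked.

The string metrics themselves are implemented in C++ (Levenshtein,
Jaro-Winkler) and R (original Metaphone, not Double Metaphone). The test
suite checks them against independent references: `utils::adist` for
Levenshtein, a naive from-definition implementation plus published worked
examples for Jaro-Winkler, and an independent transcription of the original
rule table plus hand-traced codes for Metaphone. One subtlety: under the
original rules `TH` encodes to the theta symbol `0`, so *Thompson*
(`0MPSN`) and *Tompson* (`TMPSN`) do **not** share a code, while
*Hemoglobin* and *Haemoglobin* do (`HMKLBN`).

Similarity scope defaults to corpus-wide matching; `scope = "domain"` is
accepted in the configuration for analysts who prefer within-domain matching,
at the cost of splitting elements shared across domains.

## Form domains and ranking

Forms are classified into fourteen topic domains — SDTM two-letter codes
where they exist, the custom code `ZC` for disease characteristics, and no
code for surgery — via a keyword dictionary (`assign_domains()`), with an
override table again authoritative. The dictionary is a surrogate for what
is, in real programs, a fully manual expert allocation; dictionary order is
precedence order and each form receives exactly one domain (`unassigned`
when nothing matches).

`domain_table()` ranks domains by the number of trials they appear in, then
by form count. `filter_domains()` then drops domains whose forms appear at
most once corpus-wide: a one-off special-purpose form should not seed
inventory entries. (The alternative reading — once per trial — is exposed by
simply not calling the filter, since the table carries both counts.)

`rank_elements()` scores each (element, domain) pair as the **sum of planned
enrollments of the distinct trials containing the element in that domain**.
The weight is per-trial because enrollment is a trial-level property; a
`weight = "per_form"` variant that credits every form occurrence is exposed
for sensitivity analysis. Rows are sorted by weighted score, trial count,
then label, and ranked densely; an element legitimately appearing in several
domains is kept once per domain with per-domain scores. On corpora of up to
a few thousand items the ranking is verified against a brute-force
recomputation written independently of the implementation.

`compare_inventories()` matches the current inventory against a prior element
list by UMLS concept identifier when both sides have one, else by case-folded
label; the partition into identical/new is exhaustive by construction. The
CUI-before-label precedence is the package's own rule: semantic codes are
the stronger key where they exist.

## EHR coverage

`compute_frequency()` is deliberately simple: entered values in the reference
year divided by patients in that year, times 100, rounded **half-up** to one
decimal (9574 values over 31493 patients → 30.4%). Values above 100% are
legitimate — laboratory analytes are measured many times per patient. Base
R's banker's rounding is not used because reported percentages in this field
conventionally round half away from zero.

`classify_cells()` distinguishes three cell states: a computed frequency;
*available* (the EHR can store the element, counts unknown or withheld); and
*not available*. `unknown` availability without counts degrades to
not-available with a warning, and a row claiming *not available* while
reporting entered values violates the export invariant and is rejected.
`build_heatmap()` matches export keys to inventory elements by identifier,
then semantic code, then case-folded label — ambiguous keys are rejected
rather than guessed — completes the grid (a site that reported nothing about
an element is a not-available cell), and orders rows by the number of sites
where the element is present, then mean frequency, then label. The
adverse-event subset is emitted as a separate matrix, since serious-adverse-
event documentation is the sparsest and most policy-relevant slice.

## The synthetic corpus

`generate_studyset()` emulates the *shape* of a multi-company CRF corpus:
23 trials over seven disease areas (3, 3, 2, 1, 3, 1, 10), per-area form
totals of 158, 172, 60, 64, 192, 69 and 371 (1086 forms in all), 22–164
forms per trial, four-digit planned enrollments, and a serious-adverse-event
item block on adverse-event forms. Labels are drawn from a shipped synthetic
vocabulary of 208 elements across the fourteen domains plus administrative
fields reused on every form, and perturbed by a noise model — case changes
(15%), markup wrapping (10%), unit suffixes (15%), and typos (5%, single
edits) — in a fixed draw order so a seed fully determines every artifact,
including the ODM files (whose creation timestamp is a parameter, not the
wall clock). Typos are injected only into labels of eight or more characters
and never into the first four, mirroring the empirical tendency of
misspellings to spare word onsets. Every perturbation is logged with its
recomputed edit distance, and tests verify the log against the ground truth.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: multilingual labels, free-text elements, abbreviation
variants ("Hgb" for hemoglobin) and synonym renamings beyond edit-distance
reach, and vocabulary pairs that are genuinely indistinguishable under the
default thresholds. The shipped vocabulary is deliberately separable (no two
elements match under the default rule), which is what makes exact zero-noise
recovery a meaningful test; real corpora contain near-synonym pairs that
only expert review can arbitrate, which is exactly why the override table
exists. Semantic codes in the vocabulary are syntactically valid
placeholders, not curated terminology.

`generate_exports()` likewise emulates site heterogeneity: frequency-capable
sites with fixed annual patient populations, availability-only sites (data
access policies that forbid patient-level counts), per-domain availability
profiles (demographics nearly always available, SAE fields sparse), and more
than half of sites exporting no SAE documentation at all. When the inventory
contains "Bilirubin, total", the first site reports exactly 9574 values over
31493 patients, so the worked frequency example flows through the real
pipeline.

## Numerical and degenerate-input choices

* Rounding: half-up at one decimal, applied only at the reporting boundary.
* All orderings are total (ties end at lexicographic label or key order), so
  every output is invariant under input permutation; this is property-tested.
* Labels that clean to the empty string are excluded from clustering and
  counted, not dropped silently; empty corpora yield empty tables with a
  zero `Sum` row.
* A single cluster absorbing more than `max_cluster_frac` (default 25%) of
  all items triggers a threshold-review warning on corpora of at least 50
  items — runaway single linkage is the classic failure mode of fuzzy
  matching.
* Seeds are restored after generation (`on.exit`), so the generator does not
  perturb the caller's RNG stream.

## Problem sizes

The test suite and the acceptance script run the full default corpus
(23 trials, 1086 forms, ~13,500 items) through generation, ODM round-trip,
clustering and coverage in a few minutes on one CPU; metric-oracle
equivalence uses 10^4 random string pairs; the brute-force ranking oracle
runs on small corpora (tens of elements), where O(n²) recomputation is
instant. These sizes were chosen to exercise every code path at realistic
scale while keeping a full check run comfortably interactive.

## Worked example

```{r example, eval = FALSE}
res <- run_cde_pipeline(seed = 1, out_dir = "cde_out")
res$corpus_table              # trials and forms per disease area
head(res$inventory)           # ranked, enrollment-weighted inventory
res$comparison$n_identical    # overlap with the prior element list
res$heatmap$matrix[1:5, ]     # coverage cells: "30.4" | "A" | "N/A"
```

## Known limitations

Blocking by Metaphone initial misses fuzzy matches whose first phonemes
differ. The keyword dictionary classifies forms only as well as form names
allow — a form named "Visit 3" is `unassigned` without an override. No
natural-language processing is attempted on free-text labels, no live
terminology services are queried (codes come from static tables), and the
package does not generate SDTM submission datasets: domains here are labels
for organizing an inventory, not dataset specifications.
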