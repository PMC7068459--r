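---
title: "Classifying antihypertensive medications in EHR prescribing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying antihypertensive medications in EHR prescribing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahtnclass)
```

## The classification problem

Prescribing tables in US common data models expose two handles on each
prescription: the raw medication name exactly as it left the source EHR,
and the RxNorm concept unique identifier (RxCUI) assigned during mapping.
A computable phenotype that needs "this patient is on a thiazide and an
ACE inhibitor" must turn one of those handles into an antihypertensive
drug-class assignment, and the two routes fail differently. This package
implements both, the machinery to build and curate the maps behind them,
and the statistics used to compare the results.

Drug classes are represented as a closed label vocabulary (ACE, ARB,
BETA_BLOCKER, CCB, LOOP_DIURETIC, THIAZIDE, ALDOSTERONE_ANTAGONIST,
DIRECT_RENIN_INHIBITOR, ALPHA1_BLOCKER, POTASSIUM_SPARING, VASODILATOR,
CENTRAL_ACTING, OTHER). A combination product carries the `"+"`-joined
label of its component classes (`THIAZIDE+ACE`) together with a
`drug_count` field: phenotypes such as resistant hypertension count
*drugs*, not rows, so a two-ingredient product must contribute 2. By
default `drug_count` is the number of distinct component classes, with a
per-entry override, because a three-ingredient product can exceed its
class count (e.g. two diuretics of the same class plus an ARB).

## Name-based classification

The ingredient is taken to be the first word of the raw name string —
the convention EHR feeds follow — with three refinements, applied in
this order:

1. **Exception patterns** (configurable regular expression → token rules)
   catch strings where the ingredient is not the first word. The shipped
   list is empty: such strings are site-specific, so the mechanism ships
   and the content is user-supplied.
2. **Combination joining**: a leading hyphen- or slash-separated pair
   (`HCTZ-metoprolol 25-50 MG`) is underscore-joined in input order
   (`hctz_metoprolol`). Two bare words are joined only when *both* match
   known single-ingredient tokens of the active map — the guard that
   keeps "Oral Tablet" from being absorbed into a token.
3. **First word** otherwise, lowercased, punctuation stripped. Strings
   with no alphabetic content are `unparseable` (a value, not an error).

Strength/dose tokens (numerals, `%`, MG/ML/MCG, dose-form words; shipped
as config) terminate ingredient scanning.

Because a name-keyed map can only catch a combination product whose
surface ordering it contains, `expand_combination_permutations()`
generates every ordering of every abbreviation choice
(`hctz_metoprolol`, `hydrochlorothiazide_metoprolol`, `metoprolol_hctz`,
`metoprolol_hydrochlorothiazide`) so map construction, not lookup,
absorbs the permutation problem; lookup stays an exact key match, which
keeps classification pure and order-independent.

A name decision that does not merge with the map is *discarded from
antihypertensive analyses but retained in denominators* — statins and
insulin still count in coverage totals.

The name route cannot see dose forms: oral and ophthalmic timolol
normalize to the same token. The shipped configuration therefore treats
timolol as an excluded ingredient for name-keyed maps (conservative:
misses oral timolol rather than admitting glaucoma drops).

## RxCUI-based map construction

Three builders turn terminology relationship exports into candidate maps;
all are deterministic, order-invariant and idempotent, and all emit
sorted keys.

* **ATC** (`build_atc_map`): keep RxCUIs with at least one relation whose
  ATC class name is on the acceptance list; labels are the union of the
  conferred classes. ATC models the class only, so every dose form of an
  accepted ingredient rides in — screening is a separate, downstream step.
* **MED-RT** (`build_medrt_map`): two-step filter — (1) RxCUIs with a
  `may_treat` relation denoting hypertension, then (2) of those, RxCUIs
  with at least one accepted `has_MoA` relation. Step 2 never adds keys.
  The string denoting hypertension is configuration (`"hypertension"`,
  case-insensitive exact match) because relationship exports vary.
* **Drug ontology** (`build_dron_map`): keys are the RxCUIs on the
  hypertension-indication list; classes are the union of the
  mechanism-of-action lists containing each key, plus manual class
  additions (the hand-curation step for mechanisms the ontology does not
  represent). Indication RxCUIs with no mechanism are excluded from the
  map and returned as an `unassigned` review report rather than silently
  kept or dropped. Entries with ingredient-level term types (IN, MIN,
  PIN) are excluded by default — too unspecific for record-level
  classification — with the policy configurable.

Before any builder runs, `remove_short_rxcuis()` drops relations whose
RxCUI has fewer than 4 digits: short numerics in batch output are query
artifacts, not drug identifiers. The RxCUI is stored as a string
throughout, never an integer, so the length test is literal and leading
zeros survive.

The ATC and MED-RT acceptance lists ship as editable YAML seeded with the
standard antihypertensive class names; they are configuration, not an
authoritative reproduction of any external list. Curated review then goes
through `screen_dose_forms_and_indications()` (flags ophthalmic/topical
display names and excluded ingredients; report only) and
`reconcile_maps()` (applies additions and exclusions, bumps the version
tag, and returns an audit of every key touched). A reconciliation
addition that conflicts with an existing entry's classes is an error —
silent overwrites are how curated maps rot.

Retired and remapped RxCUIs are deliberately *map content*: longitudinal
extracts contain them, so a curated map keeps them (with a status column)
and lookup still matches, reporting the status. How an upstream curator
determines retirement is out of scope; status is accepted as input, not
computed.

## Comparison and application statistics

* `coverage(mapped, total)` — percent of unique terms (or records)
  mapped, rounded **half-up** to 2 decimal places. Half-up is implemented
  as `floor(100x + 0.5 + 1e-9)/100`; the epsilon absorbs IEEE
  representation error and is far below the 2-dp resolution.
* `pairwise_compare(a, b)` — exact set algebra with sorted key output;
  the overlap and unique counts partition each input by construction.
* `categorize_differences()` — explains keys unique to one side by the
  first matching reason in fixed precedence: term type → dose form → BPH
  indication → combination → retired → uncategorized. The precedence is a
  design choice (the categories are described in the field but not
  ordered); term type leads because an IN-level key is uninformative about
  dose form, and `uncategorized` is last so every key lands somewhere and
  counts always sum to the input size.
* `class_frequency_table()` — counts each matched record exactly once,
  under its possibly-combination label. The alternative (once per
  component class) would break the "counts sum to total mapped"
  invariant; combination rows as their own labels match how per-class
  prescribing tables are conventionally reported.
* `select_htn_cohort()` — adults (≥ 18) with ≥ 1 outpatient encounter
  carrying ICD-9 401.x (dot optional, any fourth digit: `401.9` and
  `4019` both qualify — extracts mix dialects) or ICD-10 `I10` exactly
  (subcodes such as `I10.9` or `I11` do not qualify).

## The synthetic world

`generate_prescribing()` emulates a hypertensive cohort's prescribing
table. Its defaults are chosen once, from published prescribing
statistics where available, and are not tuned:

| parameter | default | basis |
|---|---|---|
| `antihypertensive_fraction` | 0.15 | share of prescriptions mapping to antihypertensives in large CDM extracts |
| `class_mixture` | published per-class shares, renormalized | the 12 classes at ≥ 1% of antihypertensive prescriptions (including the thiazide/ACE and thiazide/ARB combinations) cover ~97% of mapped records; renormalizing over them is the closest stated world |
| `confounder_fraction` | 0.02 | ophthalmic/topical/BPH products are common but a small share of all orders |
| `retired_fraction` | 0.05 | a multi-year extract retains a visible minority of retired identifiers |
| `name_noise` | 0.2 | EHR name strings vary in case, separator and abbreviation, but most rows are clean |
| `htn_patient_fraction` | 0.6 | a diagnosis extract drawn around an HTN cohort still contains non-qualifying patients |

Antihypertensive records draw a class from the mixture and an entry from
the demonstration map pair, emitting a *consistent* raw name and RxCUI —
so on clean synthetic data the two classification routes must agree
exactly, which is the ground-truth recovery test. Confounders use
dose-form-bearing names with RxCUIs absent from the curated maps;
ingredients that exist mainly as confounders (timolol, betaxolol,
minoxidil, tamsulosin, alfuzosin, silodosin) are deliberately absent from
the curated demo maps so that *no* confounder record is classifiable by
them, while the generated relation export misclassifies all of them the
way real batch output does. The relation export also plants exact counts
of short RxCUIs and IN-term-type rows so builder filters are checkable to
the row.

What the generator does **not** emulate: misspelled or truncated name
strings, sig text, NDC-level packaging, dose-strength mismatches between
name and RxCUI, temporal structure (refills, possession windows), and
genuinely ambiguous products (oral minoxidil as a true antihypertensive
alongside its topical confounder). A green end-to-end test therefore
establishes that the machinery is correct on well-formed data with known
answers — not that any particular real-world coverage number will be
reproduced, which depends on the curated map and the source system.

Determinism: all randomness flows through R's default Mersenne-Twister
generator seeded from `config$seed` (the diagnosis generator offsets the
seed by 1 so the two tables are independently reproducible); identical
configurations yield identical output across runs and platforms.

## Degenerate inputs and tie-breaks

* Empty maps read, write and compare cleanly (header-only CSV).
* Duplicate map rows with identical class payloads deduplicate silently;
  conflicting payloads are a validation error naming the key.
* Missing RxCUI cells (empty, `NA`, `NULL`) become missing values;
  non-numeric RxCUI cells are treated as missing with a warning rather
  than dropping the row (row conservation outranks cell hygiene).
* Unparseable order dates fail with the row number by default;
  `on_bad_date = "skip"` drops those rows with a warning.
* When several relation rows supply display names for one RxCUI, the
  first non-missing name in key-sorted row order wins (deterministic
  regardless of input order).
* `coverage(., 0)` is a usage error, not `NaN`.

## Known limitations

* Name-based classification is blind to dose forms and to ingredient
  synonyms absent from the synonym table; the shipped exception and
  synonym lists are minimal by design.
* No live terminology service client: all terminology input is file-based
  batch output. No remap-following for retired RxCUIs.
* The shipped acceptance lists cover the standard antihypertensive
  classes but are configuration to be audited per project, not a
  validated value set.
* Diagnosis/prescription temporal linkage is out of scope, as is any
  downstream phenotype logic (e.g. resistant-hypertension drug counting).
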