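# ahtnclass

Antihypertensive medication classification for EHR prescribing data.

## The problem

Hypertension-related computable phenotypes — most prominently resistant
hypertension, classically defined by the number of *distinct
antihypertensive drug classes* a patient requires — depend on correctly
assigning every prescription record to an antihypertensive drug class.
That assignment is harder than it looks: prescribing tables in common data
models (PCORnet CDM and kin) carry two usable handles, the free-text raw
medication name and the RxNorm concept unique identifier (RxCUI), and
standard terminologies misclassify in characteristic ways. ATC models only
the drug class, so ophthalmic timolol (a glaucoma drug) arrives as a
"beta blocking agent"; MED-RT hangs the `may_treat` hypertension relation
on the ingredient, sweeping in topical minoxidil (hair loss) and
BPH-indicated alpha-blockers (tamsulosin, alfuzosin, silodosin);
combination products need every surface permutation of their name
(HCTZ-metoprolol, metoprolol-hydrochlorothiazide, ...) and a correct
ingredient count; and longitudinal extracts contain RxCUIs that later
RxNorm releases retired or remapped.

`ahtnclass` is the engine for working with this problem end to end. It is
aimed at clinical informaticians building medication criteria for EHR
phenotypes. It:

* **builds** candidate RxCUI-keyed classification maps from terminology
  relationship exports — ATC class membership, the MED-RT two-step filter
  (`may_treat` hypertension ∩ accepted `has_MoA`), and drug-ontology
  indication ∩ mechanism-of-action RxCUI lists — with the `<4-digit`
  RxCUI removal and the IN/MIN/PIN term-type policy applied;
* **classifies** prescribing records by raw name (first-word ingredient
  extraction, underscore-joined combinations, exception lists) or by exact
  RxCUI lookup (retired/remapped keys still match, with status reported);
* **compares** competing maps: term and prescription coverage
  (`mapped / total`, 2 dp), pairwise overlap/unique key sets, and
  difference categorization (term type → dose form → BPH indication →
  combination → retired);
* **screens** map entries for ophthalmic/topical dose forms and
  BPH-indicated ingredients, and **reconciles** curated additions and
  exclusions into versioned maps with an audit trail;
* **selects** hypertension cohorts (adults ≥ 18 with ≥ 1 outpatient
  ICD-9 401.x or ICD-10 I10 diagnosis) and tabulates per-class prescribing
  frequencies;
* **simulates** a hypertensive cohort's prescribing table with ground
  truth — combination products, confounder dose forms, retired RxCUIs,
  non-antihypertensive noise — so every step is testable offline.

Reference excerpts of a curated name-keyed map (ACE inhibitors, brand and
generic), an RxCUI-keyed map, known misclassified products, and published
per-class prescribing shares ship as checksum-verified fixtures
(`load_fixture()`).

## Worked example

```r
library(ahtnclass)

# classify raw names against the packaged name-map excerpt
map <- load_fixture("table2")
classify_name("Lotensin 20 MG Oral Tablet", map)
#> <class_decision matched key=lotensin classes=ACE drug_count=1 status=active>
classify_name("Atorvastatin 40 MG Oral Tablet", map)
#> <class_decision unmatched (absent)>      # statins are discarded

coverage(729, 13627)
#> coverage: 729 / 13627 (5.35%)            # terms mapped / unique RxCUIs

# end to end on synthetic data with known ground truth
cfg  <- synthetic_config(seed = 42, n_prescriptions = 10000)
maps <- build_demo_maps(cfg$retired_fraction)
gen  <- generate_prescribing(cfg, maps)
decisions <- classify_records(gen$records, maps$name_map, maps$rxcui_map,
                              mode = "both")
prescription_coverage(decisions, "rxcui")
#> coverage: 1585 / 10000 (15.85%)          # ~15% of records are antihypertensive

head(class_frequency_table(decisions, "rxcui")$rows, 5)
#>    class_label count percent
#> 1          ACE   354   22.33
#> 2 BETA_BLOCKER   303   19.12
#> 3          CCB   273   17.22
#> 4     THIAZIDE   175   11.04
#> 5          ARB   135    8.52

# terminology-derived map vs curated map: the confounders surface as
# keys unique to the ATC side and are categorized by reason
rel  <- generate_relation_export(cfg, maps)
kept <- remove_short_rxcuis(rel)
atc  <- build_atc_map(kept$kept[kept$kept$rela_source == "ATC", ])
cmp  <- pairwise_compare(maps$rxcui_map, atc)
cmp
#> comparison: overlap 86 | unique to A 17 | unique to B 12
categorize_differences(cmp$unique_b_keys,
                       setNames(atc$entries$display_name, atc$entries$key),
                       setNames(atc$entries$term_type,   atc$entries$key)
                      )$category_counts
#>      term_type      dose_form bph_indication    combination        retired
#>              4              5              3              0              0
#>  uncategorized
#>              0
```

The 17 keys unique to the curated map are its retired RxCUIs plus the
reference excerpt entries (terminology exports no longer carry retired
identifiers); the 12 unique to the ATC map decompose exactly into the
planted ingredient-level term types, ophthalmic/topical products, and
BPH-indicated alpha-blockers.

## Command line

A thin CLI over the same functions lives at `inst/cli/ahtnclass.R`:

```sh
Rscript inst/cli/ahtnclass.R simulate  --seed 9 --dir sim --n 5000
Rscript inst/cli/ahtnclass.R build-map --source atc --relations sim/relations.tsv --out atc_map.csv
Rscript inst/cli/ahtnclass.R classify  --prescribing sim/prescribing.csv \
        --name-map sim/name_map.csv --rxcui-map sim/rxcui_map.csv --out classified.csv
Rscript inst/cli/ahtnclass.R compare   --map-a sim/rxcui_map.csv --map-b atc_map.csv --out cmp.json
Rscript inst/cli/ahtnclass.R apply     --prescribing sim/prescribing.csv \
        --rxcui-map sim/rxcui_map.csv --out coverage.json --freq freq.csv
Rscript inst/cli/ahtnclass.R cohort    --diagnoses sim/diagnoses.csv --out cohort.txt
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package — synthetic generation at n = 50,000, map building from
the relation export, curated-vs-terminology comparison and
categorization, two-method record classification, coverage, frequency
tables, and cohort selection — and writes its JSON summary to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Further reading

The methods vignette (`vignettes/antihypertensive-classification.Rmd`)
documents the classification rules, the map-construction filters, the
synthetic-data model and its limitations, and the numerical conventions
(rounding, tie-breaks, degenerate inputs).
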