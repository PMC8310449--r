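# cpmscreen

Prescription-safety screening for Chinese patent medicines (CPM), built on a
typed drug/disease/symptom knowledge graph.

CPM products are manufactured herbal formulations composed of multiple
ingredients, and their co-prescription carries risks that a conventional
drug-interaction table does not capture: the traditional *eighteen
contraindications* (mutually antagonistic herb pairs) and *nineteen fears*
(directed herb-pair taboos) act at the **ingredient** level, so two finished
products conflict whenever any cross-product pair of their ingredients is
taboo. Hidden duplication ("repeated efficacy medication") arises when
distinct products share active ingredients; dosing limits depend on the
population (children, the elderly, pregnancy, lactation, hepatic/renal
impairment); and under the principle of *syndrome differentiation and
treatment* a product should match the patient's diagnosed TCM syndrome
pattern, not only the disease name.

`cpmscreen` is a screening engine for pharmacists and pharmacovigilance
developers that makes these rules executable:

- **`kg_*`** — a typed knowledge graph as rule base: entity nodes
  (`cpm_drug`, `ingredient`, `disease`, `symptom`, `syndrome`,
  `population_group`), relation triples with per-relation endpoint-type
  signatures (`contains_ingredient`, `incompatible_with`, `fears`,
  `indicated_for_disease`, `indicated_for_syndrome`, `has_symptom`, ...),
  and population-specific dosage rules. JSON Lines interchange with full
  validation.
- **`check_*` / `review_record()`** — five checks per medical record:
  combined-use incompatibility, repeated-efficacy medication, symptomatic
  administration, dosage, and syndrome differentiation, aggregated into a
  review report with graph-path evidence per alert.
- **`segment_text()` / `train_tagger()` / `tag_text()` /
  `link_mentions()`** — a text front end for records that lack structured
  fields: maximum-probability word segmentation over a domain lexicon
  (dynamic programming on the position lattice, maximizing
  `sum(log(freq(w)/total))`), a sequence tagger over BIO tags
  (averaged structured perceptron with Viterbi decoding; pluggable backend),
  and entity linking by exact name, alias, or normalized edit similarity.
- **`evaluate_ner()`** — span-exact precision/recall/F1 per entity class
  (DIS/SYM/ZCY) with macro and micro averages.
- **`gen_kg()` / `gen_bio_corpus()` / `gen_records()`** — deterministic
  synthetic fixtures with planted, bookkept violations, so the whole
  pipeline is testable without clinical data.

## Worked example

```r
library(cpmscreen)

kg <- kg_new()
kg <- kg_add_entity(kg, "qingre",   "qingre granule",   "cpm_drug")
kg <- kg_add_entity(kg, "sanhuang", "sanhuang tablet",  "cpm_drug")
kg <- kg_add_entity(kg, "gancao",   "licorice root",    "ingredient")
kg <- kg_add_entity(kg, "yuanhua",  "genkwa flower",    "ingredient")
kg <- kg_add_entity(kg, "huangqin", "scutellaria root", "ingredient")
kg <- kg_add_entity(kg, "fever",    "wind heat fever",  "disease")
kg <- kg_add_triple(kg, "qingre",   "contains_ingredient", "gancao")
kg <- kg_add_triple(kg, "qingre",   "contains_ingredient", "huangqin")
kg <- kg_add_triple(kg, "sanhuang", "contains_ingredient", "yuanhua")
kg <- kg_add_triple(kg, "gancao",   "incompatible_with",   "yuanhua")
kg <- kg_add_triple(kg, "qingre",   "indicated_for_disease", "fever")
kg <- kg_add_triple(kg, "sanhuang", "indicated_for_disease", "fever")
kg <- kg_add_dosage_rule(kg, "qingre", 3, 9, unit = "g")

rec <- medical_record(
  "r001",
  items = list(prescription_item("qingre granule",  6, 3),
               prescription_item("sanhuang tablet", 2, 2)),
  diagnoses = "fever",
  patient   = patient_profile(35))

review_record(rec, kg)
```

```
Review report for record r001: 4 alert(s) [info=2, warning=0, critical=2]
  combined_use       flagged
  repeated_efficacy  pass
  symptomatic        pass
  dosage             flagged
  syndrome           pass
  [combined_use/critical] incompatible ingredient combination between qingre and sanhuang (gancao incompatible_with yuanhua) (drugs: qingre, sanhuang)
  [dosage/critical] daily dose 18 g of drug qingre outside rule [3, 9] g (population default_adult) (drugs: qingre)
  [dosage/info] no dosage rule for drug sanhuang; not evaluated (drugs: sanhuang)
  [syndrome/info] no (resolvable) syndrome recorded; syndrome differentiation not evaluated (drugs: )
```

The two critical alerts read: the pair (qingre granule, sanhuang tablet) is
an ingredient-level taboo combination — licorice root is incompatible with
genkwa flower — and 6 g three times daily is 18 g/day, above the 3–9 g/day
rule for the default adult population. Both prescribed products are
indicated for the recorded diagnosis, so the symptomatic category passes;
info alerts mark data the rule base cannot evaluate rather than hiding it.

## Command line

A thin dispatcher is installed at `inst/cli/cpmscreen.R`:

```sh
Rscript inst/cli/cpmscreen.R kg    validate --graph kg.jsonl
Rscript inst/cli/cpmscreen.R tag   --model m.json --lexicon lex.tsv --records r.jsonl --output tags.jsonl
Rscript inst/cli/cpmscreen.R check --graph kg.jsonl --records r.jsonl --output reports.json
Rscript inst/cli/cpmscreen.R eval  --gold gold.jsonl --predicted tags.jsonl
```

Exit codes: 0 clean, 1 input error, 2 critical alerts found (so a batch run
can gate a pipeline). A YAML config file (`--config`) mirrors the flags;
flags win.

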