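---
title: "Knowledge-graph screening of CPM prescriptions: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph screening of CPM prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmscreen)
```

## The screening model

`cpmscreen` treats prescription review as query evaluation over a typed
knowledge graph. Nodes are entities of six types — CPM products,
ingredients, diseases, symptoms, TCM syndromes, and population groups —
and edges are relation triples whose endpoint types are fixed by a
signature table (`contains_ingredient` connects a product to an
ingredient, `has_symptom` a disease to a symptom, and so on). The graph,
together with population-specific dosage rules, is the rule base; a
medical record is the monitored object; the output is a review report
with one verdict per check category and evidence triples per alert.

### Conflict semantics

The traditional taboo lists act between herbal ingredients, not finished
products: the *eighteen contraindications* are mutually antagonistic
pairs, the *nineteen fears* are directed pairs ("A fears B"). Finished
products are therefore screened through their ingredient sets: products
$A$ and $B$ conflict iff

$$\exists\, x \in \mathrm{ing}(A),\; y \in \mathrm{ing}(B):\;
  (x,y) \in \text{incompatible} \cup \text{fears}.$$

Three consequences of this definition are deliberate:

- `incompatible_with` is stored once per unordered pair and queried
  symmetrically; `fears` keeps its traditional direction in storage and
  evidence but is treated symmetrically by the safety check — a safety
  verdict should not depend on which way an edge was entered.
- An $n$-drug prescription is screened over all $n(n-1)/2$ unordered
  pairs; multi-drug monitoring is strictly the pairwise closure at the
  ingredient level, with no emergent three-way rules (none are defined in
  the source tradition).
- An ingredient may belong to both products of a pair; both orientations
  of each taboo edge are examined so such shared endpoints cannot mask a
  conflict.

### The five checks and the severity ladder

| category            | trigger                                              | severity |
|---------------------|------------------------------------------------------|----------|
| combined_use        | non-empty ingredient-conflict set for a drug pair    | critical |
| repeated_efficacy   | same product twice                                   | critical |
| repeated_efficacy   | distinct products sharing ≥ `k_shared` ingredients   | warning  |
| symptomatic         | drug with indication data, none among the candidates | warning  |
| dosage              | daily dose outside the applicable rule (inclusive)   | critical |
| dosage              | unit mismatch between item and rule                  | warning  |
| syndrome            | drug's indicated syndromes exclude the recorded one  | warning  |
| any                 | missing/unlinkable data                              | info     |

The ladder itself is a package convention: incompatibility, duplication,
and dose range are treated as hard stops; indication and syndrome
mismatches as review prompts. Drugs that cannot be linked to the graph
never fail a prescription silently — they always surface as info alerts.
A category's verdict is `flagged` iff it contains at least one alert of
severity warning or above, and every report carries all five categories.

The symptomatic check builds its candidate disease set from the recorded
diagnoses when present; otherwise it infers candidates from recorded
symptoms, requiring at least `min_overlap` (default 2) shared symptoms
per disease. One shared symptom is weak evidence when a disease maps to
dozens of symptoms, so with a single recorded symptom the category
degrades to info rather than guessing.

Dosage rules are resolved by fixed population priority — pregnant >
lactating > child > elderly > hepatic impairment > renal impairment >
default adult — which makes lookup deterministic when several groups
apply; the derived groups use configurable age cutoffs (child < 14 years,
elderly ≥ 65 years — the groups are traditional, the cutoffs are package
conventions). Bounds are inclusive: a daily dose exactly at the maximum
passes.

Toxicity is modelled only implicitly through dosage rules; no separate
"toxic ingredient" relation is invented, since the source material names
the concern but defines no rule for it.

## The text front end

Records without structured fields are populated from their two free-text
sections (course record, discharge summary):

1. **Tokenization** — characters for ideographic text, whitespace tokens
   otherwise; everything downstream is script-independent.
2. **Segmentation** — the maximum-probability path: over all ways to cut
   the token sequence into lexicon words, maximize
   $\sum_w \log(\mathrm{freq}(w)/\mathrm{total})$, computed by dynamic
   programming on the position lattice. A single out-of-lexicon token is
   usable with a smoothed pseudo-frequency of 0.5 (below any genuine
   entry, so lexicon words are preferred but every input has a path).
   Ties prefer fewer words, then the lexicographically smaller word list
   — determinism is part of the contract, and the test suite checks the
   DP against exhaustive enumeration of all $2^{n-1}$ segmentations on
   short strings.
3. **Tagging** — BIO tags over three mention classes (DIS disease, SYM
   symptom, ZCY product). The default backend is an averaged structured
   perceptron: per-token features (token identity, neighbours, lexicon
   category of the covering segmented word, B/I position within that
   word) against each tag, first-order transition weights, Viterbi
   decoding. Tokens seen once in training are masked to `<unk>`, and each
   sequence is additionally trained with *all* identity features masked,
   so unfamiliar surface forms are tagged from their lexicon category
   rather than memorized identities. Training is deterministic given
   corpus and seed. The backend contract is pluggable, so a pretrained
   contextual model can replace the perceptron without touching the rest
   of the pipeline; the default is chosen to run on a desk machine with
   no GPU and no pretrained weights.
4. **Decoding and repair** — maximal `B-X (I-X)*` runs become mentions;
   an orphan `I-X` opens a new span (the conventional repair).
5. **Linking** — exact canonical name, then alias, then fuzzy match by
   normalized edit similarity $1 - d_{\mathrm{lev}}/\max(|a|,|b|)$ with
   threshold 0.85 (a configuration knob), restricted to nodes of the
   etype matching the label. Unlinked mentions are a valid outcome.

Evaluation is span-exact (strict): a predicted mention counts iff start,
end, and label all match. The "Average" column of a per-class results
table is the unweighted macro mean; micro averages from pooled counts are
reported alongside. A class absent from both gold and prediction scores
100 (vacuous agreement), so a perfect prediction is 100 everywhere; any
other zero denominator scores 0.

## Synthetic fixtures: what they emulate and what they do not

All tests run on generated data; no pharmacopoeia or hospital corpus is
shipped. The generators emulate the *shape* of the real problem:

- `gen_kg()` — drugs with 2–8 ingredients, taboo edges planted over
  ingredient pairs at `conflict_rate` (half symmetric incompatibility,
  half directed fears), diseases with 3–12 symptoms, 1–3 indicated
  diseases and 0–2 syndromes per drug, a default dosage rule per drug
  and child-specific rules for some. These ranges are chosen as
  realistic magnitudes for manufactured formulations and desk-scale rule
  bases; the manifest records every planted fact, including the induced
  drug-level conflict and shared-ingredient pairs.
- `gen_bio_corpus()` — template sentences in a whitespace pseudo-language
  embedding graph entity names between filler tokens. At
  `ambiguity_rate`, an entity's first token is swapped for a token that
  also occurs as filler, which destroys separability by token identity —
  at rate 0 the corpus is separable by construction and a competent
  tagger should reach F1 = 100 on held-out sentences from the same
  generator.
- `gen_records()` — each record samples up to five drugs whose
  *non-planted* part is clean by construction: pairwise non-conflicting,
  non-sharing drugs; one recorded diagnosis per drug drawn from its
  indications; a syndrome common to the drugs' syndrome indications (or
  none); doses inside the population-applicable rule. Violations are then
  planted per category with the requested probability (at most one per
  category per record, to keep the gold bookkeeping unambiguous) and
  logged. Clean-by-construction is what makes "100% precision and recall
  against gold" a well-defined target rather than a tuning exercise.

What passing these tests shows: the engine implements its stated
semantics exactly (oracle equivalence), recovers planted violations
perfectly on structured records, and degrades gracefully on the text
path. What it does not show: performance on real clinical text — the
pseudo-language has no orthographic variation, no abbreviations, no
negation, and its lexicon coincides with the graph vocabulary; real
records are strictly harder, which is why the tagger backend is
pluggable.

Test and acceptance problem sizes (graphs of 12–20 drugs, corpora of
tens of sentences, batches of 170–200 records across three seeds) are
the package's chosen desk-scale study conditions; the generators accept
larger parameters unchanged.

## Numerical and degenerate-input choices

- Segmentation tie-breaks and the 0.5 OOV pseudo-frequency are fixed
  (above); score comparisons use a `1e-9` tolerance so that DP and
  enumeration agree in floating point.
- Viterbi ties resolve to the earliest label index — deterministic
  decoding.
- Unknown symptom ids in disease inference are skipped with a warning
  (tagger output may be unlinkable); unknown drugs become info alerts.
- Duplicate triples are ignored idempotently, including the reversed
  form of symmetric incompatibility edges.
- Empty text tokenizes to an empty sequence; empty mention sets and
  empty record batches are valid everywhere.
- Graph loading validates every record and reports *all* failures with
  line numbers, rather than stopping at the first.

## Known limitations

- No drug–Western-medicine interaction rules, no hepatic/renal dose
  adjustment formulas (those populations are handled as rule-selecting
  flags only), no expert-review workflow, no graph-database server or
  RDF/OWL reasoning.
- The "evidence-based treatment" and "syndrome differentiation" monitoring
  notions are treated as a single category.
- The perceptron backend is a desk-scale baseline, not a substitute for a
  pretrained contextual tagger on real clinical text.
- Fuzzy linking is edit-distance based; it will not bridge synonyms that
  share no surface form — those belong in the alias list.
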