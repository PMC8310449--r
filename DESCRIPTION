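Package: cpmscreen
Title: Prescription-Safety Screening for Chinese Patent Medicines via a Typed Knowledge Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A prescription-safety monitoring engine for Chinese patent
    medicines (CPM). A typed drug/disease/symptom knowledge graph serves as
    the rule base; a lexicon-driven segmenter and a sequence tagger extract
    drug, disease, and symptom mentions from medical-record text; a rule
    engine runs five checks (combined-use incompatibility, repeated-efficacy
    medication, symptomatic administration, dosage, and syndrome
    differentiation) and emits structured alert reports. Includes
    deterministic synthetic-fixture generators with planted, bookkept
    violations, span-exact NER evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
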