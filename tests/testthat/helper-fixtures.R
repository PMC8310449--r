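# Hand-built micro knowledge graph used across tests.
#
#   drugs:  da {ix, iw}   db {iy}   dc {iw}   dd {iz}
#   taboo:  ix incompatible_with iy   ;   iz fears iw
#   => drug conflicts: (da,db) via ix~iy ; (da,dd) and (dc,dd) via iz~iw
#   => shared ingredients: (da,dc) share iw
#   diseases: dz1 {s1,s2,s3}, dz2 {s3,s4}
#   indications: da->dz1 (syndrome sn1), db->dz2, dd->dz2 (syndrome sn2),
#                dc has no indication edges
#   dosage: da default [3,9] g + child [1.5,4.5] g ; db [2,4] g ;
#           dd [1,2] g ; dc none
toy_kg <- function() {
  kg <- kg_new()
  kg <- kg_add_entity(kg, "da", "drug alpha", "cpm_drug", aliases = "alphapill")
  kg <- kg_add_entity(kg, "db", "drug beta", "cpm_drug")
  kg <- kg_add_entity(kg, "dc", "drug gamma", "cpm_drug")
  kg <- kg_add_entity(kg, "dd", "drug delta", "cpm_drug")
  for (i in c("ix", "iy", "iz", "iw"))
    kg <- kg_add_entity(kg, i, paste0("herb ", i), "ingredient")
  kg <- kg_add_entity(kg, "dz1", "cold disorder", "disease", aliases = "common cold")
  kg <- kg_add_entity(kg, "dz2", "cough disorder", "disease")
  for (s in paste0("s", 1:4))
    kg <- kg_add_entity(kg, s, paste0("sign ", s), "symptom")
  kg <- kg_add_entity(kg, "sn1", "wind cold pattern", "syndrome")
  kg <- kg_add_entity(kg, "sn2", "heat pattern", "syndrome")
  kg <- kg_add_entity(kg, "child", "children", "population_group")
  kg <- kg_add_triple(kg, "da", "contains_ingredient", "ix")
  kg <- kg_add_triple(kg, "da", "contains_ingredient", "iw")
  kg <- kg_add_triple(kg, "db", "contains_ingredient", "iy")
  kg <- kg_add_triple(kg, "dc", "contains_ingredient", "iw")
  kg <- kg_add_triple(kg, "dd", "contains_ingredient", "iz")
  kg <- kg_add_triple(kg, "ix", "incompatible_with", "iy")
  kg <- kg_add_triple(kg, "iz", "fears", "iw")
  kg <- kg_add_triple(kg, "dz1", "has_symptom", "s1")
  kg <- kg_add_triple(kg, "dz1", "has_symptom", "s2")
  kg <- kg_add_triple(kg, "dz1", "has_symptom", "s3")
  kg <- kg_add_triple(kg, "dz2", "has_symptom", "s3")
  kg <- kg_add_triple(kg, "dz2", "has_symptom", "s4")
  kg <- kg_add_triple(kg, "da", "indicated_for_disease", "dz1")
  kg <- kg_add_triple(kg, "da", "indicated_for_syndrome", "sn1")
  kg <- kg_add_triple(kg, "db", "indicated_for_disease", "dz2")
  kg <- kg_add_triple(kg, "dd", "indicated_for_disease", "dz2")
  kg <- kg_add_triple(kg, "dd", "indicated_for_syndrome", "sn2")
  kg <- kg_add_dosage_rule(kg, "da", 3, 9, unit = "g")
  kg <- kg_add_dosage_rule(kg, "da", 1.5, 4.5, unit = "g", population = "child")
  kg <- kg_add_dosage_rule(kg, "db", 2, 4, unit = "g")
  kg <- kg_add_dosage_rule(kg, "dd", 1, 2, unit = "g")
  kg
}

toy_lexicon <- function() {
  build_lexicon(c("aa", "bb", "aa bb", "cc", "bb cc"),
                c(5, 8, 20, 3, 9), "general")
}

item <- function(drug, single = 2, times = 2, unit = "g")
  prescription_item(drug, single, times, unit)
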