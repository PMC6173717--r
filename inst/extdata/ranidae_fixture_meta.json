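{
  "name": "ranidae_sex_chromosome_turnovers",
  "version": "1.0",
  "description": "Sex-chromosome turnover history across 28 Ranidae species: 13 transition events (8 interspecific, 3 intraspecific, 2 homologous XY-to-ZW), per-tip state probabilities over the five chromosomes observed as sex-linked (Chr01, Chr02, Chr03, Chr05, Chr08), and per-chromosome species-usage totals.",
  "caveats": [
    "The two root-region events (e01, e02) have unknown chromosome identities; their placement is the most parsimonious of six possible hypotheses for the ambiguous root region.",
    "Species names for three literature-only tips are reconstructed placeholders (Rana_amurensis, Rana_dybowskii, Rana_sylvatica); which literature species carry Chr01 is assigned so that per-chromosome species totals match the usage table.",
    "The species-usage table counts species per chromosome (a species with intraspecific polymorphism counts for each chromosome it uses); the Chr02 usage of Rana temporaria is a within-species polymorphism, not one of the 13 transition events."
  ],
  "checksums": {
    "ranidae_turnover_events.tsv": "5d8f18fa6f36f666a6fe9fd28eeb7d9f",
    "ranidae_chromosome_usage.tsv": "2d65b39ec1153575d42302aee7c5ec58",
    "ranidae_tip_states.tsv": "40723165939d05ee48b6f697c25e1106"
  }
}
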