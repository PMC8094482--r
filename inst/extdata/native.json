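{
  "name": "native",
  "metabolites": [
    {
      "id": "glc",
      "name": "glucose",
      "role": "exchange",
      "formula": "C6H12O6"
    },
    {
      "id": "g6p",
      "name": "glucose 6-phosphate",
      "role": "internal",
      "formula": "C6H12O6"
    },
    {
      "id": "f6p",
      "name": "fructose 6-phosphate",
      "role": "internal",
      "formula": "C6H12O6"
    },
    {
      "id": "fbp",
      "name": "fructose 1,6-bisphosphate",
      "role": "internal",
      "formula": "C6H12O6"
    },
    {
      "id": "dhap",
      "name": "dihydroxyacetone phosphate",
      "role": "internal",
      "formula": "C3H6O3"
    },
    {
      "id": "ga3p",
      "name": "glyceraldehyde 3-phosphate",
      "role": "internal",
      "formula": "C3H6O3"
    },
    {
      "id": "pyr",
      "name": "pyruvate",
      "role": "internal",
      "formula": "C3H4O3"
    },
    {
      "id": "p5p",
      "name": "pentose 5-phosphate pool",
      "role": "internal",
      "formula": "C5H10O5"
    },
    {
      "id": "acp",
      "name": "acetyl phosphate",
      "role": "internal",
      "formula": "C2H4O2"
    },
    {
      "id": "accoa",
      "name": "acetyl-CoA (acetyl moiety)",
      "role": "internal",
      "formula": "C2H3O"
    },
    {
      "id": "gly3p",
      "name": "glycerol 3-phosphate",
      "role": "internal",
      "formula": "C3H8O3"
    },
    {
      "id": "tag",
      "name": "triacylglycerol",
      "role": "exchange",
      "formula": "C57H104O6"
    },
    {
      "id": "co2",
      "name": "carbon dioxide",
      "role": "exchange",
      "formula": "CO2"
    },
    {
      "id": "nadph",
      "name": "NADPH (pair member)",
      "role": "cofactor_pair_member"
    },
    {
      "id": "nadh",
      "name": "NADH (pair member)",
      "role": "cofactor_pair_member"
    },
    {
      "id": "atp",
      "name": "ATP (pair member)",
      "role": "cofactor_pair_member"
    }
  ],
  "reactions": [
    {
      "id": "GLK",
      "enzyme": "GLK",
      "stoich": {
        "glc": "-1",
        "atp": "-1",
        "g6p": "1"
      },
      "reversible": false,
      "tags": [
        "native"
      ]
    },
    {
      "id": "PGI",
      "enzyme": "PGI",
      "stoich": {
        "g6p": "-1",
        "f6p": "1"
      },
      "reversible": true,
      "tags": [
        "native"
      ]
    },
    {
      "id": "PFK",
      "enzyme": "PFK",
      "stoich": {
        "f6p": "-1",
        "atp": "-1",
        "fbp": "1"
      },
      "reversible": false,
      "tags": [
        "native"
      ]
    },
    {
      "id": "FBA",
      "enzyme": "FBA",
      "stoich": {
        "fbp": "-1",
        "dhap": "1",
        "ga3p": "1"
      },
      "reversible": true,
      "tags": [
        "native"
      ]
    },
    {
      "id": "TPI",
      "enzyme": "TPI",
      "stoich": {
        "dhap": "-1",
        "ga3p": "1"
      },
      "reversible": true,
      "tags": [
        "native"
      ]
    },
    {
      "id": "FBPASE",
      "enzyme": "FBP",
      "stoich": {
        "fbp": "-1",
        "f6p": "1"
      },
      "reversible": false,
      "tags": [
        "native"
      ]
    },
    {
      "id": "GLYC_LOWER",
      "enzyme": "PYK",
      "stoich": {
        "ga3p": "-1",
        "pyr": "1",
        "nadh": "1",
        "atp": "2"
      },
      "reversible": false,
      "tags": [
        "native",
        "lumped"
      ]
    },
    {
      "id": "PDH_CIT_ACL",
      "enzyme": "ACL",
      "stoich": {
        "pyr": "-1",
        "atp": "-1",
        "accoa": "1",
        "co2": "1",
        "nadh": "1"
      },
      "reversible": false,
      "tags": [
        "native",
        "lumped"
      ]
    },
    {
      "id": "OXPPP",
      "enzyme": "ZWF",
      "stoich": {
        "g6p": "-1",
        "p5p": "1",
        "co2": "1",
        "nadph": "2"
      },
      "reversible": false,
      "tags": [
        "native",
        "lumped"
      ]
    },
    {
      "id": "TKT_TAL",
      "enzyme": "TKT",
      "stoich": {
        "p5p": "-3",
        "f6p": "2",
        "ga3p": "1"
      },
      "reversible": true,
      "tags": [
        "native",
        "lumped"
      ]
    },
    {
      "id": "G3PDH",
      "enzyme": "GPD",
      "stoich": {
        "dhap": "-1",
        "nadh": "-1",
        "gly3p": "1"
      },
      "reversible": false,
      "tags": [
        "native"
      ]
    },
    {
      "id": "RESP",
      "stoich": {
        "nadh": "-1",
        "atp": "16/15"
      },
      "reversible": false,
      "tags": [
        "lumped",
        "respiration"
      ]
    },
    {
      "id": "ATPM",
      "stoich": {
        "atp": "-1"
      },
      "reversible": false,
      "tags": [
        "maintenance"
      ]
    },
    {
      "id": "TAGSYN",
      "enzyme": "FAS",
      "stoich": {
        "accoa": "-27",
        "nadph": "-48",
        "atp": "-24",
        "gly3p": "-1",
        "tag": "1"
      },
      "reversible": false,
      "tags": [
        "lumped",
        "sink"
      ]
    }
  ]
}
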