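{
  "vickermania": {
    "description": "Vickermania ingenoplastis: complexes I/II/V and alternative oxidase present, complexes III/IV and cytochrome c absent; pyruvate dismutation to acetate and ethanol; glycosomal succinate branch feeding the mitochondrial propionate cycle; no glycerol kinase.",
    "enzymes": ["hk", "pgi", "pfk", "fba", "tpi", "gapdh_g", "gapdh_c", "pgk_g",
                "g3pdh_g", "adk", "pgm", "eno", "pyk", "pepck", "mdh_g", "mdh_m",
                "fh_g", "fh_m", "frd", "cs", "ogdh", "scl", "sdh1", "sdh2", "asct",
                "pdh", "pdc", "adh_zn", "mce", "mcm", "pcc", "aox",
                "c1_nd7", "c1_nduf", "atp6", "atpB"],
    "excretes": ["ac", "etoh", "succ", "prop"],
    "flags": {
      "pentose_phosphate_pathway": "present",
      "fructose_16_bisphosphatase": "absent",
      "beta_oxidation_complete": "absent",
      "glycogen_synthesis": "absent",
      "catalase": "present",
      "heme_synthesis_terminal": "absent",
      "l_lactate_dehydrogenase": "absent",
      "hydrogenase": "present",
      "nitroreductase": "present"
    }
  },
  "phytomonas_like": {
    "description": "Phytomonas-style comparator: same respiratory losses (no complexes III/IV, no cytochrome c), Zn-type alcohol dehydrogenase present, but no methylmalonyl-CoA propionate cycle; glycerol kinase and the mitochondrial G3P:Q shuttle present; excretes pyruvate and glycerol in addition to fermentation products.",
    "enzymes": ["hk", "pgi", "pfk", "fba", "tpi", "gapdh_g", "gapdh_c", "pgk_g",
                "g3pdh_g", "glyk", "adk", "pgm", "eno", "pyk", "pepck", "mdh_g",
                "mdh_m", "fh_g", "fh_m", "frd", "cs", "ogdh", "scl", "sdh1", "sdh2",
                "asct", "pdh", "pdc", "adh_zn", "aox", "c1_nd7", "c1_nduf",
                "atp6", "atpB", "g3pq"],
    "excretes": ["ac", "etoh", "succ", "pyr", "glyc"],
    "flags": {
      "propionate_cycle": "absent"
    }
  },
  "leishmania_like": {
    "description": "Respiratory-chain comparator carrying the full curated set plus complexes III and IV and cytochrome c; used as the baseline against which the Vickermania losses are diffed. Not a Leishmania major reconstruction.",
    "enzymes": ["hk", "pgi", "pfk", "fba", "tpi", "gapdh_g", "gapdh_c", "pgk_g",
                "g3pdh_g", "adk", "pgm", "eno", "pyk", "pepck", "mdh_g", "mdh_m",
                "fh_g", "fh_m", "frd", "cs", "ogdh", "scl", "sdh1", "sdh2", "asct",
                "pdh", "pdc", "adh_zn", "mce", "mcm", "pcc", "aox",
                "c1_nd7", "c1_nduf", "atp6", "atpB",
                "cytb", "cyc1", "risp", "qcr1", "cytc",
                "cox1", "cox2", "cox3", "cox4", "cox6"],
    "excretes": ["ac", "etoh", "succ", "prop"],
    "flags": {}
  },
  "tbrucei_bloodstream": {
    "description": "Bloodstream-form Trypanosoma brucei: glycosomal glycolysis with the glycerol-3-phosphate/dihydroxyacetone phosphate shuttle and alternative oxidase; reversible glycerol kinase supports the anaerobic glycerol route; excretes pyruvate and glycerol.",
    "enzymes": ["hk", "pgi", "pfk", "fba", "tpi", "gapdh_g", "pgk_g", "g3pdh_g",
                "glyk", "adk", "pgm", "eno", "pyk", "g3pq", "aox", "atp6", "atpB"],
    "excretes": ["pyr", "glyc"],
    "flags": {}
  }
}
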