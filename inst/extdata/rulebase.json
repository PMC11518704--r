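{
  "comment": "Compound-class diagnostic fragmentation rulebase. Each class lists ordered neutral-loss chains (names resolved in the neutral-loss vocabulary) and optional class-characteristic product-ion formulas (retro-Diels-Alder and alpha-cleavage ions, given as the ion's elemental composition with the polarity it is observed in). All entries carry unit weight; minimum_hits is the number of matched entries required for a class call.",
  "default_weight": 1.0,
  "minimum_hits": 1,
  "classes": {
    "anthraquinone": {
      "chains": [["CH3"], ["CO"], ["CO2"], ["CO", "CO2"], ["CO2", "CH3"], ["CH3", "CO"], ["CH3", "CO", "CO"]],
      "fragments": []
    },
    "flavone": {
      "chains": [["Glc"], ["CO"], ["CO2"], ["H2O"], ["CH3"], ["CO", "CO2"]],
      "fragments": [
        {"formula": "C7H3O4", "polarity": "negative"},
        {"formula": "C8H5O", "polarity": "negative"},
        {"formula": "C6H3O2", "polarity": "negative"}
      ]
    },
    "isoflavone": {
      "chains": [["H2O"], ["CO"], ["CO", "CO"], ["C8H6O"], ["Glc"], ["CH3"]],
      "fragments": []
    },
    "flavanone": {
      "chains": [["C8H8O"], ["C7H4O4"], ["C6H6O"], ["C9H8O3"], ["H2O"], ["CO2"]],
      "fragments": []
    },
    "flavonol": {
      "chains": [["Glc"], ["Rha"], ["Glc", "Rha"], ["Glc", "Rha", "H"], ["Glc", "Rha", "H", "CHO"], ["Glc", "Rha", "CO2"], ["H2O"], ["CO"], ["H2O", "CO"]],
      "fragments": [
        {"formula": "C7H3O4", "polarity": "negative"},
        {"formula": "C7H5O4", "polarity": "negative"},
        {"formula": "C8H5O2", "polarity": "negative"}
      ]
    },
    "flavanol": {
      "chains": [["CO2"], ["C3H2O3"], ["C8H6O4"], ["C9H8O4"], ["H2O"]],
      "fragments": []
    },
    "tetrahydroprotoberberine": {
      "chains": [["CH3"], ["OCH3"], ["C9H10O2"], ["C9H10O2", "CH3"], ["C11H13NO2"]],
      "fragments": []
    },
    "protoberberine": {
      "chains": [["CH3"], ["CH4"], ["CH3", "CH3"], ["CH4", "CO"], ["CH3", "CH3", "CO"], ["CH3", "CO"], ["CH3", "CO", "CO"]],
      "fragments": []
    },
    "aporphine": {
      "chains": [["Me2NH"], ["MeNH2"], ["Me2NH", "CH3"], ["Me2NH", "CH3OH"], ["Me2NH", "CH3OH", "CO"]],
      "fragments": []
    },
    "benzylisoquinoline": {
      "chains": [["Me2NH"], ["Me2NH", "CH3OH"], ["CH3OH"], ["OCH3"]],
      "fragments": [
        {"formula": "C7H7O", "polarity": "positive"}
      ]
    },
    "iridoid": {
      "chains": [["Glc"], ["Rha"], ["Glc", "CO2"], ["Glc", "CO2", "H2O"], ["Glc", "CO2", "H2O", "C2H2"], ["CO2"], ["H2O"]],
      "fragments": []
    },
    "triterpenoid": {
      "chains": [["H2O"], ["CO2"], ["C6H4O4"], ["C7H4O5"], ["H2O", "CO2"]],
      "fragments": []
    },
    "triterpenoid_saponin": {
      "chains": [["Glc"], ["Rha"], ["Ara"], ["Glua"], ["Glc", "Rha"], ["Glc", "Glc"], ["Glc", "Glc", "Rha"], ["Glc", "Glc", "C6H12"], ["Glc", "H2O", "CO2"], ["H2O"], ["CO2"]],
      "fragments": []
    },
    "lignan": {
      "chains": [["CH3"], ["H2O"], ["CH2O"], ["OCH3"], ["C4H8"], ["C3H6"], ["CH3", "H2O"], ["CH3", "O"]],
      "fragments": []
    },
    "coumarin": {
      "chains": [["CO"], ["CO2"], ["CO", "CO"], ["CO", "CO2"]],
      "fragments": []
    },
    "quinic_acid_derivative": {
      "chains": [["caffeoyl"], ["C7H10O5"], ["C9H8O4"], ["C7H10O5", "CO2"], ["H2O"], ["CO2"], ["Glc"]],
      "fragments": []
    },
    "phenolic_acid": {
      "chains": [["CO2"], ["H2O"], ["CH3"], ["Glc"], ["CO2", "CH3"], ["CO2", "CO", "CO"], ["C3H4O3"]],
      "fragments": []
    },
    "aliphatic_acid": {
      "chains": [["H2O"], ["CO2"], ["H2O", "CO2"], ["H2O", "HCOOH"], ["COOH"]],
      "fragments": []
    },
    "phenylethanoid_glycoside": {
      "chains": [["caffeoyl"], ["Rha"], ["Glc"], ["H2O"], ["caffeoyl", "Rha"], ["caffeoyl", "Rha", "Glc"], ["caffeoyl", "C2H2O"], ["caffeoyl", "C2H2O", "Glc"], ["caffeoyl", "Rha", "Glc", "H2O"]],
      "fragments": [
        {"formula": "C9H7O4", "polarity": "negative"},
        {"formula": "C9H5O3", "polarity": "negative"}
      ]
    },
    "amino_acid": {
      "chains": [["NH3"], ["HCOOH"], ["NH3", "HCOOH"], ["H2O", "CO"], ["H2O"]],
      "fragments": []
    },
    "steroid": {
      "chains": [["H2O"], ["H2O", "H2O"], ["C8H18O3"], ["C8H18O3", "H2O"], ["C4H14O3"]],
      "fragments": []
    },
    "phthalide": {
      "chains": [["H2O"], ["CO"], ["C12H14O2"], ["C12H14O2", "H2O"], ["C12H14O2", "C3H6"], ["C12H14O2", "C4H8"]],
      "fragments": []
    },
    "nucleoside": {
      "chains": [["C5H8O4"], ["C5H8O4", "NH3"], ["NH3"]],
      "fragments": []
    },
    "stilbene": {
      "chains": [["Glc"], ["Glc", "H2O"], ["Glc", "CO"], ["Glc", "C7H6O"], ["Glc", "C7H6O", "CO2"]],
      "fragments": []
    },
    "other": {
      "chains": [["H2O"], ["CO"], ["CO2"]],
      "fragments": []
    }
  }
}
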