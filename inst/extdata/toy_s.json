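{
  "species_id": "toy_S",
  "metabolites": [
    {
      "id": "ac_e",
      "name": "acetate (external)",
      "compartment": "extracellular"
    },
    {
      "id": "o2_e",
      "name": "oxygen (external)",
      "compartment": "extracellular"
    },
    {
      "id": "met_e",
      "name": "methionine (external)",
      "compartment": "extracellular"
    },
    {
      "id": "ac_c",
      "name": "acetate",
      "compartment": "cytosol"
    },
    {
      "id": "o2_c",
      "name": "oxygen",
      "compartment": "cytosol"
    },
    {
      "id": "atp_c",
      "name": "ATP",
      "compartment": "cytosol"
    },
    {
      "id": "adp_c",
      "name": "ADP",
      "compartment": "cytosol"
    }
  ],
  "reactions": [
    {
      "id": "EX_ac",
      "stoichiometry": {
        "ac_e": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": true,
      "exchanged_metabolite": "ac_e"
    },
    {
      "id": "EX_o2",
      "stoichiometry": {
        "o2_e": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": true,
      "exchanged_metabolite": "o2_e"
    },
    {
      "id": "EX_met",
      "stoichiometry": {
        "met_e": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": true,
      "exchanged_metabolite": "met_e"
    },
    {
      "id": "T_ac",
      "stoichiometry": {
        "ac_e": -1,
        "ac_c": 1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "T_o2",
      "stoichiometry": {
        "o2_e": -1,
        "o2_c": 1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "RESP",
      "stoichiometry": {
        "ac_c": -1,
        "o2_c": -2,
        "adp_c": -3,
        "atp_c": 3
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "ATPM",
      "stoichiometry": {
        "atp_c": -1,
        "adp_c": 1
      },
      "lower_bound": 1,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "BIOMASS",
      "stoichiometry": {
        "atp_c": -10,
        "adp_c": 10
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    }
  ],
  "biomass_reaction_id": "BIOMASS",
  "coupled_secretions": [
    {
      "metabolite_id": "met_e",
      "rate": 0.5
    }
  ]
}
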