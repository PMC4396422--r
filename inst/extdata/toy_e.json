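{
  "species_id": "toy_E",
  "metabolites": [
    {
      "id": "lcts_e",
      "name": "lactose (external)",
      "compartment": "extracellular"
    },
    {
      "id": "o2_e",
      "name": "oxygen (external)",
      "compartment": "extracellular"
    },
    {
      "id": "ac_e",
      "name": "acetate (external)",
      "compartment": "extracellular"
    },
    {
      "id": "met_e",
      "name": "methionine (external)",
      "compartment": "extracellular"
    },
    {
      "id": "lcts_c",
      "name": "lactose",
      "compartment": "cytosol"
    },
    {
      "id": "o2_c",
      "name": "oxygen",
      "compartment": "cytosol"
    },
    {
      "id": "ac_c",
      "name": "acetate",
      "compartment": "cytosol"
    },
    {
      "id": "met_c",
      "name": "methionine",
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
      "id": "EX_lcts",
      "stoichiometry": {
        "lcts_e": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": true,
      "exchanged_metabolite": "lcts_e"
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
      "id": "EX_met",
      "stoichiometry": {
        "met_e": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": true,
      "exchanged_metabolite": "met_e"
    },
    {
      "id": "T_lcts",
      "stoichiometry": {
        "lcts_e": -1,
        "lcts_c": 1
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
      "id": "T_ac",
      "stoichiometry": {
        "ac_c": -1,
        "ac_e": 1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "T_met",
      "stoichiometry": {
        "met_e": -1,
        "met_c": 1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "AERO",
      "stoichiometry": {
        "lcts_c": -1,
        "o2_c": -2,
        "adp_c": -6,
        "atp_c": 6,
        "ac_c": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "FERM",
      "stoichiometry": {
        "lcts_c": -1,
        "adp_c": -2,
        "atp_c": 2,
        "ac_c": 2
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
      "lower_bound": 2,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    },
    {
      "id": "BIOMASS",
      "stoichiometry": {
        "atp_c": -10,
        "met_c": -0.15,
        "adp_c": 10
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "is_exchange": false,
      "exchanged_metabolite": null
    }
  ],
  "biomass_reaction_id": "BIOMASS",
  "coupled_secretions": []
}
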