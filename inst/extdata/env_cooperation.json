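{"condition":"cooperation","pools":{"lcts_e":1.2e-05,"o2_e":6.2e-05,"ac_e":0,"met_e":0},"unlimited":[],"box_edge":0.5}
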