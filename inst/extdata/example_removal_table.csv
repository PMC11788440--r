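train_id,unit_id,cec_id,r_low,r_mode,r_high
demo,rbf,ex001,0.3,0.5,0.7
demo,rbf,ex002,0.2,0.4,0.6
demo,rbf,ex003,0.35,0.55,0.75
demo,rbf,ex004,0.25,0.45,0.65
demo,rbf,ex005,0.1,0.3,0.5
demo,rbf,ex006,0.2,0.35,0.5
demo,reverse_osmosis,ex001,0.9,0.95,0.99
demo,reverse_osmosis,ex002,0.88,0.94,0.98
demo,reverse_osmosis,ex003,0.92,0.96,0.99
demo,reverse_osmosis,ex004,0.9,0.95,0.99
demo,reverse_osmosis,ex005,0.7,0.8,0.9
demo,reverse_osmosis,ex006,0.85,0.92,0.97
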