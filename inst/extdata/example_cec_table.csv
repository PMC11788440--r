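cec_id,name,category,conc_low,conc_mode,conc_high,lod,loq,ef_cancer,ef_noncancer
ex001,example-pesticide,pesticide,40,80,160,,,0.02,0.35
ex002,example-industrial,industrial,150,300,600,,,0.07,0.012
ex003,example-pharmaceutical,pharmaceutical,2,5,9,,,,0.004
ex004,example-antibiotic,antibiotic,1,2.5,6,,,0.001,0.03
ex005,example-dbp,DBP,2.3,4.6,9.2,,,11.9,0.5
ex006,example-pcp,PCP,,,,10,,0.005,0.002
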