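{"sp":500000,"ir_daily":1.4,"years":25,"df_cancer":11.5,"df_noncancer":2.7,"threshold":1e-06}
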