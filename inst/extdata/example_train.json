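{"train_id":"demo","units":[{"unit_id":"rbf","name":"riverbank filtration"},{"unit_id":"reverse_osmosis","name":"reverse osmosis"}]}
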