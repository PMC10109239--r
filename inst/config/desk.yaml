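# Desk-scale profile: small embedding dimensions and epoch count for
# minutes-scale runs on the synthetic benchmark.
profile: desk
seed: 1
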