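{"lo":50,"hi":72.2222222222222,"mean":56.4833333333333,"n":36,"d":2,"trials":4000,"probs":[0.005,0.995]}
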