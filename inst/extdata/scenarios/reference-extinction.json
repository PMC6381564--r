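{"name": "reference-extinction", "theta": 2.5, "beta": 1, "gamma": 1, "p": 0.65, "q": 0.5, "h": 1.6, "x0": 0.15, "y0": 0.895, "expected_regime": "extinction"}
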