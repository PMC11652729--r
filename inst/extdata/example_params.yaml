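# Example parameter file: mutant deleterious in both phases, half selfing.
alpha: 0.5
sO: 0.02
sP: 0.02
shet: -0.02
shom: -0.03
mu: 1.0e-4
Ne: 30
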