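# Small example study configuration: two instrument lengths crossed with
# two trial sizes, second-archetype banks, 50 replications per scenario.
instrument: {J: [4, 10], M: 3, archetype: 2}
calibration: {N: 250, variance: 1}
trial: {N: [200, 500], mu: 0, gamma: 0.2}
run: {reps: 50, seed: 1, alpha: 0.05, nodes: 201}
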