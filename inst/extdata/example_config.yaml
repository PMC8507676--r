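# Example edgame configuration: TOC shift-2 rules, small exploratory batch.
# All keys are optional; omitted keys fall back to the standard mode
# (strategy presets, 10 rounds, 28 initial patients, 10,000 runs).
strategy: IV
n_runs: 500
master_seed: 42
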