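# Demo pipeline configuration: simulate a small synthetic twin sample
# under the default generating values and fit the timing-constant and
# timing-specific models.
input:
  simulate:
    n_mz: 400
    n_dz: 600
models: ["1a", "1b"]
n_restarts: 2
seed: 7
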