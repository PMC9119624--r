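kind: dimer
n_chains: 2
chain_length: 80
patch_len: 7
eps_sp: 1.2
eps_ns: 0.5
temperature: 310
dt: 30
box_edge: 120
seed: 1
steps: 500000
report_every: 5000
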