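# Example run configuration: agent-based model with a shrinking Wnt domain
# and trailing-cell deposition. All abm keys map to abm_params() arguments;
# values not listed use the package's calibrated defaults.
model: abm
scenario: abm_shrinking_wnt
seed: 1
n_steps: 3000
sample_every: 100
snapshot_every: 1000
abm:
  wnt_shrink_rate: 0.002
  speed_wnt: 0.018
  speed_fgf: 0.016
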