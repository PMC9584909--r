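# demo pipeline configuration: 20-residue toy chain, planted two-state
# exchange over the first 60% of the chain, 40 conformers
seed: 42
chain:
  n_residues: 20
  atoms_per_residue: 1
  bond_length: 3.8
planted:
  correlated_residues: [4, 5, 6, 7, 8, 9, 10, 11, 12, 13]
  displacement_amplitude: 3.0
  state_populations: [0.5, 0.5]
  conformer_noise_sigma: 0.3
  n_conformers: 40
spectroscopy:
  tau_c: 6.9
  spectrometer_frequency: 600
  mixing_times: [8, 16, 24, 32, 40, 48, 80]
  intensity_noise_sigma: 0.02
extraction:
  max_distance: 7.0
anneal:
  n_states: 2
  n_conformers: 10
  steps: 20000
correlation:
  top_k: 10
compare:
  threshold: 1.5
  binding_site: [1, 2, 3]
  allosteric_site: [18, 19, 20]
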