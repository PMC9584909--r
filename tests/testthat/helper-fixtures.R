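# shared small fixtures, built in code

fix_chain <- function(n = 12, apr = 1, seed = 7)
  build_toy_chain(toy_chain_spec(n, atoms_per_residue = apr, seed = seed))

fix_params <- function(tau_c = 6.9, noise = 0, ...)
  spectroscopy_params(tau_c = tau_c, intensity_noise_sigma = noise, ...)

# planted two-state system plus its idealized restraints
fix_two_state <- function(n = 12, movers = 4:9, amp = 3, pops = c(0.5, 0.5),
                          noise = 0.3, n_conf = 40, cutoff = 8,
                          seed_chain = 7, seed_ens = 11,
                          sym_exempt = movers, couplings = FALSE) {
  chain <- fix_chain(n, seed = seed_chain)
  pl <- planted_two_state_spec(movers, displacement_amplitude = amp,
                               state_populations = pops,
                               conformer_noise_sigma = noise,
                               n_conformers = n_conf)
  ens <- generate_two_state_ensemble(chain, pl, seed = seed_ens)
  truth <- attr(ens, "planted")
  cp <- if (couplings)
    coupling_restraints_from_states(truth$states, chain$atoms,
                                    populations = pops)
  rs <- restraint_set(
    restraints_from_states(truth$states, chain$atoms, populations = pops,
                           cutoff = cutoff)$distance,
    couplings = cp, atoms = chain$atoms, sym_exempt = sym_exempt)
  list(chain = chain, planted = pl, ensemble = ens, truth = truth,
       restraints = rs)
}

# agreement of two label vectors up to label permutation (2 states)
label_agreement <- function(a, b) max(mean(a == b), mean(a != b))
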