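# msnmr — multi-state NMR ensemble analysis with exact NOEs

Proteins that exchange slowly between conformations average their NMR
observables over every populated state, so a single-structure model fitted
to such data is a compromise that explains nothing well. `msnmr` implements
the multi-state alternative as a reusable, fully tested R pipeline:

1. **eNOE distance extraction.** NOESY buildup series are simulated or read
   as intensity tables, corrected for spin diffusion against a reference
   structure through the full dipolar relaxation matrix
   (`exp(-R·τm)`), and converted into tiered distance restraints —
   bidirectional pairs get the highest-precision 0.1 Å window, via
   `r = (K/σ̂)^{1/6}`.
2. **Multi-state structure calculation.** A target function
   `TF = Σ(r_eff − u)₊² + Σ(l − r_eff)₊² + w_J Σ(|J_calc − J_obs| − t)₊² +
   w_sym Σ(d − 1.2 Å)₊²` with population-weighted r⁻⁶ state averaging
   `r_eff = (Σ_s w_s r_s⁻⁶)^(−1/6)` is minimized by compiled Cartesian
   simulated annealing with a deterministic L-BFGS polish. On top of it:
   state-number scans (how many states do the data need?), TF-based
   population estimation, and lowest-TF conformer selection.
3. **Correlated-sites analysis.** Conformers are clustered per residue on
   Cα distance profiles; a residue×residue mutual-information
   matrix (normalized to [0,1]) reveals which sites exchange together; a
   jackknife over restraint subsets probes how much data the correlations
   need.
4. **Ensemble comparison.** Kabsch superposition, mean structures,
   per-residue deviation profiles with a 1.5 Å threshold and excluded
   flexible ranges, ensemble distance statistics, and chemical-shift
   perturbation mapping `CSP = (|Δδ_H| + 0.14·|Δδ_N|)/2`.

A synthetic-data generator plants two-state ground truth (correlated
residue subsets, displacement amplitudes, state populations) in toy chains
and emits the corresponding NOESY buildups, scalar couplings and shift
tables, so every stage of the pipeline is testable against known answers
without downloading anything.

## Worked example

```r
library(msnmr)

# a 12-residue toy fold in which residues 4-9 exchange between two states
chain   <- build_toy_chain(toy_chain_spec(12, seed = 7))
planted <- planted_two_state_spec(4:9, displacement_amplitude = 3,
                                  n_conformers = 40)
ens     <- generate_two_state_ensemble(chain, planted, seed = 11)
truth   <- attr(ens, "planted")

# idealized eNOE restraints back-calculated from the hidden states
rs <- restraint_set(
  restraints_from_states(truth$states, chain$atoms, cutoff = 8)$distance,
  atoms = chain$atoms, sym_exempt = 4:9)

# how many states do the data require?
scan <- state_number_scan(rs, n_range = 1:3, n_conformers = 4,
                          steps = 30000, seed = 1,
                          bonds = chain_bonds(chain), bond_weight = 10)
scan$table
#>   n_states tf_median tf_best
#> 1        1    2.3111  2.3083
#> 2        2    0.0252  0.0051
#> 3        3    0.0005  0.0004
scan$selected
#> [1] 2

# which residues exchange together?
cm <- cluster_ensemble(ens, n_states = 2, seed = 5)
sort(top_correlated_residues(cm, k = 6))
#> [1] 4 5 6 7 8 9
```

A single-state model leaves a target function two orders of magnitude
above the two-state model (2.31 vs 0.03): the restraints genuinely demand
two states, and the scan stops at N = 2 because the third state buys less
than the plateau threshold. The correlation stage then recovers exactly
the planted residues 4–9 as the top correlated network.

The full pipeline (simulate → extract → anneal → correlate → compare) runs
from one configuration:

```r
man <- run_pipeline(list(seed = 42, chain = list(n_residues = 20)),
                    out_dir = "run1")
```

writing NOESY peak tables, CYANA-dialect `.upl`/`.lol` restraints,
multi-model PDB ensembles, the MI matrix and heatmap, the deviation
profile and the CSP table.

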