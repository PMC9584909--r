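---
title: "Multi-state ensemble analysis from exact NOEs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state ensemble analysis from exact NOEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msnmr)
```

# The problem

Proteins that exchange between several conformations on slow timescales
average their NMR observables over all populated states. A single-structure
model fitted to such data is a compromise that satisfies nothing well;
a *multi-state* model — several coordinate sets optimized simultaneously
against the same restraints — can instead resolve the exchanging states,
their populations, and which residues move together. `msnmr` implements
this analysis end to end at desk scale: exact-NOE (eNOE) distance
extraction with full relaxation-matrix spin-diffusion correction,
multi-state restrained optimization against a CYANA-style target function,
mutual-information detection of correlated residue networks, and
ligand-free/ligand-bound ensemble comparison. A synthetic-data generator
with planted ground truth makes every stage falsifiable.

# The synthetic systems

The toy chain is a confined self-avoiding random walk of pseudo-Cα
atoms with a fixed 3.8 Å virtual bond, optionally decorated with
pseudo-protons at 1.0–2.5 Å. This reproduces the interatomic distance
range that yields observable NOEs (2–6 Å) without any force-field
machinery.

The planted two-state ensemble displaces a chosen residue subset between
two states. Design choices that matter:

* **Per-residue displacement directions.** Each correlated residue moves
  along its own random direction, coherently across conformers. A rigid
  translation of the whole block would leave the block's internal
  distances unchanged and make moving and static residues
  indistinguishable from distance statistics (motion is relative); an
  internal rearrangement is also what real exchanging states look like.
* **Shared covalent geometry.** Both states must have identical virtual
  bond lengths, because real conformational states share their covalent
  structure. The displaced state is produced by alternating projections
  onto (i) the bond constraints and (ii) the planted per-residue
  displacement amplitude, so both hold to high precision. This is not
  cosmetic: r^-6-averaged distance data are exactly invariant under
  jointly rescaling a state and its population weight, so *populations
  are only identifiable because covalent geometry forbids scaling a
  state*. Without bond restraints the TF–population curve is flat.
* **Deterministic state allocation** (floor of population × conformers,
  remainder to state 1), so exact-fraction cases are reproducible.
* **Noise model:** isotropic Gaussian per atom (default σ = 0.3 Å) on
  coordinates; multiplicative Gaussian on NOESY intensities (default 2%,
  a typical integration uncertainty — the experimental value is rarely
  reported); additive Gaussian on shifts and couplings.

What the generator does *not* emulate: sidechain rotamers, anisotropic
tumbling, internal-motion order parameters, chemical-shift prediction
from structure, and intermediate-exchange line broadening. Passing tests
therefore demonstrate the *algorithms* recover planted signal under
idealized two-state exchange, not that any real protein is two-state.

# Relaxation matrix and eNOE extraction

Cross- and auto-relaxation rates use the standard homonuclear dipolar
expressions with rigid isotropic tumbling,
$J(\omega) = \tfrac{2}{5}\,\tau_c/(1+\omega^2\tau_c^2)$,
$\sigma_{ij} \propto r_{ij}^{-6}\,[6J(2\omega)-J(0)]$ and
$\rho_i \propto \sum_j r_{ij}^{-6}\,[J(0)+3J(\omega)+6J(2\omega)]$.
NOESY intensities are the elements of $\exp(-\mathbf{R}\tau_m)$, so
indirect (spin-diffusion) pathways are fully present in simulated data.
The 2×2 case has a closed form, which serves both as the independent
oracle for the simulator and as the model fitted to corrected buildups.

Spin-diffusion correction follows the reference-structure strategy: for
every cross peak the expected multi-spin and isolated-two-spin intensities
are computed from a relaxation matrix built from a given 3D structure, and
the measured normalized intensity is rescaled by their ratio. Inverting a
fully measured intensity matrix would need every peak observable, which
NMR sensitivity does not allow; a reference structure does.

Numerical choices: cross peaks are normalized by the geometric mean of the
two diagonal decays (symmetric in i↔j, and it cancels the mean
auto-relaxation rate exactly, leaving a one-parameter fit in σ with the
auto-rate *difference* fixed from the reference matrix). Fits use golden
section search with a refinement pass (tolerance 1e-14); standard errors
come from the usual linearized fit covariance. Distances follow from
$r = (K/\hat\sigma)^{1/6}$. Pairs measured in both transfer directions
with σ estimates agreeing within 20% become *bidirectional* restraints
with the highest-precision ±0.05 Å window (0.1 Å wide); all others are
unidirectional with a ±10% window.

The spin-diffusion demonstration uses a linear three-spin chain at
τ~c~ = 15 ns: a regime (large system, slow tumbling) where indirect
transfer through the middle spin dominates the far cross peak and an
uncorrected fit underestimates the 6 Å distance by more than 0.5 Å. At
τ~c~ = 6.9 ns the effect is present but milder (≈0.34 Å); the correction
is exact in both regimes because the simulator and the reference matrix
share the physics. The round-trip benchmark (20 spins, τ~c~ = 6.9 ns,
600 MHz, mixing times 8–80 ms, 2% noise) recovers >90% of distances
within 0.3 Å and all bidirectional ones within 0.15 Å.

A magnetization-conservation property (column sums of the propagator
constant) holds only in the spin-diffusion limit where $J(\omega)$ and
$J(2\omega)$ vanish; the property test therefore uses a very long
correlation time with zero external leakage. At 6.9 ns the column sums
drift by ~1% over 80 ms — that is physics, not error.

# The multi-state target function and annealer

For a model with states $s = 1..N$ and weights $w_s$:

$$\mathrm{TF} = \sum_{\mathrm{upper}} (r_\mathrm{eff}-u)_+^2
 + \sum_{\mathrm{lower}} (l-r_\mathrm{eff})_+^2
 + w_J \sum (\,|J_\mathrm{calc}-J_\mathrm{obs}|-t\,)_+^2
 + w_\mathrm{sym} \sum_{\mathrm{atoms,\ pairs}} (d-1.2\,\text{Å})_+^2$$

with $r_\mathrm{eff} = (\sum_s w_s r_s^{-6})^{-1/6}$ (NOE-physical
averaging; the effective distance is dominated by the shortest state) and
$J_\mathrm{calc} = \sum_s w_s J(\theta_s)$ (couplings average linearly).
Symmetry restraints are flat-bottom quadratics on the inter-state
displacement of every atom, free below 1.2 Å, weight 0.1 by default; they
keep states together except where data force them apart, and known
flexible regions can be exempted.

Minimization is Cartesian Metropolis annealing (compiled kernel, per-atom
moves with incremental energy evaluation, geometric temperature and step
schedules), replacing torsion-angle dynamics: the contract is "minimize
the same TF", not "reproduce a specific dynamics trajectory". Covalent
geometry is represented by harmonic reference bonds (weight 10 in the
scans) — essential for population identifiability as noted above. Two
further choices proved decisive:

* **Split continuation.** Multi-state runs first anneal a collapsed
  single-state model, then replicate it into N perturbed copies (0.8 Å
  noise) and relax at low temperature (0.2). Starting the multi-state
  search hot freezes all states into one compromise structure — a strong
  wrong basin.
* **Deterministic polish.** Every annealed model is finished by L-BFGS on
  the same energy (analytic-free gradient via per-atom central
  differences in the compiled kernel). This removes run-to-run stochastic
  residuals, so TF differences between calculations reflect the data.

The state-number scan anneals at N = 1..9 (tests use 1..3 for speed) and
selects the smallest N whose median TF either drops below an absolute
floor (0.1, "the data are explained") or improves on N−1 by less than 20%.
The population scan offers two modes; the default *refit* mode anneals
reference models at anchor weights {0.3, 0.5, 0.7} and quenches each along
the weight grid (warm-started from its neighbour), reporting the pointwise
minimum over anchors. Continuation keeps annealing noise correlated along
the curve and prevents basin jumps between the two label-swapped optima;
the anchors remove the bias a single uniform-weight reference would
impose. The identifiable quantity is the population *pair* — the TF is
exactly invariant under swapping states together with weights — so
recovered values are reported as the major-state population, and the
acceptance measurement takes the median over three replicate planted
systems and interpolates the curve minimum parabolically. Measured
resolution at this system size (12 residues, ~66 distance + 9 coupling
restraints): equal populations are recovered within ±0.05, while
asymmetric populations (0.7/0.3) come back biased toward equality with
errors up to ~0.15 depending on the seed. The limit is residual
compensability — the model can absorb part of a weight change through
small coordinated rearrangements inside the restraint windows — not
annealing noise (tighter windows shift, but do not remove, the bias).
This mirrors the general experience that TF-based population estimates
are semiquantitative.

# Correlated-sites analysis

Features are per-residue Cα distance profiles (each residue's
distances to all others, sequence neighbours |i−j| ≤ 2 excluded).
Conformers are clustered per residue by k-means with 10 restarts; the MI
matrix normalizes each pair's mutual information by the smaller label
entropy, so perfectly coupled two-state behaviour scores 1 and
independence ~0 (finite-sample bias at 40 conformers is ≈0.05 and is not
subtracted by default, matching the usual [0,1] display convention).
Residues are ranked by the row sum of off-diagonal MI; the top 15 form
the reported network; consensus state labels come from a majority vote
after pairwise label alignment.

One addition was necessary: a **motion gate**. Distance geometry
propagates the state signal of the moving residues into *every* residue's
profile (a static residue's distances to the movers shift too), so naive
per-residue clustering assigns near-perfect state labels everywhere and
the MI matrix saturates. The gate only attempts state separation at
residues whose motion score — the *median* over profile columns of the
per-column conformer variance — exceeds 1.5× the chain's lower-quartile
score. A residue that itself moves shifts essentially all of its profile
columns, while a static residue shows variance only in the minority of
columns pointing at moving regions, which the median ignores. Gated-out
residues are flagged degenerate and contribute zero MI. With this gate,
planted 15-residue networks in 60-residue chains are recovered with
precision and recall ≥0.93 at displacement/noise = 10 (3 Å / 0.3 Å);
recovery degrades gracefully toward the detection boundary around
signal-to-noise 5.

The jackknife removes a random fraction of distance restraints, re-runs
the two-state calculation, and summarizes the mean MI over the top
network (the summary statistic is a package choice; the stability
literature does not fix one). Only the lowest-TF conformers (default:
the better half) enter the correlation step — poorly converged runs blur
the states. At desk scale (12 residues, 12 conformers per replicate,
40k steps) the full-data network MI is ≈0.3–0.5 rather than 1: the
annealing yield of fully converged two-state conformers is the limiting
factor, which is also why structure calculations at experimental scale
compute 1000 conformers and keep 20.

# Ensemble comparison

Kabsch superposition is the closed-form SVD solution with a determinant
correction (proper rotations only; collinear selections are rejected).
Mean structures are arithmetic Cα means over all states and
conformers after superposition onto a common reference (by convention
the first ligand-free conformer). The deviation profile flags residues
whose mean positions differ by more than 1.5 Å, with flexible ranges
excluded from flagging. Ensemble distances are reported as mean ± sample
sd (n−1). RMSD to a reference uses per-conformer Cα RMSD averaged
over conformers (best-conformer and per-conformer values are also
returned, since conventions differ between studies). CSP combines
per-residue ¹H and ¹⁵N shift differences as the atom-weighted mean
$(|\Delta\delta_H| + 0.14\,|\Delta\delta_N|)/2$ (the quadratic form is
selectable; 0.14 is the standard ¹⁵N weight).

# Problem sizes and reproducibility

The shipped tests and the acceptance script use: 20-spin systems for
extraction, 12-residue chains for annealing-based scans (4–16 conformers,
25k–40k Metropolis steps), 60-residue chains (40 conformers) for network
recovery, and 5×5 jackknife replicates — sizes chosen so the whole suite
runs on a laptop in minutes while every recovery stays comfortably inside
its tolerance. All randomness flows from explicit integer seeds through
one deterministic seed-derivation function; identical seeds give
bit-identical ensembles, observables, annealing runs and TSV outputs.

# Known limitations

* Chirality is invisible to distance data: annealed structures may be
  mirror images. All downstream statistics (distances, MI, couplings via
  cos θ) are mirror-invariant; superposition-based RMSD to a reference is
  not, and is reported against the better-matching hand in tests.
* Population estimates are pair-valued (label symmetry) with ±0.1
  resolution at desk scale.
* The motion gate assumes at least a quarter of the chain is
  conformationally quiet (it uses the lower-quartile score as the rigid
  baseline); for systems where nearly everything moves, disable it
  (`motion_gate = 0`) and expect a saturated MI matrix.
* The annealer is not a replacement for torsion-angle dynamics at real
  protein scale; it is a desk-scale minimizer of the same target
  function.

# A minimal session

```{r example, eval = FALSE}
chain <- build_toy_chain(toy_chain_spec(12, seed = 7))
planted <- planted_two_state_spec(4:9, displacement_amplitude = 3,
                                  n_conformers = 40)
ens <- generate_two_state_ensemble(chain, planted, seed = 11)
truth <- attr(ens, "planted")

rs <- restraint_set(
  restraints_from_states(truth$states, chain$atoms, cutoff = 8)$distance,
  atoms = chain$atoms, sym_exempt = 4:9)
scan <- state_number_scan(rs, n_range = 1:3, n_conformers = 4,
                          steps = 30000, seed = 1,
                          bonds = chain_bonds(chain), bond_weight = 10)
scan$selected       # 2

cm <- cluster_ensemble(ens, n_states = 2, seed = 5)
top_correlated_residues(cm, k = 6)   # the planted residues
```
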