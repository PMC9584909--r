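# toy chains, planted ensembles and simulated observables

test_that("toy chain geometry honours its specification", {
  spec <- toy_chain_spec(15, atoms_per_residue = 2, seed = 3)
  chain <- build_toy_chain(spec)
  ca <- chain$coords[chain$atoms$elety == "CA", ]
  bonds <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(abs(bonds - spec$bond_length) < 1e-9))
  # pseudo-protons stay within the configured attachment range
  h <- which(chain$atoms$elety != "CA")
  hd <- sqrt(rowSums((chain$coords[h, ] - ca[chain$atoms$resno[h], ])^2))
  expect_true(all(hd >= spec$h_dist_range[1] - 1e-9 &
                  hd <= spec$h_dist_range[2] + 1e-9))
  # non-bonded clash distance respected
  d <- as.matrix(dist(ca))
  nb <- abs(row(d) - col(d)) > 1
  expect_true(min(d[nb]) >= spec$clash - 1e-9)
  # same seed, same chain; different seed, different chain
  expect_identical(build_toy_chain(spec)$coords, chain$coords)
  spec2 <- toy_chain_spec(15, atoms_per_residue = 2, seed = 4)
  expect_false(identical(build_toy_chain(spec2)$coords, chain$coords))
  expect_error(toy_chain_spec(4), "n_residues")
})

test_that("planted ensembles allocate states deterministically and displace coherently", {
  fx <- fix_two_state(pops = c(0.5, 0.5), n_conf = 40)
  expect_identical(sum(fx$ensemble$state_labels == 1L), 20L)
  expect_identical(sum(fx$ensemble$state_labels == 2L), 20L)
  # state-2 structure moves only the correlated residues
  moved <- sqrt(rowSums((fx$truth$states[[2]] - fx$truth$states[[1]])^2))
  expect_true(all(moved[fx$chain$atoms$resno %in% 4:9] > 0.5))
  expect_true(all(moved[!fx$chain$atoms$resno %in% 4:9] < 1e-12))
  # displaced state keeps the covalent (virtual-bond) geometry
  s2 <- fx$truth$states[[2]]
  bl <- sqrt(rowSums((s2[-1, ] - s2[-nrow(s2), ])^2))
  expect_true(all(abs(bl - 3.8) < 1e-6))
  # identical seeds give bit-identical ensembles
  fx2 <- fix_two_state(pops = c(0.5, 0.5), n_conf = 40)
  expect_identical(fx2$ensemble$coords, fx$ensemble$coords)
  # amplitude 0 keeps both states identical
  chain <- fix_chain()
  pl0 <- planted_two_state_spec(4:9, 0, conformer_noise_sigma = 0.2)
  tr0 <- attr(generate_two_state_ensemble(chain, pl0, seed = 2), "planted")
  expect_identical(tr0$states[[1]], tr0$states[[2]])
  # invalid specifications are rejected
  expect_error(planted_two_state_spec(1:3, -1), "amplitude")
  expect_error(planted_two_state_spec(integer(0), 2), "empty")
  expect_error(planted_two_state_spec(1:3, 2, c(0.2, 0.3)), "summing to 1")
  expect_error(generate_two_state_ensemble(
    chain, planted_two_state_spec(40:45, 2)), "subset")
})

test_that("deterministic population allocation follows floor-plus-remainder", {
  chain <- fix_chain()
  for (case in list(c(0.7, 0.3, 40, 28), c(0.25, 0.75, 12, 3),
                    c(0.55, 0.45, 10, 6))) {
    pl <- planted_two_state_spec(4:9, 2, c(case[1], case[2]),
                                 n_conformers = case[3])
    ens <- generate_two_state_ensemble(chain, pl, seed = 1)
    expect_identical(sum(ens$state_labels == 1L), as.integer(case[4]))
  }
})

test_that("simulated couplings follow the Karplus relation and state averaging", {
  expect_equal(karplus_j(90), 0.7)            # cos 90 = 0 leaves only C
  expect_equal(karplus_j(0), 7.9 - 1.0 + 0.7) # A + B + C
  # two states at 1:1 average arithmetically
  j1 <- karplus_j(60); j2 <- karplus_j(180)
  chain <- fix_chain(6)
  # build a two-conformer ensemble with prescribed torsions via direct
  # geometry: use the analytic average as the oracle instead
  expect_equal((j1 + j2) / 2, 0.5 * j1 + 0.5 * j2)
  fx <- fix_two_state(noise = 0)
  tab <- simulate_couplings(fx$ensemble)
  # noise-free ensemble couplings equal the population mean of the
  # per-state couplings (linear averaging oracle)
  cp <- coupling_restraints_from_states(fx$truth$states, fx$chain$atoms,
                                        populations = c(0.5, 0.5))
  expect_equal(tab$j_hz, cp$target, tolerance = 1e-10)
  expect_identical(nrow(tab), fx$chain$spec$n_residues - 3L)
})

test_that("shift tables carry the planted perturbations", {
  res <- 1:20
  st <- simulate_shift_tables(res, binding_site = 3:6,
                              allosteric_site = 15:17,
                              effect_h = 0.2, effect_n = 1.0)
  expect_identical(st$apo$residue, st$holo$residue)
  # zero effects, zero noise: identical tables
  st0 <- simulate_shift_tables(res, 3:6, effect_h = 0, effect_n = 0)
  expect_equal(st0$apo$shift_ppm, st0$holo$shift_ppm)
  tab <- csp(st$apo, st$holo)
  expect_equal(tab$csp[tab$residue %in% 3:6],
               rep((0.2 + 0.14 * 1.0) / 2, 4))
  expect_true(all(tab$csp[tab$residue %in% 3:6] >
                  max(tab$csp[!tab$residue %in% 3:6])))
  # allosteric site ranks directly after the binding site
  ord <- order(-tab$csp)
  expect_setequal(tab$residue[ord[1:4]], 3:6)
  expect_setequal(tab$residue[ord[5:7]], 15:17)
  expect_error(simulate_shift_tables(res, binding_site = 25), "subsets")
})
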