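# simulated annealing, state-number scan, conformer selection

test_that("annealing recovers a rigid structure from its own restraints", {
  chain <- fix_chain(12)
  rs <- restraints_from_states(chain$coords, chain$atoms, cutoff = 8)
  ens <- anneal_multistate(rs, n_states = 1, n_conformers = 4,
                           steps = 30000, seed = 3,
                           bonds = chain_bonds(chain))
  expect_lt(min(ens$tf), 0.1)
  best <- ens$coords[, , 1, 1]
  direct <- kabsch_superpose(best, chain$coords)$rmsd
  mirror <- kabsch_superpose(best %*% diag(c(-1, 1, 1)), chain$coords)$rmsd
  expect_lt(min(direct, mirror), 0.5)   # distances cannot fix chirality
})

test_that("annealing is seed-deterministic and sorted by TF", {
  fx <- fix_two_state(n = 8, movers = 3:5)
  e1 <- anneal_multistate(fx$restraints, n_states = 2, n_conformers = 3,
                          steps = 5000, seed = 11)
  e2 <- anneal_multistate(fx$restraints, n_states = 2, n_conformers = 3,
                          steps = 5000, seed = 11)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$tf, e2$tf)
  expect_true(!is.unsorted(e1$tf))
  e3 <- anneal_multistate(fx$restraints, n_states = 2, n_conformers = 3,
                          steps = 5000, seed = 12, polish = FALSE)
  e4 <- anneal_multistate(fx$restraints, n_states = 2, n_conformers = 3,
                          steps = 5000, seed = 11, polish = FALSE)
  expect_false(identical(e3$coords, e4$coords))
  expect_error(anneal_multistate(
    restraint_set(fx$restraints$distance[0, ], atoms = fx$restraints$atoms),
    n_states = 1), "no distance restraints")
})

test_that("annealed TF matches an exhaustive grid search on a tiny system", {
  # 3 atoms, 1 state: gauge-fix atom1 at origin, atom2 on x, atom3 in xy,
  # and scan the 3 remaining degrees of freedom exhaustively
  atoms <- data.frame(eleno = 1:3, elety = rep("CA", 3), resno = 1:3)
  rs <- restraint_set(data.frame(atom_i = c(1, 2, 1), atom_j = c(2, 3, 3),
                                 upper = c(3.9, 3.9, 6.1),
                                 lower = c(3.7, 3.7, 5.9)), atoms = atoms)
  grid_best <- Inf
  for (x2 in seq(3.0, 4.6, 0.05)) for (x3 in seq(-1, 6, 0.1))
    for (y3 in seq(0.1, 5, 0.1)) {
      x <- array(c(0, x2, x3, 0, 0, y3, 0, 0, 0), c(3, 3, 1))
      grid_best <- min(grid_best, target_function(x, rs)$total)
    }
  ens <- anneal_multistate(rs, n_states = 1, n_conformers = 3,
                           steps = 10000, seed = 5)
  expect_lte(min(ens$tf), grid_best + 0.05 * max(grid_best, 0.01))
})

test_that("select_lowest_tf keeps the best conformers deterministically", {
  fx <- fix_two_state(n = 8, movers = 3:5)
  ens <- anneal_multistate(fx$restraints, n_states = 2, n_conformers = 6,
                           steps = 4000, seed = 2, polish = FALSE)
  sel <- select_lowest_tf(ens, 3)
  expect_identical(sel$n_conformers, 3L)
  expect_equal(sel$tf, sort(ens$tf)[1:3])
  expect_lte(max(sel$tf), sort(ens$tf)[4])
  expect_identical(select_lowest_tf(ens, 6)$tf, ens$tf)   # k = n identity
  expect_error(select_lowest_tf(ens, 0), "positive")
  expect_error(select_lowest_tf(ens, 7), "exceeds")
})

test_that("state-number scan separates one- and two-state systems", {
  fx <- fix_two_state(n = 12, movers = 4:9, cutoff = 8)
  chain <- fx$chain
  sc2 <- state_number_scan(fx$restraints, n_range = 1:3, n_conformers = 3,
                           steps = 25000, seed = 3,
                           bonds = chain_bonds(chain), bond_weight = 10)
  expect_identical(sc2$selected, 2L)
  expect_gte(sc2$table$tf_median[1], 5 * sc2$table$tf_median[2])
  # TF never gets worse with more states (up to 5% annealing tolerance)
  tf <- sc2$table$tf_median
  expect_true(all(diff(tf) <= 0.05 * pmax(tf[-length(tf)], 0.01)))
  rigid <- restraints_from_states(chain$coords, chain$atoms, cutoff = 8)
  sc1 <- state_number_scan(rigid, n_range = 1:2, n_conformers = 3,
                           steps = 25000, seed = 3,
                           bonds = chain_bonds(chain), bond_weight = 10)
  expect_identical(sc1$selected, 1L)
  expect_error(state_number_scan(rigid, integer(0)), "empty")
})

test_that("population grids outside (0,1) are rejected", {
  fx <- fix_two_state(n = 8, movers = 3:5)
  expect_error(population_scan(fx$restraints, grid = c(0, 0.5)), "inside")
})
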