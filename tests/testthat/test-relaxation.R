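# dipolar relaxation matrix and NOESY buildup simulation

test_that("cross-relaxation rates follow the r^-6 law and tumbling regime", {
  p <- fix_params()
  R1 <- build_relaxation_matrix(rbind(c(0, 0, 0), c(3, 0, 0)), p)
  R2 <- build_relaxation_matrix(rbind(c(0, 0, 0), c(6, 0, 0)), p)
  expect_equal(R2$rates[1, 2] / R1$rates[1, 2], 2^-6, tolerance = 1e-12)
  # slow tumbling at 6.9 ns / 600 MHz: negative sigma (spin-diffusion regime)
  expect_lt(R1$rates[1, 2], 0)
  expect_gt(R1$rates[1, 1], 0)
  # permuting the spin order permutes rows and columns consistently
  xyz <- fix_chain(6)$coords
  Ra <- build_relaxation_matrix(xyz, p, spins = c(1, 3, 5))
  Rb <- build_relaxation_matrix(xyz, p, spins = c(5, 1, 3))
  perm <- match(Ra$spins, Rb$spins)
  expect_equal(unname(Rb$rates[perm, perm]), unname(Ra$rates),
               tolerance = 1e-12)
  expect_error(build_relaxation_matrix(rbind(c(0, 0, 0), c(0.1, 0, 0)), p),
               "degenerate")
})

test_that("matrix-exponential buildups match the closed-form two-spin solution", {
  p <- fix_params()
  xy <- rbind(c(0, 0, 0), c(4, 0, 0))
  R <- build_relaxation_matrix(xy, p)
  b <- simulate_noesy_buildups(xy, p)
  oracle <- two_spin_intensity(R$rates[1, 1], R$rates[2, 2], R$rates[1, 2],
                               p$mixing_times * 1e-3)
  i12 <- which(b$peaks$spin_i == 1 & b$peaks$spin_j == 2)
  expect_equal(b$cross[i12, ], oracle$cross, tolerance = 1e-10)
  expect_equal(b$diagonal["1", ], oracle$diag1, tolerance = 1e-10)
  expect_identical(ncol(b$cross), 7L)   # the full mixing-time grid
  expect_identical(b$mixing_times, c(8, 16, 24, 32, 40, 48, 80))
})

test_that("short-mixing-time limit reproduces the ISPA rate", {
  p1 <- spectroscopy_params(6.9, 600, mixing_times = 1,
                            intensity_noise_sigma = 0)
  xy <- rbind(c(0, 0, 0), c(3.5, 0, 0))
  R <- build_relaxation_matrix(xy, p1)
  b <- simulate_noesy_buildups(xy, p1)
  # cross intensity ~ -sigma * tau_m as tau_m -> 0
  rate <- -b$cross[1, 1] / 1e-3
  expect_lt(abs(rate - R$rates[1, 2]) / abs(R$rates[1, 2]), 0.01)
})

test_that("magnetization is conserved in the spin-diffusion (no-leakage) limit", {
  # J(omega), J(2*omega) vanish for very slow tumbling, leaving only the
  # magnetization-conserving zero-quantum pathway
  p <- spectroscopy_params(tau_c = 1e6, intensity_noise_sigma = 0,
                           rho_ext = 0)
  xyz <- fix_chain(6)$coords
  R <- build_relaxation_matrix(xyz, p)
  A <- msnmr:::propagate_magnetization(R$rates, c(0.008, 0.08, 0.4))
  for (a in A) expect_equal(colSums(a), rep(1, ncol(a)), tolerance = 1e-8)
})

test_that("spin diffusion inflates far cross peaks in a three-spin chain", {
  p <- fix_params(tau_c = 15)
  x3 <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  b <- simulate_noesy_buildups(x3, p)
  iac <- which(b$peaks$spin_i == 1 & b$peaks$spin_j == 3)
  R <- build_relaxation_matrix(x3, p)
  iso <- two_spin_intensity(R$rates[1, 1], R$rates[3, 3], R$rates[1, 3],
                            0.080)
  expect_gt(b$cross[iac, 7], iso$cross[1])  # 80 ms far peak
})

test_that("slow-exchange mixtures average buildups by population", {
  p <- fix_params()
  xa <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  xb <- xa; xb[3, ] <- c(0, 5.5, 0)
  mix <- ensemble_averaged_buildups(list(xa, xb), c(0.7, 0.3), p)
  ba <- simulate_noesy_buildups(xa, p); bb <- simulate_noesy_buildups(xb, p)
  expect_equal(mix$cross, 0.7 * ba$cross + 0.3 * bb$cross, tolerance = 1e-12)
})

test_that("identical seeds reproduce noisy observables bit-for-bit", {
  p <- fix_params(noise = 0.02)
  xyz <- fix_chain(6)$coords
  b1 <- simulate_noesy_buildups(xyz, p, seed = 9)
  b2 <- simulate_noesy_buildups(xyz, p, seed = 9)
  expect_identical(b1$cross, b2$cross)
  b3 <- simulate_noesy_buildups(xyz, p, seed = 10)
  expect_false(identical(b3$cross, b1$cross))
})
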