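# spin-diffusion correction, cross-relaxation fitting, distance conversion

test_that("correction is the identity when no indirect pathway exists", {
  p <- fix_params()
  xy <- rbind(c(0, 0, 0), c(3.5, 0, 0))
  b <- simulate_noesy_buildups(xy, p)
  ref <- build_relaxation_matrix(xy, p)
  corr <- correct_spin_diffusion(b, ref)
  norm <- msnmr:::normalize_buildups(simulate_noesy_buildups(xy, p))
  expect_equal(corr$cross, norm$cross, tolerance = 1e-10)
  # three spins, but reference declares the third one uncoupled
  x3 <- rbind(c(0, 0, 0), c(3, 0, 0), c(40, 40, 40))
  b3 <- simulate_noesy_buildups(x3, p, max_distance = 10)
  ref3 <- build_relaxation_matrix(x3, p)
  corr3 <- correct_spin_diffusion(b3, ref3)
  i12 <- which(corr3$peaks$spin_i == 1 & corr3$peaks$spin_j == 2)
  n3 <- msnmr:::normalize_buildups(b3)
  expect_equal(corr3$cross[i12, ], n3$cross[i12, ], tolerance = 1e-8)
})

test_that("three-spin chain: correction restores the far distance", {
  p <- fix_params(tau_c = 15)
  x3 <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  b <- simulate_noesy_buildups(x3, p)
  ref <- build_relaxation_matrix(x3, p)
  dl <- (ref$rates[1, 1] - ref$rates[3, 3]) / 2
  iac <- which(b$peaks$spin_i == 1 & b$peaks$spin_j == 3)
  raw <- msnmr:::normalize_buildups(b)
  f_raw <- fit_cross_relaxation(raw$cross[iac, ], raw$mixing_times, dl = dl)
  r_raw <- sigma_to_restraint(f_raw$sigma, p, "unidirectional")$r_hat
  corr <- correct_spin_diffusion(b, ref)
  f_cor <- fit_cross_relaxation(corr$cross[iac, ], corr$mixing_times,
                                dl = dl)
  r_cor <- sigma_to_restraint(f_cor$sigma, p, "unidirectional")$r_hat
  expect_lt(abs(r_cor - 6), 0.1)
  expect_gt(abs(r_raw - 6), 0.5)   # uncorrected badly underestimates
  expect_lt(r_raw, 6)
})

test_that("cross-relaxation fits are exact on noise-free data", {
  tau <- c(8, 16, 24, 32, 40, 48, 80)
  model <- msnmr:::two_spin_model(-0.5, 0.02, tau * 1e-3)
  fit <- fit_cross_relaxation(model, tau, dl = 0.02)
  expect_equal(fit$sigma, -0.5, tolerance = 1e-6)
  expect_error(fit_cross_relaxation(c(0.1), 8), "3 mixing-time")
  # initial-slope variant recovers the rate at short mixing times
  tau_s <- c(0.5, 1, 1.5)
  short <- msnmr:::two_spin_model(-0.5, 0, tau_s * 1e-3)
  fit2 <- fit_cross_relaxation(short, tau_s, method = "initial_slope")
  expect_equal(fit2$sigma, -0.5, tolerance = 1e-2)
})

test_that("noisy fits recover sigma within a few percent (Monte Carlo)", {
  p <- fix_params(noise = 0.02)
  xy <- rbind(c(0, 0, 0), c(3.2, 0, 0))
  R <- build_relaxation_matrix(xy, p)
  dl <- (R$rates[1, 1] - R$rates[2, 2]) / 2
  errs <- vapply(1:100, function(k) {
    b <- simulate_noesy_buildups(xy, p, seed = 1000 + k)
    nb <- msnmr:::normalize_buildups(b)
    f <- fit_cross_relaxation(nb$cross[1, ], nb$mixing_times, dl = dl)
    abs(f$sigma - R$rates[1, 2]) / abs(R$rates[1, 2])
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("sigma-to-distance conversion inverts the rate law", {
  p <- fix_params()
  R <- build_relaxation_matrix(rbind(c(0, 0, 0), c(4, 0, 0)), p)
  r <- sigma_to_restraint(R$rates[1, 2], p, "bidirectional")
  expect_equal(r$r_hat, 4, tolerance = 1e-9)
  expect_equal(r$upper - r$lower, 0.1)         # highest-precision window
  r64 <- sigma_to_restraint(R$rates[1, 2] * 64, p, "unidirectional")
  expect_equal(r64$r_hat, 2, tolerance = 1e-9)
  expect_equal(r64$upper / r64$r_hat, 1.1)
  expect_equal(r64$lower / r64$r_hat, 0.9)
  expect_error(sigma_to_restraint(-R$rates[1, 2], p), "sign")
})

test_that("full extraction round trip recovers a 20-spin structure", {
  chain <- fix_chain(10, apr = 2, seed = 5)
  p <- fix_params(noise = 0.02)
  b <- simulate_noesy_buildups(chain, p, max_distance = 5.5, seed = 42)
  ref <- build_relaxation_matrix(chain$coords, p)
  rs <- extract_distance_restraints(b, ref, chain$atoms)
  d <- rs$distance
  rtrue <- as.matrix(dist(chain$coords))[cbind(d$atom_i, d$atom_j)]
  err <- abs(attr(rs, "provenance")$r_hat - rtrue)
  expect_gte(mean(err <= 0.3), 0.9)
  bi <- d$class == "bidirectional"
  expect_gt(sum(bi), 0)
  expect_true(all(err[bi] <= 0.15))
  expect_true(all(d$lower <= d$upper))
})
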