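# mutual-information correlated-sites analysis

test_that("distance features have the declared shape and variance ordering", {
  fx <- fix_two_state(n = 12, movers = 4:9, amp = 3, noise = 0.3)
  df <- residue_distance_features(fx$ensemble, exclude_neighbors = 0)
  expect_length(df$features, 12)
  expect_identical(ncol(df$features[[1]]), 11L)   # n_residues - 1
  expect_identical(nrow(df$features[[1]]), 40L)
  # planted residues show more feature variance than static ones
  v <- vapply(df$features, function(f) mean(apply(f, 2, var)), numeric(1))
  expect_gt(mean(v[4:9]), mean(v[c(1:3, 10:12)]))
  # the motion score separates movers from statics much more sharply when
  # the moving block is a minority of the chain
  fx2 <- fix_two_state(n = 20, movers = 6:11, amp = 3, noise = 0.3)
  sc <- residue_motion_scores(residue_distance_features(fx2$ensemble))
  expect_gt(min(sc[6:11]), 1.5 * max(sc[setdiff(1:20, 6:11)]))
  # identical conformers give zero variance
  ens0 <- multistate_ensemble(
    array(rep(fx$chain$coords, 2), c(nrow(fx$chain$coords), 3, 1, 2)),
    fx$chain$atoms)
  df0 <- residue_distance_features(ens0)
  expect_true(all(vapply(df0$features, function(f)
    max(apply(f, 2, var)), numeric(1)) < 1e-20))
})

test_that("per-residue clustering recovers the planted state labels", {
  fx <- fix_two_state(n = 20, movers = 6:11, amp = 3, noise = 0.3)
  df <- residue_distance_features(fx$ensemble)
  for (i in 6:11) {
    a <- cluster_conformers(df$features[[i]], 2, seed = 100 + i)
    expect_gte(label_agreement(a$labels, fx$ensemble$state_labels), 0.95)
  }
  # degenerate features collapse to one flagged cluster
  flat <- matrix(1, 10, 5)
  a0 <- cluster_conformers(flat, 2)
  expect_true(a0$degenerate)
  expect_identical(a0$labels, rep(1L, 10))
  expect_error(cluster_conformers(matrix(1, 1, 3), 2), "fewer conformers")
  # deterministic across repeated calls
  a1 <- cluster_conformers(df$features[[7]], 2, seed = 7)
  a2 <- cluster_conformers(df$features[[7]], 2, seed = 7)
  expect_identical(a1$labels, a2$labels)
})

test_that("normalized MI is 1 for coupled labels, small for independent ones", {
  mk <- function(labels) structure(list(labels = labels, quality = 1,
                                        degenerate = FALSE),
                                   class = "StateAssignment")
  coupled <- rep(1:2, each = 20)
  m1 <- mutual_information_matrix(list(mk(coupled), mk(coupled)))
  expect_equal(m1$values[1, 2], 1)
  m2 <- mutual_information_matrix(list(mk(coupled), mk(3L - coupled)))
  expect_equal(m2$values[1, 2], 1)      # label permutation is irrelevant
  set.seed(5)
  vals <- replicate(50, {
    a <- mk(sample(1:2, 40, TRUE)); b <- mk(sample(1:2, 40, TRUE))
    mutual_information_matrix(list(a, b))$values[1, 2]
  })
  expect_lt(mean(vals), 0.15)           # finite-sample bias stays small
  # matrix structure: symmetric, unit diagonal, [0, 1]
  fx <- fix_two_state()
  cm <- cluster_ensemble(fx$ensemble, seed = 3)
  expect_identical(cm$values, t(cm$values))
  expect_true(all(diag(cm$values) == 1))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  # degenerate residues zero their off-diagonal entries
  m3 <- mutual_information_matrix(list(
    mk(coupled),
    structure(list(labels = rep(1L, 40), quality = 0, degenerate = TRUE),
              class = "StateAssignment")))
  expect_equal(m3$values[1, 2], 0)
})

test_that("MI is invariant under conformer reordering", {
  fx <- fix_two_state(n = 12)
  cm <- cluster_ensemble(fx$ensemble, seed = 3)
  perm <- sample(seq_len(fx$ensemble$n_conformers))
  ens2 <- multistate_ensemble(fx$ensemble$coords[, , , perm, drop = FALSE],
                              fx$ensemble$atoms)
  cm2 <- cluster_ensemble(ens2, seed = 3)
  expect_equal(cm2$values, cm$values, tolerance = 1e-10)
})

test_that("clustering MI agrees with the brute-force best-partition oracle", {
  fx <- fix_two_state(n = 10, movers = 3:6, n_conf = 12, noise = 0.25)
  df <- residue_distance_features(fx$ensemble)
  # oracle: exhaustively minimize the within-cluster sum of squares (the
  # same objective k-means approximates) over all 2^(n-1)-1 two-partitions
  brute <- function(f) {
    n <- nrow(f)
    best <- NULL; best_obj <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
      lab <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
      if (min(tabulate(lab, 2)) < 1) next
      obj <- sum(vapply(1:2, function(g) {
        rows <- f[lab == g, , drop = FALSE]
        sum(sweep(rows, 2, colMeans(rows))^2)
      }, numeric(1)))
      if (obj < best_obj) { best_obj <- obj; best <- lab }
    }
    best
  }
  idx <- 3:6                       # the planted residues
  oracle_labs <- lapply(df$features[idx], brute)
  pipe <- lapply(seq_along(idx), function(k)
    cluster_conformers(df$features[[idx[k]]], 2, seed = k))
  mk <- function(l) structure(list(labels = l, degenerate = FALSE),
                              class = "StateAssignment")
  for (k in seq_along(idx)) for (j in seq_along(idx)) {
    mi_pipe <- mutual_information_matrix(
      list(mk(pipe[[k]]$labels), mk(pipe[[j]]$labels)))$values[1, 2]
    mi_oracle <- mutual_information_matrix(
      list(mk(oracle_labs[[k]]), mk(oracle_labs[[j]])))$values[1, 2]
    expect_lt(abs(mi_pipe - mi_oracle), 0.05)
  }
})

test_that("top-correlated extraction recovers the planted network", {
  fx <- fix_two_state(n = 20, movers = 4:13, amp = 3, noise = 0.3,
                      seed_chain = 7, seed_ens = 11)
  cm <- cluster_ensemble(fx$ensemble, seed = 5)
  top <- top_correlated_residues(cm, k = 10)
  expect_gte(mean(top %in% 4:13), 0.9)
  expect_setequal(top_correlated_residues(cm, k = 20), 1:20)
  expect_error(top_correlated_residues(cm, k = 0), "positive")
})

test_that("consensus assignment matches the hidden states", {
  fx <- fix_two_state(n = 12, movers = 4:9, amp = 3, noise = 0.3)
  cm <- cluster_ensemble(fx$ensemble, seed = 5)
  top <- top_correlated_residues(cm, k = 6)
  cons <- consensus_state_assignment(cm, top)
  expect_gte(label_agreement(cons$labels, fx$ensemble$state_labels), 0.95)
  # single-residue consensus equals that residue's own assignment
  one <- consensus_state_assignment(cm, top[1])
  idx <- match(top[1], cm$residues)
  expect_identical(one$labels, cm$assignments[[idx]]$labels)
  # flipping a residue's labels leaves the consensus partition unchanged
  cm2 <- cm
  i2 <- match(top[2], cm2$residues)
  cm2$assignments[[i2]]$labels <- 3L - cm2$assignments[[i2]]$labels
  cons2 <- consensus_state_assignment(cm2, top)
  expect_gte(label_agreement(cons2$labels, cons$labels), 1)
})

test_that("planted-pair MI decreases as conformer noise grows", {
  mis <- vapply(c(0.2, 0.6, 1.8), function(sg) {
    fx <- fix_two_state(n = 12, movers = 4:9, amp = 3, noise = sg,
                        seed_ens = 17)
    cm <- cluster_ensemble(fx$ensemble, seed = 5)
    v <- cm$values[4:9, 4:9]
    mean(v[upper.tri(v)])
  }, numeric(1))
  expect_true(all(diff(mis) < 0))
})
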