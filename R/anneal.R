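# Simulated-annealing driver for multi-state structure calculation and the
# scans built on top of it (state number, populations).

# flat restraint arrays shared with the C++ kernel (0-based indices)
restraint_arrays <- function(restraints, bonds = NULL, bond_weight = 0.1) {
  d <- restraints$distance
  cp <- restraints$couplings
  if (is.null(cp))
    cp <- data.frame(a1 = integer(0), a2 = integer(0), a3 = integer(0),
                     a4 = integer(0), target = numeric(0), A = numeric(0),
                     B = numeric(0), C = numeric(0), tol = numeric(0))
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  sym_atoms <- which(!(restraints$atoms$resno %in% restraints$sym_exempt))
  list(di = as.integer(d$atom_i - 1L), dj = as.integer(d$atom_j - 1L),
       dup = as.numeric(d$upper), dlo = as.numeric(d$lower),
       ca1 = as.integer(cp$a1 - 1L), ca2 = as.integer(cp$a2 - 1L),
       ca3 = as.integer(cp$a3 - 1L), ca4 = as.integer(cp$a4 - 1L),
       ctar = as.numeric(cp$target), cA = as.numeric(cp$A),
       cB = as.numeric(cp$B), cC = as.numeric(cp$C),
       ctol = as.numeric(cp$tol),
       w_coupling = restraints$coupling_weight,
       sym_atoms = as.integer(sym_atoms - 1L),
       sym_width = restraints$sym_width,
       sym_weight = restraints$sym_weight,
       bi = as.integer(bonds$i - 1L), bj = as.integer(bonds$j - 1L),
       br0 = as.numeric(bonds$r0), w_bond = bond_weight)
}

# [natoms,3,nstates] -> C++ layout (xyz fastest, then atom, then state)
to_cpp_layout <- function(x) as.vector(aperm(x, c(2, 1, 3)))
from_cpp_layout <- function(v, natoms, nstates)
  aperm(array(v, c(3, natoms, nstates)), c(2, 1, 3))

#' Multi-state structure calculation by simulated annealing
#'
#' Minimizes the [target_function()] (plus weak harmonic reference bonds
#' keeping the chain connected) by Cartesian Metropolis annealing with a
#' geometric temperature and step-size schedule. Each conformer is an
#' independent run seeded deterministically from `(seed, conformer index)`;
#' the returned ensemble is sorted by target function (ties by run index).
#'
#' @param restraints a [restraint_set()]; must contain at least one distance
#'   restraint.
#' @param n_states number of simultaneously optimized states.
#' @param n_conformers number of independent annealing runs.
#' @param steps Metropolis steps per run.
#' @param seed master seed.
#' @param weights state population weights used in the r^-6 averaging
#'   (default uniform).
#' @param bonds optional data.frame `i`, `j`, `r0` of harmonic reference
#'   bonds (e.g. [chain_bonds()]); weight `bond_weight`.
#' @param bond_weight weight of the reference-bond term (excluded from the
#'   reported TF).
#' @param t0,t1 initial/final temperature of the geometric schedule.
#' @param step0,step1 initial/final Gaussian move size (Angstrom).
#' @param init optional `natoms x 3 x n_states (x n_conformers)` starting
#'   coordinates; by default runs start from a random cloud sized to the
#'   chain.
#' @param split_t0,split_noise multi-state runs use a continuation
#'   protocol: half the steps anneal a collapsed (single-state) model,
#'   which is then replicated into `n_states` copies perturbed by
#'   `split_noise` (Angstrom) and relaxed at the low temperature
#'   `split_t0`, letting mutually inconsistent restraints pull the states
#'   apart. Starting the multi-state search hot instead tends to freeze
#'   all states into one compromise structure.
#' @param polish run a deterministic L-BFGS minimization from each
#'   annealed model (recommended: removes run-to-run stochastic residuals,
#'   so TF differences between calculations reflect the data, not the
#'   annealing noise).
#' @param polish_maxit iteration cap for the polish step.
#' @return a `MultiStateEnsemble` with per-conformer `$tf`.
#' @export
anneal_multistate <- function(restraints, n_states = 2L, n_conformers = 10L,
                              steps = 30000L, seed = 1L, weights = NULL,
                              bonds = NULL, bond_weight = 0.1,
                              t0 = 5, t1 = 1e-4, step0 = 2.0, step1 = 0.02,
                              init = NULL, split_t0 = 0.2,
                              split_noise = 0.8, polish = TRUE,
                              polish_maxit = 200L) {
  stopifnot(inherits(restraints, "RestraintSet"))
  if (nrow(restraints$distance) == 0) stop("no distance restraints")
  if (steps < 1) stop("steps must be >= 1")
  natoms <- nrow(restraints$atoms)
  n_states <- as.integer(n_states)
  if (is.null(weights)) weights <- rep(1 / n_states, n_states)
  check_weights(weights, n_states)
  arrays <- restraint_arrays(restraints, bonds, bond_weight)
  radius <- 2.5 * natoms^(1 / 3)
  if (!is.null(init) && length(dim(init)) == 3L)
    init <- array(init, c(dim(init), n_conformers))

  coords <- array(NA_real_, c(natoms, 3L, n_states, n_conformers))
  tf <- numeric(n_conformers)
  run_one <- function(c, seed_c) {
    set.seed(seed_c)
    if (!is.null(init)) {
      x0 <- array(init[, , , c], c(natoms, 3L, n_states))
      return(.anneal_cpp(to_cpp_layout(x0), natoms, n_states, arrays,
                         weights, as.integer(steps), t0, t1, step0, step1))
    }
    base <- matrix(runif(natoms * 3, -radius, radius), natoms, 3)
    if (n_states == 1L) {
      x0 <- array(base, c(natoms, 3L, 1L))
      return(.anneal_cpp(to_cpp_layout(x0), natoms, 1L, arrays,
                         weights, as.integer(steps), t0, t1, step0, step1))
    }
    # continuation: fold one state, then split it into n_states copies
    half <- max(1L, as.integer(steps) %/% 2L)
    one <- .anneal_cpp(to_cpp_layout(array(base, c(natoms, 3L, 1L))),
                       natoms, 1L, arrays, 1.0, half, t0, t1, step0, step1)
    folded <- from_cpp_layout(one$coords, natoms, 1L)
    x0 <- array(NA_real_, c(natoms, 3L, n_states))
    for (s in seq_len(n_states))
      x0[, , s] <- folded[, , 1] +
        matrix(rnorm(natoms * 3, sd = split_noise), natoms, 3)
    .anneal_cpp(to_cpp_layout(x0), natoms, n_states, arrays, weights,
                half, split_t0, t1, 1.0, step1)
  }
  polish_run <- function(res) {
    if (!polish) return(res)
    fn <- function(v) .energy_cpp(v, natoms, n_states, arrays, weights)$energy
    gr <- function(v) .energy_grad_cpp(v, natoms, n_states, arrays,
                                       weights, 1e-5)$grad
    opt <- tryCatch(
      stats::optim(res$coords, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = polish_maxit, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value > res$energy)
      return(res)
    list(coords = opt$par,
         tf = .energy_cpp(opt$par, natoms, n_states, arrays, weights)$tf,
         energy = opt$value)
  }
  for (c in seq_len(n_conformers)) {
    res <- run_one(c, derive_seed(seed, c))
    if (!is.finite(res$energy)) {         # restart once from a fresh seed
      message("annealing run ", c, " diverged; restarting")
      res <- run_one(c, derive_seed(seed, c, 999L))
    }
    res <- polish_run(res)
    coords[, , , c] <- from_cpp_layout(res$coords, natoms, n_states)
    tf[c] <- res$tf
  }
  ord <- order(tf, seq_along(tf))
  multistate_ensemble(coords[, , , ord, drop = FALSE], restraints$atoms,
                      tf = tf[ord], weights = weights)
}

#' Keep the lowest-target-function conformers
#'
#' @param ensemble an annealed `MultiStateEnsemble` with `$tf`.
#' @param k number of conformers to keep (`1 <= k <= n_conformers`); ties in
#'   TF are broken by conformer index.
#' @return the reduced ensemble.
#' @export
select_lowest_tf <- function(ensemble, k) {
  stopifnot(inherits(ensemble, "MultiStateEnsemble"))
  if (k <= 0) stop("k must be positive")
  if (k > ensemble$n_conformers) stop("k exceeds the number of conformers")
  if (is.null(ensemble$tf)) stop("ensemble carries no TF values")
  ord <- order(ensemble$tf, seq_along(ensemble$tf))[seq_len(k)]
  multistate_ensemble(ensemble$coords[, , , ord, drop = FALSE],
                      ensemble$atoms, tf = ensemble$tf[ord],
                      weights = ensemble$weights,
                      state_labels = ensemble$state_labels[ord])
}

#' Scan the number of states against the target function
#'
#' Runs the annealer for each state count and reports the median and best
#' TF. The selected state number is the smallest N whose relative TF
#' improvement over N-1 falls below `threshold`, or whose TF is already
#' below `tf_floor` (the data are then fully explained and additional
#' states are not warranted).
#'
#' @param restraints a `RestraintSet`.
#' @param n_range state counts to scan (default 1:9).
#' @param threshold relative improvement below which the scan plateaus
#'   (default 0.2).
#' @param tf_floor absolute TF below which a model counts as fitting the
#'   data.
#' @param ... passed to [anneal_multistate()] (`n_conformers`, `steps`,
#'   `seed`, ...).
#' @return list with `table` (data.frame `n_states`, `tf_median`,
#'   `tf_best`) and `selected`.
#' @export
state_number_scan <- function(restraints, n_range = 1:9, threshold = 0.2,
                              tf_floor = 0.1, ...) {
  if (!length(n_range)) stop("empty state-number range")
  tab <- data.frame(n_states = n_range, tf_median = NA_real_,
                    tf_best = NA_real_)
  ensembles <- vector("list", length(n_range))
  for (k in seq_along(n_range)) {
    ens <- anneal_multistate(restraints, n_states = n_range[k], ...)
    ensembles[[k]] <- ens
    tab$tf_median[k] <- stats::median(ens$tf)
    tab$tf_best[k] <- min(ens$tf)
  }
  selected <- n_range[length(n_range)]
  for (k in seq_along(n_range)) {
    if (tab$tf_median[k] <= tf_floor) { selected <- n_range[k]; break }
    if (k > 1) {
      impr <- (tab$tf_median[k - 1] - tab$tf_median[k]) /
        max(tab$tf_median[k - 1], 1e-12)
      if (impr < threshold) { selected <- n_range[k - 1]; break }
    }
  }
  list(table = tab, selected = selected, ensembles = ensembles)
}

#' Estimate state populations from the target-function curve
#'
#' Re-evaluates (mode `"refit"`: a short warm-started quench from one
#' annealed reference model) or fully re-anneals (mode `"reanneal"`) the
#' two-state model at each population weight on a grid, and returns the
#' weight minimizing the TF. The TF is invariant under jointly swapping
#' states and weights, so the identifiable quantity is the population pair;
#' warm-starting from a single reference model anchors the state labels
#' along the curve.
#'
#' @param restraints a `RestraintSet`.
#' @param grid population weights of state 1 to evaluate, inside (0,1).
#' @param mode `"refit"` (default, fast) or `"reanneal"`.
#' @param n_conformers,steps,seed annealing controls for the reference
#'   model (and, in `"reanneal"` mode, each grid point).
#' @param n_track how many of the best reference conformers are tracked
#'   along the grid in `"refit"` mode (their TFs are averaged).
#' @param anchors weights at which full reference calculations are run in
#'   `"refit"` mode; the curve is the pointwise minimum over anchors.
#' @param refit_steps quench length per grid point in `"refit"` mode.
#' @param ... passed to [anneal_multistate()].
#' @return list with `curve` (data.frame `w`, `tf`), `w_hat` (argmin),
#'   and `model` (the reference ensemble).
#' @export
population_scan <- function(restraints, grid = seq(0.1, 0.9, by = 0.05),
                            mode = c("refit", "reanneal"),
                            n_conformers = 5L, n_track = 3L, steps = 30000L,
                            seed = 1L, refit_steps = 8000L,
                            anchors = c(0.3, 0.5, 0.7), ...) {
  mode <- match.arg(mode)
  if (any(grid <= 0 | grid >= 1)) stop("population grid must be inside (0,1)")
  grid <- sort(grid)
  ref <- anneal_multistate(restraints, n_states = 2L,
                           n_conformers = n_conformers, steps = steps,
                           seed = seed, ...)
  if (mode == "reanneal") {
    tf <- vapply(seq_along(grid), function(k) {
      w <- c(grid[k], 1 - grid[k])
      min(anneal_multistate(restraints, n_states = 2L,
                            n_conformers = n_conformers, steps = steps,
                            seed = derive_seed(seed, k),
                            weights = w, ...)$tf)
    }, numeric(1))
    return(list(curve = data.frame(w = grid, tf = tf),
                w_hat = grid[which.min(tf)], model = ref))
  }
  # continuation refit: models are annealed at a few anchor weights, then
  # each model is quenched along the grid starting from its anchor, so
  # annealing noise is correlated along each track and no track can jump
  # between state-swap basins. The reported curve is the pointwise minimum
  # over anchors of the per-anchor mean track: the anchor closest to the
  # true populations produces the best-fitting models near them, which
  # removes the bias a single uniform-weight reference would impose.
  n_track <- min(n_track, n_conformers)
  natoms <- dim(ref$coords)[1]
  per_anchor <- matrix(NA_real_, length(anchors), length(grid))
  for (ai in seq_along(anchors)) {
    a <- anchors[ai]
    ens_a <- if (abs(a - 0.5) < 1e-9) ref else
      anneal_multistate(restraints, n_states = 2L,
                        n_conformers = n_conformers, steps = steps,
                        seed = derive_seed(seed, 500L + ai),
                        weights = c(a, 1 - a), ...)
    tfmat <- matrix(NA_real_, n_track, length(grid))
    start <- which.min(abs(grid - a))
    for (m in seq_len(n_track)) {
      base <- array(ens_a$coords[, , , m], c(natoms, 3L, 2L))
      for (branch in list(start:length(grid), rev(seq_len(start)))) {
        cur <- base
        for (k in branch) {
          w <- c(grid[k], 1 - grid[k])
          ens <- anneal_multistate(restraints, n_states = 2L,
                                   n_conformers = 1L, steps = refit_steps,
                                   seed = derive_seed(seed, ai, m, k),
                                   weights = w, init = cur,
                                   t0 = 0.1, t1 = 1e-6, step0 = 0.4,
                                   step1 = 0.005, ...)
          cur <- array(ens$coords[, , , 1], c(natoms, 3L, 2L))
          tfmat[m, k] <- ens$tf[1]
        }
      }
    }
    per_anchor[ai, ] <- apply(tfmat, 2, mean)
  }
  tf <- apply(per_anchor, 2, min)
  list(curve = data.frame(w = grid, tf = tf),
       w_hat = grid[which.min(tf)], model = ref, tf_anchors = per_anchor)
}
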