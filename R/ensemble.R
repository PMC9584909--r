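#' Construct a multi-state ensemble object
#'
#' The central container of the package: `n_conformers` independent
#' solutions, each holding one coordinate set per exchanging state. A
#' conventional conformer bundle (e.g. a deposited NMR ensemble, or the
#' output of the synthetic generator where every conformer realises a single
#' hidden state) is the `n_states = 1` case.
#'
#' @param coords numeric array `n_atoms x 3 x n_states x n_conformers`
#'   (Angstrom). A plain `n_atoms x 3` matrix is promoted to a single
#'   conformer of a single state.
#' @param atoms data.frame with at least `elety` and `resno` per atom.
#' @param state_labels optional integer vector of per-conformer hidden state
#'   labels (synthetic ground truth, kept for oracle tests).
#' @param tf optional numeric vector of per-conformer target-function values.
#' @param weights optional state population weights (non-negative, sum 1).
#' @return object of class `MultiStateEnsemble`.
#' @export
multistate_ensemble <- function(coords, atoms, state_labels = NULL,
                                tf = NULL, weights = NULL) {
  if (is.matrix(coords)) dim(coords) <- c(dim(coords), 1L, 1L)
  if (length(dim(coords)) == 3L) dim(coords) <- c(dim(coords), 1L)
  stopifnot(length(dim(coords)) == 4L, dim(coords)[2] == 3L)
  if (nrow(atoms) != dim(coords)[1])
    stop("atoms table does not match coordinate array")
  n_states <- dim(coords)[3]; n_conf <- dim(coords)[4]
  if (!is.null(state_labels)) stopifnot(length(state_labels) == n_conf)
  if (!is.null(tf)) stopifnot(length(tf) == n_conf)
  if (is.null(weights)) weights <- rep(1 / n_states, n_states)
  check_weights(weights, n_states)
  structure(list(coords = coords, atoms = atoms, n_states = n_states,
                 n_conformers = n_conf, state_labels = state_labels,
                 tf = tf, weights = weights),
            class = "MultiStateEnsemble")
}

check_weights <- function(weights, n_states) {
  if (length(weights) != n_states || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("state weights must be non-negative and sum to 1")
  invisible(weights)
}

#' @export
print.MultiStateEnsemble <- function(x, ...) {
  cat(sprintf("MultiStateEnsemble: %d atoms, %d state(s) x %d conformer(s)\n",
              dim(x$coords)[1], x$n_states, x$n_conformers))
  if (!is.null(x$tf))
    cat(sprintf("  target function: best %.4g, median %.4g\n",
                min(x$tf), stats::median(x$tf)))
  invisible(x)
}

#' Flatten the states of an ensemble into plain conformers
#'
#' Converts an `n_states x n_conformers` ensemble into a single-state
#' ensemble of `n_states * n_conformers` structures (conformer-major,
#' state-minor order), which is what the correlation analysis consumes.
#' Already-flat ensembles are returned unchanged.
#'
#' @param ensemble a [multistate_ensemble()].
#' @return a `MultiStateEnsemble` with `n_states = 1`; the originating state
#'   index of every flattened structure is kept in `state_labels`.
#' @export
flatten_states <- function(ensemble) {
  stopifnot(inherits(ensemble, "MultiStateEnsemble"))
  if (ensemble$n_states == 1L) return(ensemble)
  d <- dim(ensemble$coords)
  out <- array(NA_real_, c(d[1], 3L, 1L, d[3] * d[4]))
  labels <- integer(d[3] * d[4]); k <- 0L
  for (c in seq_len(d[4])) for (s in seq_len(d[3])) {
    k <- k + 1L
    out[, , 1L, k] <- ensemble$coords[, , s, c]
    labels[k] <- s
  }
  multistate_ensemble(out, ensemble$atoms, state_labels = labels)
}

#' Specify a planted two-state displacement
#'
#' Defines the hidden ground truth of a synthetic ensemble: a chosen subset
#' of residues moves coherently (same displacement vector) by a fixed
#' amplitude between two exchanging states, while every other residue only
#' jitters isotropically. Any fraction of the chain can be made correlated,
#' emulating folds in which most of the domain shuffles between two states.
#'
#' @param correlated_residues integer set of residue indices carrying the
#'   two-state displacement.
#' @param displacement_amplitude inter-state displacement in Angstrom (>= 0).
#' @param state_populations two fractions in (0,1) summing to 1.
#' @param conformer_noise_sigma isotropic per-atom Gaussian noise (Angstrom).
#' @param n_conformers number of conformers generated.
#' @return object of class `PlantedTwoStateSpec`.
#' @export
planted_two_state_spec <- function(correlated_residues,
                                   displacement_amplitude,
                                   state_populations = c(0.5, 0.5),
                                   conformer_noise_sigma = 0.3,
                                   n_conformers = 40L) {
  if (displacement_amplitude < 0)
    stop("displacement_amplitude must be >= 0")
  p <- state_populations
  if (length(p) != 2 || any(p <= 0) || any(p >= 1) || abs(sum(p) - 1) > 1e-8)
    stop("state_populations must be two fractions in (0,1) summing to 1")
  if (length(correlated_residues) == 0 && displacement_amplitude > 0)
    stop("two states requested but the correlated residue set is empty")
  if (conformer_noise_sigma < 0) stop("conformer_noise_sigma must be >= 0")
  structure(list(correlated_residues = as.integer(correlated_residues),
                 displacement_amplitude = displacement_amplitude,
                 state_populations = p,
                 conformer_noise_sigma = conformer_noise_sigma,
                 n_conformers = as.integer(n_conformers)),
            class = "PlantedTwoStateSpec")
}

#' Generate a planted two-state conformer ensemble
#'
#' State 1 is the toy chain itself; state 2 displaces all atoms of each
#' correlated residue by the planted amplitude along that residue's own
#' random direction. The displacement is coherent: the direction belongs to
#' the state, so every conformer of state 2 carries the identical
#' rearrangement (an internal two-state motion, not a rigid translation of
#' a block). Conformers are allocated to states deterministically (floor of
#' the population times `n_conformers`, remainder to state 1) so
#' exact-fraction cases are reproducible, then each conformer receives
#' independent isotropic Gaussian noise. True state labels and the
#' noise-free state coordinates are retained for oracle tests.
#'
#' @param chain a [build_toy_chain()] result.
#' @param planted a [planted_two_state_spec()].
#' @param seed integer seed (defaults to the chain seed + 1).
#' @return a single-state `MultiStateEnsemble` of `n_conformers` structures
#'   with `state_labels` set; attribute `planted` stores the ground truth
#'   (state coordinate sets, displacement vector, populations).
#' @export
generate_two_state_ensemble <- function(chain, planted,
                                        seed = chain$spec$seed + 1L) {
  stopifnot(inherits(chain, "ToyChain"),
            inherits(planted, "PlantedTwoStateSpec"))
  if (length(planted$correlated_residues) &&
      !all(planted$correlated_residues %in% chain$atoms$resno))
    stop("correlated residue set is not a subset of the chain residues")
  set.seed(seed)
  n_atoms <- nrow(chain$coords)
  cres <- planted$correlated_residues
  u <- random_unit_vector(max(1, length(cres)))   # one direction per residue
  state1 <- chain$coords
  state2 <- chain$coords
  for (k in seq_along(cres)) {
    rows <- which(chain$atoms$resno == cres[k])
    state2[rows, ] <- sweep(state2[rows, , drop = FALSE], 2,
                            planted$displacement_amplitude * u[k, ], `+`)
  }
  # both states share the covalent geometry: project the displaced state
  # back onto the chain's bond lengths (only correlated residues move)
  if (planted$displacement_amplitude > 0 && length(cres)) {
    ca <- which(chain$atoms$elety == "CA")
    ca <- ca[order(chain$atoms$resno[ca])]
    free <- chain$atoms$resno[ca] %in% cres
    base_ca <- state1[ca, , drop = FALSE]
    ca2 <- state2[ca, , drop = FALSE]
    # alternating projections: keep the chain's bond lengths while holding
    # every correlated residue's displacement at the planted amplitude
    for (it in 1:40) {
      ca2 <- project_chain_bonds(ca2, free, chain$spec$bond_length,
                                 iters = 5L)
      dv <- ca2 - base_ca
      nrm <- sqrt(rowSums(dv^2))
      scale <- ifelse(free & nrm > 1e-9,
                      planted$displacement_amplitude / nrm, 1)
      ca2 <- base_ca + dv * scale
    }
    ca2 <- project_chain_bonds(ca2, free, chain$spec$bond_length,
                               iters = 200L)
    shift <- ca2 - state2[ca, , drop = FALSE]
    state2[ca, ] <- ca2
    h <- which(chain$atoms$elety != "CA")
    if (length(h)) {   # pseudo-protons ride rigidly on their Calpha
      hm <- match(chain$atoms$resno[h], chain$atoms$resno[ca])
      state2[h, ] <- state2[h, ] + shift[hm, , drop = FALSE]
    }
  }

  n <- planted$n_conformers
  n1 <- floor(planted$state_populations[1] * n)
  n2 <- floor(planted$state_populations[2] * n)
  n1 <- n1 + (n - n1 - n2)          # remainder goes to state 1
  labels <- rep(c(1L, 2L), c(n1, n - n1))

  coords <- array(NA_real_, c(n_atoms, 3L, 1L, n))
  for (c in seq_len(n)) {
    base <- if (labels[c] == 1L) state1 else state2
    coords[, , 1L, c] <- base +
      matrix(rnorm(n_atoms * 3, sd = planted$conformer_noise_sigma),
             n_atoms, 3)
  }
  ens <- multistate_ensemble(coords, chain$atoms, state_labels = labels)
  attr(ens, "planted") <- list(states = list(state1, state2),
                               directions = u,
                               populations = planted$state_populations,
                               correlated_residues =
                                 planted$correlated_residues,
                               spec = planted)
  ens
}

# Gauss-Seidel projection of a Calpha trace onto fixed sequential bond
# lengths; only atoms with free = TRUE may move. Keeps the displaced
# geometry as close as possible to its target while restoring the covalent
# (virtual-bond) constraints both states must share.
project_chain_bonds <- function(x, free, r0, iters = 200L, tol = 1e-9) {
  n <- nrow(x)
  for (it in seq_len(iters)) {
    worst <- 0
    for (b in seq_len(n - 1)) {
      i <- b; j <- b + 1
      if (!free[i] && !free[j]) next
      v <- x[j, ] - x[i, ]
      d <- sqrt(sum(v^2))
      err <- d - r0
      worst <- max(worst, abs(err))
      if (d < 1e-12) { v <- c(1, 0, 0); d <- 1 }
      corr <- err * v / d
      if (free[i] && free[j]) {
        x[i, ] <- x[i, ] + corr / 2
        x[j, ] <- x[j, ] - corr / 2
      } else if (free[j]) {
        x[j, ] <- x[j, ] - corr
      } else {
        x[i, ] <- x[i, ] + corr
      }
    }
    if (worst < tol) break
  }
  x
}

# Calpha coordinates of one flattened conformer, ordered by residue number
ca_coords <- function(ensemble, conformer = 1L, state = 1L) {
  idx <- which(ensemble$atoms$elety == "CA")
  idx <- idx[order(ensemble$atoms$resno[idx])]
  list(xyz = ensemble$coords[idx, , state, conformer, drop = FALSE][, , 1, 1],
       resno = ensemble$atoms$resno[idx])
}
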