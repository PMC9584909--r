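#' Construct a restraint set
#'
#' Container for the experimental input of the multi-state engine:
#' upper/lower distance limits (with their precision class), scalar-coupling
#' restraints, and the flat-bottom symmetry restraints that keep the states
#' of one conformer in proximity.
#'
#' @param distance data.frame with `atom_i`, `atom_j`, `upper`, `lower`
#'   (Angstrom) and optionally `class`, `sigma`, `sigma_se`.
#' @param couplings optional data.frame with `a1..a4` (atom indices of the
#'   torsion), `target` (Hz), `A`, `B`, `C` (Karplus, Hz), `tol` (Hz).
#' @param atoms atom table (`elety`, `resno`) the restraints refer to.
#' @param sym_width flat-bottom half-width of the symmetry restraints in
#'   Angstrom: inter-state displacements below this are not penalized.
#' @param sym_weight weight of the symmetry term in the target function.
#' @param sym_exempt residues exempted from symmetry restraints (flexible
#'   regions allowed extra inter-state amplitude).
#' @param coupling_weight weight of the scalar-coupling term.
#' @return object of class `RestraintSet`.
#' @export
restraint_set <- function(distance, couplings = NULL, atoms,
                          sym_width = 1.2, sym_weight = 0.1,
                          sym_exempt = integer(0), coupling_weight = 1.0) {
  stopifnot(is.data.frame(distance),
            all(c("atom_i", "atom_j", "upper", "lower") %in% names(distance)))
  if (any(distance$lower > distance$upper + 1e-9))
    stop("lower limit exceeds upper limit for restraint(s) ",
         paste(which(distance$lower > distance$upper + 1e-9), collapse = ","))
  if (any(distance$lower <= 0)) stop("lower limits must be positive")
  if (sym_width <= 0) stop("symmetry well bottom width must be positive")
  if (length(sym_exempt) && !all(sym_exempt %in% atoms$resno))
    stop("symmetry-exempt range outside the chain")
  if (is.null(distance$class)) distance$class <- "unidirectional"
  structure(list(distance = distance, couplings = couplings, atoms = atoms,
                 sym_width = sym_width, sym_weight = sym_weight,
                 sym_exempt = as.integer(sym_exempt),
                 coupling_weight = coupling_weight),
            class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf("RestraintSet: %d distance restraints (%d bidirectional), %d couplings\n",
              nrow(x$distance), sum(x$distance$class == "bidirectional"),
              if (is.null(x$couplings)) 0L else nrow(x$couplings)))
  invisible(x)
}

#' Number of restraints
#' @param restraints a `RestraintSet`.
#' @return named vector with distance/coupling counts.
#' @export
restraint_counts <- function(restraints) {
  c(distance = nrow(restraints$distance),
    bidirectional = sum(restraints$distance$class == "bidirectional"),
    couplings = if (is.null(restraints$couplings)) 0L
                else nrow(restraints$couplings))
}

#' Back-calculate distance restraints from known state coordinates
#'
#' Produces the restraints an ideal eNOE experiment on a slow-exchange state
#' mixture would deliver: for every atom pair within the NOE cutoff the
#' population-weighted r^-6 effective distance over the states, bracketed by
#' a narrow window. Used to plant ground-truth data for the annealer and in
#' self-consistency tests.
#'
#' @param state_coords list of `n x 3` coordinate matrices (one per state),
#'   or a single matrix for a rigid structure.
#' @param atoms atom table.
#' @param populations state populations (default uniform).
#' @param cutoff NOE observability cutoff on the effective distance
#'   (Angstrom).
#' @param window full width of the upper-lower window (Angstrom).
#' @param min_seq_sep minimum residue separation |i-j| of restrained pairs
#'   (1 keeps sequential contacts).
#' @param ... further arguments passed to [restraint_set()].
#' @return a [restraint_set()].
#' @export
restraints_from_states <- function(state_coords, atoms, populations = NULL,
                                   cutoff = 7.0, window = 0.1,
                                   min_seq_sep = 1L, ...) {
  if (is.matrix(state_coords)) state_coords <- list(state_coords)
  ns <- length(state_coords)
  if (is.null(populations)) populations <- rep(1 / ns, ns)
  check_weights(populations, ns)
  n <- nrow(state_coords[[1]])
  d6 <- matrix(0, n, n)
  for (s in seq_len(ns)) {
    r <- as.matrix(stats::dist(state_coords[[s]]))
    d6 <- d6 + populations[s] * r^-6
  }
  diag(d6) <- NA
  reff <- d6^(-1 / 6)
  pairs <- which(upper.tri(reff), arr.ind = TRUE)
  sep <- abs(atoms$resno[pairs[, 1]] - atoms$resno[pairs[, 2]])
  keep <- reff[pairs] <= cutoff & sep >= min_seq_sep
  pairs <- pairs[keep, , drop = FALSE]
  r <- reff[pairs]
  restraint_set(
    distance = data.frame(atom_i = pairs[, 1], atom_j = pairs[, 2],
                          upper = r + window / 2,
                          lower = pmax(r - window / 2, 0.01),
                          class = "bidirectional"),
    atoms = atoms, ...)
}

#' Back-calculate scalar-coupling restraints from known state coordinates
#'
#' For every window of four consecutive Calpha pseudo-atoms, the target
#' coupling is the population-weighted mean of the per-state Karplus
#' couplings -- scalar couplings average linearly under conformational
#' exchange, which makes them strongly population-sensitive restraints.
#'
#' @param state_coords list of state coordinate matrices (or one matrix).
#' @param atoms atom table.
#' @param populations state populations (default uniform).
#' @param karplus a [karplus_params()].
#' @param tol restraint tolerance in Hz (violations inside it are free).
#' @param noise_sigma additive Gaussian noise on the targets (Hz).
#' @param seed seed for the noise.
#' @return data.frame `a1..a4`, `target`, `A`, `B`, `C`, `tol` suitable for
#'   [restraint_set()]'s `couplings` argument.
#' @export
coupling_restraints_from_states <- function(state_coords, atoms,
                                            populations = NULL,
                                            karplus = karplus_params(),
                                            tol = 0.1, noise_sigma = 0,
                                            seed = 1L) {
  if (is.matrix(state_coords)) state_coords <- list(state_coords)
  ns <- length(state_coords)
  if (is.null(populations)) populations <- rep(1 / ns, ns)
  check_weights(populations, ns)
  ca <- which(atoms$elety == "CA")
  ca <- ca[order(atoms$resno[ca])]
  n <- length(ca)
  if (n < 4) stop("chain too short for torsion restraints")
  rows <- lapply(seq_len(n - 3), function(k) {
    at <- ca[k:(k + 3)]
    j <- 0
    for (s in seq_len(ns)) {
      ct <- torsion_cos(state_coords[[s]][at, ])
      j <- j + populations[s] *
        (karplus$A * ct^2 + karplus$B * ct + karplus$C)
    }
    data.frame(a1 = at[1], a2 = at[2], a3 = at[3], a4 = at[4], target = j,
               A = karplus$A, B = karplus$B, C = karplus$C, tol = tol)
  })
  out <- do.call(rbind, rows)
  if (noise_sigma > 0) {
    set.seed(seed)
    out$target <- out$target + rnorm(nrow(out), sd = noise_sigma)
  }
  out
}

#' Randomly subsample distance restraints
#'
#' Keeps a given fraction of the distance restraints, drawn uniformly at
#' random; couplings and symmetry settings are untouched. `fraction = 1`
#' returns the set unchanged (identical order).
#'
#' @param restraints a `RestraintSet`.
#' @param fraction fraction in (0, 1] to retain.
#' @param seed integer seed.
#' @return a `RestraintSet`.
#' @export
subsample_restraints <- function(restraints, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(restraints)
  set.seed(seed)
  n <- nrow(restraints$distance)
  keep <- sort(sample.int(n, max(1, round(fraction * n))))
  restraints$distance <- restraints$distance[keep, , drop = FALSE]
  restraints
}
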