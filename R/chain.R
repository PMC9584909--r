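#' Specify a toy polypeptide chain
#'
#' A toy chain is a self-avoiding random walk of pseudo-Calpha atoms with a
#' fixed bond length, optionally decorated with pseudo-protons attached to
#' each Calpha. It stands in for a compact protein fold: it produces the
#' short interatomic distances (2-6 Angstrom) that give observable NOEs,
#' without any force-field realism.
#'
#' @param n_residues number of residues (>= 5).
#' @param atoms_per_residue atoms per residue: one Calpha plus
#'   `atoms_per_residue - 1` pseudo-protons.
#' @param bond_length Calpha-Calpha spacing in Angstrom (default 3.8, the
#'   trans peptide value).
#' @param clash minimum distance allowed between non-bonded Calpha atoms.
#' @param compactness confinement radius multiplier; the walk is kept within
#'   `compactness * bond_length * n_residues^(1/3)` of its start, which
#'   yields globular-protein-like packing densities.
#' @param h_dist_range range (Angstrom) for the Calpha-pseudo-proton bond.
#' @param seed integer seed; the same seed gives bit-identical chains.
#' @return an object of class `ToyChainSpec`.
#' @seealso [build_toy_chain()]
#' @export
toy_chain_spec <- function(n_residues, atoms_per_residue = 1L,
                           bond_length = 3.8, clash = 3.4,
                           compactness = 1.35, h_dist_range = c(1.0, 2.5),
                           seed = 1L) {
  if (n_residues < 5) stop("n_residues must be >= 5")
  if (atoms_per_residue < 1) stop("atoms_per_residue must be >= 1")
  if (bond_length <= 0) stop("bond_length must be positive")
  if (length(h_dist_range) != 2 || any(h_dist_range <= 0) ||
      h_dist_range[1] > h_dist_range[2])
    stop("h_dist_range must be an increasing positive pair")
  structure(list(n_residues = as.integer(n_residues),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 bond_length = bond_length, clash = clash,
                 compactness = compactness, h_dist_range = h_dist_range,
                 seed = as.integer(seed)),
            class = "ToyChainSpec")
}

random_unit_vector <- function(n = 1) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Build a toy chain from its specification
#'
#' Runs the confined self-avoiding walk. Every Calpha-Calpha bond has exactly
#' the specified length; pseudo-protons are placed at a random direction and
#' a random distance within `h_dist_range` from their Calpha.
#'
#' @param spec a [toy_chain_spec()].
#' @param max_restarts how many times the whole walk may be restarted when it
#'   traps itself before giving up.
#' @return an object of class `ToyChain`: list with `coords` (n_atoms x 3
#'   matrix, Angstrom), `atoms` (data.frame with `eleno`, `elety`, `resno`),
#'   and the `spec`.
#' @export
build_toy_chain <- function(spec, max_restarts = 50L) {
  stopifnot(inherits(spec, "ToyChainSpec"))
  set.seed(spec$seed)
  n <- spec$n_residues
  radius <- spec$compactness * spec$bond_length * n^(1 / 3)
  for (attempt in seq_len(max_restarts)) {
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in seq_len(n)[-1]) {
      placed <- FALSE
      for (try in 1:200) {
        cand <- ca[i - 1, ] + spec$bond_length * drop(random_unit_vector())
        if (sqrt(sum(cand^2)) > radius) next
        if (i > 2) {
          d2 <- rowSums(sweep(ca[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
          if (min(d2) < spec$clash^2) next
        }
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("self-avoiding walk failed; relax clash/compactness")

  npr <- spec$atoms_per_residue - 1L
  coords <- matrix(NA_real_, n * spec$atoms_per_residue, 3)
  elety <- character(nrow(coords)); resno <- integer(nrow(coords))
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    coords[k, ] <- ca[i, ]; elety[k] <- "CA"; resno[k] <- i
    if (npr > 0) for (h in seq_len(npr)) {
      k <- k + 1L
      d <- runif(1, spec$h_dist_range[1], spec$h_dist_range[2])
      coords[k, ] <- ca[i, ] + d * drop(random_unit_vector())
      elety[k] <- paste0("H", h); resno[k] <- i
    }
  }
  atoms <- data.frame(eleno = seq_len(k), elety = elety, resno = resno,
                      stringsAsFactors = FALSE)
  structure(list(coords = coords, atoms = atoms, spec = spec),
            class = "ToyChain")
}

#' Bonded topology of a toy chain
#'
#' Harmonic reference bonds used by the annealer to keep unrestrained atoms
#' attached: consecutive Calpha atoms at the chain bond length and each
#' pseudo-proton at its generated distance from its Calpha.
#'
#' @param chain a [build_toy_chain()] result.
#' @return data.frame with columns `i`, `j` (atom indices) and `r0` (Angstrom).
#' @export
chain_bonds <- function(chain) {
  stopifnot(inherits(chain, "ToyChain"))
  at <- chain$atoms
  ca_idx <- which(at$elety == "CA")
  bi <- ca_idx[-length(ca_idx)]; bj <- ca_idx[-1]
  hi <- which(at$elety != "CA")
  if (length(hi)) {
    hj <- ca_idx[match(at$resno[hi], at$resno[ca_idx])]
    bi <- c(bi, hi); bj <- c(bj, hj)
  }
  r0 <- sqrt(rowSums((chain$coords[bi, , drop = FALSE] -
                      chain$coords[bj, , drop = FALSE])^2))
  data.frame(i = bi, j = bj, r0 = r0)
}
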