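#' Simulate NOESY buildup series through the full relaxation matrix
#'
#' Cross- and diagonal-peak intensities are the elements of
#' `exp(-R tau_m)` for the full dipolar relaxation matrix `R` of the
#' selected spins, so indirect (spin-diffusion) transfer pathways are fully
#' present in the simulated data. Multiplicative Gaussian noise with the
#' relative sigma from `params` is applied to every intensity.
#'
#' @param coords single-conformer `n x 3` coordinates (Angstrom) or a
#'   `ToyChain`.
#' @param params a [spectroscopy_params()].
#' @param spins indices of the spins to simulate (>= 2).
#' @param max_distance only emit cross peaks for spin pairs closer than this
#'   (Angstrom); mimics the NOE observability cutoff. `Inf` keeps all pairs.
#' @param seed seed for the intensity noise.
#' @return object of class `BuildupSet`: `peaks` (data.frame `peak_id`,
#'   `spin_i`, `spin_j`), `cross` (peaks x mixing times), `diagonal`
#'   (spins x mixing times), `mixing_times` (ms), flags `normalized` and
#'   `corrected`.
#' @export
simulate_noesy_buildups <- function(coords, params, spins = NULL,
                                    max_distance = Inf, seed = 1L) {
  if (inherits(coords, "ToyChain")) coords <- coords$coords
  R <- build_relaxation_matrix(coords, params, spins)
  spins <- R$spins
  n <- length(spins)
  tau_s <- params$mixing_times * 1e-3
  A <- propagate_magnetization(R$rates, tau_s)

  r <- as.matrix(stats::dist(coords[spins, , drop = FALSE]))
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- pairs[r[pairs] <= max_distance, , drop = FALSE]
  # both directions: i -> j and j -> i are separate observed peaks
  pi <- c(pairs[, 1], pairs[, 2]); pj <- c(pairs[, 2], pairs[, 1])
  peaks <- data.frame(peak_id = seq_along(pi),
                      spin_i = spins[pi], spin_j = spins[pj])

  cross <- vapply(seq_along(tau_s),
                  function(t) A[[t]][cbind(pj, pi)], numeric(length(pi)))
  cross <- matrix(cross, nrow = length(pi))
  diagonal <- vapply(seq_along(tau_s),
                     function(t) diag(A[[t]]), numeric(n))
  diagonal <- matrix(diagonal, nrow = n,
                     dimnames = list(as.character(spins), NULL))
  if (params$intensity_noise_sigma > 0) {
    set.seed(seed)
    cross <- cross * (1 + matrix(rnorm(length(cross),
                                       sd = params$intensity_noise_sigma),
                                 nrow = nrow(cross)))
    diagonal <- diagonal *
      (1 + matrix(rnorm(length(diagonal),
                        sd = params$intensity_noise_sigma),
                  nrow = nrow(diagonal)))
  }
  structure(list(peaks = peaks, cross = cross, diagonal = diagonal,
                 mixing_times = params$mixing_times, spins = spins,
                 params = params, normalized = FALSE, corrected = FALSE,
                 reference = R),
            class = "BuildupSet")
}

#' Population-weighted buildups of a slow-exchange state mixture
#'
#' In slow exchange each state contributes its own NOESY intensities in
#' proportion to its population; the observed buildup is their weighted sum.
#' Used to emit spectroscopic data that carries the planted multi-state
#' signature.
#'
#' @param state_coords list of `n x 3` coordinate matrices, one per state.
#' @param populations state populations (sum 1).
#' @param params,spins,max_distance,seed as in [simulate_noesy_buildups()].
#' @return a `BuildupSet` (noise applied once, after mixing).
#' @export
ensemble_averaged_buildups <- function(state_coords, populations, params,
                                       spins = NULL, max_distance = Inf,
                                       seed = 1L) {
  check_weights(populations, length(state_coords))
  noiseless <- spectroscopy_params(params$tau_c,
                                   params$spectrometer_frequency,
                                   params$mixing_times, 0, params$rho_ext)
  sets <- lapply(state_coords, function(x)
    simulate_noesy_buildups(x, noiseless, spins, max_distance = Inf))
  base <- sets[[1]]
  for (s in seq_along(sets)[-1])
    if (!identical(sets[[s]]$peaks$spin_i, base$peaks$spin_i))
      stop("state geometries yield different peak lists")
  base$cross <- Reduce(`+`, Map(function(s, p) p * s$cross,
                                sets, as.list(populations)))
  base$diagonal <- Reduce(`+`, Map(function(s, p) p * s$diagonal,
                                   sets, as.list(populations)))
  # apply the observability cutoff on the population-mean geometry
  if (is.finite(max_distance)) {
    xm <- Reduce(`+`, Map(`*`, state_coords, populations))
    r <- as.matrix(stats::dist(xm[base$spins, , drop = FALSE]))
    si <- match(base$peaks$spin_i, base$spins)
    sj <- match(base$peaks$spin_j, base$spins)
    keep <- r[cbind(si, sj)] <= max_distance
    base$peaks <- data.frame(peak_id = seq_len(sum(keep)),
                             spin_i = base$peaks$spin_i[keep],
                             spin_j = base$peaks$spin_j[keep])
    base$cross <- base$cross[keep, , drop = FALSE]
  }
  if (params$intensity_noise_sigma > 0) {
    set.seed(seed)
    base$cross <- base$cross *
      (1 + matrix(rnorm(length(base$cross),
                        sd = params$intensity_noise_sigma),
                  nrow = nrow(base$cross)))
    base$diagonal <- base$diagonal *
      (1 + matrix(rnorm(length(base$diagonal),
                        sd = params$intensity_noise_sigma),
                  nrow = nrow(base$diagonal)))
  }
  base$params <- params
  base$reference <- NULL
  base
}
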