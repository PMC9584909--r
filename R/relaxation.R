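# Dipolar 1H-1H relaxation in the rigid isotropic-tumbling limit.
# All closed forms here double as the analytic oracles for the simulator.

.gamma_h <- 2.6752218744e8      # rad s^-1 T^-1
.hbar    <- 1.054571817e-34     # J s
.mu0_4pi <- 1e-7                # T m A^-1

# dipolar prefactor (1/10) * (mu0/4pi * hbar * gamma^2)^2, in Angstrom^6 s^-2
.q_dip <- 0.1 * (.mu0_4pi * .hbar * .gamma_h^2)^2 * 1e60

#' Rigid-tumbling spectral density
#'
#' `J(omega) = (2/5) tau_c / (1 + omega^2 tau_c^2)` for isotropic rotational
#' diffusion with no internal motion (order parameter 1).
#'
#' @param omega angular frequency in rad/s.
#' @param tau_c rotational correlation time in ns.
#' @return spectral density in seconds.
#' @export
spectral_density <- function(omega, tau_c) {
  tc <- tau_c * 1e-9
  0.4 * tc / (1 + (omega * tc)^2)
}

#' Spectroscopy parameters
#'
#' @param tau_c rotational correlation time in ns (> 0).
#' @param spectrometer_frequency proton Larmor frequency in MHz.
#' @param mixing_times NOESY mixing times in ms, strictly increasing.
#' @param intensity_noise_sigma relative (multiplicative) Gaussian noise on
#'   simulated intensities; 0.02 emulates typical NOESY integration error.
#' @param rho_ext external auto-relaxation leakage rate in 1/s added to every
#'   diagonal rate (0 = closed spin system).
#' @return object of class `SpectroscopyParams`.
#' @export
spectroscopy_params <- function(tau_c = 6.9, spectrometer_frequency = 600,
                                mixing_times = c(8, 16, 24, 32, 40, 48, 80),
                                intensity_noise_sigma = 0.02,
                                rho_ext = 0) {
  if (tau_c <= 0) stop("tau_c must be positive")
  if (length(mixing_times) < 1 || any(mixing_times <= 0) ||
      any(diff(mixing_times) <= 0))
    stop("mixing_times must be positive and strictly increasing")
  if (intensity_noise_sigma < 0) stop("intensity_noise_sigma must be >= 0")
  structure(list(tau_c = tau_c,
                 spectrometer_frequency = spectrometer_frequency,
                 mixing_times = mixing_times,
                 intensity_noise_sigma = intensity_noise_sigma,
                 rho_ext = rho_ext),
            class = "SpectroscopyParams")
}

# cross- and auto-relaxation rate constants per r^-6 (r in Angstrom)
dipolar_constants <- function(params) {
  w <- 2 * pi * params$spectrometer_frequency * 1e6
  j0 <- spectral_density(0, params$tau_c)
  j1 <- spectral_density(w, params$tau_c)
  j2 <- spectral_density(2 * w, params$tau_c)
  list(sigma = .q_dip * (6 * j2 - j0),           # Angstrom^6 s^-1
       rho   = .q_dip * (j0 + 3 * j1 + 6 * j2))
}

#' Build the full dipolar relaxation matrix for a set of spins
#'
#' Off-diagonal entries are the cross-relaxation rates
#' `sigma_ij = q r_ij^-6 (6 J(2w) - J(0))`; diagonal entries are the
#' auto-relaxation rates `rho_i = sum_j q r_ij^-6 (J(0) + 3 J(w) + 6 J(2w))`
#' plus the configurable external leakage. The matrix exponential of
#' `-R * tau_m` propagates NOESY intensities over the mixing time.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom) of one conformer, or a
#'   `ToyChain`.
#' @param params a [spectroscopy_params()].
#' @param spins integer indices of the rows of `coords` to treat as spins
#'   (default: all).
#' @return object of class `RelaxationMatrix`: `rates` (s^-1, symmetric in
#'   the off-diagonal block), `spins`, `tau_c`, `field`.
#' @export
build_relaxation_matrix <- function(coords, params, spins = NULL) {
  if (inherits(coords, "ToyChain")) coords <- coords$coords
  stopifnot(inherits(params, "SpectroscopyParams"), ncol(coords) == 3)
  if (is.null(spins)) spins <- seq_len(nrow(coords))
  if (length(spins) < 2) stop("need at least 2 spins")
  x <- coords[spins, , drop = FALSE]
  n <- nrow(x)
  r <- as.matrix(stats::dist(x))
  close <- which(r <= 0.5 & upper.tri(r), arr.ind = TRUE)
  if (nrow(close))
    stop(sprintf("degenerate geometry: spins %d and %d are %.3f Angstrom apart",
                 spins[close[1, 1]], spins[close[1, 2]],
                 r[close[1, 1], close[1, 2]]))
  k <- dipolar_constants(params)
  r6 <- r^-6; diag(r6) <- 0
  rates <- k$sigma * r6
  diag(rates) <- k$rho * rowSums(r6) + params$rho_ext
  structure(list(rates = rates, spins = spins, tau_c = params$tau_c,
                 field = params$spectrometer_frequency,
                 params = params),
            class = "RelaxationMatrix")
}

# exp(-R t) for symmetric R, one matrix per mixing time (t in s)
propagate_magnetization <- function(rates, times_s) {
  e <- eigen((rates + t(rates)) / 2, symmetric = TRUE)
  lapply(times_s, function(t)
    e$vectors %*% (exp(-e$values * t) * t(e$vectors)))
}

#' Closed-form two-spin NOESY intensities
#'
#' Analytic solution of `exp(-R tau)` for the 2 x 2 relaxation matrix with
#' auto rates `rho1`, `rho2` and cross rate `sigma`. Serves as the
#' independent oracle for the matrix-exponential simulator and as the model
#' fitted by [fit_cross_relaxation()].
#'
#' @param rho1,rho2 auto-relaxation rates (1/s).
#' @param sigma cross-relaxation rate (1/s).
#' @param tau mixing times in seconds.
#' @return list with vectors `cross`, `diag1`, `diag2` over `tau`.
#' @export
two_spin_intensity <- function(rho1, rho2, sigma, tau) {
  rb <- (rho1 + rho2) / 2
  dl <- (rho1 - rho2) / 2
  lam <- sqrt(dl^2 + sigma^2)
  sh <- if (lam > 0) sinh(lam * tau) / lam else tau
  ex <- exp(-rb * tau)
  list(cross = -ex * sigma * sh,
       diag1 = ex * (cosh(lam * tau) - dl * sh),
       diag2 = ex * (cosh(lam * tau) + dl * sh))
}
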