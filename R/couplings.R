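#' Karplus parameters
#'
#' Coefficients of the Karplus relation `J = A cos^2(theta) + B cos(theta)
#' + C` linking a three-bond scalar coupling to its torsion angle. Defaults
#' are standard 3J(HaHb)-class values.
#'
#' @param A,B,C coefficients in Hz.
#' @return object of class `KarplusParams`.
#' @export
karplus_params <- function(A = 7.9, B = -1.0, C = 0.7) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C))
  structure(list(A = A, B = B, C = C), class = "KarplusParams")
}

#' @rdname karplus_params
#' @param theta torsion angle in degrees.
#' @param params a `KarplusParams`.
#' @export
karplus_j <- function(theta, params = karplus_params()) {
  ct <- cos(theta * pi / 180)
  params$A * ct^2 + params$B * ct + params$C
}

# cosine of the torsion angle defined by four points (rows of a matrix)
torsion_cos <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  den <- sqrt(sum(n1^2) * sum(n2^2))
  if (den < 1e-12) return(1)  # degenerate (collinear) window: define theta = 0
  max(-1, min(1, sum(n1 * n2) / den))
}

#' Simulate ensemble-averaged scalar couplings
#'
#' For every residue whose window of four consecutive Calpha pseudo-atoms
#' exists, the torsion angle is evaluated in each conformer (and state) and
#' the Karplus coupling is averaged arithmetically over all of them --
#' scalar couplings average linearly under fast conformational exchange.
#' Residues too close to the chain end are skipped with a log entry.
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @param karplus a [karplus_params()].
#' @param noise_sigma additive Gaussian noise on the averaged J (Hz).
#' @param seed seed for the noise.
#' @return data.frame with `residue` (the first residue of the torsion
#'   window), `theta_mean_deg`, `j_hz`; attribute `skipped` lists residues
#'   without a complete window.
#' @export
simulate_couplings <- function(ensemble, karplus = karplus_params(),
                               noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(ensemble, "MultiStateEnsemble"))
  flat <- flatten_states(ensemble)
  idx <- which(flat$atoms$elety == "CA")
  idx <- idx[order(flat$atoms$resno[idx])]
  resno <- flat$atoms$resno[idx]
  n <- length(idx)
  residues <- resno[seq_len(max(0, n - 3))]
  skipped <- setdiff(resno, residues)
  out <- data.frame(residue = residues, theta_mean_deg = NA_real_,
                    j_hz = NA_real_)
  for (k in seq_along(residues)) {
    rows <- idx[k:(k + 3)]
    js <- thetas <- numeric(flat$n_conformers)
    for (c in seq_len(flat$n_conformers)) {
      ct <- torsion_cos(flat$coords[rows, , 1, c])
      thetas[c] <- acos(ct) * 180 / pi
      js[c] <- karplus$A * ct^2 + karplus$B * ct + karplus$C
    }
    out$theta_mean_deg[k] <- mean(thetas)
    out$j_hz[k] <- mean(js)
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    out$j_hz <- out$j_hz + rnorm(nrow(out), sd = noise_sigma)
  }
  if (length(skipped))
    message("couplings: skipped residues without a full torsion window: ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}

#' Simulate apo/holo chemical-shift tables with planted perturbations
#'
#' Apo shifts are drawn from realistic amide distributions (1H around
#' 8.3 ppm, 15N around 118 ppm); holo shifts add the configured offsets on
#' the binding site (large) and the allosteric site (smaller), plus
#' additive noise. The ground-truth offsets are retained for oracle tests.
#'
#' @param residues residue numbers covered by both tables.
#' @param binding_site,allosteric_site residue subsets (may overlap).
#' @param effect_h,effect_n binding-site offsets for 1H and 15N in ppm.
#' @param allo_scale allosteric offsets as a fraction of the binding-site
#'   effect (default 0.4, i.e. clearly smaller).
#' @param noise_sigma_h,noise_sigma_n additive noise per nucleus (ppm).
#' @param seed integer seed.
#' @return list with data.frames `apo` and `holo` (columns `residue`,
#'   `atom`, `shift_ppm`) and the ground-truth `offsets` table.
#' @export
simulate_shift_tables <- function(residues, binding_site,
                                  allosteric_site = integer(0),
                                  effect_h = 0.2, effect_n = 1.0,
                                  allo_scale = 0.4,
                                  noise_sigma_h = 0, noise_sigma_n = 0,
                                  seed = 1L) {
  if (!all(binding_site %in% residues) || !all(allosteric_site %in% residues))
    stop("site definitions must be subsets of the residue range")
  set.seed(seed)
  n <- length(residues)
  apo <- data.frame(residue = rep(residues, 2),
                    atom = rep(c("H", "N"), each = n),
                    shift_ppm = c(rnorm(n, 8.3, 0.45), rnorm(n, 118, 4)))
  dh <- dn <- numeric(n)
  dh[residues %in% allosteric_site] <- effect_h * allo_scale
  dn[residues %in% allosteric_site] <- effect_n * allo_scale
  dh[residues %in% binding_site] <- effect_h
  dn[residues %in% binding_site] <- effect_n
  holo <- apo
  holo$shift_ppm <- holo$shift_ppm + c(dh, dn) +
    c(rnorm(n, 0, noise_sigma_h), rnorm(n, 0, noise_sigma_n))
  list(apo = apo, holo = holo,
       offsets = data.frame(residue = residues, dh = dh, dn = dn))
}
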