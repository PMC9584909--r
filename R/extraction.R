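# eNOE distance extraction: normalization, spin-diffusion correction against
# a reference structure, cross-relaxation fitting, distance conversion.

# normalized cross intensity: I_ij / sqrt(I_ii * I_jj). For an isolated pair
# the mean auto-relaxation cancels, leaving a one-parameter (sigma) model up
# to the auto-rate *difference*, which is taken from the reference matrix.
normalize_buildups <- function(buildups) {
  stopifnot(inherits(buildups, "BuildupSet"))
  if (buildups$normalized) return(buildups)
  si <- match(buildups$peaks$spin_i, buildups$spins)
  sj <- match(buildups$peaks$spin_j, buildups$spins)
  buildups$cross <- buildups$cross /
    sqrt(buildups$diagonal[si, , drop = FALSE] *
         buildups$diagonal[sj, , drop = FALSE])
  buildups$normalized <- TRUE
  buildups
}

# normalized two-spin model: cross and diagonals of exp(-R2 tau) combined,
# as a function of sigma with the auto-rate half-difference dl fixed.
# The mean auto rate cancels exactly in the normalized form.
two_spin_model <- function(sigma, dl, tau) {
  lam <- sqrt(dl^2 + sigma^2)
  sh <- if (lam > 0) sinh(lam * tau) / lam else tau
  ch <- cosh(lam * tau)
  -sigma * sh / sqrt(pmax(ch^2 - (dl * sh)^2, 1e-300))
}

# predicted normalized cross intensity from a full relaxation matrix
predicted_normalized <- function(rates, i, j, tau_s) {
  A <- propagate_magnetization(rates, tau_s)
  vapply(A, function(a) a[i, j] / sqrt(a[i, i] * a[j, j]), numeric(1))
}

#' Correct NOESY cross peaks for spin diffusion
#'
#' For every cross peak the expected multi-spin intensity and the expected
#' isolated-two-spin intensity are computed from a reference relaxation
#' matrix (built from a given 3D structure); the measured, normalized
#' intensity is rescaled by their ratio. The result is an effective two-spin
#' buildup from which the direct cross-relaxation rate can be fitted.
#' Full-matrix inversion of measured intensities is deliberately avoided:
#' only a reference structure, not a complete peak matrix, is required.
#'
#' @param buildups a `BuildupSet` (raw or normalized).
#' @param reference a [build_relaxation_matrix()] covering all spins that
#'   appear in `buildups`.
#' @param floor predicted intensities below this magnitude make a peak
#'   `uncorrectable`; it is flagged and excluded downstream.
#' @return the `BuildupSet`, normalized, with corrected cross intensities,
#'   `corrected = TRUE`, and a logical `uncorrectable` column in `peaks`.
#' @export
correct_spin_diffusion <- function(buildups, reference, floor = 1e-12) {
  stopifnot(inherits(reference, "RelaxationMatrix"))
  if (!all(c(buildups$peaks$spin_i, buildups$peaks$spin_j) %in%
           reference$spins))
    stop("reference matrix does not cover all spins in the buildup set")
  b <- normalize_buildups(buildups)
  tau_s <- b$mixing_times * 1e-3
  Afull <- propagate_magnetization(reference$rates, tau_s)
  uncorrectable <- logical(nrow(b$peaks))
  for (p in seq_len(nrow(b$peaks))) {
    i <- match(b$peaks$spin_i[p], reference$spins)
    j <- match(b$peaks$spin_j[p], reference$spins)
    full <- vapply(Afull, function(a)
      a[i, j] / sqrt(a[i, i] * a[j, j]), numeric(1))
    rho_i <- reference$rates[i, i]; rho_j <- reference$rates[j, j]
    sig <- reference$rates[i, j]
    iso <- two_spin_model(sig, (rho_i - rho_j) / 2, tau_s)
    if (any(abs(full) < floor & abs(iso) >= floor)) {
      uncorrectable[p] <- TRUE
      next
    }
    ratio <- ifelse(abs(full) < floor, 1, iso / full)
    b$cross[p, ] <- b$cross[p, ] * ratio
  }
  if (any(uncorrectable))
    message(sum(uncorrectable), " peak(s) flagged uncorrectable")
  b$peaks$uncorrectable <- uncorrectable
  b$corrected <- TRUE
  b
}

#' Fit the cross-relaxation rate of one buildup series
#'
#' Least-squares fit of the normalized two-spin buildup model to one peak's
#' intensity series; the auto-rate difference entering the model is fixed
#' from the reference matrix (the mean auto rate cancels in the normalized
#' intensities). Alternatively the initial-slope (ISPA-style) linearization
#' can be requested, which regresses intensity on mixing time through the
#' origin.
#'
#' @param intensity normalized intensities over the mixing-time grid (>= 3
#'   points).
#' @param mixing_times_ms the grid in ms.
#' @param dl auto-relaxation half-difference `(rho_i - rho_j)/2` in 1/s.
#' @param method `"two_spin"` (default) or `"initial_slope"`.
#' @param interval search interval for sigma (1/s).
#' @return list with `sigma` (1/s), `se` (standard error from the fit
#'   covariance), `rss`, `method`.
#' @export
fit_cross_relaxation <- function(intensity, mixing_times_ms, dl = 0,
                                 method = c("two_spin", "initial_slope"),
                                 interval = c(-100, 100)) {
  method <- match.arg(method)
  keep <- is.finite(intensity)
  intensity <- intensity[keep]
  tau <- mixing_times_ms[keep] * 1e-3
  if (length(intensity) < 3)
    stop("need at least 3 mixing-time points to fit a buildup")
  if (method == "initial_slope") {
    fit <- lm(intensity ~ 0 + tau)
    sl <- unname(coef(fit)[1])
    return(list(sigma = -sl, se = unname(sqrt(diag(vcov(fit))[1])),
                rss = sum(fit$residuals^2), method = method))
  }
  sse <- function(s) sum((intensity - two_spin_model(s, dl, tau))^2)
  # sign of sigma is opposite the initial slope; search the right half-line
  slope <- sum(intensity * tau) / sum(tau^2)
  iv <- if (slope >= 0) c(interval[1], 0) else c(0, interval[2])
  opt <- optimize(sse, iv, tol = 1e-12)
  # refine once around the optimum for full precision
  w <- max(1e-6, abs(opt$minimum) * 1e-3)
  opt <- optimize(sse, c(opt$minimum - w, opt$minimum + w), tol = 1e-14)
  s_hat <- opt$minimum
  h <- max(1e-8, abs(s_hat) * 1e-6)
  dm <- (two_spin_model(s_hat + h, dl, tau) -
         two_spin_model(s_hat - h, dl, tau)) / (2 * h)
  dof <- max(1, length(tau) - 1)
  s2 <- opt$objective / dof
  se <- sqrt(s2 / max(sum(dm^2), 1e-300))
  list(sigma = s_hat, se = se, rss = opt$objective, method = method)
}

#' Convert a cross-relaxation rate into a distance restraint
#'
#' Inverts the r^-6 law: `r = (K / sigma)^(1/6)` with
#' `K = q (6 J(2w) - J(0))` fixed by the correlation time and field.
#' Bidirectional restraints (both transfer directions measured and
#' agreeing) get the highest-precision window `r +- 0.05` Angstrom (0.1
#' Angstrom wide); unidirectional restraints get a relative window
#' (default +-10%).
#'
#' @param sigma fitted cross-relaxation rate (1/s); must have the sign the
#'   tumbling regime implies.
#' @param params a [spectroscopy_params()].
#' @param class `"bidirectional"` or `"unidirectional"`.
#' @param unidir_tol relative half-window for unidirectional restraints.
#' @param sigma_se optional standard error carried into the output.
#' @return one-row data.frame with `upper`, `lower`, `r_hat`, `class`,
#'   `sigma`, `sigma_se`.
#' @export
sigma_to_restraint <- function(sigma, params,
                               class = c("bidirectional", "unidirectional"),
                               unidir_tol = 0.10, sigma_se = NA_real_) {
  class <- match.arg(class)
  K <- dipolar_constants(params)$sigma
  if (sign(sigma) != sign(K) || sigma == 0)
    stop(sprintf(paste0("sigma (%.3g 1/s) has the wrong sign for this ",
                        "tumbling regime (expected sign %d)"),
                 sigma, sign(K)))
  r_hat <- (K / sigma)^(1 / 6)
  if (class == "bidirectional") {
    upper <- r_hat + 0.05; lower <- r_hat - 0.05
  } else {
    upper <- r_hat * (1 + unidir_tol); lower <- r_hat * (1 - unidir_tol)
  }
  data.frame(r_hat = r_hat, upper = upper, lower = max(lower, 0.01),
             class = class, sigma = sigma, sigma_se = sigma_se)
}

#' Extract distance restraints from a buildup set
#'
#' The complete extraction stage: spin-diffusion correction against the
#' reference matrix, per-peak cross-relaxation fits, merging of
#' forward/backward peaks into bidirectional restraints where both
#' directions agree, and conversion to upper/lower limits.
#'
#' @param buildups a `BuildupSet`.
#' @param reference a `RelaxationMatrix` built from the reference structure.
#' @param atoms atom table giving `resno`/`elety` for the spin indices.
#' @param bidir_tol maximum relative disagreement of the two directional
#'   sigma estimates for a pair to qualify as bidirectional.
#' @param unidir_tol relative half-window for unidirectional restraints.
#' @param correct apply spin-diffusion correction (set `FALSE` only to
#'   study the uncorrected baseline).
#' @return a [restraint_set()]; the per-peak provenance (fitted sigma,
#'   standard error, class) is in `attr(, "provenance")`.
#' @export
extract_distance_restraints <- function(buildups, reference, atoms,
                                        bidir_tol = 0.2, unidir_tol = 0.10,
                                        correct = TRUE) {
  b <- if (correct) correct_spin_diffusion(buildups, reference)
       else normalize_buildups(buildups)
  if (is.null(b$peaks$uncorrectable)) b$peaks$uncorrectable <- FALSE
  tau <- b$mixing_times
  fits <- vector("list", nrow(b$peaks))
  for (p in seq_len(nrow(b$peaks))) {
    if (b$peaks$uncorrectable[p]) next
    i <- match(b$peaks$spin_i[p], reference$spins)
    j <- match(b$peaks$spin_j[p], reference$spins)
    dl <- (reference$rates[i, i] - reference$rates[j, j]) / 2
    fits[[p]] <- tryCatch(
      fit_cross_relaxation(b$cross[p, ], tau, dl = dl),
      error = function(e) NULL)
  }
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  pair_key <- key(b$peaks$spin_i, b$peaks$spin_j)
  rows <- list()
  for (k in unique(pair_key)) {
    idx <- which(pair_key == k & !vapply(fits, is.null, logical(1)))
    if (!length(idx)) next
    sig <- vapply(fits[idx], `[[`, numeric(1), "sigma")
    se <- vapply(fits[idx], `[[`, numeric(1), "se")
    i <- b$peaks$spin_i[idx[1]]; j <- b$peaks$spin_j[idx[1]]
    bidir <- length(idx) >= 2 &&
      abs(diff(range(sig))) / abs(mean(sig)) <= bidir_tol
    s_hat <- mean(sig)
    rest <- tryCatch(
      sigma_to_restraint(s_hat, b$params,
                         if (bidir) "bidirectional" else "unidirectional",
                         unidir_tol = unidir_tol,
                         sigma_se = sqrt(mean(se^2)) / sqrt(length(idx))),
      error = function(e) NULL)
    if (is.null(rest)) next
    rest$atom_i <- min(i, j); rest$atom_j <- max(i, j)
    rows[[length(rows) + 1]] <- rest
  }
  if (!length(rows)) stop("no restraints could be extracted")
  prov <- do.call(rbind, rows)
  rs <- restraint_set(
    distance = data.frame(atom_i = prov$atom_i, atom_j = prov$atom_j,
                          upper = prov$upper, lower = prov$lower,
                          class = prov$class, sigma = prov$sigma,
                          sigma_se = prov$sigma_se),
    atoms = atoms)
  attr(rs, "provenance") <- prov
  rs
}
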