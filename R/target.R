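#' Population-weighted effective distance over states
#'
#' NOE-physical r^-6 averaging: `r_eff = (sum_s w_s r_s^-6)^(-1/6)`. The
#' effective distance is dominated by the shortest state distance, which is
#' exactly how an ensemble-averaged NOE sees a distance distribution.
#'
#' @param r vector of per-state distances (Angstrom, > 0).
#' @param weights state weights (non-negative, sum 1; default uniform).
#' @return effective distance in Angstrom.
#' @export
effective_distance <- function(r, weights = NULL) {
  if (any(r <= 0)) stop("state distance of zero: degenerate geometry")
  if (is.null(weights)) weights <- rep(1 / length(r), length(r))
  check_weights(weights, length(r))
  sum(weights * r^-6)^(-1 / 6)
}

# single multi-state model coordinates as [natoms, 3, nstates]
as_model_array <- function(model) {
  if (inherits(model, "MultiStateEnsemble")) {
    stopifnot(model$n_conformers == 1L)
    x <- model$coords[, , , 1, drop = FALSE]
    dim(x) <- dim(x)[1:3]
    return(x)
  }
  if (is.matrix(model)) dim(model) <- c(dim(model), 1L)
  stopifnot(length(dim(model)) == 3L, dim(model)[2] == 3L)
  model
}

#' Multi-state target function
#'
#' The quantity minimized during structure calculation: the sum of squared
#' restraint violations of one multi-state model,
#' `TF = sum (r_eff - upper)_+^2 + sum (lower - r_eff)_+^2
#'  + w_J sum (|J_calc - J_obs| - tol)_+^2
#'  + w_sym sum (d_states - width)_+^2`,
#' where distance terms use the population-weighted r^-6 effective distance
#' over states, the coupling term averages the Karplus coupling over states,
#' and the symmetry term is a flat-bottom quadratic on the inter-state
#' displacement of every non-exempt atom (movements below the bottom width,
#' 1.2 Angstrom by default, are free).
#'
#' @param model `natoms x 3 x nstates` coordinate array (or an ensemble with
#'   a single conformer).
#' @param restraints a [restraint_set()].
#' @param weights state population weights (default uniform).
#' @return object of class `TargetFunctionReport`: `total`, `terms`
#'   (upper/lower/coupling/symmetry), and a `violations` data.frame.
#' @export
target_function <- function(model, restraints, weights = NULL) {
  x <- as_model_array(model)
  ns <- dim(x)[3]
  if (is.null(weights)) weights <- rep(1 / ns, ns)
  check_weights(weights, ns)
  d <- restraints$distance
  natoms <- dim(x)[1]
  if (max(d$atom_i, d$atom_j) > natoms)
    stop("restraints refer to atoms missing from the model: ",
         paste(unique(c(d$atom_i, d$atom_j)[c(d$atom_i, d$atom_j) > natoms]),
               collapse = ","))
  # effective distances, vectorized over restraints
  inv6 <- matrix(0, nrow(d), 1)
  for (s in seq_len(ns)) {
    dx <- matrix(x[d$atom_i, , s], ncol = 3) -
      matrix(x[d$atom_j, , s], ncol = 3)
    rs <- sqrt(rowSums(dx^2))
    if (any(rs == 0)) stop("coincident restrained atoms: degenerate geometry")
    inv6 <- inv6 + weights[s] * rs^-6
  }
  reff <- drop(inv6)^(-1 / 6)
  up_viol <- pmax(0, reff - d$upper)
  lo_viol <- pmax(0, d$lower - reff)
  terms <- c(upper = sum(up_viol^2), lower = sum(lo_viol^2),
             coupling = 0, symmetry = 0)

  viol <- data.frame(type = character(0), index = integer(0),
                     magnitude = numeric(0))
  if (any(up_viol > 0))
    viol <- rbind(viol, data.frame(type = "upper",
                                   index = which(up_viol > 0),
                                   magnitude = up_viol[up_viol > 0]))
  if (any(lo_viol > 0))
    viol <- rbind(viol, data.frame(type = "lower",
                                   index = which(lo_viol > 0),
                                   magnitude = lo_viol[lo_viol > 0]))

  cp <- restraints$couplings
  if (!is.null(cp) && nrow(cp)) {
    for (k in seq_len(nrow(cp))) {
      jc <- 0
      for (s in seq_len(ns)) {
        ct <- torsion_cos(x[c(cp$a1[k], cp$a2[k], cp$a3[k], cp$a4[k]), , s])
        jc <- jc + weights[s] * (cp$A[k] * ct^2 + cp$B[k] * ct + cp$C[k])
      }
      v <- max(0, abs(jc - cp$target[k]) - cp$tol[k])
      if (v > 0)
        viol <- rbind(viol, data.frame(type = "coupling", index = k,
                                       magnitude = v))
      terms["coupling"] <- terms["coupling"] +
        restraints$coupling_weight * v^2
    }
  }

  if (ns > 1 && restraints$sym_weight > 0) {
    sym_atoms <- which(!(restraints$atoms$resno %in% restraints$sym_exempt))
    for (s in seq_len(ns - 1)) for (t in (s + 1):ns) {
      dx <- x[sym_atoms, , s, drop = FALSE] - x[sym_atoms, , t, drop = FALSE]
      disp <- sqrt(rowSums(matrix(dx, ncol = 3)^2))
      v <- pmax(0, disp - restraints$sym_width)
      terms["symmetry"] <- terms["symmetry"] +
        restraints$sym_weight * sum(v^2)
      if (any(v > 0))
        viol <- rbind(viol, data.frame(type = "symmetry",
                                       index = sym_atoms[v > 0],
                                       magnitude = v[v > 0]))
    }
  }
  structure(list(total = sum(terms), terms = terms, violations = viol,
                 weights = weights),
            class = "TargetFunctionReport")
}

#' @export
print.TargetFunctionReport <- function(x, ...) {
  cat(sprintf("TF = %.4g  (upper %.3g, lower %.3g, coupling %.3g, symmetry %.3g); %d violation(s)\n",
              x$total, x$terms["upper"], x$terms["lower"],
              x$terms["coupling"], x$terms["symmetry"], nrow(x$violations)))
  invisible(x)
}

#' Target function of every conformer in an ensemble
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @param restraints a `RestraintSet`.
#' @param weights state weights (default: the ensemble's).
#' @return numeric vector of per-conformer TF totals.
#' @export
ensemble_tf <- function(ensemble, restraints, weights = NULL) {
  stopifnot(inherits(ensemble, "MultiStateEnsemble"))
  weights <- weights %||% ensemble$weights
  vapply(seq_len(ensemble$n_conformers), function(c) {
    x <- ensemble$coords[, , , c, drop = FALSE]
    dim(x) <- dim(x)[1:3]
    target_function(x, restraints, weights)$total
  }, numeric(1))
}
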