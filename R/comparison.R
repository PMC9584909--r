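# Apo/holo comparison: Kabsch superposition, mean structures, per-residue
# deviation profiles, ensemble distance statistics and CSP mapping.

#' Kabsch superposition
#'
#' Closed-form least-squares optimal proper rotation and translation
#' mapping `mobile` onto `reference` (SVD of the covariance matrix with a
#' determinant correction, so mirror solutions are never returned).
#'
#' @param mobile,reference `n x 3` paired coordinate matrices (n >= 3,
#'   non-collinear).
#' @param sel optional row indices used to compute the fit (the transform
#'   is still applied to all rows of `mobile`).
#' @return list with `R` (3 x 3 proper rotation, `det(R) = +1`),
#'   `translation`, `rmsd` (over `sel`), `coords` (all of `mobile`
#'   transformed). The transform is `x %*% t(R) + translation` applied to
#'   row vectors.
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3)
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 3) stop("need at least 3 paired atoms")
  P <- mobile[sel, , drop = FALSE]; Q <- reference[sel, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selections differ in length")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] < 1e-8 * max(svd(Pc)$d[1], 1))
    stop("degenerate (collinear) atom selection")
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- cq - drop(R %*% cp)
  fit <- sweep(Pc %*% t(R), 2, cq, `+`)
  rmsd <- sqrt(mean(rowSums((fit - Q)^2)))
  coords <- sweep(mobile %*% t(R), 2, translation, `+`)
  list(R = R, translation = translation, rmsd = rmsd, coords = coords)
}

#' Superpose every conformer of an ensemble onto a reference frame
#'
#' Each flattened structure is superposed (over Calpha atoms by default)
#' onto the reference conformer -- by convention the first conformer of the
#' ligand-free ensemble. The reference maps to itself with the identity
#' transform.
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @param reference `n x 3` reference coordinates; default: the ensemble's
#'   own first flattened structure.
#' @param sel atom indices used for the fit (default: all Calpha).
#' @return the flattened ensemble with superposed coordinates; per-structure
#'   RMSDs in `attr(, "rmsd")`.
#' @export
superpose_ensemble <- function(ensemble, reference = NULL, sel = NULL) {
  flat <- flatten_states(ensemble)
  if (is.null(sel)) sel <- which(flat$atoms$elety == "CA")
  if (is.null(reference)) reference <- flat$coords[, , 1, 1]
  rmsd <- numeric(flat$n_conformers)
  for (c in seq_len(flat$n_conformers)) {
    k <- kabsch_superpose(flat$coords[, , 1, c], reference, sel = sel)
    flat$coords[, , 1, c] <- k$coords
    rmsd[c] <- k$rmsd
  }
  attr(flat, "rmsd") <- rmsd
  flat
}

#' Mean Calpha structure of a superposed ensemble
#'
#' Arithmetic mean of the Calpha coordinates over all conformers of all
#' states; the ensemble must already be in a common frame
#' ([superpose_ensemble()]).
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @return matrix `n_residues x 3` with residue numbers as rownames.
#' @export
mean_structure <- function(ensemble) {
  flat <- flatten_states(ensemble)
  ca <- which(flat$atoms$elety == "CA")
  ca <- ca[order(flat$atoms$resno[ca])]
  m <- apply(flat$coords[ca, , 1, , drop = FALSE], c(1, 2), mean)
  rownames(m) <- flat$atoms$resno[ca]
  m
}

#' Per-residue deviation between two mean structures
#'
#' Euclidean distance between the mean apo and mean holo Calpha positions
#' of every residue; residues deviating more than the threshold are
#' flagged, except those in excluded (flexible) ranges, which are never
#' flagged.
#'
#' @param mean_apo,mean_holo matrices from [mean_structure()] with matching
#'   residue rownames.
#' @param threshold flag threshold in Angstrom (default 1.5).
#' @param exclude residue numbers excluded from flagging.
#' @return object of class `DeviationProfile` (a data.frame with `residue`,
#'   `deviation`, `flag`, `excluded`).
#' @export
deviation_profile <- function(mean_apo, mean_holo, threshold = 1.5,
                              exclude = integer(0)) {
  ra <- rownames(mean_apo); rh <- rownames(mean_holo)
  if (!identical(ra, rh))
    stop("residue indexing mismatch: ",
         paste(union(setdiff(ra, rh), setdiff(rh, ra)), collapse = ","))
  dev <- sqrt(rowSums((mean_apo - mean_holo)^2))
  res <- as.integer(ra)
  out <- data.frame(residue = res, deviation = dev,
                    excluded = res %in% exclude)
  out$flag <- out$deviation > threshold & !out$excluded
  class(out) <- c("DeviationProfile", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Ensemble statistics of one interatomic distance
#'
#' Distance between two atoms in every structure of the ensemble (all
#' states of all conformers), reported as mean +- sample sd (n-1
#' denominator). Distances are intramolecular, hence invariant under
#' superposition.
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @param atom_a,atom_b atom selectors: either atom indices or
#'   `list(resno =, elety =)`.
#' @return list with `mean`, `sd`, `distances`.
#' @export
ensemble_distance <- function(ensemble, atom_a, atom_b) {
  flat <- flatten_states(ensemble)
  resolve <- function(a) {
    if (is.list(a)) {
      i <- which(flat$atoms$resno == a$resno & flat$atoms$elety == a$elety)
      if (length(i) != 1)
        stop("atom not found: residue ", a$resno, " ", a$elety)
      i
    } else {
      if (a > nrow(flat$atoms)) stop("atom index out of range: ", a)
      as.integer(a)
    }
  }
  i <- resolve(atom_a); j <- resolve(atom_b)
  d <- sqrt(colSums(matrix(flat$coords[i, , 1, ] - flat$coords[j, , 1, ],
                           nrow = 3)^2))
  list(mean = mean(d), sd = if (length(d) > 1) sd(d) else 0, distances = d)
}

#' Mean Calpha RMSD of an ensemble to a reference structure
#'
#' Superposes every structure of the ensemble onto the reference over the
#' selected residues and reports the mean per-structure Calpha RMSD (the
#' convention used here; best-structure and mean-structure values are also
#' returned).
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @param reference `n x 3` Calpha reference coordinates with residue
#'   numbers as rownames (or an unnamed matrix matching the ensemble's
#'   residue order).
#' @param exclude residue numbers left out of the fit and the RMSD.
#' @return list with `mean`, `best`, `per_conformer`.
#' @export
rmsd_to_reference <- function(ensemble, reference, exclude = integer(0)) {
  flat <- flatten_states(ensemble)
  ca <- which(flat$atoms$elety == "CA")
  ca <- ca[order(flat$atoms$resno[ca])]
  resno <- flat$atoms$resno[ca]
  if (!is.null(rownames(reference))) {
    common <- intersect(resno, as.integer(rownames(reference)))
    common <- setdiff(common, exclude)
    ei <- ca[match(common, resno)]
    ri <- match(common, as.integer(rownames(reference)))
  } else {
    keep <- !(resno %in% exclude)
    ei <- ca[keep]; ri <- which(keep)
    if (nrow(reference) != length(resno))
      stop("unnamed reference must match the ensemble residue count")
  }
  if (length(ei) < 3) stop("fewer than 3 mappable residues")
  ref <- reference[ri, , drop = FALSE]
  per <- vapply(seq_len(flat$n_conformers), function(c)
    kabsch_superpose(flat$coords[ei, , 1, c], ref)$rmsd, numeric(1))
  list(mean = mean(per), best = min(per), per_conformer = per)
}

#' Chemical shift perturbations between apo and holo shift tables
#'
#' Combined CSP per residue from the 1H and 15N shift differences:
#' `(|dH| + w_N |dN|) / 2` (atom-weighted mean, default) or the quadratic
#' form `sqrt((dH^2 + (w_N dN)^2) / 2)`. Residues missing either nucleus in
#' either table are marked missing, not zero-filled.
#'
#' @param shifts_apo,shifts_holo data.frames with `residue`, `atom`
#'   (`"H"`/`"N"`), `shift_ppm`.
#' @param w_n 15N atom weight (default 0.14).
#' @param form `"mean"` or `"quadratic"`.
#' @return object of class `CSPTable` (data.frame `residue`, `d_h`, `d_n`,
#'   `csp`, `missing`).
#' @export
csp <- function(shifts_apo, shifts_holo, w_n = 0.14,
                form = c("mean", "quadratic")) {
  form <- match.arg(form)
  get <- function(tab, nuc) {
    x <- tab[tab$atom == nuc, ]
    setNames(x$shift_ppm, x$residue)
  }
  residues <- sort(unique(c(shifts_apo$residue, shifts_holo$residue)))
  ah <- get(shifts_apo, "H"); an <- get(shifts_apo, "N")
  hh <- get(shifts_holo, "H"); hn <- get(shifts_holo, "N")
  key <- as.character(residues)
  d_h <- hh[key] - ah[key]
  d_n <- hn[key] - an[key]
  miss <- !is.finite(d_h) | !is.finite(d_n)
  val <- if (form == "mean") (abs(d_h) + w_n * abs(d_n)) / 2
         else sqrt((d_h^2 + (w_n * d_n)^2) / 2)
  out <- data.frame(residue = residues, d_h = unname(d_h),
                    d_n = unname(d_n), csp = unname(val),
                    missing = unname(miss))
  out$csp[miss] <- NA_real_
  class(out) <- c("CSPTable", "data.frame")
  attr(out, "w_n") <- w_n
  attr(out, "form") <- form
  out
}
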