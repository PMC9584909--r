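# Correlated-sites detection from conformer ensembles: per-residue distance
# features, conformer clustering, normalized mutual information, network
# extraction, consensus state assignment and jackknife stability.

#' Per-residue distance features of an ensemble
#'
#' For every residue, the feature matrix holds (one row per conformer) that
#' residue's Calpha distances to every other residue's Calpha within the
#' same conformer. Sequence neighbours within `exclude_neighbors` positions
#' can be dropped to remove trivial bonded correlation. Multi-state
#' ensembles are flattened first (every state of every conformer is one
#' structure).
#'
#' @param ensemble a `MultiStateEnsemble` (>= 2 structures after
#'   flattening).
#' @param exclude_neighbors drop features for residues with
#'   `|i - j| <= exclude_neighbors` (0 keeps all).
#' @return object of class `DistanceFeatures`: list of per-residue feature
#'   matrices, plus `residues` and the flattened ensemble's `state_labels`.
#' @export
residue_distance_features <- function(ensemble, exclude_neighbors = 2L) {
  flat <- flatten_states(ensemble)
  if (flat$n_conformers < 2) stop("need at least 2 conformers")
  ca <- which(flat$atoms$elety == "CA")
  ca <- ca[order(flat$atoms$resno[ca])]
  residues <- flat$atoms$resno[ca]
  nres <- length(residues); ncf <- flat$n_conformers
  # all pairwise Calpha distances per conformer
  dmats <- lapply(seq_len(ncf), function(c)
    as.matrix(stats::dist(flat$coords[ca, , 1, c])))
  feats <- vector("list", nres)
  for (i in seq_len(nres)) {
    keep <- which(abs(residues - residues[i]) > exclude_neighbors)
    m <- matrix(unlist(lapply(dmats, function(d) d[i, keep])),
                nrow = ncf, byrow = TRUE)
    colnames(m) <- as.character(residues[keep])
    feats[[i]] <- m
  }
  names(feats) <- as.character(residues)
  structure(list(features = feats, residues = residues,
                 n_conformers = ncf, true_labels = flat$state_labels),
            class = "DistanceFeatures")
}

#' Cluster the conformers of one residue into states
#'
#' k-means (with restarts) on one residue's distance-feature rows.
#' Degenerate features (no spread above `tol`) give a single cluster with
#' a warning flag instead of an error.
#'
#' @param features feature matrix (conformers x reference distances) for one
#'   residue, e.g. one element of [residue_distance_features()].
#' @param n_states number of clusters (conformers >= n_states).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @param tol feature spread below which the residue counts as degenerate.
#' @return object of class `StateAssignment`: `labels` (1..n_states per
#'   conformer), `quality` (between-cluster over total sum of squares),
#'   `degenerate` flag.
#' @export
cluster_conformers <- function(features, n_states = 2L, seed = 1L,
                               nstart = 10L, tol = 1e-9) {
  stopifnot(is.matrix(features))
  ncf <- nrow(features)
  if (ncf < n_states) stop("fewer conformers than requested states")
  degenerate <- function()
    structure(list(labels = rep(1L, ncf), quality = 0, degenerate = TRUE),
              class = "StateAssignment")
  if (max(apply(features, 2, function(col) diff(range(col)))) < tol)
    return(degenerate())
  set.seed(seed)
  km <- tryCatch(kmeans(features, centers = n_states, nstart = nstart),
                 error = function(e) NULL)
  if (is.null(km)) return(degenerate())
  structure(list(labels = as.integer(km$cluster),
                 quality = km$betweenss / max(km$totss, 1e-300),
                 degenerate = FALSE),
            class = "StateAssignment")
}

#' Per-residue motion scores of a distance-feature set
#'
#' The median over feature columns of the per-column conformer variance.
#' A residue that itself exchanges between states shifts essentially all
#' of its reference distances, so its median column variance is high; a
#' static residue only sees variance in the minority of columns pointing
#' at moving regions, which the median ignores. Used to gate the
#' correlation analysis: distance geometry otherwise propagates the state
#' signal of the moving residues into every residue's profile.
#'
#' @param features a [residue_distance_features()] result.
#' @return numeric vector of motion scores (Angstrom^2), one per residue.
#' @export
residue_motion_scores <- function(features) {
  stopifnot(inherits(features, "DistanceFeatures"))
  vapply(features$features, function(f)
    median(apply(f, 2, stats::var)), numeric(1))
}

# mutual information (nats) and entropies of two label vectors
label_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  c(mi = mi, hx = hx, hy = hy)
}

#' Normalized mutual-information matrix over residues
#'
#' Entry (i, j) is the mutual information of the two residues' conformer
#' state assignments, normalized by the smaller of the two label entropies
#' so that perfectly coupled two-state behaviour scores 1 and independence
#' scores 0. Degenerate (single-cluster) residues get zero off-diagonal
#' entries; the diagonal is defined as 1.
#'
#' @param assignments list of `StateAssignment` objects (one per residue,
#'   same conformer set), e.g. from [cluster_ensemble()].
#' @param residues optional residue numbers for dimnames.
#' @return object of class `CorrelationMatrix`: `values` (residue x
#'   residue, in `[0, 1]`), `assignments`.
#' @export
mutual_information_matrix <- function(assignments, residues = NULL) {
  n <- length(assignments)
  ncf <- length(assignments[[1]]$labels)
  for (a in assignments)
    if (length(a$labels) != ncf)
      stop("assignments do not share one conformer index set")
  vals <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (assignments[[i]]$degenerate || assignments[[j]]$degenerate) next
    m <- label_mi(assignments[[i]]$labels, assignments[[j]]$labels)
    den <- min(m["hx"], m["hy"])
    v <- if (den <= 0) 0 else min(1, max(0, m[["mi"]] / den))
    vals[i, j] <- vals[j, i] <- v
  }
  if (!is.null(residues))
    dimnames(vals) <- list(residues, residues)
  structure(list(values = vals, assignments = assignments,
                 residues = residues %||% seq_len(n),
                 normalization = "min-entropy"),
            class = "CorrelationMatrix")
}

#' Cluster every residue of an ensemble and build its MI matrix
#'
#' Convenience wrapper: [residue_distance_features()] then
#' [cluster_conformers()] per residue then [mutual_information_matrix()].
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @param n_states clusters per residue.
#' @param seed master seed (each residue derives its own).
#' @param exclude_neighbors see [residue_distance_features()].
#' @param nstart see [cluster_conformers()].
#' @param motion_gate state separation is only attempted at residues whose
#'   motion score ([residue_motion_scores()]) exceeds `motion_gate` times
#'   the lower-quartile score of the chain (the rigid baseline); the rest
#'   are marked degenerate (zero MI rows). Set to 0 to disable.
#' @return a `CorrelationMatrix`; the per-residue assignments are inside.
#' @export
cluster_ensemble <- function(ensemble, n_states = 2L, seed = 1L,
                             exclude_neighbors = 2L, nstart = 10L,
                             motion_gate = 1.5) {
  df <- residue_distance_features(ensemble, exclude_neighbors)
  scores <- residue_motion_scores(df)
  active <- rep(TRUE, length(scores))
  if (motion_gate > 0) {
    baseline <- stats::quantile(scores, 0.25, names = FALSE)
    active <- scores > motion_gate * max(baseline, 1e-12)
  }
  assignments <- lapply(seq_along(df$features), function(i) {
    if (!active[i])
      return(structure(list(labels = rep(1L, df$n_conformers), quality = 0,
                            degenerate = TRUE),
                       class = "StateAssignment"))
    cluster_conformers(df$features[[i]], n_states,
                       seed = derive_seed(seed, i), nstart = nstart)
  })
  out <- mutual_information_matrix(assignments, residues = df$residues)
  out$motion_scores <- scores
  out
}

#' Top correlated residues
#'
#' Ranks residues by the row sum of their off-diagonal mutual information
#' and returns the top `k` (ties broken by residue number).
#'
#' @param cormat a `CorrelationMatrix`.
#' @param k how many residues (default 15).
#' @return integer vector of residue numbers, sorted by rank.
#' @export
top_correlated_residues <- function(cormat, k = 15L) {
  stopifnot(inherits(cormat, "CorrelationMatrix"))
  if (k <= 0) stop("k must be positive")
  v <- cormat$values
  if (k > nrow(v)) stop("k exceeds the number of residues")
  score <- rowSums(v) - diag(v)
  ord <- order(-score, cormat$residues)
  cormat$residues[ord[seq_len(k)]]
}

# align labels of b onto a by the permutation maximizing agreement
align_labels <- function(a, b, n_states) {
  perms <- permutations(n_states)
  best <- b; best_agree <- -1
  for (p in seq_len(nrow(perms))) {
    bb <- perms[p, ][b]
    agree <- sum(bb == a)
    if (agree > best_agree) { best_agree <- agree; best <- bb }
  }
  best
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    ins <- cbind(k, sub + (sub >= k))
    out <- rbind(out, ins)
  }
  out
}

#' Consensus state assignment over the correlated network
#'
#' Aligns the per-residue cluster labels of the top-correlated residues
#' (pairwise best-permutation matching against the highest-ranked residue)
#' and takes a per-conformer majority vote. Exact ties go to state 1 and
#' are flagged.
#'
#' @param cormat a `CorrelationMatrix` carrying per-residue assignments.
#' @param top residue numbers of the correlated network (non-empty), e.g.
#'   from [top_correlated_residues()].
#' @param n_states number of states.
#' @return a `StateAssignment` with `ties` flag vector.
#' @export
consensus_state_assignment <- function(cormat, top, n_states = 2L) {
  stopifnot(inherits(cormat, "CorrelationMatrix"))
  if (!length(top)) stop("empty top-residue set")
  idx <- match(top, cormat$residues)
  if (anyNA(idx)) stop("top residues not in the correlation matrix")
  labs <- lapply(cormat$assignments[idx], `[[`, "labels")
  ref <- labs[[1]]
  aligned <- lapply(labs, align_labels, a = ref, n_states = n_states)
  votes <- do.call(rbind, aligned)
  ncf <- ncol(votes)
  labels <- integer(ncf); ties <- logical(ncf)
  for (c in seq_len(ncf)) {
    tab <- tabulate(votes[, c], nbins = n_states)
    w <- which(tab == max(tab))
    labels[c] <- w[1]
    ties[c] <- length(w) > 1
  }
  structure(list(labels = labels, quality = mean(votes == rep(labels, each = nrow(votes))),
                 degenerate = FALSE, ties = ties),
            class = "StateAssignment")
}

#' Mean mutual information over the top-correlated network
#'
#' The summary statistic used by the jackknife: the mean off-diagonal MI
#' among the `top_k` highest-ranked residues.
#'
#' @param cormat a `CorrelationMatrix`.
#' @param top_k network size.
#' @return mean MI (dimensionless, in `[0, 1]`).
#' @export
network_mi <- function(cormat, top_k = 15L) {
  top <- top_correlated_residues(cormat, k = min(top_k, nrow(cormat$values)))
  idx <- match(top, cormat$residues)
  v <- cormat$values[idx, idx]
  mean(v[upper.tri(v)])
}

#' Jackknife stability of the structural correlations
#'
#' Removes a random fraction of the distance restraints, re-runs the
#' two-state structure calculation and the correlation analysis, and
#' reports the mean and sd of the network MI per retained fraction. The
#' curve shows how much experimental data the emergence of structural
#' correlations requires.
#'
#' @param restraints the full `RestraintSet`.
#' @param fractions retained fractions in (0, 1].
#' @param n_reps replicates per fraction.
#' @param n_states,n_conformers,steps annealing controls per replicate.
#' @param n_keep how many of the lowest-TF conformers enter the
#'   correlation analysis (mirrors selecting the best conformers of a
#'   structure calculation; default: the better half).
#' @param top_k network size for the MI summary.
#' @param seed master seed; every (fraction, replicate) derives its own.
#' @param ... passed to [anneal_multistate()].
#' @return data.frame `fraction`, `mean_mi`, `sd_mi`, `n_ok`.
#' @export
jackknife_correlation <- function(restraints, fractions = seq(0.2, 1, 0.2),
                                  n_reps = 5L, n_states = 2L,
                                  n_conformers = 8L, steps = 20000L,
                                  top_k = 10L, seed = 1L,
                                  n_keep = max(2L, n_conformers %/% 2L),
                                  ...) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  out <- data.frame(fraction = fractions, mean_mi = NA_real_,
                    sd_mi = NA_real_, n_ok = 0L)
  for (f in seq_along(fractions)) {
    mis <- numeric(0)
    for (r in seq_len(n_reps)) {
      mi <- tryCatch({
        sub <- subsample_restraints(restraints, fractions[f],
                                    seed = derive_seed(seed, f, r))
        ens <- anneal_multistate(sub, n_states = n_states,
                                 n_conformers = n_conformers,
                                 steps = steps,
                                 seed = derive_seed(seed, f, r, 1L), ...)
        ens <- select_lowest_tf(ens, min(n_keep, ens$n_conformers))
        cm <- cluster_ensemble(ens, n_states = n_states,
                               seed = derive_seed(seed, f, r, 2L))
        network_mi(cm, top_k)
      }, error = function(e) {
        message("jackknife replicate dropped: ", conditionMessage(e))
        NA_real_
      })
      if (is.finite(mi)) mis <- c(mis, mi)
    }
    out$mean_mi[f] <- mean(mis)
    out$sd_mi[f] <- if (length(mis) > 1) sd(mis) else 0
    out$n_ok[f] <- length(mis)
  }
  out
}
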