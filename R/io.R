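# Readers/writers: multi-model PDB (via bio3d), CYANA-dialect .upl/.lol
# restraint files, TSV tables, YAML configuration. All writers use stable
# ordering and fixed float formatting so reruns are byte-identical.

.res3 <- "ALA"  # generic residue name for toy pseudo-residues

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL block per structure, conformer-major and state-minor, plus a
#' REMARK header encoding the state layout and (optionally) a sidecar TSV
#' mapping each model to its conformer and state. This stays valid PDB for
#' external viewers while preserving the multi-state arrangement.
#'
#' @param ensemble a `MultiStateEnsemble`.
#' @param path output PDB path.
#' @param sidecar write `<path>.states.tsv` (default TRUE).
#' @return invisibly, the path.
#' @export
write_ensemble_pdb <- function(ensemble, path, sidecar = TRUE) {
  stopifnot(inherits(ensemble, "MultiStateEnsemble"))
  d <- dim(ensemble$coords)
  nmod <- d[3] * d[4]
  xyz <- matrix(NA_real_, nmod, d[1] * 3)
  map <- data.frame(model = seq_len(nmod), conformer = NA_integer_,
                    state = NA_integer_)
  k <- 0L
  for (c in seq_len(d[4])) for (s in seq_len(d[3])) {
    k <- k + 1L
    xyz[k, ] <- as.vector(t(ensemble$coords[, , s, c]))
    map$conformer[k] <- c; map$state[k] <- s
  }
  at <- ensemble$atoms
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = rep(.res3, nrow(at)), eleno = seq_len(nrow(at)),
                   elety = at$elety)
  body <- readLines(path)
  header <- c(sprintf("REMARK 250 MSNMR STATES %d CONFORMERS %d ORDER CONFORMER-MAJOR",
                      d[3], d[4]))
  writeLines(c(header, body), path)
  if (sidecar) {
    write.table(map, paste0(path, ".states.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a multi-model PDB file into an ensemble
#'
#' Models are grouped into conformers and states according to the sidecar
#' TSV written by [write_ensemble_pdb()] when present; otherwise every
#' MODEL becomes one conformer of a single-state ensemble. Residue
#' numbering is preserved; when alternate locations are present only the
#' highest-occupancy copy of each atom is kept. Missing Calpha atoms
#' produce a warning listing the residues.
#'
#' @param path PDB file.
#' @param sidecar path of the conformer/state table; default
#'   `<path>.states.tsv` if it exists.
#' @return a `MultiStateEnsemble`.
#' @export
read_ensemble_pdb <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error in ", path, ": ",
                         conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("PDB parse error: no ATOM records in ", path)
  keep <- seq_len(nrow(at))
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key),
                          function(i) i[which.max(occ[i])]))
    keep <- sort(keep)
  }
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  nmod <- nrow(xyz); natoms <- length(keep)
  coords_all <- array(NA_real_, c(natoms, 3, nmod))
  for (m in seq_len(nmod))
    coords_all[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[keep, ]
  atoms <- data.frame(eleno = seq_len(natoms), elety = at$elety[keep],
                      resno = at$resno[keep], stringsAsFactors = FALSE)
  no_ca <- setdiff(unique(atoms$resno), atoms$resno[atoms$elety == "CA"])
  if (length(no_ca))
    warning("residues without Calpha: ", paste(no_ca, collapse = ","))
  if (is.null(sidecar)) {
    cand <- paste0(path, ".states.tsv")
    sidecar <- if (file.exists(cand)) cand else NA
  }
  if (!is.na(sidecar) && !is.null(sidecar) && file.exists(sidecar)) {
    map <- read.table(sidecar, header = TRUE, sep = "\t")
    ns <- max(map$state); nc <- max(map$conformer)
    if (nrow(map) != nmod) stop("sidecar does not match the model count")
    coords <- array(NA_real_, c(natoms, 3, ns, nc))
    for (k in seq_len(nmod))
      coords[, , map$state[k], map$conformer[k]] <- coords_all[, , k]
    return(multistate_ensemble(coords, atoms))
  }
  dim(coords_all) <- c(natoms, 3, 1, nmod)
  multistate_ensemble(coords_all, atoms)
}

#' Write distance restraints as CYANA-dialect .upl/.lol files
#'
#' Whitespace-delimited columns: residue number, residue name, atom name
#' for both partners, then the limit in Angstrom (2 decimals). A provenance
#' TSV with the fitted cross-relaxation rates and restraint classes is
#' written alongside the .upl file.
#'
#' @param restraints a `RestraintSet`.
#' @param upl_path,lol_path output paths for upper and lower limits.
#' @param provenance write `<upl_path>.prov.tsv` (default TRUE).
#' @return invisibly, the two paths.
#' @export
write_restraints <- function(restraints, upl_path, lol_path,
                             provenance = TRUE) {
  d <- restraints$distance
  at <- restraints$atoms
  line <- function(limit)
    sprintf("%4d %-4s %-5s %4d %-4s %-5s %8.2f",
            at$resno[d$atom_i], .res3, at$elety[d$atom_i],
            at$resno[d$atom_j], .res3, at$elety[d$atom_j], limit)
  writeLines(line(d$upper), upl_path)
  writeLines(line(d$lower), lol_path)
  if (provenance) {
    prov <- data.frame(atom_i = d$atom_i, atom_j = d$atom_j,
                       class = d$class,
                       sigma = if (is.null(d$sigma)) NA else d$sigma,
                       sigma_se = if (is.null(d$sigma_se)) NA else d$sigma_se)
    write.table(format(prov, digits = 6), paste0(upl_path, ".prov.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(upl_path, lol_path))
}

#' Read CYANA-dialect restraint files
#'
#' Pairs each .lol entry with its .upl partner by atom identity and
#' validates `lower <= upper`. Atoms not present in the supplied topology
#' are listed in a warning and their restraints dropped.
#'
#' @param upl_path,lol_path input files.
#' @param atoms atom table (`elety`, `resno`) defining the topology.
#' @param ... passed to [restraint_set()] (symmetry settings etc.).
#' @return a `RestraintSet`.
#' @export
read_restraints <- function(upl_path, lol_path, atoms, ...) {
  parse <- function(path) {
    x <- read.table(path, header = FALSE,
                    col.names = c("res_i", "name_i", "atom_i",
                                  "res_j", "name_j", "atom_j", "limit"))
    x
  }
  up <- parse(upl_path); lo <- parse(lol_path)
  lookup <- function(resno, elety) {
    i <- match(paste(resno, elety), paste(atoms$resno, atoms$elety))
    i
  }
  ai <- lookup(up$res_i, up$atom_i); aj <- lookup(up$res_j, up$atom_j)
  bad <- is.na(ai) | is.na(aj)
  if (any(bad)) {
    warning("dropping restraints with atoms missing from topology: ",
            paste(unique(c(paste(up$res_i, up$atom_i)[is.na(ai)],
                           paste(up$res_j, up$atom_j)[is.na(aj)])),
                  collapse = "; "))
    up <- up[!bad, ]; ai <- ai[!bad]; aj <- aj[!bad]
  }
  key <- function(t) paste(t$res_i, t$atom_i, t$res_j, t$atom_j)
  lo_idx <- match(key(up), key(lo))
  lower <- ifelse(is.na(lo_idx), 0.01, lo$limit[lo_idx])
  if (any(lower > up$limit + 1e-9))
    stop("lower limit exceeds upper limit for pair(s): ",
         paste(key(up)[lower > up$limit + 1e-9], collapse = "; "))
  restraint_set(distance = data.frame(atom_i = ai, atom_j = aj,
                                      upper = up$limit, lower = lower),
                atoms = atoms, ...)
}

#' Write a TSV table with fixed formatting
#'
#' @param x data.frame.
#' @param path output path.
#' @param digits significant digits for numeric columns.
#' @return invisibly, the path.
#' @export
write_tsv_table <- function(x, path, digits = 6) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = digits,
                                               format = "g"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a correlation matrix heatmap to PNG
#'
#' @param cormat a `CorrelationMatrix`.
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
write_mi_heatmap <- function(cormat, path) {
  v <- cormat$values
  png(path, width = 800, height = 760)
  on.exit(dev.off())
  image(seq_len(nrow(v)), seq_len(ncol(v)), v, zlim = c(0, 1),
        col = hcl.colors(64, "viridis"), xlab = "residue",
        ylab = "residue", main = "normalized mutual information",
        useRaster = TRUE)
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration holding the stage parameters and the master seed.
#' Unknown keys (at the top level or within a stage) are rejected before
#' any stage runs; the parsed config round-trips losslessly through
#' [yaml::write_yaml()].
#'
#' @param path YAML file.
#' @return named list of class `PipelineConfig`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

known_config_keys <- list(
  top = c("seed", "chain", "planted", "spectroscopy", "extraction",
          "anneal", "correlation", "compare", "output"),
  chain = c("n_residues", "atoms_per_residue", "bond_length", "seed"),
  planted = c("correlated_residues", "displacement_amplitude",
              "state_populations", "conformer_noise_sigma", "n_conformers"),
  spectroscopy = c("tau_c", "spectrometer_frequency", "mixing_times",
                   "intensity_noise_sigma"),
  extraction = c("max_distance", "bidir_tol", "unidir_tol"),
  anneal = c("n_states", "n_conformers", "steps", "sym_exempt"),
  correlation = c("top_k", "exclude_neighbors"),
  compare = c("threshold", "exclude", "binding_site", "allosteric_site",
              "effect_h", "effect_n", "w_n"),
  output = c("dir"))

validate_config <- function(cfg) {
  extra <- setdiff(names(cfg), known_config_keys$top)
  if (length(extra)) stop("unknown configuration key(s): ",
                          paste(extra, collapse = ", "))
  for (sect in setdiff(names(cfg), "seed")) {
    extra <- setdiff(names(cfg[[sect]]), known_config_keys[[sect]])
    if (length(extra))
      stop("unknown key(s) in '", sect, "': ", paste(extra, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = c("PipelineConfig", "list"))
}
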