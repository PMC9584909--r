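#!/usr/bin/env Rscript
# Optional validation against deposited PDZ2 ensembles. Requires local
# copies of the multi-model PDB files (download them yourself, e.g. the
# apo and peptide-bound eNOE ensembles 7QCX / 7QCY and the crystal
# references 3LNX / 3LNY from the wwPDB). Nothing here is run by the test
# suite; it is a convenience script for users with the files at hand.
#
# Usage:
#   Rscript scripts/validate_deposited.R --apo 7qcx.pdb --holo 7qcy.pdb \
#       --crystal-apo 3lnx.pdb [--crystal-holo 3lny.pdb]
#
# Reports:
#   * Gly23 Calpha - Lys72 Calpha distance (mean +- sd) in both ensembles
#   * per-conformer Calpha RMSD to the crystal reference (mean), with the
#     Gly24-Gly34 loop and the N-terminal tail excluded
#   * residues whose mean Calpha positions deviate > 1.5 A between apo
#     and holo (same exclusions)

suppressMessages(library(msnmr))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else NULL
}
apo_path <- get_arg("--apo"); holo_path <- get_arg("--holo")
cry_path <- get_arg("--crystal-apo")
if (is.null(apo_path) || is.null(holo_path))
  stop("need --apo and --holo multi-model PDB paths")

loop <- 24:34
nterm <- 1:5

apo <- read_ensemble_pdb(apo_path)
holo <- read_ensemble_pdb(holo_path)

report_distance <- function(ens, label) {
  d <- ensemble_distance(ens, list(resno = 23, elety = "CA"),
                         list(resno = 72, elety = "CA"))
  cat(sprintf("%s Gly23-Lys72 Calpha distance: %.2f +- %.2f A\n",
              label, d$mean, d$sd))
}
report_distance(apo, "apo")
report_distance(holo, "holo")

apo_s <- superpose_ensemble(apo)
holo_s <- superpose_ensemble(holo, reference = apo_s$coords[, , 1, 1])
dev <- deviation_profile(mean_structure(apo_s), mean_structure(holo_s),
                         threshold = 1.5, exclude = c(loop, nterm))
cat("residues deviating > 1.5 A (loop/N-terminus excluded):\n  ",
    paste(dev$residue[dev$flag], collapse = " "), "\n")

if (!is.null(cry_path)) {
  cry <- read_ensemble_pdb(cry_path)
  ref <- ca_ref <- {
    ca <- which(cry$atoms$elety == "CA")
    m <- cry$coords[ca, , 1, 1]
    rownames(m) <- cry$atoms$resno[ca]
    m
  }
  r <- rmsd_to_reference(apo, ref, exclude = c(loop, nterm))
  cat(sprintf("apo ensemble mean Calpha RMSD to crystal: %.2f A (best %.2f)\n",
              r$mean, r$best))
  cry_holo <- get_arg("--crystal-holo")
  if (!is.null(cry_holo)) {
    ch <- read_ensemble_pdb(cry_holo)
    ca <- which(ch$atoms$elety == "CA")
    mh <- ch$coords[ca, , 1, 1]; rownames(mh) <- ch$atoms$resno[ca]
    rh <- rmsd_to_reference(holo, mh, exclude = c(loop, nterm))
    cat(sprintf("holo ensemble mean Calpha RMSD to crystal: %.2f A (best %.2f)\n",
                rh$mean, rh$best))
  }
}
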