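# End-to-end pipeline: simulate -> extract -> anneal -> correlate -> compare,
# with all randomness derived from one master seed and deterministic TSV
# outputs.

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in dependency order: synthetic-data generation (toy chain,
#' planted two-state ensemble, slow-exchange NOESY buildups, couplings and
#' shift tables), eNOE extraction (spin-diffusion correction against the
#' population-mean reference structure, restraint generation), two-state
#' annealing, correlation analysis (MI matrix, top network, consensus
#' states) and apo/holo comparison (superposition, deviation profile, CSP).
#' Every stage writes its outputs as TSV (plus PDB/PNG where appropriate)
#' into the output directory and appends a manifest entry.
#'
#' @param config a `PipelineConfig` from [read_config()], or a list with
#'   the same structure.
#' @param out_dir output directory (created if needed); overrides
#'   `config$output$dir`.
#' @return list of per-stage manifests (stage name, parameters, seed,
#'   outputs, status); the computed objects are in `attr(, "results")`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "PipelineConfig")) config <- validate_config(config)
  out_dir <- out_dir %||% config$output$dir %||% tempfile("msnmr_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  manifests <- list()
  results <- list()
  note <- function(stage, params, outputs, status = "ok") {
    manifests[[stage]] <<- list(stage = stage, params = params,
                                seed = seed, outputs = outputs,
                                status = status)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, list(), character(0), paste("failed:", conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- simulate -------------------------------------------------------
  run_stage("simulate", {
    ch <- config$chain %||% list()
    chain <- build_toy_chain(toy_chain_spec(
      n_residues = ch$n_residues %||% 20L,
      atoms_per_residue = ch$atoms_per_residue %||% 1L,
      bond_length = ch$bond_length %||% 3.8,
      seed = ch$seed %||% derive_seed(seed, 1L)))
    pl <- config$planted %||% list()
    nres <- chain$spec$n_residues
    planted <- planted_two_state_spec(
      correlated_residues = pl$correlated_residues %||%
        seq_len(ceiling(0.6 * nres)),
      displacement_amplitude = pl$displacement_amplitude %||% 3.0,
      state_populations = pl$state_populations %||% c(0.5, 0.5),
      conformer_noise_sigma = pl$conformer_noise_sigma %||% 0.3,
      n_conformers = pl$n_conformers %||% 40L)
    ens <- generate_two_state_ensemble(chain, planted,
                                       seed = derive_seed(seed, 2L))
    sp <- config$spectroscopy %||% list()
    params <- spectroscopy_params(
      tau_c = sp$tau_c %||% 6.9,
      spectrometer_frequency = sp$spectrometer_frequency %||% 600,
      mixing_times = sp$mixing_times %||% c(8, 16, 24, 32, 40, 48, 80),
      intensity_noise_sigma = sp$intensity_noise_sigma %||% 0.02)
    truth <- attr(ens, "planted")
    buildups <- ensemble_averaged_buildups(
      truth$states, truth$populations, params,
      max_distance = (config$extraction %||% list())$max_distance %||% 7,
      seed = derive_seed(seed, 3L))
    couplings <- simulate_couplings(ens, noise_sigma = 0.1,
                                    seed = derive_seed(seed, 4L))
    pdb <- file.path(out_dir, "planted_ensemble.pdb")
    write_ensemble_pdb(ens, pdb)
    peaks <- data.frame(peak_id = buildups$peaks$peak_id,
                        spin_i = rep(buildups$peaks$spin_i,
                                     ncol(buildups$cross)),
                        spin_j = rep(buildups$peaks$spin_j,
                                     ncol(buildups$cross)),
                        mixing_time_ms = rep(buildups$mixing_times,
                                             each = nrow(buildups$cross)),
                        intensity = as.vector(buildups$cross))
    peaks_path <- file.path(out_dir, "noesy_peaks.tsv")
    write_tsv_table(peaks, peaks_path)
    results$chain <- chain; results$ensemble <- ens
    results$params <- params; results$buildups <- buildups
    results$couplings <- couplings
    note("simulate",
         list(n_residues = nres, n_conformers = planted$n_conformers),
         c(pdb, peaks_path))
  })

  ## --- extract --------------------------------------------------------
  run_stage("extract", {
    truth <- attr(results$ensemble, "planted")
    refcoords <- Reduce(`+`, Map(`*`, truth$states,
                                 as.list(truth$populations)))
    reference <- build_relaxation_matrix(refcoords, results$params)
    ex <- config$extraction %||% list()
    rs <- extract_distance_restraints(results$buildups, reference,
                                      results$chain$atoms,
                                      bidir_tol = ex$bidir_tol %||% 0.2,
                                      unidir_tol = ex$unidir_tol %||% 0.10)
    an <- config$anneal %||% list()
    if (length(an$sym_exempt))
      rs <- restraint_set(rs$distance, rs$couplings, rs$atoms,
                          sym_exempt = an$sym_exempt)
    upl <- file.path(out_dir, "restraints.upl")
    lol <- file.path(out_dir, "restraints.lol")
    write_restraints(rs, upl, lol)
    results$restraints <- rs
    note("extract", list(n_restraints = nrow(rs$distance)), c(upl, lol))
  })

  ## --- anneal ---------------------------------------------------------
  run_stage("anneal", {
    an <- config$anneal %||% list()
    ens <- anneal_multistate(results$restraints,
                             n_states = an$n_states %||% 2L,
                             n_conformers = an$n_conformers %||% 10L,
                             steps = an$steps %||% 20000L,
                             seed = derive_seed(seed, 5L),
                             bonds = chain_bonds(results$chain))
    tf_path <- file.path(out_dir, "target_function.tsv")
    write_tsv_table(data.frame(conformer = seq_along(ens$tf), tf = ens$tf),
                    tf_path)
    pdb <- file.path(out_dir, "annealed_ensemble.pdb")
    write_ensemble_pdb(ens, pdb)
    results$annealed <- ens
    note("anneal", list(n_states = ens$n_states,
                        n_conformers = ens$n_conformers), c(tf_path, pdb))
  })

  ## --- correlate ------------------------------------------------------
  run_stage("correlate", {
    co <- config$correlation %||% list()
    cm <- cluster_ensemble(results$annealed,
                           n_states = results$annealed$n_states,
                           seed = derive_seed(seed, 6L),
                           exclude_neighbors = co$exclude_neighbors %||% 2L)
    top <- top_correlated_residues(
      cm, k = min(co$top_k %||% 15L, nrow(cm$values)))
    consensus <- consensus_state_assignment(cm, top,
                                            results$annealed$n_states)
    mi_path <- file.path(out_dir, "mi_matrix.tsv")
    write_tsv_table(as.data.frame(cm$values), mi_path)
    lab_path <- file.path(out_dir, "state_labels.tsv")
    write_tsv_table(data.frame(structure = seq_along(consensus$labels),
                               state = consensus$labels), lab_path)
    png_path <- file.path(out_dir, "mi_heatmap.png")
    write_mi_heatmap(cm, png_path)
    results$cormat <- cm; results$top <- top
    results$consensus <- consensus
    note("correlate", list(top_k = length(top)),
         c(mi_path, lab_path, png_path))
  })

  ## --- compare --------------------------------------------------------
  run_stage("compare", {
    cp <- config$compare %||% list()
    nres <- results$chain$spec$n_residues
    binding <- cp$binding_site %||% seq_len(min(4, nres))
    allo <- cp$allosteric_site %||% (nres - seq_len(min(3, nres - 4)) + 1)
    truth <- attr(results$ensemble, "planted")
    holo_chain <- results$chain
    holo_spec <- planted_two_state_spec(
      correlated_residues = truth$correlated_residues,
      displacement_amplitude = truth$spec$displacement_amplitude,
      state_populations = truth$populations,
      conformer_noise_sigma = truth$spec$conformer_noise_sigma,
      n_conformers = results$ensemble$n_conformers)
    # ligand-bound ensemble: displace the binding site of the base fold
    holo_chain$coords[holo_chain$atoms$resno %in% binding, ] <-
      holo_chain$coords[holo_chain$atoms$resno %in% binding, ] + 2.0
    holo <- generate_two_state_ensemble(holo_chain, holo_spec,
                                        seed = derive_seed(seed, 7L))
    apo_s <- superpose_ensemble(results$ensemble)
    ref <- apo_s$coords[, , 1, 1]
    holo_s <- superpose_ensemble(holo, reference = ref)
    dev <- deviation_profile(mean_structure(apo_s), mean_structure(holo_s),
                             threshold = cp$threshold %||% 1.5,
                             exclude = cp$exclude %||% integer(0))
    shifts <- simulate_shift_tables(seq_len(nres), binding, allo,
                                    effect_h = cp$effect_h %||% 0.2,
                                    effect_n = cp$effect_n %||% 1.0,
                                    noise_sigma_h = 0.01,
                                    noise_sigma_n = 0.05,
                                    seed = derive_seed(seed, 8L))
    csp_tab <- csp(shifts$apo, shifts$holo, w_n = cp$w_n %||% 0.14)
    dev_path <- file.path(out_dir, "deviation_profile.tsv")
    write_tsv_table(as.data.frame(dev), dev_path)
    csp_path <- file.path(out_dir, "csp.tsv")
    write_tsv_table(as.data.frame(csp_tab), csp_path)
    results$deviation <- dev; results$csp <- csp_tab
    note("compare", list(threshold = cp$threshold %||% 1.5),
         c(dev_path, csp_path))
  })

  out <- manifests
  attr(out, "results") <- results
  invisible(out)
}
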