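#' Default run configuration
#'
#' Every stage parameter defaults to the conventional value for this kind
#' of comparative kinase-trajectory analysis: 0.3 correlation display
#' mask, 100x100 free-energy bins at 300 K, 100 k-means centers with 100
#' iterations, 4.5 A / 75% contact criterion, 1 kcal/mol per-residue
#' significance threshold. Any entry can be overridden via `...` or a
#' YAML file ([read_run_config()]).
#'
#' @param ... overrides, e.g. `msm = list(k = 20)` merges into the stage
#'   defaults
#' @return nested list of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    temperature = 300,
    stages = c("stability", "dccm", "pca", "msm", "energetics", "network"),
    synthetic = list(n_residues = 50L, loop_span = 10:17, n_frames = 400L,
                     jitter_sd = 0.25, closed = FALSE),
    stability = list(equilibrated_window = 0.5),
    dccm = list(mask = 0.3),
    pca = list(n_bins = 100L, n_modes = 10L),
    msm = list(k = 100L, max_iterations = 100L, lag = 5L, n_metastates = 3L,
               n_timescales = 3L),
    energetics = list(threshold = 1.0),
    network = list(cutoff = 4.5, occupancy = 0.75, neighbor_offset = 2L))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the same nesting as [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# internal: build a synthetic two-lobe system per the config. `closed`
# selects whether the state path dwells in the closed basin.
synthesize_system <- function(cfg) {
  syn <- cfg$synthetic
  sys <- make_loop_protein(n_residues = syn$n_residues,
                           loop_span = syn$loop_span, seed = cfg$seed)
  nf <- syn$n_frames
  # metastable order parameter on [0, 1]: 0 = open, 1 = closed. The
  # ligand-free system dwells in a broad open basin; the ligand-bound
  # system is locked in a deep, narrow closed basin (the ligand contact
  # rigidifies the loop).
  spec <- if (isTRUE(syn$closed))
    well_spec(centers = c(0.15, 0.9), depths = c(0.6, 4), widths = c(0.2, 0.05),
              temperature = cfg$temperature, friction = 1, timestep = 2e-4)
  else
    well_spec(centers = c(0.15, 0.9), depths = c(2.5, 0.6), widths = c(0.2, 0.06),
              temperature = cfg$temperature, friction = 1, timestep = 2e-3)
  x0 <- if (isTRUE(syn$closed)) 0.9 else 0.15
  path <- sample_overdamped_dynamics(spec, nf, seed = cfg$seed + 7L, x0 = x0)
  s <- pmin(pmax(path[, 1], 0), 1)
  traj <- interpolate_trajectory(sys$open_frame, sys$closed_frame, s,
                                 sys$topology, jitter_sd = syn$jitter_sd,
                                 seed = cfg$seed + 13L, frame_interval = 1)
  list(system = sys, trajectory = traj, state_path = s)
}

#' Run the full comparative analysis pipeline on one system
#'
#' Orchestrates the analysis stages — stability (RMSD/RMSF), residue
#' cross-correlation, PCA with free-energy landscapes, Markov state
#' model, MM/GBSA energetics and the community network — over a
#' trajectory, writing per-stage TSV/JSON outputs plus a machine-readable
#' summary and a log of all effective parameters to `out_dir`.
#'
#' The input is either a synthetic system generated from
#' `config$synthetic` (the default; ligand-bound "closed" behaviour is
#' selected by `synthetic$closed`) or a caller-supplied trajectory.
#'
#' @param config a [run_config()]
#' @param traj optional [trajectory()] to analyse instead of a synthetic
#'   system
#' @param system optional list describing the system regions when `traj`
#'   is supplied: `loop_span`, `hinge_span` residue ids, `ligand_atom`
#' @param out_dir output directory (default: a tempdir subdirectory)
#' @return object of class `md_report` (a nested list of stage results)
#'   with `out_dir` attached.
#' @export
run_pipeline <- function(config = run_config(), traj = NULL, system = NULL,
                         out_dir = tempfile("kindyn_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(traj)) {
    syn <- synthesize_system(config)
    traj <- syn$trajectory
    system <- syn$system
  }
  if (is.null(system)) stopf("a system description is required with a user trajectory")
  top <- traj$topology
  loop_ids <- system$loop_span
  hinge_ids <- system$hinge_span
  prot_ca <- which(top$name == "CA" & !top$is_ligand)
  loop_atoms <- which(top$resid %in% loop_ids & top$name == "CA")
  scaffold_atoms <- setdiff(prot_ca, loop_atoms)
  lig_atoms <- which(top$is_ligand)

  report <- list(config = config)
  stage <- function(name, expr) {
    if (!(name %in% config$stages)) return(NULL)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  report$stability <- stage("stability", {
    series <- rmsd_series(traj, 1L, fit_selection = prot_ca,
                          report_selection = prot_ca)
    loop_series <- rmsd_series(traj, 1L, fit_selection = scaffold_atoms,
                               report_selection = loop_atoms)
    fl <- rmsf(traj, selection = prot_ca, fit_selection = scaffold_atoms)
    utils::write.table(data.frame(frame = seq_along(series), rmsd = series),
                       file.path(out_dir, "rmsd.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(resid = names(fl), rmsf = fl),
                       file.path(out_dir, "rmsf.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(rmsd = series, loop_rmsd = loop_series, rmsf = fl,
         equilibrated = equilibrated_summary(
           series, config$stability$equilibrated_window))
  })

  report$dccm <- stage("dccm", {
    C <- dccm(traj, selection = prot_ca, fit_selection = scaffold_atoms)
    write_correlation_tsv(C, file.path(out_dir, "dccm.tsv"))
    masked <- mask_correlations(C, config$dccm$mask)
    blocks <- list(
      loop_loop = region_correlation_summary(
        C, as.character(loop_ids), as.character(loop_ids)),
      loop_hinge = region_correlation_summary(
        C, as.character(loop_ids), as.character(hinge_ids)))
    list(matrix = C, masked = masked, blocks = blocks)
  })

  report$pca <- stage("pca", {
    pc <- fit_pca(traj, selection = prot_ca, fit_selection = scaffold_atoms,
                  n_modes = min(config$pca$n_modes, n_frames(traj) - 1L))
    dist_series <- loop_distance_series(traj, loop_atoms, lig_atoms)
    loop_rmsd <- report$stability$loop_rmsd
    if (is.null(loop_rmsd))
      loop_rmsd <- rmsd_series(traj, 1L, fit_selection = scaffold_atoms,
                               report_selection = loop_atoms)
    fel_pc <- free_energy_landscape(pc$projections[, 1], pc$projections[, 2],
                                    config$pca$n_bins, config$temperature)
    fel_geo <- free_energy_landscape(loop_rmsd, dist_series,
                                     config$pca$n_bins, config$temperature)
    utils::write.table(
      data.frame(frame = seq_len(nrow(pc$projections)),
                 pc1 = pc$projections[, 1], pc2 = pc$projections[, 2],
                 loop_rmsd = loop_rmsd, loop_ligand_dist = dist_series),
      file.path(out_dir, "pca_projections.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    list(model = pc, distance = dist_series, fel_pc = fel_pc,
         fel_geometry = fel_geo,
         porcupine = porcupine_field(pc, 1L))
  })

  report$msm <- stage("msm", {
    pc <- report$pca$model
    if (is.null(pc)) stopf("msm stage requires the pca stage")
    proj <- pc$projections[, 1:2, drop = FALSE]
    k <- min(config$msm$k, nrow(unique(proj)) - 1L)
    labels <- cluster_microstates(proj, k = k,
                                  max_iterations = config$msm$max_iterations,
                                  seed = config$seed)
    model <- estimate_transition_matrix(labels, lag = config$msm$lag)
    nm <- min(config$msm$n_metastates, nrow(model$transition))
    part <- pcca_metastates(model, nm)
    its <- implied_timescales(labels, lags = unique(pmax(1L, round(
      config$msm$lag * c(0.5, 1, 2, 3)))), n_timescales = config$msm$n_timescales)
    reps <- representative_frames(part, proj)
    meta_of_frame <- rep(NA_integer_, model$n_states)
    meta_of_frame[model$active] <- part$assignment
    mfpts <- list()
    for (a in seq_len(nm)) for (b in seq_len(nm)) {
      if (a == b) next
      mfpts[[sprintf("M%d_to_M%d", a, b)]] <- mfpt(
        model, which(part$assignment == a), which(part$assignment == b),
        frame_interval = traj$frame_interval)$frames
    }
    jsonlite::write_json(
      list(transition = model$transition, stationary = model$stationary,
           membership = part$membership, mfpt_frames = mfpts),
      file.path(out_dir, "msm.json"), auto_unbox = TRUE, digits = NA)
    list(labels = labels, model = model, partition = part, its = its,
         representatives = reps, mfpt_frames = mfpts)
  })

  report$energetics <- stage("energetics", {
    n <- nrow(top)
    charges <- ifelse(top$is_ligand, -0.3, 0.05)
    # sigma chosen so a bead pair in closed contact (~3.6 A) sits near the
    # Lennard-Jones minimum 2^(1/6) sigma
    lj <- data.frame(eps = rep(0.15, n), sigma = rep(3.2, n))
    pair_tab <- ligand_interaction_table(traj, charges, lj)
    decomp <- per_residue_decompose(pair_tab, config$energetics$threshold)
    utils::write.table(decomp, file.path(out_dir, "per_residue_energy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # species tables from the planted per-frame interaction total:
    # complex = interaction, receptor = ligand = 0 (single-trajectory
    # convention on the toy evaluator)
    tot <- tapply(pair_tab$energy, pair_tab$frame, sum)
    mk <- function(v, sp) energy_table(data.frame(
      E_internal = 0, E_elec = 0, E_vdw = as.numeric(v), G_pol = 0, G_np = 0),
      species = sp)
    combo <- mmgbsa_combine(
      mk(tot, "complex"),
      mk(rep(0, length(tot)), "receptor"),
      mk(rep(0, length(tot)), "ligand"))
    list(decomposition = decomp, binding = combo)
  })

  report$network <- stage("network", {
    C <- report$dccm$matrix
    if (is.null(C)) stopf("network stage requires the dccm stage")
    edges <- contact_edges(traj, cutoff = config$network$cutoff,
                           occupancy = config$network$occupancy,
                           neighbor_offset = config$network$neighbor_offset)
    g <- weight_edges(edges, C)
    part <- girvan_newman_communities(g)
    strengths <- intercommunity_strengths(g, part)
    summ <- network_summary(part, strengths)
    loop_hinge_edge <- any(
      (edges$resid_i %in% loop_ids & edges$resid_j %in% hinge_ids) |
      (edges$resid_j %in% loop_ids & edges$resid_i %in% hinge_ids))
    write_network_json(g, part, file.path(out_dir, "network.json"))
    list(edges = edges, graph = g, partition = part, strengths = strengths,
         summary = summ, loop_hinge_edge = loop_hinge_edge)
  })

  summary_obj <- list(
    seed = config$seed,
    stages = intersect(config$stages, names(report)),
    rmsd_mean = report$stability$equilibrated$mean,
    rmsd_sd = report$stability$equilibrated$sd,
    loop_rmsf_mean = if (!is.null(report$stability)) mean(
      report$stability$rmsf[as.character(loop_ids)]) else NULL,
    loop_ligand_distance_mean = if (!is.null(report$pca))
      mean(report$pca$distance) else NULL,
    dG_binding = report$energetics$binding$dG_mean,
    n_communities = report$network$summary$n_communities,
    n_pathways = report$network$summary$n_pathways,
    loop_hinge_edge = report$network$loop_hinge_edge)
  jsonlite::write_json(summary_obj[!vapply(summary_obj, is.null, TRUE)],
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_obj <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  parameters = unclass(config))
  jsonlite::write_json(log_obj, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  report$system <- list(loop_span = loop_ids, hinge_span = hinge_ids)
  report$summary <- summary_obj
  structure(report, out_dir = out_dir, class = "md_report")
}

#' @export
print.md_report <- function(x, ...) {
  cat("<md_report> stages:", paste(x$summary$stages, collapse = ", "), "\n")
  if (!is.null(x$summary$rmsd_mean))
    cat(sprintf("  equilibrated RMSD %.2f +/- %.2f A\n", x$summary$rmsd_mean,
                x$summary$rmsd_sd))
  if (!is.null(x$summary$dG_binding))
    cat(sprintf("  dG_binding %.2f kcal/mol\n", x$summary$dG_binding))
  if (!is.null(x$summary$n_communities))
    cat(sprintf("  %d communities, %d pathways\n", x$summary$n_communities,
                x$summary$n_pathways))
  invisible(x)
}

#' Compare two pipeline reports side by side
#'
#' Deltas are reported as `b - a` for every stage both reports ran:
#' equilibrated RMSD mean, per-residue RMSF, loop-ligand distance mean,
#' correlation block means, binding free energy and community counts,
#' plus the loop-to-hinge contact flag of each system.
#'
#' @param report_a,report_b `md_report`s over matching residue maps
#' @return list of deltas, class `md_comparison`
#' @export
compare_systems <- function(report_a, report_b) {
  out <- list()
  if (!is.null(report_a$stability) && !is.null(report_b$stability)) {
    ra <- report_a$stability$rmsf; rb <- report_b$stability$rmsf
    if (!identical(names(ra), names(rb))) {
      bad <- c(setdiff(names(ra), names(rb)), setdiff(names(rb), names(ra)))
      stopf("residue maps disagree; unmatched residues: %s",
            paste(unique(bad), collapse = ", "))
    }
    out$d_rmsd_mean <- report_b$stability$equilibrated$mean -
      report_a$stability$equilibrated$mean
    out$d_rmsf <- rb - ra
    loop <- as.character(report_a$system$loop_span)
    out$d_loop_rmsf_mean <- mean(rb[loop]) - mean(ra[loop])
  }
  if (!is.null(report_a$dccm) && !is.null(report_b$dccm)) {
    out$d_loop_hinge_correlation <- report_b$dccm$blocks$loop_hinge$mean -
      report_a$dccm$blocks$loop_hinge$mean
  }
  if (!is.null(report_a$pca) && !is.null(report_b$pca)) {
    out$d_loop_ligand_distance <- mean(report_b$pca$distance) -
      mean(report_a$pca$distance)
  }
  if (!is.null(report_a$energetics) && !is.null(report_b$energetics)) {
    out$d_dG_binding <- report_b$energetics$binding$dG_mean -
      report_a$energetics$binding$dG_mean
  }
  if (!is.null(report_a$network) && !is.null(report_b$network)) {
    out$d_n_communities <- report_b$network$summary$n_communities -
      report_a$network$summary$n_communities
    out$d_n_pathways <- report_b$network$summary$n_pathways -
      report_a$network$summary$n_pathways
    out$loop_hinge_edge <- c(a = report_a$network$loop_hinge_edge,
                             b = report_b$network$loop_hinge_edge)
  }
  structure(out, class = "md_comparison")
}

#' @export
print.md_comparison <- function(x, ...) {
  for (nm in setdiff(names(x), "d_rmsf")) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(v, digits = 4),
                                          collapse = " ")))
  }
  invisible(x)
}
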