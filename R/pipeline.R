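# End-to-end pipeline: parse inputs, stability observables,
# representative selection, residue interaction network, centralities and
# hot-spot reports, essential dynamics, correlation network and
# communities. All outputs are TSV/JSON, deterministic, and stamped with
# a hash of the configuration.

#' Pipeline configuration
#'
#' Bundles all thresholds of the analysis with their conventional
#' defaults: 7 Angstrom contact cutoff, hydrogen bonds at 3.5 Angstrom
#' and 30 degrees deviation, hot spots at `C_B >= 0.05`, state differences
#' at `|dC_B| >= 0.02`, cosine-content filter 0.2, 32 landscape bins at
#' 300 K, correlation cutoff 0.5.
#'
#' @param states Named list of states; each state is a list with elements
#'   `structure` (PDB path), `ensemble` (multi-model PDB path, optional)
#'   and `energies` (two-column table path, optional).
#' @param outdir Output directory for reports.
#' @param contact_cutoff,hbond_dmax,hbond_amax,cb_threshold,delta_threshold,cosine_threshold,fel_bins,temperature,corr_cutoff
#'   Analysis parameters; see the individual stage functions.
#' @param seed Integer seed recorded in the summary (the analysis stages
#'   themselves are deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(states, outdir,
                            contact_cutoff = 7, hbond_dmax = 3.5,
                            hbond_amax = 30, cb_threshold = 0.05,
                            delta_threshold = 0.02, cosine_threshold = 0.2,
                            fel_bins = 32, temperature = 300,
                            corr_cutoff = 0.5, seed = 1L) {
  if (is.null(names(states)) || any(!nzchar(names(states))))
    stop("config error: states must be a named list")
  for (p in c(contact_cutoff, hbond_dmax, hbond_amax, cb_threshold,
              delta_threshold, cosine_threshold, fel_bins, temperature,
              corr_cutoff))
    if (!is.numeric(p) || p <= 0) stop("config error: thresholds must be positive")
  out <- list(states = states, outdir = outdir,
              contact_cutoff = contact_cutoff, hbond_dmax = hbond_dmax,
              hbond_amax = hbond_amax, cb_threshold = cb_threshold,
              delta_threshold = delta_threshold,
              cosine_threshold = cosine_threshold, fel_bins = fel_bins,
              temperature = temperature, corr_cutoff = corr_cutoff,
              seed = as.integer(seed))
  class(out) <- "pipeline_config"
  out
}

#' Serialise / restore a pipeline configuration
#'
#' Configurations round-trip through JSON unchanged: reading a written
#' config yields an object with the identical hash.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  states <- lapply(raw$states, as.list)
  do.call(pipeline_config, c(list(states = states, outdir = raw$outdir),
                             raw[setdiff(names(raw), c("states", "outdir"))]))
}

# deterministic 31-bit polynomial hash of the canonical serialisation of
# the configuration (double arithmetic keeps every step exact)
config_hash <- function(config) {
  flat <- config[setdiff(names(config), c("states", "outdir"))]
  s <- paste(names(flat), vapply(flat, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  s <- paste0(s, ";states=", paste(names(config$states), collapse = ","))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_tsv_report <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config=", hash), con)
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

analyse_state <- function(name, st, cfg, hash, log) {
  rep_file <- function(stub) file.path(cfg$outdir, paste0(stub, "_", name, ".tsv"))
  out <- list()

  if (is.null(st$ensemble)) stop("state '", name, "': ensemble input required")
  ens <- read_ensemble(st$ensemble)
  log("state %s: %d frames, %d residues", name, n_frames(ens),
      n_residues(ens$topology))

  # stability observables
  rms <- rmsd_series(ens)
  rmsf_ca <- rmsf(ens)
  stab <- data.frame(time_ps = ens$times, rmsd_backbone = rms)
  write_tsv_report(stab, rep_file("stability"), hash)
  rt <- residue_table(ens$topology)
  write_tsv_report(data.frame(label = rt$label, rmsf_ca = rmsf_ca),
                   rep_file("rmsf"), hash)

  # hydrogen-bond observables when a ligand is present
  if (any(ens$topology$atoms$het)) {
    counts <- hbond_count_series(ens, cfg$hbond_dmax, cfg$hbond_amax)
    occ <- hbond_occupancy(ens, cfg$hbond_dmax, cfg$hbond_amax)
    write_tsv_report(data.frame(time_ps = ens$times, n_hbonds = counts),
                     rep_file("hbonds"), hash)
    write_tsv_report(as.data.frame(occ), rep_file("occupancy"), hash)
    out$mean_hbonds <- mean(counts)
    log("state %s: mean protein-ligand H-bonds %.3f", name, mean(counts))
  }

  # representative selection (energy table optional)
  if (!is.null(st$energies)) {
    en <- read_energy_table(st$energies)
    if (nrow(en) != n_frames(ens))
      stop("state '", name, "': energy table rows do not match frame count")
    energies <- en$energy
  } else {
    warning("state '", name, "': no energy table; using frame 1 as representative")
    energies <- c(0, rep(1, n_frames(ens) - 1))
  }
  sel <- select_representative(ens, energies)
  write_tsv_report(data.frame(frame = seq_len(n_frames(ens)),
                              energy = energies,
                              rmsd_to_min = sel$rmsd_to_min,
                              in_top_set = seq_len(n_frames(ens)) %in% sel$top_set,
                              representative = seq_len(n_frames(ens)) == sel$frame_index),
                   rep_file("representative"), hash)
  log("state %s: representative frame %d", name, sel$frame_index)
  rep_struct <- frame_structure(ens, sel$frame_index)

  # SASA of the representative structure
  sa <- sasa(rep_struct)
  write_tsv_report(data.frame(label = names(sa$per_residue),
                              sasa_nm2 = sa$per_residue),
                   rep_file("sasa"), hash)
  out$sasa_total <- sa$total

  # residue interaction network and centralities
  net <- build_network(rep_struct, cutoff = cfg$contact_cutoff,
                       hbonds = find_hbonds(rep_struct,
                                            d_max = cfg$hbond_dmax,
                                            angle_max = cfg$hbond_amax))
  write_network(net, rep_file("network"), rep_file("nodes"), hash = hash)
  ct <- centrality_table(net, state = name)
  write_tsv_report(as.data.frame(ct), rep_file("centrality"), hash)
  hs <- hotspots(ct, cfg$cb_threshold)
  write_tsv_report(as.data.frame(hs), rep_file("hotspots"), hash)
  log("state %s: network %d edges, %d hot spots", name, nrow(net$edges),
      nrow(hs))
  out$centrality <- ct

  # essential dynamics
  pca <- backbone_pca(ens)
  write_tsv_report(summary(pca), rep_file("pca"), hash)
  modes <- fel_modes(pca, cfg$cosine_threshold)
  if (length(modes) == 2) {
    fel <- free_energy_landscape(pca$projections[, modes[1]],
                                 pca$projections[, modes[2]],
                                 n_bins = cfg$fel_bins,
                                 temperature = cfg$temperature)
    grid <- expand.grid(bin_x = seq_len(cfg$fel_bins),
                        bin_y = seq_len(cfg$fel_bins))
    grid$free_energy_kT <- as.vector(fel$free_energy)
    grid <- grid[is.finite(grid$free_energy_kT), , drop = FALSE]
    write_tsv_report(grid, rep_file("fel"), hash)
    log("state %s: FEL on modes %s, %d minima", name,
        paste(modes, collapse = "/"), nrow(fel$minima))
  } else {
    log("state %s: fewer than 2 modes pass the cosine filter; FEL skipped",
        name)
    write_tsv_report(data.frame(bin_x = integer(), bin_y = integer(),
                                free_energy_kT = numeric()),
                     rep_file("fel"), hash)
  }
  out$eigenvalue_sum <- pca$trace

  # correlation network and communities
  cij <- cross_correlation(ens)
  cm <- as.data.frame(as.table(unclass(cij)))
  names(cm) <- c("res_i", "res_j", "c_ij")
  write_tsv_report(cm, rep_file("correlation"), hash)
  cg <- build_correlation_network(cij, cfg$corr_cutoff)
  part <- detect_communities(cg)
  write_tsv_report(data.frame(label = rt$label, community = part$membership),
                   rep_file("communities"), hash)
  log("state %s: %d communities (Q = %.3f)", name, part$n_communities,
      part$modularity)
  out$n_communities <- part$n_communities
  out$modularity <- part$modularity
  out
}

#' Run the full analysis pipeline
#'
#' Executes, per state: parse, stability observables, representative
#' selection, residue interaction network, centralities with hot-spot
#' reports, essential dynamics with free-energy landscape, and the
#' correlation network with communities; then cross-state
#' betweenness-difference reports against the first state. Every report
#' file carries the configuration hash in a leading `#` comment line and
#' reruns with identical inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default FALSE; messages go to
#'   standard error).
#' @return Invisibly, a list with the output directory, the config hash
#'   and the per-state summaries (also written to `summary.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  results <- list()
  for (name in names(config$states)) {
    results[[name]] <- tryCatch(
      analyse_state(name, config$states[[name]], config, hash, log),
      error = function(e) stop("stage failure in state '", name, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  # cross-state betweenness differences against the first state
  snames <- names(config$states)
  if (length(snames) > 1) {
    for (other in snames[-1]) {
      dr <- delta_hotspots(results[[snames[1]]]$centrality,
                           results[[other]]$centrality,
                           config$delta_threshold)
      write_tsv_report(as.data.frame(dr),
                       file.path(config$outdir,
                                 paste0("delta_", snames[1], "_vs_", other, ".tsv")),
                       hash)
      log("delta %s vs %s: %d residues above %.3g", snames[1], other,
          nrow(dr), config$delta_threshold)
    }
  }
  summary <- list(
    config_hash = hash,
    parameters = config[setdiff(names(config), c("states", "outdir"))],
    states = lapply(results, function(r)
      r[setdiff(names(r), "centrality")]))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(outdir = config$outdir, config_hash = hash,
                 results = results))
}

#' Write synthetic fixture files for a spec
#'
#' Thin wrapper over the synthetic generator: writes the reference
#' structure, the multi-model ensemble and a per-frame energy table
#' (a smooth quadratic well plus a deterministic ripple, so the energy
#' minimum falls mid-trajectory) into a directory.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory.
#' @param prefix File name prefix (default "state").
#' @return Named character vector of the written paths.
#' @export
simulate_fixture <- function(spec, dir, prefix = "state") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- make_structure(spec)
  ens <- make_ensemble(spec, s)
  f_str <- file.path(dir, paste0(prefix, "_structure.pdb"))
  f_ens <- file.path(dir, paste0(prefix, "_ensemble.pdb"))
  f_en <- file.path(dir, paste0(prefix, "_energy.xvg"))
  write_pdb(s, f_str)
  write_pdb(ens, f_ens)
  nf <- n_frames(ens)
  tt <- ens$times
  energy <- 100 + 0.5 * (seq_len(nf) - 0.6 * nf)^2 + 3 * sin(seq_len(nf))
  write_energy_table(tt, energy, f_en)
  c(structure = f_str, ensemble = f_ens, energies = f_en)
}
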