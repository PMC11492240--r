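# Pipeline stage commands. Each cmd_* function is what the command-line
# wrapper (inst/cli/reinet.R) calls for one subcommand: it reads a plain-text
# YAML config, runs the corresponding package functions, and writes the
# stage's artifacts plus provenance (config echo, package version, input
# checksums) into the output directory, so identical config + inputs give
# byte-identical numeric outputs.

RUN_CONFIG_KEYS <- c(
  "pdb", "psf", "parameters", "trajectory", "chain", "stride",
  "cutoff", "switch_on", "coulomb_const", "dielectric", "elec_scheme", "scale14_elec",
  "network", "com_cutoff", "com_mode", "atom_cutoff", "min_energy",
  "energy_dir", "network_dir",
  "normalization", "direction", "report_residues", "write_bfactor_pdb",
  "sub_matrix", "gap_open", "gap_extend",
  "out_dir", "seed"
)

#' Read and validate a pipeline run configuration
#'
#' Plain-text YAML; unknown keys are rejected so a typo cannot silently fall
#' back to a default. `overrides` (named list, e.g. from command-line flags)
#' take precedence over the file.
#'
#' @param path YAML config path (optional if all keys come from `overrides`).
#' @param overrides Named list of overriding values.
#' @return A named `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_usage(sprintf("config file not found: %s", path))
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop_validation(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

cfg_get <- function(config, key, default = NULL, required = FALSE) {
  val <- config[[key]]
  if (is.null(val)) {
    if (required) stop_usage(sprintf("config key '%s' is required", key))
    return(default)
  }
  val
}

cfg_nb_params <- function(config) {
  nb_params(
    cutoff = cfg_get(config, "cutoff", 12),
    switch_on = cfg_get(config, "switch_on", 10),
    coulomb_const = cfg_get(config, "coulomb_const", 332.0636),
    dielectric = cfg_get(config, "dielectric", 1),
    elec_scheme = cfg_get(config, "elec_scheme", "shifted"),
    scale14_elec = cfg_get(config, "scale14_elec", 1)
  )
}

write_provenance <- function(config, out_dir, inputs) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_echo.yaml"))
  files <- as.character(unlist(inputs, use.names = FALSE))
  files <- files[file.exists(files)]
  sums <- if (length(files) > 0L) tools::md5sum(files) else character(0)
  writeLines(
    c(sprintf("reinet %s", as.character(utils::packageVersion("reinet"))),
      if (length(sums) > 0L) sprintf("%s  %s", sums, names(sums))),
    file.path(out_dir, "provenance.txt")
  )
}

load_system <- function(config) {
  psf <- cfg_get(config, "psf", required = TRUE)
  prm <- cfg_get(config, "parameters", required = TRUE)
  trj <- cfg_get(config, "trajectory", required = TRUE)
  if (!file.exists(psf)) stop_usage(sprintf("PSF file not found: %s", psf))
  if (!file.exists(prm)) stop_usage(sprintf("parameter file not found: %s", prm))
  if (!file.exists(trj)) stop_usage(sprintf("trajectory file not found: %s", trj))
  topo <- read_topology(psf, prm)
  traj <- read_trajectory(topo, trj, stride = cfg_get(config, "stride", 1L))
  list(topology = topo, trajectory = traj,
       inputs = list(psf = psf, parameters = prm, trajectory = trj))
}

#' Pipeline stage: pairwise interaction energy matrix
#'
#' Reads the system named in the config, evaluates the trajectory-mean
#' absolute residue pair energies, and writes the matrix files plus
#' provenance into `out_dir`. Logs the pair count before and after the
#' distance prefilter.
#'
#' @param config A `run_config` (see [read_run_config()]); needs `psf`,
#'   `parameters`, `trajectory`, `out_dir`, optional nonbonded keys and
#'   `stride`.
#' @return The [pair_energy_matrix()], invisibly.
#' @export
cmd_energy <- function(config) {
  sys <- load_system(config)
  out_dir <- cfg_get(config, "out_dir", required = TRUE)
  params <- cfg_nb_params(config)
  nres <- n_residues(sys$topology)
  cand <- candidate_pairs(sys$topology, sys$trajectory, params)
  message(sprintf("residue pairs: %d total, %d after distance prefilter",
                  (nres * (nres - 1L)) %/% 2L, nrow(cand)))
  pem <- pair_energy_matrix(sys$topology, sys$trajectory, params)
  write_pair_energy_matrix(pem, out_dir)
  write_provenance(config, out_dir, sys$inputs)
  invisible(pem)
}

#' Pipeline stage: residue network construction
#'
#' Builds the network type named by the config key `network`:
#' `"energy"` (from a previous [cmd_energy()] output directory, key
#' `energy_dir`), `"com"` (centre-of-mass contacts from the trajectory), or
#' `"atom"` (directed atom-contact network from the final snapshot).
#'
#' @param config A `run_config`.
#' @return The [resnet()], invisibly.
#' @export
cmd_network <- function(config) {
  out_dir <- cfg_get(config, "out_dir", required = TRUE)
  type <- cfg_get(config, "network", required = TRUE)
  if (!type %in% c("energy", "com", "atom")) {
    stop_usage("config key 'network' must be one of energy, com, atom")
  }
  if (type == "energy") {
    edir <- cfg_get(config, "energy_dir", required = TRUE)
    if (!file.exists(file.path(edir, "energy_matrix.tsv"))) {
      stop_usage(sprintf("no energy matrix found in '%s'", edir))
    }
    pem <- read_pair_energy_matrix(edir)
    net <- build_energy_network(pem, min_energy = cfg_get(config, "min_energy", 1e-8))
    inputs <- list(energy_matrix = file.path(edir, "energy_matrix.tsv"))
  } else {
    sys <- load_system(config)
    inputs <- sys$inputs
    net <- if (type == "com") {
      build_residue_com_network(sys$topology, sys$trajectory,
                                cutoff = cfg_get(config, "com_cutoff", 8),
                                mode = cfg_get(config, "com_mode", "weighted"))
    } else {
      build_atom_contact_network(sys$topology, get_frame(sys$trajectory),
                                 atom_cutoff = cfg_get(config, "atom_cutoff", 3.5))
    }
  }
  write_network(net, out_dir)
  write_provenance(config, out_dir, inputs)
  invisible(net)
}

#' Pipeline stage: shortest-path profile and ratio report
#'
#' Consumes a network directory (`network_dir`), runs the all-pairs shortest
#' path analysis, writes the path matrix, the (normalised) per-residue
#' profile, and a JSON ratio report covering any residues named in
#' `report_residues` plus the global extremes. Optionally maps the profile
#' onto a structure via the B-factor column when the config names a `pdb`
#' (and, for PSF-derived systems, the matching topology inputs).
#'
#' @param config A `run_config`.
#' @return The normalised `residue_profile`, invisibly.
#' @export
cmd_analyze <- function(config) {
  out_dir <- cfg_get(config, "out_dir", required = TRUE)
  ndir <- cfg_get(config, "network_dir", required = TRUE)
  if (!file.exists(file.path(ndir, "network_adjacency.tsv"))) {
    stop_usage(sprintf("no network found in '%s'", ndir))
  }
  net <- read_network(ndir)
  pm <- all_pairs_shortest_paths(net)
  prof <- average_shortest_path_profile(pm, direction = cfg_get(config, "direction", "in"))
  prof <- normalize_profile(prof, method = cfg_get(config, "normalization", "mean"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_matrix_tsv(unclass(pm), file.path(out_dir, "path_matrix.tsv"))
  write_residue_profile(prof, out_dir)

  fin <- prof$value[is.finite(prof$value)]
  report <- list(
    semantics = net$semantics,
    profile_mean = mean(fin),
    global_min = list(label = prof$label[which.min(prof$value)],
                      value = min(prof$value)),
    global_max_finite = list(label = prof$label[which(prof$value == max(fin))[1]],
                             value = max(fin))
  )
  want <- cfg_get(config, "report_residues", character(0))
  report$residues <- lapply(as.character(want), function(lab) {
    list(label = lab, value = prof$value[match(lab, prof$label)],
         ratio = peak_to_average_ratio(prof, lab))
  })
  jsonlite::write_json(report, file.path(out_dir, "ratio_report.json"),
                       digits = NA, auto_unbox = TRUE)

  if (!is.null(cfg_get(config, "pdb")) && isTRUE(cfg_get(config, "write_bfactor_pdb", TRUE))) {
    st <- read_structure(cfg_get(config, "pdb"), chain = cfg_get(config, "chain"))
    if (n_residues(st$topology) == nrow(prof)) {
      write_profile_structure(st$frame, st$topology, prof,
                              file.path(out_dir, "profile_bfactor.pdb"))
    } else {
      warn("PDB residue count does not match the profile; skipping B-factor structure")
    }
  }
  write_provenance(config, out_dir,
                   list(network = file.path(ndir, "network_adjacency.tsv")))
  invisible(prof)
}

#' Pipeline stage: cross-structure profile comparison
#'
#' Aligns the sequences of two analysed systems and writes the per-column
#' absolute difference of their normalised profiles. Profiles must come from
#' networks with the same semantics; mixing network types is refused.
#'
#' @param config_a,config_b `run_config`s whose `out_dir`s hold
#'   [cmd_analyze()] outputs; each must also name the system inputs (`psf` +
#'   `parameters`, or `pdb`) so sequences can be extracted.
#' @param out_dir Output directory for the comparison.
#' @return The `aligned_comparison`, invisibly.
#' @export
cmd_compare <- function(config_a, config_b, out_dir) {
  prof_a <- read_residue_profile(cfg_get(config_a, "out_dir", required = TRUE))
  prof_b <- read_residue_profile(cfg_get(config_b, "out_dir", required = TRUE))
  sem_a <- attr(prof_a, "semantics"); sem_b <- attr(prof_b, "semantics")
  if (!is.null(sem_a) && !is.null(sem_b) && !identical(sem_a, sem_b)) {
    stop_validation(sprintf(
      "profiles come from different network types (%s vs %s); comparison refused",
      sem_a, sem_b))
  }
  seq_of <- function(config) {
    if (!is.null(cfg_get(config, "psf"))) {
      topo <- read_topology(cfg_get(config, "psf"),
                            cfg_get(config, "parameters", required = TRUE))
    } else if (!is.null(cfg_get(config, "pdb"))) {
      topo <- read_structure(cfg_get(config, "pdb"),
                             chain = cfg_get(config, "chain"))$topology
    } else {
      stop_usage("comparison needs 'psf'+'parameters' or 'pdb' in each config")
    }
    extract_sequence(topo)
  }
  map <- global_align(seq_of(config_a), seq_of(config_b),
                      sub_matrix = cfg_get(config_a, "sub_matrix", "BLOSUM62"),
                      gap_open = cfg_get(config_a, "gap_open", 10),
                      gap_extend = cfg_get(config_a, "gap_extend", 0.5))
  cmp <- compare_profiles(prof_a, prof_b, map)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(cmp), file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  write_alignment_fasta(map, file.path(out_dir, "alignment.fasta"))
  jsonlite::write_json(
    list(mean_abs_difference = attr(cmp, "mean_abs_difference"),
         n_columns = attr(map, "n_columns"),
         n_pairs = nrow(alignment_pairs(map)),
         alignment_params = attr(map, "params")),
    file.path(out_dir, "comparison_summary.json"), digits = NA, auto_unbox = TRUE
  )
  write_provenance(config_a, out_dir, list())
  invisible(cmp)
}
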