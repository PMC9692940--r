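# End-to-end pipeline wiring, structured table output, run manifests and the
# engine behind the command-line entry points (inst/cli/mdoc).

mdoc_version <- function() {
  as.character(utils::packageVersion("mdoc"))
}

#' Write a tab-separated table with a provenance header
#'
#' The header line names the producing tool version and the column units.
#'
#' @param df data.frame
#' @param path output path
#' @param what one-line description including units
#' @return invisibly, the path
#' @export
write_table <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mdoc %s | %s", mdoc_version(), what), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_config_schema <- list(
  top = c("seed", "output_dir", "scenario", "simulation", "analysis"),
  scenario = c("template", "p_minor", "minima", "barrier", "order_parameter",
               "noise_scale"),
  simulation = c("n_steps", "dt", "temperature", "tau_thermostat",
                 "snapshot_interval", "tau_memory", "ramp_steps"),
  analysis = c("bin_width", "boundary")
)

#' Read and validate a pipeline configuration file
#'
#' YAML ("key: value") with sections \code{scenario}, \code{simulation},
#' \code{analysis} plus top-level \code{seed} and \code{output_dir}. Unknown
#' keys are rejected by name. Command-line flags override config keys.
#'
#' @param path config file
#' @param overrides named list overriding top-level or section keys (names
#'   like "simulation.n_steps")
#' @return validated config list
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) cfg[[parts]] <- overrides[[nm]]
    else cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  bad <- setdiff(names(cfg), pipeline_config_schema$top)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in c("scenario", "simulation", "analysis")) {
    bad <- setdiff(names(cfg[[sec]]), pipeline_config_schema[[sec]])
    if (length(bad)) stop("unknown config key(s) in ", sec, ": ",
                          paste(bad, collapse = ", "))
  }
  cfg
}

get_or <- function(lst, key, default) {
  if (is.null(lst[[key]])) default else lst[[key]]
}

#' Run the synth -> simulate -> analyze pipeline
#'
#' Builds the configured two-state scenario, generates its reference
#' observables, runs the restrained simulation, and writes the analysis
#' products (restraint table, trajectory, diagnostics, torsion distribution,
#' conformer table, chi-square report) plus a run manifest into the output
#' directory.
#'
#' @param config_path path to a YAML pipeline config
#' @param overrides named list of key overrides (see
#'   \code{\link{read_pipeline_config}})
#' @return invisibly, a list with the analysis results and output paths
#' @export
run_pipeline <- function(config_path, overrides = list()) {
  cfg <- read_pipeline_config(config_path, overrides)
  seed <- as.integer(get_or(cfg, "seed", 1))
  out_dir <- get_or(cfg, "output_dir", "mdoc_out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc_cfg <- get_or(cfg, "scenario", list())
  sim_cfg <- get_or(cfg, "simulation", list())
  an_cfg <- get_or(cfg, "analysis", list())

  t0 <- proc.time()["elapsed"]
  scenario <- two_state_scenario(
    p_minor = get_or(sc_cfg, "p_minor", 0.2),
    minima = get_or(sc_cfg, "minima", 60),
    barrier = get_or(sc_cfg, "barrier", 6),
    order_parameter = get_or(sc_cfg, "order_parameter", 1),
    noise_scale = get_or(sc_cfg, "noise_scale", 1),
    seed = seed
  )
  table <- generate_reference_observables(scenario)
  mol_path <- file.path(out_dir, "molecule.xyz")
  restr_path <- file.path(out_dir, "restraints.tsv")
  write_xyz(scenario$mol, mol_path)
  write_restraints(table, restr_path)
  message(sprintf("[synth] %d restraints generated (%.2f s)",
                  nrow(table), proc.time()["elapsed"] - t0))

  t1 <- proc.time()["elapsed"]
  config <- md_config(
    n_steps = get_or(sim_cfg, "n_steps", 4e5),
    dt = get_or(sim_cfg, "dt", 0.5),
    temperature = get_or(sim_cfg, "temperature", 306.3),
    tau_thermostat = get_or(sim_cfg, "tau_thermostat", 100),
    seed = seed,
    snapshot_interval = get_or(sim_cfg, "snapshot_interval", 50),
    tau_memory = get_or(sim_cfg, "tau_memory", 10000),
    ramp_steps = get_or(sim_cfg, "ramp_steps", 20000)
  )
  rs <- restraint_set(scenario$mol, table)
  sim <- run_simulation(scenario$mol, scenario$ff, rs, config,
                        types = scenario$types)
  traj_path <- file.path(out_dir, "trajectory.xyz")
  diag_path <- file.path(out_dir, "diagnostics.tsv")
  write_trajectory_xyz(sim$trajectory, scenario$mol$atoms$element, traj_path)
  write_table(sim$diagnostics, diag_path,
              "per-snapshot diagnostics; temperature K, energies kcal/mol, time fs")
  message(sprintf("[simulate] %d steps, mean T %.1f K (%.2f s)",
                  config$n_steps, sim$mean_temperature,
                  proc.time()["elapsed"] - t1))

  t2 <- proc.time()["elapsed"]
  quad <- scenario$soft_torsions[[1]]
  keep <- sim$trajectory$times > config$ramp_steps * config$dt + 2 * config$tau_memory
  if (sum(keep) < 10) { # very short runs: analyse the second half instead
    keep <- seq_along(sim$trajectory$times) > length(sim$trajectory$times) / 2
  }
  series <- torsion_series(sim$trajectory$coords, quad)[keep]
  dist <- torsion_distribution(series, get_or(an_cfg, "bin_width", 2))
  ctab <- joint_state_probabilities(list(soft = series),
                                    get_or(an_cfg, "boundary", 0))
  comp <- predict_observables(sim$trajectory, rs, config$field_axis)
  rep <- chi2_report(comp)
  dist_path <- file.path(out_dir, "torsion_distribution.tsv")
  conf_path <- file.path(out_dir, "conformer_table.tsv")
  chi2_path <- file.path(out_dir, "chi2_report.tsv")
  write_table(dist, dist_path, "torsion distribution; midpoint deg, probability %")
  write_table(as.data.frame(ctab), conf_path, "joint conformer states; probability %")
  write_table(as.data.frame(rep), chi2_path,
              "observable comparison; RDC Hz, NOE A, J3 Hz")
  for (ty in unique(comp$type)) {
    sub <- chi2_report(comp[comp$type == ty, ])
    message(sprintf("[analyze] %s: n = %d, quality n/chi2 = %.2f, outliers = %d",
                    ty, attr(sub, "n"), attr(sub, "quality"), attr(sub, "n_outliers")))
  }
  message(sprintf("[analyze] done (%.2f s)", proc.time()["elapsed"] - t2))

  outputs <- c(mol_path, restr_path, traj_path, diag_path, dist_path,
               conf_path, chi2_path)
  manifest_path <- write_manifest(out_dir, cfg, seed, inputs = config_path,
                                  outputs = outputs)
  invisible(list(scenario = scenario, sim = sim, distribution = dist,
                 conformers = ctab, chi2 = rep, outputs = outputs,
                 manifest = manifest_path))
}

#' Write a run manifest
#'
#' Records the config snapshot, input digests, seed, tool version and output
#' file list; written atomically (temp file + rename) at run end.
#'
#' @param out_dir output directory
#' @param cfg config list snapshot
#' @param seed seed used
#' @param inputs input file paths
#' @param outputs output file paths
#' @return the manifest path
#' @export
write_manifest <- function(out_dir, cfg, seed, inputs, outputs) {
  manifest <- list(
    tool = "mdoc", version = mdoc_version(), seed = seed,
    config = cfg,
    inputs = as.list(stats::setNames(as.character(tools::md5sum(inputs)), inputs)),
    outputs = as.list(stats::setNames(as.character(tools::md5sum(outputs)), outputs))
  )
  path <- file.path(out_dir, "manifest.json")
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  path
}

#' Score a calculated observable table against an experimental one
#'
#' Both tables are restraint-style TSVs (type, atom1, atom2, value, error);
#' rows are matched on (type, atom1, atom2) and a chi-square report is
#' produced per class and overall.
#'
#' @param exp_path experimental table
#' @param calc_path calculated table
#' @return list with the overall \code{mdoc_chi2} report and a per-class
#'   summary data.frame
#' @export
score_tables <- function(exp_path, calc_path) {
  ex <- read_restraints(exp_path)
  ca <- read_restraints(calc_path)
  key <- function(d) paste(d$type, d$atom1, d$atom2)
  m <- match(key(ex), key(ca))
  if (anyNA(m)) stop("calculated table lacks rows for: ",
                     paste(key(ex)[is.na(m)], collapse = "; "))
  comp <- data.frame(label = paste(ex$atom1, ex$atom2, sep = "-"),
                     type = ex$type, q_exp = ex$value, q_calc = ca$value[m],
                     error = ex$error)
  if (any(is.na(comp$error))) {
    comp$error[is.na(comp$error) & comp$type == "RDC"] <- DEFAULT_RDC_ERROR
    comp$error[is.na(comp$error) & comp$type == "J3"] <- DEFAULT_J_ERROR
    nn <- is.na(comp$error) & comp$type == "NOE"
    comp$error[nn] <- default_noe_error(comp$q_exp[nn])
  }
  overall <- chi2_report(comp)
  per_class <- do.call(rbind, lapply(unique(comp$type), function(ty) {
    r <- chi2_report(comp[comp$type == ty, ])
    data.frame(type = ty, n = attr(r, "n"), chi2 = attr(r, "chi2"),
               quality = attr(r, "quality"), n_outliers = attr(r, "n_outliers"),
               min_inv_chi2 = attr(r, "min_inv_chi2"))
  }))
  list(overall = overall, per_class = per_class)
}
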