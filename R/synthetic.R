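# Synthetic scenarios with known ground truth: toy molecules with a
# controllable two-state torsional equilibrium and ensemble-averaged
# observables generated from known populations.

#' Build a flexible toy molecule with a tunable double-well torsion
#'
#' Templates:
#' \itemize{
#'   \item \code{"chain"}: a butane-like backbone X-CH2-CH2-X in which the
#'     terminal methyls are replaced by halogen-like caps, so the monitored
#'     central torsion is the only internal rotor (8 atoms, no methyl
#'     spinning).
#'   \item \code{"chain2"}: X-CH2-CH2-CH2-X with two soft torsions (11 atoms),
#'     for joint conformer-state analyses.
#' }
#' The soft torsion(s) get the potential A (cos phi - cos phi0)^2 (+ optional
#' sin-phase tilt), giving symmetric minima at +/- phi0 with the barrier over
#' phi = 0 equal to \code{barrier}, and a strongly penalized trans region.
#' Nonbonded parameters are kept small so the torsion term dominates the
#' profile, and the bending terms are deliberately stiff so that each
#' torsional state stays close to the rigid geometry its reference observables
#' are computed from.
#'
#' @param template one of \code{"chain"}, \code{"chain2"}
#' @param minima position of the torsion minima (degrees, +/- this value)
#' @param barrier barrier height over the phi = 0 crossing (kcal/mol)
#' @param asymmetry energy offset E(+minima) - E(-minima) (kcal/mol); applied
#'   as a sin-phase cosine term
#' @param start_torsion torsion value(s) of the built coordinates (degrees)
#' @return list with \code{mol}, \code{ff}, \code{soft_torsions} (list of
#'   4-index vectors), \code{types}
#' @export
make_flexible_toy <- function(template = c("chain", "chain2"), minima = 60,
                              barrier = 6, asymmetry = 0,
                              start_torsion = minima) {
  template <- match.arg(template)
  if (minima <= 0 || minima >= 180) stop("minima must be in (0, 180) degrees")
  A <- barrier / (1 - cos(deg2rad(minima)))^2
  tors <- data.frame(
    type1 = c("CL", "CL", "CL"), type2 = c("C", "C", "C"),
    type3 = c("C", "C", "C"), type4 = c("CL", "CL", "CL"),
    v = c(A / 2, -2 * A * cos(deg2rad(minima)), asymmetry / (2 * sin(deg2rad(minima)))),
    n = c(2L, 1L, 1L), phase = c(0, 0, 90),
    stringsAsFactors = FALSE
  )
  if (template == "chain2") {
    t2 <- tors
    t2$type4 <- "C" # CL-C-C-C soft torsions of the longer chain
    tors <- t2
  }
  ff <- structure(list(
    atomtypes = data.frame(
      type = c("H", "C", "CL"),
      epsilon = c(0.005, 0.02, 0.01),
      sigma = c(2.3, 3.2, 3.0),
      charge = c(0, 0, 0), stringsAsFactors = FALSE),
    bonds = data.frame(
      type1 = c("C", "C", "C"), type2 = c("C", "H", "CL"),
      k = c(310, 340, 232), r0 = c(1.526, 1.09, 1.79),
      stringsAsFactors = FALSE),
    angles = data.frame(
      type1 = "X", type2 = "C", type3 = "X",
      k = 150, theta0 = 109.471, stringsAsFactors = FALSE),
    torsions = rbind(
      data.frame(type1 = "X", type2 = "C", type3 = "C", type4 = "X",
                 v = 0, n = 3L, phase = 0, stringsAsFactors = FALSE),
      tors),
    scale14_lj = 0.5, scale14_coulomb = 0.833
  ), class = "mdoc_forcefield")

  th <- 109.471
  if (template == "chain") {
    zm <- rbind(
      zmatrix_row("Cl"),
      zmatrix_row("C", a = 1, r = 1.79),
      zmatrix_row("C", a = 2, r = 1.526, b = 1, theta = th),
      zmatrix_row("Cl", a = 3, r = 1.79, b = 2, theta = th, c = 1, phi = start_torsion),
      zmatrix_row("H", a = 2, r = 1.09, b = 3, theta = th, c = 4, phi = wrap_angle(start_torsion + 120)),
      zmatrix_row("H", a = 2, r = 1.09, b = 3, theta = th, c = 4, phi = wrap_angle(start_torsion - 120)),
      zmatrix_row("H", a = 3, r = 1.09, b = 2, theta = th, c = 1, phi = wrap_angle(start_torsion + 120)),
      zmatrix_row("H", a = 3, r = 1.09, b = 2, theta = th, c = 1, phi = wrap_angle(start_torsion - 120))
    )
    labels <- c("Cl1", "C1", "C2", "Cl2", "H1a", "H1b", "H2a", "H2b")
    bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5), c(2, 6), c(3, 7), c(3, 8))
    soft <- list(c(1, 2, 3, 4))
  } else {
    start_torsion <- rep_len(start_torsion, 2)
    zm <- rbind(
      zmatrix_row("Cl"),
      zmatrix_row("C", a = 1, r = 1.79),
      zmatrix_row("C", a = 2, r = 1.526, b = 1, theta = th),
      zmatrix_row("C", a = 3, r = 1.526, b = 2, theta = th, c = 1, phi = start_torsion[1]),
      zmatrix_row("Cl", a = 4, r = 1.79, b = 3, theta = th, c = 2, phi = start_torsion[2]),
      zmatrix_row("H", a = 2, r = 1.09, b = 3, theta = th, c = 4, phi = wrap_angle(start_torsion[1] + 120)),
      zmatrix_row("H", a = 2, r = 1.09, b = 3, theta = th, c = 4, phi = wrap_angle(start_torsion[1] - 120)),
      zmatrix_row("H", a = 3, r = 1.09, b = 4, theta = th, c = 5, phi = wrap_angle(start_torsion[2] + 120)),
      zmatrix_row("H", a = 3, r = 1.09, b = 4, theta = th, c = 5, phi = wrap_angle(start_torsion[2] - 120)),
      zmatrix_row("H", a = 4, r = 1.09, b = 3, theta = th, c = 2, phi = wrap_angle(start_torsion[1] + 120)),
      zmatrix_row("H", a = 4, r = 1.09, b = 3, theta = th, c = 2, phi = wrap_angle(start_torsion[1] - 120))
    )
    labels <- c("Cl1", "C1", "C2", "C3", "Cl2", "H1a", "H1b", "H2a", "H2b", "H3a", "H3b")
    bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                   c(2, 6), c(2, 7), c(3, 8), c(3, 9), c(4, 10), c(4, 11))
    soft <- list(c(1, 2, 3, 4), c(2, 3, 4, 5))
  }
  xyz <- build_from_zmatrix(zm)
  types <- ifelse(zm$element == "Cl", "CL", zm$element)
  mol <- molecule(zm$element, xyz, bonds = bonds, labels = labels)
  list(mol = mol, ff = ff, soft_torsions = soft, types = types)
}

#' Define a two-state conformer scenario
#'
#' A toy molecule with one soft torsion whose two states (at +/- the torsion
#' minimum) are populated with known ground-truth probabilities; synthetic
#' ensemble-averaged observables are generated from those populations by
#' \code{\link{generate_reference_observables}}.
#'
#' @param p_minor ground-truth population of the minor state, in (0, 1)
#' @param minima torsion minima (degrees); major state at +minima, minor at
#'   -minima
#' @param barrier torsional barrier over phi = 0 (kcal/mol)
#' @param order_parameter axial orientational order parameter applied to the
#'   per-state dipolar tensors when generating RDC targets; the default of 1
#'   (a notionally fully aligned sample) keeps the tensorial constraints
#'   informative about the conformer mixture on the toy system
#' @param noise_scale multiplier on the class noise defaults (RDC 0.5 Hz,
#'   NOE 0.05/0.11 A, 3J 0.65 Hz); 0 gives exact mixture averages
#' @param temperature equilibrium temperature (K) at which the ground-truth
#'   populations hold; fixes the toy's torsional asymmetry
#' @param seed seed for the generated noise
#' @return list of class \code{mdoc_scenario}
#'
#' @details The toy's two torsional wells are offset by the Boltzmann energy
#' difference kT log((1-p)/p) consistent with the ground-truth populations --
#' the synthetic observables assume an equilibrium mixture, so the molecule
#' that produced them must have that equilibrium. With the default barrier the
#' states interconvert far too slowly for unrestrained vacuum MD to reach that
#' equilibrium on the nanosecond scale; the time-averaged restraints supply
#' the transitions.
#' @export
two_state_scenario <- function(p_minor = 0.2, minima = 60, barrier = 6,
                               order_parameter = 1, noise_scale = 1,
                               temperature = 306.3, seed = 1) {
  if (p_minor < 0 || p_minor >= 1) stop("p_minor must be in [0, 1)")
  # E(minor) - E(major), capped for the p -> 0 stiff-well limit
  dE <- if (p_minor == 0) 4 else
    min(4, KB_KCAL * temperature * log((1 - p_minor) / p_minor))
  toy <- make_flexible_toy("chain", minima = minima, barrier = barrier,
                           asymmetry = -dE, start_torsion = minima)
  structure(c(toy, list(
    p_minor = p_minor, phi_major = minima, phi_minor = -minima,
    order_parameter = order_parameter, noise_scale = noise_scale,
    temperature = temperature, seed = as.integer(seed)
  )), class = "mdoc_scenario")
}

# coordinates of the scenario molecule posed at a given soft-torsion value
scenario_frame <- function(scenario, phi) {
  quad <- scenario$soft_torsions[[1]]
  phi0 <- measure_torsion(scenario$mol$xyz, quad[1], quad[2], quad[3], quad[4])
  moving <- bond_side_atoms(scenario$mol, quad[2], quad[3])
  rotate_about_bond(scenario$mol$xyz, quad[2], quad[3], moving, deg2rad(phi - phi0))
}

#' Generate ensemble-averaged reference observables for a scenario
#'
#' RDC targets are the population-weighted mixture of the per-state dipolar
#' tensors (in the common molecular frame of the rigid core) scaled by a
#' single axial order parameter; NOE targets are
#' (p r1^-6 + (1-p) r2^-6)^(-1/6); 3J targets are the population-weighted
#' Karplus couplings. Gaussian noise with the class sigma defaults (times
#' \code{noise_scale}) is added using the scenario seed; errors are filled by
#' the standard rules (RDC 0.5 Hz, NOE 0.05/0.11 A by distance, 3J 1.25 Hz).
#'
#' @param scenario an \code{mdoc_scenario}
#' @return restraint data.frame (columns type, atom1, atom2, value, error,
#'   weight)
#' @export
generate_reference_observables <- function(scenario) {
  mol <- scenario$mol
  p <- 1 - scenario$p_minor
  f1 <- scenario_frame(scenario, scenario$phi_major)
  f2 <- scenario_frame(scenario, scenario$phi_minor)
  karplus <- haasnoot_altona_params()
  set.seed(scenario$seed)
  rows <- list()

  # RDC: one per C-H bond of the rotor carbons
  ch <- list(c("C1", "H1a"), c("C1", "H1b"), c("C2", "H2a"), c("C2", "H2b"))
  for (pr in ch) {
    ij <- atom_index(mol, pr)
    g <- mol$atoms$gamma[ij]
    D1 <- dipolar_tensor(f1, ij[1], ij[2], g[1], g[2])
    D2 <- dipolar_tensor(f2, ij[1], ij[2], g[1], g[2])
    val <- scenario$order_parameter * rdc_value(p * D1 + (1 - p) * D2)
    val <- val + scenario$noise_scale * stats::rnorm(1, 0, DEFAULT_RDC_ERROR)
    rows[[length(rows) + 1]] <- data.frame(
      type = "RDC", atom1 = pr[1], atom2 = pr[2], value = val,
      error = DEFAULT_RDC_ERROR, weight = NA_real_)
  }

  hh <- list(c("H1a", "H2a"), c("H1a", "H2b"), c("H1b", "H2a"), c("H1b", "H2b"))
  for (pr in hh) {
    ij <- atom_index(mol, pr)
    r1 <- measure_distance(f1, ij[1], ij[2])
    r2 <- measure_distance(f2, ij[1], ij[2])
    val <- (p * r1^-6 + (1 - p) * r2^-6)^(-1 / 6)
    err <- default_noe_error(val)
    val <- val + scenario$noise_scale * stats::rnorm(1, 0, err)
    rows[[length(rows) + 1]] <- data.frame(
      type = "NOE", atom1 = pr[1], atom2 = pr[2], value = val,
      error = err, weight = NA_real_)
  }

  for (pr in hh) {
    ij <- atom_index(mol, pr)
    path <- resolve_j_path(mol, ij[1], ij[2], karplus)
    j1 <- karplus_3j(torsion_series(f1, path$quad), path$substituents, karplus)
    j2 <- karplus_3j(torsion_series(f2, path$quad), path$substituents, karplus)
    val <- p * j1 + (1 - p) * j2
    val <- val + scenario$noise_scale * stats::rnorm(1, 0, 0.65)
    rows[[length(rows) + 1]] <- data.frame(
      type = "J3", atom1 = pr[1], atom2 = pr[2], value = val,
      error = DEFAULT_J_ERROR, weight = NA_real_)
  }
  do.call(rbind, rows)
}

#' Default simulation configuration for population-recovery runs
#'
#' 200 ps at 0.5 fs (4e5 steps), 306.3 K, 5 ps restraint memory (short enough
#' for tens of restraint-driven flip cycles within the run), 10 ps force
#' ramp, snapshots every 50 fs, pseudo-force cap 40 kcal/(mol A).
#'
#' @param seed RNG seed
#' @param n_steps number of steps (default 4e5)
#' @return an \code{mdoc_config}
#' @export
recovery_config <- function(seed = 1, n_steps = 4e5) {
  md_config(n_steps = n_steps, dt = 0.5, temperature = 306.3,
            tau_thermostat = 100, seed = seed, snapshot_interval = 50,
            tau_memory = 5000, ramp_steps = 20000, force_cap = 40)
}

#' Full-pipeline conformer population recovery experiment
#'
#' Generates reference observables from the scenario's ground-truth
#' populations, runs the restrained simulation, classifies the soft-torsion
#' trajectory into +/-gauche states, and compares the recovered minor-state
#' population with the ground truth. Uncertainty is estimated by a block
#' bootstrap over contiguous trajectory segments.
#'
#' @param scenario an \code{mdoc_scenario}
#' @param config an \code{mdoc_config}; the default is
#'   \code{recovery_config(scenario$seed)}
#' @param equilibration_fs initial time span discarded before counting states
#'   (default: ramp duration plus two memory time constants)
#' @param n_blocks,n_boot block bootstrap settings
#' @return list with \code{recovered_pct}, \code{truth_pct},
#'   \code{uncertainty_pct}, the torsion \code{series} (analysed part) and the
#'   simulation result
#' @export
population_recovery_experiment <- function(scenario, config = NULL,
                                           equilibration_fs = NULL,
                                           n_blocks = 50, n_boot = 200) {
  if (is.null(config)) config <- recovery_config(scenario$seed)
  table <- generate_reference_observables(scenario)
  rs <- restraint_set(scenario$mol, table, field_axis = config$field_axis)
  sim <- run_simulation(scenario$mol, scenario$ff, rs, config,
                        types = scenario$types)
  if (is.null(equilibration_fs)) {
    equilibration_fs <- config$ramp_steps * config$dt + 2 * config$tau_memory
  }
  quad <- scenario$soft_torsions[[1]]
  keep <- sim$trajectory$times > equilibration_fs
  series <- torsion_series(sim$trajectory$coords, quad)[keep]
  minor_label <- classify_gauche(wrap_angle(scenario$phi_minor))
  frac <- function(s) 100 * mean(classify_gauche(s) == minor_label)
  recovered <- frac(series)
  # block bootstrap
  blocks <- split(series, cut(seq_along(series), n_blocks, labels = FALSE))
  set.seed(config$seed + 77777L)
  boot <- vapply(seq_len(n_boot), function(b) {
    frac(unlist(blocks[sample.int(n_blocks, replace = TRUE)], use.names = FALSE))
  }, numeric(1))
  list(recovered_pct = recovered, truth_pct = 100 * scenario$p_minor,
       uncertainty_pct = stats::sd(boot), series = series, sim = sim,
       restraints = table)
}
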