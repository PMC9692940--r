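# Velocity-Verlet integrator with Berendsen weak-coupling thermostat, driving
# physical forces plus NMR pseudo-forces, and trajectory bookkeeping.

#' Simulation configuration
#'
#' @param n_steps number of integration steps
#' @param dt time step (fs); 0.5 fs is required by explicit hydrogens
#' @param temperature thermostat setpoint (K)
#' @param tau_thermostat Berendsen coupling time (fs); 0 disables the
#'   thermostat (NVE)
#' @param seed random seed for velocity initialization (recorded in outputs)
#' @param snapshot_interval snapshot spacing (fs); must be an integer multiple
#'   of \code{dt}
#' @param tau_memory exponential-memory time constant of the time-averaged
#'   restraints (fs)
#' @param ramp_steps restraint force constants ramp linearly from zero over
#'   this many steps
#' @param force_cap per-restraint pseudo-force cap (kcal mol^-1 A^-1 per atom;
#'   the restraint's force set is rescaled if any atom exceeds it; <= 0
#'   disables). Numerical safeguard against impulsive kicks when a
#'   time-averaged restraint engages far outside its tolerance.
#' @param field_axis magnetic-field direction (laboratory frame)
#' @return object of class \code{mdoc_config}
#' @export
md_config <- function(n_steps, dt = 0.5, temperature = 306.3,
                      tau_thermostat = 100, seed = 1,
                      snapshot_interval = 50, tau_memory = 10000,
                      ramp_steps = 10000, force_cap = 20,
                      field_axis = c(0, 0, 1)) {
  if (dt <= 0) stop("time step must be positive")
  snap_every <- snapshot_interval / dt
  if (abs(snap_every - round(snap_every)) > 1e-9) {
    stop("snapshot interval must be an integer multiple of the time step")
  }
  structure(list(
    n_steps = as.integer(n_steps), dt = dt, temperature = temperature,
    tau_thermostat = tau_thermostat, seed = as.integer(seed),
    snapshot_interval = snapshot_interval, snap_every = as.integer(round(snap_every)),
    tau_memory = tau_memory, ramp_steps = as.integer(ramp_steps),
    force_cap = force_cap, field_axis = field_axis / vnorm(field_axis)
  ), class = "mdoc_config")
}

#' Steps needed to cover a simulation duration
#'
#' @param duration_fs duration (fs)
#' @param dt time step (fs)
#' @return integer-valued step count (error if not an exact multiple)
#' @export
n_steps_for <- function(duration_fs, dt = 0.5) {
  steps <- duration_fs / dt
  if (abs(steps - round(steps)) > 1e-6) stop("duration is not a multiple of the time step")
  round(steps)
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws velocities from the Maxwell-Boltzmann distribution at the given
#' temperature and removes center-of-mass momentum. The same seed reproduces
#' the identical draw.
#'
#' @param mol molecule (only masses are used)
#' @param temperature target temperature (K)
#' @param seed RNG seed
#' @return n x 3 velocity matrix (A/fs)
#' @export
initialize_velocities <- function(mol, temperature, seed = 1) {
  n <- n_atoms(mol)
  if (n < 1) stop("molecule has no atoms")
  if (temperature <= 0) stop("temperature must be positive")
  m <- mol$atoms$mass
  kb_int <- KB_KCAL * KCAL_TO_INTERNAL # amu A^2 fs^-2 K^-1
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(kb_int * temperature / m)
  # remove center-of-mass momentum
  p <- colSums(v * m)
  sweep(v, 2, p / sum(m))
}

#' Instantaneous kinetic temperature from velocities
#'
#' @param vel n x 3 velocities (A/fs)
#' @param mass masses (amu)
#' @param ndof degrees of freedom (default 3n - 3, COM motion removed)
#' @return temperature (K)
#' @export
kinetic_temperature <- function(vel, mass, ndof = 3 * length(mass) - 3) {
  ke <- sum(0.5 * mass * rowSums(vel^2)) / KCAL_TO_INTERNAL
  2 * ke / (ndof * KB_KCAL)
}

#' One velocity-Verlet step against an arbitrary force provider
#'
#' Reference implementation used for integrator verification; the production
#' loop runs compiled. \code{force_provider(pos)} must return forces in
#' kcal mol^-1 A^-1 for positions in A.
#'
#' @param state list(pos, vel, mass, force) -- \code{force} may be NULL on the
#'   first call
#' @param force_provider function(pos) -> force matrix
#' @param dt time step (fs)
#' @return updated state (with \code{force} populated)
#' @export
velocity_verlet_step <- function(state, force_provider, dt) {
  if (is.null(state$force)) state$force <- force_provider(state$pos)
  if (!all(is.finite(state$force))) stop("integration aborted: non-finite force")
  acc <- state$force * KCAL_TO_INTERNAL / state$mass
  vel_half <- state$vel + 0.5 * dt * acc
  pos_new <- state$pos + dt * vel_half
  f_new <- force_provider(pos_new)
  if (!all(is.finite(f_new))) stop("integration aborted: non-finite force")
  vel_new <- vel_half + 0.5 * dt * f_new * KCAL_TO_INTERNAL / state$mass
  list(pos = pos_new, vel = vel_new, mass = state$mass, force = f_new)
}

#' Run a (restrained) molecular dynamics simulation
#'
#' Combines the physical force field with pseudo-forces that drive
#' exponentially time-averaged observables (RDC tensors, NOE r^-6 averages,
#' 3J couplings) toward their experimental targets. Fully deterministic given
#' (config, seed).
#'
#' @param mol molecule with coordinates as the start structure
#' @param ff force field
#' @param restraints an \code{mdoc_restraint_set} or NULL for unrestrained MD
#' @param config an \code{mdoc_config}
#' @param types atom-type labels (default: element symbols)
#' @return list with \code{trajectory} (class \code{mdoc_trajectory}),
#'   \code{diagnostics} (data.frame per snapshot: temperature, energies),
#'   \code{observables} (memory-averaged observable per restraint per
#'   snapshot), \code{final} state and \code{mean_temperature}
#' @export
run_simulation <- function(mol, ff, restraints = NULL, config, types = NULL) {
  ffspec <- build_ffspec(mol, ff, types)
  rspec <- build_restraintspec(mol, restraints, config$field_axis)
  vel <- initialize_velocities(mol, max(config$temperature, 1e-6), config$seed)
  res <- cpp_run_md(mol$xyz, vel, mol$atoms$mass, ffspec, rspec,
                    list(dt = config$dt, nsteps = config$n_steps,
                         temperature = config$temperature,
                         tau_t = config$tau_thermostat,
                         snap_every = config$snap_every,
                         tau_mem = config$tau_memory,
                         ramp_steps = config$ramp_steps,
                         force_cap = config$force_cap,
                         field_axis = config$field_axis))
  traj <- structure(list(
    coords = res$coords, times = res$times,
    interval = config$snapshot_interval,
    labels = mol$atoms$label, seed = config$seed
  ), class = "mdoc_trajectory")
  diagnostics <- as.data.frame(res$diagnostics)
  diagnostics$time_fs <- res$times
  list(trajectory = traj, diagnostics = diagnostics,
       observables = list(rdc = res$obs_rdc, noe = res$obs_noe, j3 = res$obs_j),
       final = list(pos = res$final_pos, vel = res$final_vel),
       mean_temperature = res$mean_temperature,
       config = config)
}

#' @export
print.mdoc_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("mdoc_trajectory: %d frames x %d atoms, every %g fs (%.3f ps total), seed %d\n",
              d[1], d[2], x$interval, d[1] * x$interval / 1000, x$seed))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{mdoc_trajectory}
#' @return integer
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory
#' @param traj an \code{mdoc_trajectory}
#' @param i frame index
#' @return n x 3 coordinate matrix
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj an \code{mdoc_trajectory}
#' @param elements element symbols of the atoms
#' @param path output path
#' @return invisibly, the path
#' @export
write_trajectory_xyz <- function(traj, elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    writeLines(c(sprintf("%d", length(elements)),
                 sprintf("frame %d t= %.3f fs", f, traj$times[f]),
                 sprintf("%-3s %14.8f %14.8f %14.8f",
                         elements, xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file path
#' @param interval snapshot interval (fs) to record in the object; inferred
#'   from the "t=" comment fields when possible
#' @return list(trajectory, elements)
#' @export
read_trajectory_xyz <- function(path, interval = NA) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("trajectory parse error: bad atom count")
  block <- n + 2
  nf <- length(lines) %/% block
  if (nf < 1) stop("trajectory parse error: no complete frame")
  coords <- array(NA_real_, c(nf, n, 3))
  times <- numeric(nf)
  elements <- NULL
  for (f in seq_len(nf)) {
    off <- (f - 1) * block
    tok <- strsplit(trimws(lines[off + 2 + seq_len(n)]), "\\s+")
    mat <- t(vapply(tok, function(tt) as.numeric(tt[2:4]), numeric(3)))
    if (anyNA(mat)) stop("trajectory parse error in frame ", f)
    coords[f, , ] <- mat
    if (f == 1) elements <- vapply(tok, `[[`, character(1), 1)
    m <- regmatches(lines[off + 2], regexec("t= *([-0-9.eE]+)", lines[off + 2]))[[1]]
    times[f] <- if (length(m) == 2) as.numeric(m[2]) else f
  }
  if (is.na(interval)) {
    interval <- if (nf > 1) times[2] - times[1] else 1
  }
  traj <- structure(list(coords = coords, times = times, interval = interval,
                         labels = paste0(elements, seq_len(n)), seed = NA_integer_),
                    class = "mdoc_trajectory")
  list(trajectory = traj, elements = elements)
}
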