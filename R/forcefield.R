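# Minimal classical force field: harmonic bonds/angles (E = k (x - x0)^2,
# Amber-style, no 1/2), cosine torsion series V (1 + cos(n phi - phase)),
# 12-6 Lennard-Jones and Coulomb with 1-2/1-3 exclusion and scaled 1-4
# interactions. Single molecule in vacuum: no cutoffs, no periodic boundaries.

#' Read a force-field parameter file
#'
#' Tab-separated sections introduced by header lines ATOMTYPES, BONDS, ANGLES,
#' TORSIONS. Columns:
#' \itemize{
#'   \item ATOMTYPES: type, epsilon (kcal/mol), sigma (A), charge (e)
#'   \item BONDS: type1, type2, k (kcal mol^-1 A^-2), r0 (A)
#'   \item ANGLES: type1, type2, type3, k (kcal mol^-1 rad^-2), theta0 (deg)
#'   \item TORSIONS: type1..type4, v (kcal/mol), n, phase (deg)
#' }
#' "X" is a wildcard for the outer atoms of angles and torsions. Lines
#' starting with "#" are comments.
#'
#' @param path file path
#' @param scale14_lj,scale14_coulomb 1-4 scaling factors (defaults 0.5, 0.833)
#' @return object of class \code{mdoc_forcefield}
#' @export
read_forcefield <- function(path, scale14_lj = 0.5, scale14_coulomb = 0.833) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sec <- cumsum(lines %in% c("ATOMTYPES", "BONDS", "ANGLES", "TORSIONS"))
  secname <- lines[lines %in% c("ATOMTYPES", "BONDS", "ANGLES", "TORSIONS")]
  parse_sec <- function(name, cols, numeric_from) {
    body <- lines[sec == match(name, secname) & !(lines %in% secname)]
    if (!length(body)) {
      out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    } else {
      tok <- do.call(rbind, strsplit(body, "\t"))
      if (ncol(tok) != length(cols)) stop("force-field section ", name, ": expected ",
                                          length(cols), " columns")
      out <- as.data.frame(tok, stringsAsFactors = FALSE)
      names(out) <- cols
    }
    for (cc in cols[numeric_from:length(cols)]) out[[cc]] <- as.numeric(out[[cc]])
    out
  }
  ff <- list(
    atomtypes = parse_sec("ATOMTYPES", c("type", "epsilon", "sigma", "charge"), 2),
    bonds = parse_sec("BONDS", c("type1", "type2", "k", "r0"), 3),
    angles = parse_sec("ANGLES", c("type1", "type2", "type3", "k", "theta0"), 4),
    torsions = parse_sec("TORSIONS", c("type1", "type2", "type3", "type4",
                                       "v", "n", "phase"), 5),
    scale14_lj = scale14_lj, scale14_coulomb = scale14_coulomb
  )
  bad <- c(ff$bonds$k, ff$angles$k) < 0
  if (any(bad)) stop("force constants must be >= 0")
  if (any(ff$atomtypes$epsilon < 0) || any(ff$atomtypes$sigma <= 0)) {
    stop("LJ parameters require epsilon >= 0 and sigma > 0")
  }
  class(ff) <- "mdoc_forcefield"
  ff
}

#' The bundled toy force field (H/C/N/O/Cl)
#'
#' Generic small-molecule parameters adequate for the synthetic test systems;
#' not fitted to any particular compound.
#'
#' @return an \code{mdoc_forcefield}
#' @export
toy_forcefield <- function() {
  read_forcefield(system.file("extdata", "toy_forcefield.tsv", package = "mdoc"))
}

#' @export
print.mdoc_forcefield <- function(x, ...) {
  cat(sprintf("mdoc_forcefield: %d atom types, %d bond / %d angle / %d torsion entries\n",
              nrow(x$atomtypes), nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  cat(sprintf("  1-4 scaling: LJ %.3f, Coulomb %.3f\n", x$scale14_lj, x$scale14_coulomb))
  invisible(x)
}

match2 <- function(tab, c1, c2, t1, t2) {
  which((tab[[c1]] == t1 & tab[[c2]] == t2) | (tab[[c1]] == t2 & tab[[c2]] == t1))
}

# Resolve molecule topology against the parameter tables into the flat,
# 0-based structure consumed by the C++ core.
build_ffspec <- function(mol, ff, types = NULL) {
  if (is.null(types)) types <- mol$atoms$element
  at <- ff$atomtypes
  ti <- match(types, at$type)
  if (anyNA(ti)) stop("no ATOMTYPES entry for type(s): ",
                      paste(unique(types[is.na(ti)]), collapse = ", "))
  eps <- at$epsilon[ti]; sig <- at$sigma[ti]
  q <- mol$atoms$charge

  bonds <- mol$bonds
  bk <- br0 <- numeric(nrow(bonds))
  for (r in seq_len(nrow(bonds))) {
    hit <- match2(ff$bonds, "type1", "type2", types[bonds[r, 1]], types[bonds[r, 2]])
    if (!length(hit)) stop("no BONDS entry for ", types[bonds[r, 1]], "-", types[bonds[r, 2]])
    bk[r] <- ff$bonds$k[hit[1]]; br0[r] <- ff$bonds$r0[hit[1]]
  }

  angles <- mol$topology$angles
  ak <- ath0 <- numeric(nrow(angles))
  for (r in seq_len(nrow(angles))) {
    t1 <- types[angles[r, 1]]; t2 <- types[angles[r, 2]]; t3 <- types[angles[r, 3]]
    hit <- which(ff$angles$type2 == t2 &
                   ((ff$angles$type1 == t1 & ff$angles$type3 == t3) |
                      (ff$angles$type1 == t3 & ff$angles$type3 == t1)))
    if (!length(hit)) {
      hit <- which(ff$angles$type2 == t2 & ff$angles$type1 == "X" & ff$angles$type3 == "X")
    }
    if (!length(hit)) stop("no ANGLES entry for ", t1, "-", t2, "-", t3)
    ak[r] <- ff$angles$k[hit[1]]; ath0[r] <- deg2rad(ff$angles$theta0[hit[1]])
  }

  tors <- mol$topology$torsions
  tlist <- list()
  for (r in seq_len(nrow(tors))) {
    tt <- types[tors[r, ]]
    tab <- ff$torsions
    hit <- which((tab$type1 == tt[1] & tab$type2 == tt[2] & tab$type3 == tt[3] & tab$type4 == tt[4]) |
                   (tab$type1 == tt[4] & tab$type2 == tt[3] & tab$type3 == tt[2] & tab$type4 == tt[1]))
    if (!length(hit)) {
      hit <- which(tab$type1 == "X" & tab$type4 == "X" &
                     ((tab$type2 == tt[2] & tab$type3 == tt[3]) |
                        (tab$type2 == tt[3] & tab$type3 == tt[2])))
    }
    if (!length(hit)) stop("no TORSIONS entry for ", paste(tt, collapse = "-"))
    for (h in hit) {
      tlist[[length(tlist) + 1]] <-
        c(tors[r, ], tab$v[h], tab$n[h], deg2rad(tab$phase[h]))
    }
  }
  tmat <- if (length(tlist)) do.call(rbind, tlist) else matrix(0, 0, 7)

  nb <- mol$topology$nb_pairs
  i <- nb[, 1]; j <- nb[, 2]; is14 <- nb[, 3] == 1
  epsij <- sqrt(eps[i] * eps[j])
  sigij <- (sig[i] + sig[j]) / 2
  a <- 4 * epsij * sigij^12
  b <- 4 * epsij * sigij^6
  qq <- COULOMB_KCAL * q[i] * q[j]
  a[is14] <- a[is14] * ff$scale14_lj
  b[is14] <- b[is14] * ff$scale14_lj
  qq[is14] <- qq[is14] * ff$scale14_coulomb

  list(
    bond_idx = bonds - 1L, bond_k = bk, bond_r0 = br0,
    angle_idx = angles - 1L, angle_k = ak, angle_theta0 = ath0,
    tors_idx = matrix(as.integer(tmat[, 1:4]), ncol = 4) - 1L,
    tors_v = as.numeric(tmat[, 5]), tors_n = as.integer(tmat[, 6]),
    tors_phase = as.numeric(tmat[, 7]),
    nb_idx = matrix(as.integer(nb[, 1:2]), ncol = 2) - 1L,
    nb_a = a, nb_b = b, nb_qq = qq
  )
}

#' Energy and analytic forces of a configuration
#'
#' Evaluates the physical force field for a molecule (optionally at substitute
#' coordinates). Forces are the exact negative gradient of the energy; the
#' per-component breakdown sums to the total.
#'
#' @param mol an \code{mdoc_molecule}
#' @param ff an \code{mdoc_forcefield}
#' @param xyz optional n x 3 coordinates overriding \code{mol$xyz}
#' @param types atom-type labels (default: element symbols)
#' @return list(energy kcal/mol, forces n x 3 kcal mol^-1 A^-1, breakdown)
#' @export
energy_forces <- function(mol, ff, xyz = NULL, types = NULL) {
  spec <- build_ffspec(mol, ff, types)
  if (is.null(xyz)) xyz <- mol$xyz
  cpp_ff_energy_forces(as_xyz_matrix(xyz), spec)
}

#' Relaxed torsion profile of a molecule along one dihedral
#'
#' Rigid scan: rotates the atoms on the l-side of the j-k bond about that bond
#' and evaluates the energy at each grid point (no minimization of the other
#' degrees of freedom).
#'
#' @param mol molecule
#' @param ff force field
#' @param quad four atom indices defining the torsion
#' @param grid torsion values to visit (degrees)
#' @param types atom-type labels (default: element symbols)
#' @return data.frame(phi, energy)
#' @export
torsion_scan <- function(mol, ff, quad, grid = seq(-180, 175, by = 5), types = NULL) {
  phi0 <- measure_torsion(mol$xyz, quad[1], quad[2], quad[3], quad[4])
  moving <- bond_side_atoms(mol, quad[2], quad[3])
  e <- vapply(grid, function(phi) {
    xyz <- rotate_about_bond(mol$xyz, quad[2], quad[3], moving, deg2rad(phi - phi0))
    energy_forces(mol, ff, xyz = xyz, types = types)$energy
  }, numeric(1))
  data.frame(phi = grid, energy = e)
}

# atoms on the k-side of bond j-k (excluding j's side), via graph traversal
bond_side_atoms <- function(mol, j, k) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (r in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds[r, 1]; b <- mol$bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- rep(FALSE, n)
  seen[j] <- TRUE
  queue <- k; seen[k] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  out <- which(seen)
  setdiff(out, j)
}

# rotate `moving` atoms by angle (radians) about the j->k axis; positive angle
# increases the IUPAC torsion measured with j,k as the central bond
rotate_about_bond <- function(xyz, j, k, moving, angle) {
  axis <- vunit(xyz[k, ] - xyz[j, ])
  # right-handed rotation of the far side about the j->k axis increases the
  # IUPAC torsion
  ang <- angle
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  origin <- xyz[k, ]
  out <- xyz
  rel <- sweep(xyz[moving, , drop = FALSE], 2, origin)
  out[moving, ] <- sweep(rel %*% t(R), 2, origin, "+")
  out
}
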