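# Restraint tables, exponential-memory accumulators, target tensors and the
# pseudo-energy/pseudo-force terms that drive time-averaged observables toward
# experimental targets -- the core of orientational-constraint MD.

#' Default NOE distance error
#'
#' 0.05 A for distances below 2.8 A, 0.11 A for longer distances (up to the
#' ~4.5 A NOE detection range).
#'
#' @param distance experimental distance (A)
#' @return error (A)
#' @export
default_noe_error <- function(distance) {
  ifelse(distance < 2.8, 0.05, 0.11)
}

# class-level defaults: RDC measurement error, NOE rule above, 3J combined
# error = 0.65 Hz experimental + 0.6 Hz Karplus-curve uncertainty
DEFAULT_RDC_ERROR <- 0.5
DEFAULT_J_ERROR <- 1.25

#' Read a restraint table
#'
#' Tab-separated with a header line; columns \code{type} (RDC, NOE or J3),
#' \code{atom1}, \code{atom2}, \code{value}, \code{error}, \code{weight}.
#' Missing (NA) errors are filled by the class rules: 0.5 Hz for RDC,
#' the 0.05/0.11 A distance rule for NOE, 1.25 Hz combined error for J3.
#' Missing weights get the class defaults of \code{\link{restraint_set}}.
#'
#' @param path file path
#' @return data.frame
#' @export
read_restraints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("type", "atom1", "atom2", "value")
  if (!all(need %in% names(df))) {
    stop("restraint table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$error)) df$error <- NA_real_
  if (is.null(df$weight)) df$weight <- NA_real_
  bad <- !df$type %in% c("RDC", "NOE", "J3")
  if (any(bad)) stop("unknown restraint type(s): ", paste(unique(df$type[bad]), collapse = ", "))
  df
}

#' Write a restraint/observable table
#'
#' Full-precision tab-separated output so that a write/read round trip is
#' bit-exact.
#'
#' @param df data.frame as from \code{\link{read_restraints}}
#' @param path output path
#' @return invisibly, the path
#' @export
write_restraints <- function(df, path) {
  out <- df
  for (cc in names(out)) {
    if (is.numeric(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve a restraint table against a molecule
#'
#' Maps atom labels to indices, fills defaulted errors and weights, derives
#' the H-C-C-H dihedral path of each 3J restraint from the bond graph and
#' resolves its Karplus substituent corrections (group electronegativities
#' with beta correction; orientation signs xi from the reference geometry).
#'
#' @param mol molecule
#' @param table restraint data.frame (see \code{\link{read_restraints}})
#' @param rdc_weight,noe_weight,j_weight default force constants
#'   (kcal mol^-1 per squared unit of the observable) used where the table
#'   has no weight
#' @param karplus Karplus coefficient list (see
#'   \code{\link{haasnoot_altona_params}})
#' @param field_axis magnetic-field direction for RDC target tensors
#' @return object of class \code{mdoc_restraint_set}
#' @export
restraint_set <- function(mol, table, rdc_weight = 1e-4, noe_weight = 1e6,
                          j_weight = 2e5, karplus = haasnoot_altona_params(),
                          field_axis = c(0, 0, 1)) {
  table$error <- as.numeric(table$error)
  table$weight <- as.numeric(table$weight)
  rdc <- table[table$type == "RDC", , drop = FALSE]
  noe <- table[table$type == "NOE", , drop = FALSE]
  j3 <- table[table$type == "J3", , drop = FALSE]

  rdc_idx <- cbind(atom_index(mol, rdc$atom1), atom_index(mol, rdc$atom2))
  g1 <- mol$atoms$gamma[rdc_idx[, 1]]; g2 <- mol$atoms$gamma[rdc_idx[, 2]]
  if (nrow(rdc) > 0 && any(g1 == 0 | g2 == 0)) stop("RDC restraint on an NMR-silent atom")
  rdc$error[is.na(rdc$error)] <- DEFAULT_RDC_ERROR
  rdc$weight[is.na(rdc$weight)] <- rdc_weight

  noe_idx <- cbind(atom_index(mol, noe$atom1), atom_index(mol, noe$atom2))
  noe$error[is.na(noe$error)] <- default_noe_error(noe$value[is.na(noe$error)])
  noe$weight[is.na(noe$weight)] <- noe_weight

  j_idx <- cbind(atom_index(mol, j3$atom1), atom_index(mol, j3$atom2))
  j3$error[is.na(j3$error)] <- DEFAULT_J_ERROR
  j3$weight[is.na(j3$weight)] <- j_weight
  jpaths <- lapply(seq_len(nrow(j3)), function(r) {
    resolve_j_path(mol, j_idx[r, 1], j_idx[r, 2], karplus)
  })

  if (any(c(rdc$error, noe$error, j3$error) <= 0)) stop("restraint errors must be positive")

  structure(list(
    rdc = cbind(rdc, i = rdc_idx[, 1], j = rdc_idx[, 2],
                coef = if (nrow(rdc)) dmax_coupling(1, g1, g2) else numeric(0)),
    noe = cbind(noe, i = noe_idx[, 1], j = noe_idx[, 2]),
    j3 = j3, jpaths = jpaths, karplus = karplus, field_axis = field_axis
  ), class = "mdoc_restraint_set")
}

#' @export
print.mdoc_restraint_set <- function(x, ...) {
  cat(sprintf("mdoc_restraint_set: %d RDC, %d NOE, %d 3J restraints\n",
              nrow(x$rdc), nrow(x$noe), nrow(x$j3)))
  invisible(x)
}

# H-C-C-H (or analogous) path and Karplus substituent data for one 3J pair
resolve_j_path <- function(mol, h1, h2, karplus) {
  nbrs <- function(a) {
    b <- mol$bonds
    c(b[b[, 1] == a, 2], b[b[, 2] == a, 1])
  }
  c1 <- nbrs(h1); c2 <- nbrs(h2)
  if (length(c1) != 1 || length(c2) != 1) {
    stop("3J restraint atoms must each have exactly one bonded neighbor")
  }
  bonded <- any((mol$bonds[, 1] == min(c1, c2)) & (mol$bonds[, 2] == max(c1, c2)))
  if (!bonded || c1 == c2) stop("3J restraint atoms are not in a vicinal H-C-C-H arrangement")
  quad <- c(h1, c1, c2, h2)

  dchi_of <- function(a) {
    d <- karplus$delta_chi[mol$atoms$element[a]]
    if (is.na(d)) 0 else unname(d)
  }
  subs <- list()
  phi_ref <- measure_torsion(mol$xyz, h1, c1, c2, h2)
  for (s in setdiff(nbrs(c1), c(h1, c2))) {
    beta <- setdiff(nbrs(s), c1)
    dchi <- dchi_of(s) - karplus$P[["P7"]] * sum(vapply(beta, dchi_of, numeric(1)))
    delta <- wrap_angle(measure_torsion(mol$xyz, s, c1, c2, h2) - phi_ref)
    subs[[length(subs) + 1]] <- c(dchi = dchi, xi = if (delta > 0) 1 else -1)
  }
  for (s in setdiff(nbrs(c2), c(h2, c1))) {
    beta <- setdiff(nbrs(s), c2)
    dchi <- dchi_of(s) - karplus$P[["P7"]] * sum(vapply(beta, dchi_of, numeric(1)))
    delta <- wrap_angle(measure_torsion(mol$xyz, h1, c1, c2, s) - phi_ref)
    subs[[length(subs) + 1]] <- c(dchi = dchi, xi = if (delta > 0) -1 else 1)
  }
  subdf <- if (length(subs)) as.data.frame(do.call(rbind, subs)) else
    data.frame(dchi = numeric(0), xi = numeric(0))
  list(quad = quad, substituents = subdf)
}

wrap_angle <- function(x) {
  x <- x %% 360
  ifelse(x > 180, x - 360, x)
}

#' Exponential-memory accumulator
#'
#' Maintains the recursion new_avg = (1 - lambda) * current + lambda * old_avg
#' with lambda = exp(-dt/tau), giving a running average with an exponential
#' memory window of time constant tau.
#'
#' @param tau memory time constant (fs); ignored if \code{lambda} given
#' @param dt update interval (fs)
#' @param lambda decay factor per update, in [0, 1); overrides tau
#' @param init initial average (scalar or matrix); NULL until first update
#' @return object of class \code{mdoc_memory}
#' @export
memory_accumulator <- function(tau = 10000, dt = 0.5, lambda = NULL, init = NULL) {
  if (is.null(lambda)) lambda <- exp(-dt / tau)
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  structure(list(average = init, lambda = lambda, tau = tau, dt = dt),
            class = "mdoc_memory")
}

#' Update an exponential-memory average
#'
#' @param acc an \code{mdoc_memory}
#' @param current current observable value (same shape as the average)
#' @return the updated accumulator
#' @export
update_memory_average <- function(acc, current) {
  if (is.null(acc$average)) {
    acc$average <- current
  } else {
    if (length(acc$average) != length(current)) stop("shape mismatch in memory update")
    acc$average <- (1 - acc$lambda) * current + acc$lambda * acc$average
  }
  acc
}

#' Target tensor of an RDC restraint
#'
#' Axially symmetric traceless tensor about the field axis whose
#' field-direction component equals the experimental coupling:
#' T = D_exp (3 b b^T - I) / 2, so for a z field T = diag(-D/2, -D/2, D).
#' The construction uses all tensor elements as constraints while making the
#' minimal assumption (axial symmetry about the field) about the components
#' not fixed by the measured coupling; it is isolated here so alternative
#' constructions can be swapped in.
#'
#' @param d_exp experimental RDC (Hz)
#' @param field_axis field direction (unit vector; normalized internally)
#' @return 3 x 3 symmetric traceless matrix (Hz)
#' @export
build_target_tensor <- function(d_exp, field_axis = c(0, 0, 1)) {
  b <- field_axis / vnorm(field_axis)
  d_exp * (3 * outer(b, b) - diag(3)) / 2
}

#' Pseudo-energy and pseudo-forces of a tensorial (RDC) restraint
#'
#' E = weight * sum_ab (avg_ab - target_ab)^2. The force differentiates only
#' the current-step contribution (1 - lambda) * D(t) of the memory average
#' (standard time-averaged-restraint practice).
#'
#' @param avg_tensor memory-averaged dipolar tensor (3 x 3, Hz)
#' @param target_tensor target tensor (3 x 3, Hz)
#' @param weight force constant (kcal mol^-1 Hz^-2)
#' @param xyz n x 3 coordinates (A)
#' @param pair atom indices of the spin pair
#' @param gamma1,gamma2 gyromagnetic ratios of the pair
#' @param one_minus_lambda current-step weight of the memory recursion
#' @return list(energy, forces n x 3)
#' @export
tensor_pseudo_energy_force <- function(avg_tensor, target_tensor, weight, xyz,
                                       pair, gamma1, gamma2,
                                       one_minus_lambda = 1) {
  coef <- dmax_coupling(1, gamma1, gamma2)
  cpp_pseudo_rdc(as_xyz_matrix(xyz), as.integer(pair) - 1L, coef,
                 avg_tensor, target_tensor, weight, one_minus_lambda)
}

#' Pseudo-energy and pseudo-forces of an NOE distance restraint
#'
#' Flat-bottom harmonic on r_eff - r_exp with r_eff = <r^-6>^(-1/6): zero
#' within +/- error, quadratic outside, gradient through the current-step term
#' of the r^-6 memory average.
#'
#' @param avg_r6 memory-averaged <r^-6> (A^-6)
#' @param restraint list(value, error, weight)
#' @param xyz coordinates
#' @param pair proton pair indices
#' @param one_minus_lambda current-step weight
#' @return list(energy, forces)
#' @export
distance_pseudo_energy_force <- function(avg_r6, restraint, xyz, pair,
                                         one_minus_lambda = 1) {
  cpp_pseudo_noe(as_xyz_matrix(xyz), as.integer(pair) - 1L, avg_r6,
                 restraint$value, restraint$error, restraint$weight,
                 one_minus_lambda)
}

#' Pseudo-energy and pseudo-forces of a 3J coupling restraint
#'
#' Flat-bottom harmonic on <J> - J_exp with half-width the combined error;
#' the gradient chains through the Karplus curve and the dihedral derivative.
#'
#' @param avg_j memory-averaged coupling (Hz)
#' @param restraint list(value, error, weight)
#' @param xyz coordinates
#' @param quad the four dihedral-path atom indices (H, C, C, H)
#' @param substituents Karplus substituent data.frame (dchi, xi) or NULL
#' @param karplus coefficient list
#' @param one_minus_lambda current-step weight
#' @return list(energy, forces)
#' @export
j_pseudo_energy_force <- function(avg_j, restraint, xyz, quad,
                                  substituents = NULL,
                                  karplus = haasnoot_altona_params(),
                                  one_minus_lambda = 1) {
  ks <- karplus_cpp_spec(karplus, substituents)
  cpp_pseudo_j(as_xyz_matrix(xyz), as.integer(quad) - 1L, ks,
               avg_j, restraint$value, restraint$error, restraint$weight,
               one_minus_lambda)
}

karplus_cpp_spec <- function(karplus, substituents = NULL) {
  P <- karplus$P
  if (is.null(substituents)) substituents <- data.frame(dchi = numeric(0), xi = numeric(0))
  list(p1 = unname(P[["P1"]]), p2 = unname(P[["P2"]]), p3 = unname(P[["P3"]]),
       p4 = unname(P[["P4"]]), p5 = unname(P[["P5"]]), p6 = unname(P[["P6"]]),
       dchi = as.numeric(substituents$dchi), xi = as.numeric(substituents$xi))
}

# flat structure handed to the compiled MD loop
build_restraintspec <- function(mol, rs, field_axis = c(0, 0, 1)) {
  empty <- list(
    rdc = list(idx = matrix(integer(0), 0, 2), coef = numeric(0),
               target = matrix(0, 0, 9), weight = numeric(0)),
    noe = list(idx = matrix(integer(0), 0, 2), rexp = numeric(0),
               err = numeric(0), weight = numeric(0)),
    j3 = list(idx = matrix(integer(0), 0, 4), jexp = numeric(0), err = numeric(0),
              weight = numeric(0), p1 = numeric(0), p2 = numeric(0),
              p3 = numeric(0), p4 = numeric(0), p5 = numeric(0), p6 = numeric(0),
              sub_ptr = 0L, sub_dchi = numeric(0), sub_xi = numeric(0))
  )
  if (is.null(rs)) return(empty)
  out <- empty
  if (nrow(rs$rdc) > 0) {
    tgt <- t(vapply(seq_len(nrow(rs$rdc)), function(r) {
      as.numeric(t(build_target_tensor(rs$rdc$value[r], field_axis)))
    }, numeric(9)))
    out$rdc <- list(idx = cbind(rs$rdc$i, rs$rdc$j) - 1L, coef = rs$rdc$coef,
                    target = tgt, weight = rs$rdc$weight)
  }
  if (nrow(rs$noe) > 0) {
    out$noe <- list(idx = cbind(rs$noe$i, rs$noe$j) - 1L, rexp = rs$noe$value,
                    err = rs$noe$error, weight = rs$noe$weight)
  }
  if (nrow(rs$j3) > 0) {
    P <- rs$karplus$P
    m <- nrow(rs$j3)
    quads <- t(vapply(rs$jpaths, function(p) p$quad, numeric(4)))
    nsub <- vapply(rs$jpaths, function(p) nrow(p$substituents), integer(1))
    out$j3 <- list(
      idx = matrix(as.integer(quads), ncol = 4) - 1L,
      jexp = rs$j3$value, err = rs$j3$error, weight = rs$j3$weight,
      p1 = rep(unname(P[["P1"]]), m), p2 = rep(unname(P[["P2"]]), m),
      p3 = rep(unname(P[["P3"]]), m), p4 = rep(unname(P[["P4"]]), m),
      p5 = rep(unname(P[["P5"]]), m), p6 = rep(unname(P[["P6"]]), m),
      sub_ptr = as.integer(cumsum(c(0L, nsub))),
      sub_dchi = unlist(lapply(rs$jpaths, function(p) p$substituents$dchi)),
      sub_xi = unlist(lapply(rs$jpaths, function(p) p$substituents$xi))
    )
    if (is.null(out$j3$sub_dchi)) { out$j3$sub_dchi <- numeric(0); out$j3$sub_xi <- numeric(0) }
  }
  out
}
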