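# Shared helpers: finite-difference force checks, random rigid transforms,
# and small fixture molecules built in code.

# relative error between analytic forces and central finite differences
fd_force_relerr <- function(energy_fn, pos, forces, h = 1e-5) {
  fd <- matrix(0, nrow(pos), 3)
  for (a in seq_len(nrow(pos))) {
    for (k in 1:3) {
      pp <- pos; pp[a, k] <- pp[a, k] + h
      pm <- pos; pm[a, k] <- pm[a, k] - h
      fd[a, k] <- -(energy_fn(pp) - energy_fn(pm)) / (2 * h)
    }
  }
  max(abs(fd - forces)) / max(abs(forces), 1e-10)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# independent torsion oracle: two-plane normal-vector definition with atan2
torsion_oracle <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, ] - xyz[i, ]
  b2 <- xyz[k, ] - xyz[j, ]
  b3 <- xyz[l, ] - xyz[k, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  b2h <- b2 / sqrt(sum(b2^2))
  phi <- atan2(sum(cr(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

# 2-atom C-H fixture with a matching minimal force field
diatomic_fixture <- function() {
  mol <- molecule(c("C", "H"), rbind(c(0, 0, 0), c(0.77, 0.77, 0)),
                  bonds = rbind(c(1, 2)))
  ff <- structure(list(
    atomtypes = data.frame(type = c("C", "H"), epsilon = c(0.1, 0.015),
                           sigma = c(3.4, 2.6), charge = 0,
                           stringsAsFactors = FALSE),
    bonds = data.frame(type1 = "C", type2 = "H", k = 340, r0 = 1.09,
                       stringsAsFactors = FALSE),
    angles = data.frame(type1 = character(0), type2 = character(0),
                        type3 = character(0), k = numeric(0), theta0 = numeric(0)),
    torsions = data.frame(type1 = character(0), type2 = character(0),
                          type3 = character(0), type4 = character(0),
                          v = numeric(0), n = integer(0), phase = numeric(0)),
    scale14_lj = 0.5, scale14_coulomb = 0.833
  ), class = "mdoc_forcefield")
  list(mol = mol, ff = ff)
}

# random small "molecules" exercising every force-field term type
random_toy_configs <- function(n_configs = 5, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n_configs), function(i) {
    toy <- make_flexible_toy("chain")
    xyz <- toy$mol$xyz + matrix(stats::rnorm(3 * n_atoms(toy$mol), sd = 0.08),
                                ncol = 3)
    list(toy = toy, xyz = xyz)
  })
}
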