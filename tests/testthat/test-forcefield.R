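# Physical force field: energies, analytic gradients, invariances

test_that("harmonic bond follows E = k (r - r0)^2 with restoring force 2 k dr", {
  fix <- diatomic_fixture()
  mol <- molecule(c("C", "H"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
                  bonds = rbind(c(1, 2)))
  ff <- fix$ff
  ff$bonds$k <- 100; ff$bonds$r0 <- 1.5
  ef <- energy_forces(mol, ff)
  expect_equal(ef$breakdown[["bond"]], 1.0, tolerance = 1e-12)
  expect_equal(sqrt(sum(ef$forces[1, ]^2)), 20, tolerance = 1e-10)
  expect_equal(ef$forces[1, ], -ef$forces[2, ], tolerance = 1e-12)
})

test_that("LJ pair has zero force and energy -eps at r = 2^(1/6) sigma", {
  mol <- molecule(c("Ar", "Ar"), rbind(c(0, 0, 0), c(2^(1 / 6) * 3.4, 0, 0)),
                  masses = c(39.9, 39.9))
  ff <- structure(list(
    atomtypes = data.frame(type = "Ar", epsilon = 0.25, sigma = 3.4, charge = 0),
    bonds = data.frame(type1 = character(0), type2 = character(0),
                       k = numeric(0), r0 = numeric(0)),
    angles = data.frame(type1 = character(0), type2 = character(0),
                        type3 = character(0), k = numeric(0), theta0 = numeric(0)),
    torsions = data.frame(type1 = character(0), type2 = character(0),
                          type3 = character(0), type4 = character(0),
                          v = numeric(0), n = integer(0), phase = numeric(0)),
    scale14_lj = 0.5, scale14_coulomb = 0.833), class = "mdoc_forcefield")
  ef <- energy_forces(mol, ff, types = c("Ar", "Ar"))
  expect_equal(ef$energy, -0.25, tolerance = 1e-12)
  expect_lt(max(abs(ef$forces)), 1e-10)
})

test_that("analytic forces match finite differences on randomized molecules", {
  for (cfg in random_toy_configs(5)) {
    ef <- energy_forces(cfg$toy$mol, cfg$toy$ff, xyz = cfg$xyz,
                        types = cfg$toy$types)
    rel <- fd_force_relerr(function(x) {
      energy_forces(cfg$toy$mol, cfg$toy$ff, xyz = x, types = cfg$toy$types)$energy
    }, cfg$xyz, ef$forces)
    expect_lt(rel, 1e-5)
  }
  # with charges switched on, Coulomb gradients are exercised too
  toy <- make_flexible_toy("chain")
  toy$mol$atoms$charge <- c(-0.2, 0.1, 0.1, -0.2, 0.05, 0.05, 0.05, 0.05)
  ef <- energy_forces(toy$mol, toy$ff, types = toy$types)
  expect_gt(abs(ef$breakdown[["coulomb"]]), 0)
  rel <- fd_force_relerr(function(x) {
    energy_forces(toy$mol, toy$ff, xyz = x, types = toy$types)$energy
  }, toy$mol$xyz, ef$forces)
  expect_lt(rel, 1e-5)
})

test_that("breakdown sums to total; net force and torque vanish", {
  for (cfg in random_toy_configs(3, seed = 99)) {
    ef <- energy_forces(cfg$toy$mol, cfg$toy$ff, xyz = cfg$xyz,
                        types = cfg$toy$types)
    expect_equal(sum(unlist(ef$breakdown)), ef$energy,
                 tolerance = 1e-10)
    expect_lt(max(abs(colSums(ef$forces))), 1e-8)
    torque <- colSums(t(vapply(seq_len(nrow(cfg$xyz)), function(a) {
      r <- cfg$xyz[a, ]; f <- ef$forces[a, ]
      c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
        r[1] * f[2] - r[2] * f[1])
    }, numeric(3))))
    expect_lt(max(abs(torque)), 1e-8)
  }
})

test_that("energy is invariant under rigid rotation and translation", {
  set.seed(3)
  toy <- make_flexible_toy("chain")
  e0 <- energy_forces(toy$mol, toy$ff, types = toy$types)$energy
  for (rep in 1:10) {
    R <- random_rotation()
    xyz2 <- sweep(toy$mol$xyz %*% t(R), 2, rnorm(3, sd = 5), "+")
    e2 <- energy_forces(toy$mol, toy$ff, xyz = xyz2, types = toy$types)$energy
    expect_lt(abs(e2 - e0) / abs(e0), 1e-9)
  }
})

test_that("overlapping nonbonded atoms raise a singularity error", {
  toy <- make_flexible_toy("chain")
  xyz <- toy$mol$xyz
  xyz[7, ] <- xyz[5, ] # two hydrogens on different carbons coincide
  expect_error(energy_forces(toy$mol, toy$ff, xyz = xyz, types = toy$types),
               "singular|overlapping")
})

test_that("parameter files parse with sections, wildcards and validation", {
  ff <- toy_forcefield()
  expect_s3_class(ff, "mdoc_forcefield")
  expect_true(all(c("H", "C", "N", "O", "CL") %in% ff$atomtypes$type))
  expect_true(all(ff$bonds$k >= 0))
  # molecule fully covered by the file, including wildcard angles/torsions
  zm <- rbind(
    mdoc:::zmatrix_row("C"),
    mdoc:::zmatrix_row("C", a = 1, r = 1.526),
    mdoc:::zmatrix_row("O", a = 2, r = 1.41, b = 1, theta = 109.5),
    mdoc:::zmatrix_row("H", a = 1, r = 1.09, b = 2, theta = 109.5, c = 3, phi = 0),
    mdoc:::zmatrix_row("H", a = 1, r = 1.09, b = 2, theta = 109.5, c = 3, phi = 120),
    mdoc:::zmatrix_row("H", a = 1, r = 1.09, b = 2, theta = 109.5, c = 3, phi = -120),
    mdoc:::zmatrix_row("H", a = 2, r = 1.09, b = 1, theta = 109.5, c = 4, phi = 60),
    mdoc:::zmatrix_row("H", a = 2, r = 1.09, b = 1, theta = 109.5, c = 4, phi = -60),
    mdoc:::zmatrix_row("H", a = 3, r = 0.96, b = 2, theta = 104.5, c = 1, phi = 180)
  )
  xyz <- build_from_zmatrix(zm)
  mol <- molecule(zm$element, xyz,
                  bonds = rbind(c(1, 2), c(2, 3), c(1, 4), c(1, 5), c(1, 6),
                                c(2, 7), c(2, 8), c(3, 9)))
  ef <- energy_forces(mol, ff) # errors if any term is uncovered
  expect_true(is.finite(ef$energy))
  # missing parameters are reported by name
  mol2 <- molecule(c("N", "N"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                   bonds = rbind(c(1, 2)))
  expect_error(energy_forces(mol2, ff), "N-N")
})
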