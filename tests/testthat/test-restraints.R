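# Memory averaging, target tensors, pseudo-energies and pseudo-forces

gH <- gyromagnetic_ratio("H")
gC <- gyromagnetic_ratio("C")

test_that("exponential memory recursion behaves at its limits", {
  acc <- memory_accumulator(lambda = 0, init = 5)
  acc <- update_memory_average(acc, 2)
  expect_equal(acc$average, 2) # no memory
  acc <- memory_accumulator(lambda = 0.5, init = 0)
  acc <- update_memory_average(acc, 2)
  expect_equal(acc$average, 1.0)
  # constant input converges geometrically: residual = lambda^n * |c - start|
  lam <- exp(-0.5 / 100)
  acc <- memory_accumulator(lambda = lam, init = 0)
  n <- 2000
  for (s in seq_len(n)) acc <- update_memory_average(acc, 3)
  expect_equal(acc$average, 3 * (1 - lam^n), tolerance = 1e-12)
  expect_lt(abs(acc$average - 3), lam^n * 3 + 1e-12)
  # works elementwise on tensors
  acc <- memory_accumulator(lambda = 0.25, init = diag(3))
  acc <- update_memory_average(acc, matrix(1, 3, 3))
  expect_equal(acc$average, 0.75 * matrix(1, 3, 3) + 0.25 * diag(3))
  expect_error(update_memory_average(acc, 1:2), "shape")
  expect_error(memory_accumulator(lambda = 1), "lambda")
})

test_that("target tensors are axial, traceless, and field-aligned", {
  expect_equal(build_target_tensor(0), matrix(0, 3, 3))
  expect_equal(build_target_tensor(10), diag(c(-5, -5, 10)))
  set.seed(17)
  for (rep in 1:10) {
    b <- rnorm(3); b <- b / sqrt(sum(b^2))
    T1 <- build_target_tensor(7.5, b)
    expect_lt(abs(sum(diag(T1))), 1e-10)
    expect_equal(drop(t(b) %*% T1 %*% b), 7.5, tolerance = 1e-10)
    # equals R diag(-D/2,-D/2,D) R^T for any rotation taking z to b
    z <- c(0, 0, 1)
    v <- c(z[2] * b[3] - z[3] * b[2], z[3] * b[1] - z[1] * b[3],
           z[1] * b[2] - z[2] * b[1])
    cth <- sum(z * b)
    V <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + V + V %*% V / (1 + cth)
    expect_lt(max(abs(T1 - R %*% diag(c(-3.75, -3.75, 7.5)) %*% t(R))), 1e-9)
  }
})

test_that("tensorial pseudo-force is the exact gradient of its pseudo-energy", {
  set.seed(23)
  for (rep in 1:5) {
    pos <- matrix(rnorm(12, sd = 1.5), 4, 3)
    oml <- runif(1, 0.1, 0.9)
    w <- runif(1, 0.1, 2)
    tgt <- build_target_tensor(rnorm(1, 0, 10))
    avg0 <- matrix(rnorm(9), 3, 3); avg0 <- (avg0 + t(avg0)) / 2
    avg0 <- avg0 - diag(3) * sum(diag(avg0)) / 3
    efun <- function(x) {
      D <- dipolar_tensor(x, 1, 2, gC, gH)
      sum(w * (oml * D + (1 - oml) * avg0 - tgt)^2)
    }
    avg <- oml * dipolar_tensor(pos, 1, 2, gC, gH) + (1 - oml) * avg0
    r <- tensor_pseudo_energy_force(avg, tgt, w, pos, c(1, 2), gC, gH, oml)
    expect_equal(r$energy, efun(pos), tolerance = 1e-10)
    expect_lt(fd_force_relerr(efun, pos, r$forces), 1e-5)
    # zero net translational force; net torque generally nonzero
    expect_lt(max(abs(colSums(r$forces))), 1e-8)
    tq <- colSums(t(vapply(1:4, function(a) {
      rr <- pos[a, ]; f <- r$forces[a, ]
      c(rr[2] * f[3] - rr[3] * f[2], rr[3] * f[1] - rr[1] * f[3],
        rr[1] * f[2] - rr[2] * f[1])
    }, numeric(3))))
    expect_gt(max(abs(tq)), 1e-6)
    # satisfied constraint: zero energy and force
    D <- dipolar_tensor(pos, 1, 2, gC, gH)
    r0 <- tensor_pseudo_energy_force(D, D, w, pos, c(1, 2), gC, gH, oml)
    expect_equal(r0$energy, 0)
    expect_lt(max(abs(r0$forces)), 1e-12)
    # linear in the weight
    r2 <- tensor_pseudo_energy_force(avg, tgt, 2 * w, pos, c(1, 2), gC, gH, oml)
    expect_equal(r2$energy, 2 * r$energy, tolerance = 1e-12)
    expect_equal(r2$forces, 2 * r$forces, tolerance = 1e-12)
  }
})

test_that("NOE flat-bottom pseudo-term: dead zone, wings, exact gradient", {
  pos <- rbind(c(0, 0, 0), c(2.0, 0, 0))
  rst <- list(value = 2.0, error = 0.05, weight = 3)
  # r_eff inside the window: zero energy and force
  inside <- distance_pseudo_energy_force((2.02)^-6, rst, pos, c(1, 2), 0.4)
  expect_equal(inside$energy, 0)
  expect_lt(max(abs(inside$forces)), 1e-14)
  # r_eff = r_exp + 2e: energy = w e^2, force pulls the pair together
  up <- distance_pseudo_energy_force((2.0 + 2 * 0.05)^-6, rst, pos, c(1, 2), 0.4)
  expect_equal(up$energy, 3 * 0.05^2, tolerance = 1e-12)
  expect_lt(up$forces[2, 1], 0) # atom 2 pulled toward atom 1
  expect_equal(up$forces[1, ], -up$forces[2, ], tolerance = 1e-12)
  # exact gradient through the chain rule
  set.seed(29)
  for (rep in 1:5) {
    posr <- matrix(rnorm(6, sd = 2), 2, 3)
    oml <- 0.35
    avg0 <- 0.02
    efun <- function(x) {
      r <- sqrt(sum((x[2, ] - x[1, ])^2))
      m <- oml * r^-6 + (1 - oml) * avg0
      dev <- m^(-1 / 6) - rst$value
      u <- if (dev > rst$error) dev - rst$error else
        if (dev < -rst$error) dev + rst$error else 0
      rst$weight * u^2
    }
    m0 <- oml * sum((posr[2, ] - posr[1, ])^2)^-3 + (1 - oml) * avg0
    r <- distance_pseudo_energy_force(m0, rst, posr, c(1, 2), oml)
    expect_equal(r$energy, efun(posr), tolerance = 1e-10)
    if (r$energy > 0) expect_lt(fd_force_relerr(efun, posr, r$forces), 1e-5)
  }
})

test_that("3J flat-bottom pseudo-term chains through Karplus and dihedral", {
  ka <- haasnoot_altona_params()
  subs <- data.frame(dchi = c(0.8, 0.3), xi = c(1, -1))
  rst <- list(value = 9, error = 1.25, weight = 2)
  set.seed(37)
  for (rep in 1:5) {
    pos <- matrix(rnorm(12, sd = 1.5), 4, 3)
    oml <- 0.45
    avg0 <- 5
    efun <- function(x) {
      J <- karplus_3j(measure_torsion(x, 1, 2, 3, 4), subs, ka)
      avg <- oml * J + (1 - oml) * avg0
      u <- if (avg - rst$value > rst$error) avg - rst$value - rst$error else
        if (avg - rst$value < -rst$error) avg - rst$value + rst$error else 0
      rst$weight * u^2
    }
    avgJ <- oml * karplus_3j(measure_torsion(pos, 1, 2, 3, 4), subs, ka) +
      (1 - oml) * avg0
    r <- j_pseudo_energy_force(avgJ, rst, pos, c(1, 2, 3, 4), subs, ka, oml)
    expect_equal(r$energy, efun(pos), tolerance = 1e-10)
    if (r$energy > 0) expect_lt(fd_force_relerr(efun, pos, r$forces), 1e-5)
    expect_lt(max(abs(colSums(r$forces))), 1e-8) # internal forces only
  }
  # satisfied constraint
  r0 <- j_pseudo_energy_force(9, rst, matrix(rnorm(12), 4, 3), 1:4, subs, ka, 0.5)
  expect_equal(r0$energy, 0)
  expect_lt(max(abs(r0$forces)), 1e-14)
  # at a Karplus extremum the torsional force vanishes even when J deviates
  zm <- rbind(
    mdoc:::zmatrix_row("H"),
    mdoc:::zmatrix_row("C", a = 1, r = 1.09),
    mdoc:::zmatrix_row("C", a = 2, r = 1.53, b = 1, theta = 109.5),
    mdoc:::zmatrix_row("H", a = 3, r = 1.09, b = 2, theta = 109.5, c = 1, phi = 0)
  )
  pos0 <- build_from_zmatrix(zm)
  rext <- j_pseudo_energy_force(20, rst, pos0, c(1, 2, 3, 4), NULL, ka, 0.5)
  expect_gt(rext$energy, 0)
  expect_lt(max(abs(rext$forces)), 1e-8) # dJ/dphi = 0 at phi = 0
})

test_that("restraint sets resolve labels, paths, and default errors", {
  sc <- two_state_scenario(noise_scale = 0, seed = 2)
  tab <- data.frame(type = c("RDC", "NOE", "NOE", "J3"),
                    atom1 = c("C1", "H1a", "H1a", "H1a"),
                    atom2 = c("H1a", "H2a", "H2b", "H2a"),
                    value = c(5, 2.5, 3.1, 6),
                    error = NA_real_, weight = NA_real_)
  rs <- restraint_set(sc$mol, tab)
  expect_equal(rs$rdc$error, 0.5)
  expect_equal(rs$noe$error, c(0.05, 0.11)) # the 2.8 A rule
  expect_equal(rs$j3$error, 1.25) # combined experimental + curve error
  # the J path is the vicinal H-C-C-H quad
  expect_equal(rs$jpaths[[1]]$quad,
               atom_index(sc$mol, c("H1a", "C1", "C2", "H2a")))
  # each coupled carbon carries two substituents (Cl and the geminal H)
  expect_equal(nrow(rs$jpaths[[1]]$substituents), 4)
  expect_error(restraint_set(sc$mol, data.frame(
    type = "J3", atom1 = "H1a", atom2 = "H1b", value = 5,
    error = NA_real_, weight = NA_real_)), "vicinal")
  expect_error(restraint_set(sc$mol, data.frame(
    type = "RDC", atom1 = "Cl1", atom2 = "C1", value = 5,
    error = NA_real_, weight = NA_real_)), "NMR-silent")
  expect_error(restraint_set(sc$mol, data.frame(
    type = "NOE", atom1 = "H1a", atom2 = "H9x", value = 2,
    error = NA_real_, weight = NA_real_)), "unknown atom")
})

test_that("a single RDC restraint aligns a rigid diatomic to its target", {
  fix <- diatomic_fixture()
  dmax <- dmax_coupling(1.09, gC, gH)
  tab <- data.frame(type = "RDC", atom1 = "C1", atom2 = "H2", value = dmax,
                    error = 0.5, weight = 1e-3)
  rs <- restraint_set(fix$mol, tab)
  cfg <- md_config(n_steps = 1e5, dt = 0.5, temperature = 50,
                   tau_thermostat = 50, seed = 4, snapshot_interval = 50,
                   tau_memory = 2000, ramp_steps = 5000, force_cap = 20)
  sim <- run_simulation(fix$mol, fix$ff, rs, cfg)
  late <- sim$trajectory$times > 30000
  avgD <- mean(sim$observables$rdc[late, 1])
  expect_lt(abs(avgD / dmax - 1), 0.15) # bond settles along the field
})
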