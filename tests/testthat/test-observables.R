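# Back-calculated NMR observables: dipolar tensors, RDC projections, NOE
# effective distances, Karplus couplings

gH <- gyromagnetic_ratio("H")
gC <- gyromagnetic_ratio("C")

test_that("13C-1H dipolar coupling at 1.09 A is about -23.3 kHz", {
  expect_equal(dmax_coupling(1.09, gC, gH), -23328, tolerance = 1e-3)
  expect_error(dmax_coupling(0, gC, gH), "distance")
})

test_that("dipolar tensors are symmetric, traceless and axial about the bond", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.09))
  D <- dipolar_tensor(xyz, 1, 2, gC, gH)
  dmax <- dmax_coupling(1.09, gC, gH)
  expect_equal(D[3, 3], dmax, tolerance = 1e-12)
  expect_equal(D[1, 1], -dmax / 2, tolerance = 1e-12)
  expect_equal(D[2, 2], -dmax / 2, tolerance = 1e-12)
  expect_lt(max(abs(D[upper.tri(D)]), abs(D[lower.tri(D)])), 1e-10)
  set.seed(21)
  for (rep in 1:20) {
    xyz <- matrix(rnorm(6), 2, 3)
    D <- dipolar_tensor(xyz, 1, 2, gC, gH)
    expect_lt(max(abs(D - t(D))), 1e-10)
    expect_lt(abs(sum(diag(D))), 1e-8)
  }
  expect_error(dipolar_tensor(rbind(c(0, 0, 0), c(0, 0, 0)), 1, 2, gC, gH),
               "singular|coincident")
})

test_that("dipolar tensor is rotation-equivariant: D(R r) = R D R^T", {
  set.seed(31)
  xyz <- rbind(c(0.2, -0.4, 0.1), c(1.0, 0.3, -0.5))
  D <- dipolar_tensor(xyz, 1, 2, gC, gH)
  for (rep in 1:10) {
    R <- random_rotation()
    D2 <- dipolar_tensor(xyz %*% t(R), 1, 2, gC, gH)
    expect_lt(max(abs(D2 - R %*% D %*% t(R))) / abs(dmax_coupling(1, gC, gH)), 1e-10)
  }
})

test_that("rdc_value projects on the field axis with the 3cos^2-1 law", {
  xyz <- rbind(c(0, 0, 0), c(1.09, 0, 0)) # bond perpendicular to z
  D <- dipolar_tensor(xyz, 1, 2, gC, gH)
  dmax <- dmax_coupling(1.09, gC, gH)
  expect_equal(rdc_value(D), -dmax / 2, tolerance = 1e-10)
  # magic angle null
  ma <- acos(1 / sqrt(3))
  xyzm <- rbind(c(0, 0, 0), 1.09 * c(sin(ma), 0, cos(ma)))
  expect_lt(abs(rdc_value(dipolar_tensor(xyzm, 1, 2, gC, gH))), 1e-6 * abs(dmax))
  expect_error(rdc_value(D, c(0, 0, 0)), "nonzero")
})

test_that("isotropic orientational average of the RDC is zero", {
  set.seed(5)
  n <- 1e5
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  vals <- 1 * (3 * v[, 3]^2 - 1) / 2 # unit-Dmax couplings
  se <- sd(vals) / sqrt(n)
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("NOE effective distance obeys r^-6 averaging and power-mean bounds", {
  expect_equal(effective_noe_distance(rep(2, 100)), 2.0, tolerance = 1e-12)
  expect_equal(effective_noe_distance(c(2, 4)), ((2^-6 + 4^-6) / 2)^(-1 / 6),
               tolerance = 1e-12)
  expect_equal(effective_noe_distance(c(2, 4)), 2.239, tolerance = 1e-3)
  set.seed(13)
  for (rep in 1:20) {
    r <- runif(50, 1.5, 5)
    reff <- effective_noe_distance(r)
    expect_gte(reff, min(r))
    expect_lte(reff, mean(r))
    # strictly decreases when any sample distance decreases
    r2 <- r; r2[7] <- r2[7] * 0.9
    expect_lt(effective_noe_distance(r2), reff)
  }
  expect_error(effective_noe_distance(numeric(0)), "empty")
  expect_equal(effective_noe_distance(0.01, is_mean_r6 = TRUE), 0.01^(-1 / 6))
})

test_that("Karplus curve reduces to A cos^2 + B cos + C without corrections", {
  p <- haasnoot_altona_params()
  expect_equal(karplus_3j(90), unname(p$P[["P3"]]), tolerance = 1e-12)
  for (phi in seq(-180, 180, by = 15)) {
    expect_equal(karplus_3j(phi), karplus_3j(-phi), tolerance = 1e-12)
    expect_equal(karplus_3j(phi),
                 p$P[["P1"]] * cos(phi * pi / 180)^2 +
                   p$P[["P2"]] * cos(phi * pi / 180) + p$P[["P3"]],
                 tolerance = 1e-12)
  }
})

test_that("full Haasnoot-Altona evaluation matches an independent implementation", {
  p <- haasnoot_altona_params()
  subs <- data.frame(dchi = c(1.3 - 0.14 * 0.4, 0.4, -0.05), xi = c(1, -1, 1))
  # independently coded generalized Karplus expression
  oracle <- function(phi_deg) {
    ph <- phi_deg * pi / 180
    J <- p$P[["P1"]] * cos(ph)^2 + p$P[["P2"]] * cos(ph) + p$P[["P3"]]
    for (s in 1:nrow(subs)) {
      J <- J + subs$dchi[s] *
        (p$P[["P4"]] + p$P[["P5"]] *
           cos(subs$xi[s] * ph + p$P[["P6"]] * pi / 180 * abs(subs$dchi[s]))^2)
    }
    J
  }
  for (phi in seq(-180, 180, by = 10)) {
    expect_equal(karplus_3j(phi, subs, p), oracle(phi), tolerance = 1e-10)
    # compiled evaluator used inside the MD loop agrees too
    expect_equal(mdoc:::cpp_karplus(mdoc:::karplus_cpp_spec(p, subs), phi * pi / 180),
                 oracle(phi), tolerance = 1e-10)
  }
  # derivative consistent with the curve
  h <- 1e-6
  for (phi in c(-120, -35, 10, 60, 170)) {
    num <- (karplus_3j(phi + h, subs, p) - karplus_3j(phi - h, subs, p)) /
      (2 * h * pi / 180)
    expect_equal(mdoc:::karplus_3j_deriv(phi, subs, p), num, tolerance = 1e-5)
  }
})

test_that("observable tables round-trip bit-exactly", {
  df <- data.frame(type = c("RDC", "NOE", "J3"), atom1 = c("C1", "H1a", "H1b"),
                   atom2 = c("H1a", "H2a", "H2b"),
                   value = c(pi, exp(1), sqrt(2)),
                   error = c(0.5, 0.05, 1.25), weight = c(NA, 2.5, 3.25))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(df, f)
  df2 <- read_restraints(f)
  expect_identical(df$value, df2$value)
  expect_identical(df$error, df2$error)
  expect_identical(df$weight, df2$weight)
  expect_identical(df$atom1, df2$atom1)
})
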