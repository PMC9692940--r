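# Quality statistics, assignment resolution, torsion distributions, joint
# conformer tables, flip aggregates, trajectory back-calculation

test_that("chi-square report reproduces the worked outlier values", {
  comp <- data.frame(label = c("H14-C14", "H12-H23a"),
                     q_exp = c(31.50, 2.232), q_calc = c(30.72, 2.308),
                     error = c(0.5, 0.05))
  rep <- chi2_report(comp)
  expect_equal(round(rep$inv_chi2_i[1], 2), 0.41)
  expect_equal(round(rep$inv_chi2_i[2], 2), 0.43)
  expect_true(all(rep$outlier)) # both lie outside their error
  # perfect fit: chi2 = 0, quality +Inf, no outliers
  perfect <- chi2_report(data.frame(label = letters[1:3], q_exp = 1:3,
                                    q_calc = 1:3, error = 0.1))
  expect_equal(attr(perfect, "chi2"), 0)
  expect_identical(attr(perfect, "quality"), Inf)
  expect_equal(attr(perfect, "n_outliers"), 0)
  expect_error(chi2_report(data.frame(label = "x", q_exp = 1, q_calc = 1,
                                      error = 0)), "positive")
})

test_that("quality n/chi2 > 1 iff mean weighted squared deviation < 1", {
  set.seed(41)
  for (rep_i in 1:10) {
    n <- sample(3:30, 1)
    comp <- data.frame(label = seq_len(n), q_exp = rnorm(n, 5),
                       q_calc = rnorm(n, 5), error = runif(n, 0.2, 1))
    r <- chi2_report(comp)
    msd <- mean(((comp$q_exp - comp$q_calc) / comp$error)^2)
    expect_equal(attr(r, "quality") > 1, msd < 1)
    expect_equal(attr(r, "chi2"), sum(r$chi2_i))
    expect_equal(r$outlier, abs(comp$q_exp - comp$q_calc) > comp$error)
  }
})

test_that("chi-square minimization swaps both ambiguous coupling groups", {
  predicted <- c(4.975, 12.148, 7.902, 4.407)
  experimental <- c(10.70, 7.20, 3.34, 8.47)
  res <- resolve_assignment(predicted, experimental,
                            groups = list(c(1, 2), c(3, 4)))
  expect_equal(res$assignment, c(2, 1, 4, 3)) # both groups interchange
  expect_lt(res$chi2, res$chi2_identity)
  # pairing after the swap: 4.975 <-> 7.20, 12.148 <-> 10.70 etc.
  expect_equal(experimental[res$assignment], c(7.20, 10.70, 8.47, 3.34))
})

test_that("assignment resolution never worsens chi2 and breaks ties stably", {
  # identical predictions: identity permutation by lexicographic tie-break
  res <- resolve_assignment(c(5, 5), c(4, 6), groups = list(c(1, 2)))
  expect_equal(res$assignment, c(1, 2))
  set.seed(43)
  for (rep_i in 1:10) {
    p <- rnorm(6); e <- rnorm(6)
    res <- resolve_assignment(p, e, groups = list(1:3, 4:6))
    expect_lte(res$chi2, res$chi2_identity + 1e-12)
    expect_true(all(sort(res$assignment) == 1:6))
  }
  expect_error(resolve_assignment(1:2, 1:3, list(1:2)), "equal length")
  expect_error(resolve_assignment(1:2, 2:1, list(1:5)), "out of range")
})

test_that("torsion distributions are normalized probability histograms", {
  d <- torsion_distribution(rep(40, 100), bin_width = 2)
  expect_equal(sum(d$probability), 100, tolerance = 1e-9)
  occ <- d[d$probability > 0, ]
  expect_equal(nrow(occ), 1) # single occupied bin
  expect_equal(occ$probability, 100)
  expect_lte(abs(occ$midpoint - 40), 1)
  d2 <- torsion_distribution(c(rep(-60, 50), rep(60, 50)), bin_width = 5)
  expect_equal(sort(d2$probability[d2$probability > 0]), c(50, 50))
  set.seed(47)
  u <- runif(1e6, -180, 180)
  d3 <- torsion_distribution(u, bin_width = 10)
  p0 <- 100 / 36
  sigma <- 100 * sqrt((1 / 36) * (35 / 36) / 1e6)
  expect_true(all(abs(d3$probability - p0) < 3.5 * sigma))
  expect_equal(sum(d3$probability), 100, tolerance = 1e-9)
  expect_error(torsion_distribution(numeric(0)), "empty")
  expect_error(torsion_distribution(1:5, bin_width = 7), "divide")
})

test_that("gauche classification is sign-based with configurable boundary", {
  expect_equal(classify_gauche(40), "+g")
  expect_equal(classify_gauche(-40), "-g")
  expect_equal(classify_gauche(0.0001), "+g")
  expect_equal(classify_gauche(-0.0001), "-g")
  expect_equal(classify_gauche(0), "-g") # boundary itself goes to -g
  expect_equal(classify_gauche(30, boundary = 35), "-g")
  expect_equal(classify_gauche(c(170, -170, 40), three_state = TRUE),
               c("t", "t", "+g"))
})

test_that("joint state probabilities match brute-force tuple counting", {
  # constructed 3:1 label sequence
  ct <- joint_state_probabilities(list(a = c(40, 40, 40, -40)))
  expect_equal(ct$probability, c(75, 25))
  expect_equal(ct$state, c("{+g}", "{-g}"))
  set.seed(53)
  s1 <- runif(5000, -180, 180)
  s2 <- runif(5000, -180, 180)
  s3 <- runif(5000, -180, 180)
  ct <- joint_state_probabilities(list(C = s1, F = s2, G = s3))
  # counting oracle
  lab <- paste0("{", classify_gauche(s1), ", ", classify_gauche(s2), ", ",
                classify_gauche(s3), "}")
  cnt <- sort(table(lab), decreasing = TRUE)
  expect_equal(ct$state, names(cnt))
  expect_equal(ct$probability, as.numeric(cnt) / 50)
  expect_equal(sum(ct$probability), 100, tolerance = 1e-9)
  expect_error(joint_state_probabilities(list(a = 1:3, b = 1:4)), "length")
})

test_that("flip aggregates reproduce the published ring-flip totals", {
  tab <- conformer_table(
    states = c("{+g, +g, -g}", "{+g, +g, +g}", "{-g, +g, -g}",
               "{-g, +g, +g}", "{+g, -g, -g}", "{-g, -g, -g}"),
    probabilities = c(76.45, 18.49, 3.61, 1.06, 0.36, 0.02))
  expect_equal(round_half_up(aggregate_flip(tab, 1, "-g"), 1), 4.7)
  expect_equal(round_half_up(aggregate_flip(tab, 2, "-g"), 1), 0.4)
  expect_equal(round_half_up(aggregate_flip(tab, 3, "+g"), 1), 19.6)
  # labels of one torsion always sum to the table total
  for (k in 1:3) {
    expect_equal(aggregate_flip(tab, k, "+g") + aggregate_flip(tab, k, "-g"),
                 sum(tab$probability), tolerance = 1e-12)
  }
  expect_error(aggregate_flip(tab, 4, "+g"), "out of range")
  expect_error(conformer_table("{+g}", 50), "sum to 100")
})

test_that("trajectory-mean observables follow the class averaging rules", {
  sc <- two_state_scenario(noise_scale = 0, seed = 3)
  tab <- generate_reference_observables(sc)
  rs <- restraint_set(sc$mol, tab)
  # single-frame trajectory: per-frame values unchanged
  f1 <- mdoc:::scenario_frame(sc, 60)
  traj1 <- structure(list(coords = array(f1, c(1, nrow(f1), 3)), times = 0,
                          interval = 1, labels = sc$mol$atoms$label, seed = 1L),
                     class = "mdoc_trajectory")
  comp1 <- predict_observables(traj1, rs)
  noe1 <- comp1[comp1$type == "NOE", ]
  expect_equal(noe1$q_calc[1], measure_distance(f1, atom_index(sc$mol, "H1a"),
                                                atom_index(sc$mol, "H2a")),
               tolerance = 1e-12)
  # two frames with NOE distances 2 and 4 -> 2.239 A
  base <- matrix(0, 2, 3)
  fr <- array(0, c(2, 2, 3))
  fr[1, 2, 1] <- 2; fr[2, 2, 1] <- 4
  mol2 <- molecule(c("H", "H"), base, bonds = NULL,
                   labels = c("Ha", "Hb"))
  rs2 <- restraint_set(mol2, data.frame(type = "NOE", atom1 = "Ha",
                                        atom2 = "Hb", value = 2.2,
                                        error = NA_real_, weight = NA_real_))
  traj2 <- structure(list(coords = fr, times = 0:1, interval = 1,
                          labels = c("Ha", "Hb"), seed = 1L),
                     class = "mdoc_trajectory")
  comp2 <- predict_observables(traj2, rs2)
  expect_equal(comp2$q_calc, ((2^-6 + 4^-6) / 2)^(-1 / 6), tolerance = 1e-12)
  expect_equal(comp2$q_calc, 2.239, tolerance = 1e-3)
  # isotropically rotated copies of one frame: mean RDC ~ 0
  set.seed(59)
  nfr <- 4000
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.09))
  frs <- array(0, c(nfr, 2, 3))
  for (f in seq_len(nfr)) frs[f, , ] <- xyz %*% t(random_rotation())
  molr <- molecule(c("C", "H"), xyz, labels = c("C1", "H1"))
  rsr <- restraint_set(molr, data.frame(type = "RDC", atom1 = "C1",
                                        atom2 = "H1", value = 0,
                                        error = NA_real_, weight = NA_real_))
  trajr <- structure(list(coords = frs, times = seq_len(nfr), interval = 1,
                          labels = c("C1", "H1"), seed = 1L),
                     class = "mdoc_trajectory")
  compr <- predict_observables(trajr, rsr)
  dmax <- abs(dmax_coupling(1.09, gyromagnetic_ratio("C"), gyromagnetic_ratio("H")))
  # sampling error of the mean of (3cos^2-1)/2 couplings
  se <- dmax * sqrt(1 / 5) / sqrt(nfr)
  expect_lt(abs(compr$q_calc), 4 * se)
})
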