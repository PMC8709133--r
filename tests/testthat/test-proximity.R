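track <- function(pos, e) {
  m <- cbind(pos, e)
  colnames(m) <- c("x_um", "y_um", "z_um", "edep_keV")
  m
}

test_that("worked pair examples reproduce the hand-computed masses", {
  # two 1 keV deposits 5 nm apart: both orderings carry 1*1/2 each, so the
  # [4, 6] nm bin holds 1 keV of mass, t = 0.5 keV/nm = 500 keV/um
  trk <- track(rbind(c(0, 0, 0), c(0.005, 0, 0)), c(1, 1))
  pc <- estimate_proximity(trk, bin_edges = c(0.004, 0.006))
  expect_equal(pc$bin_mass_keV, 1)
  expect_equal(pc$t_keV_per_um, 1 / 0.002)
  expect_equal(pc$out_of_range_mass_keV, 0)

  # a single deposit has no pairs
  pc1 <- estimate_proximity(track(rbind(c(0, 0, 0)), 2),
                            bin_edges = c(0, 1))
  expect_true(all(pc1$t_keV_per_um == 0))

  # collinear deposits of 1, 2, 3 keV at 0, 10, 30 nm: ordered-pair masses
  # 2*1*2/6 at 10 nm, 2*2*3/6 at 20 nm, 2*1*3/6 at 30 nm
  trk <- track(rbind(c(0, 0, 0), c(0.010, 0, 0), c(0.030, 0, 0)),
               c(1, 2, 3))
  edges <- c(0.005, 0.015, 0.025, 0.035)
  pc <- estimate_proximity(trk, edges)
  expect_equal(pc$bin_mass_keV, c(2 / 3, 2, 1))
  expect_equal(sum(pc$bin_mass_keV), 6 - 14 / 6)
})

test_that("binned estimator equals the brute-force double loop exactly", {
  edges <- c(0, 0.05, 0.1, 0.2, 0.4, 0.8)
  set.seed(201)
  for (n in c(2, 5, 50, 200)) {
    tracks <- list(random_track(n), random_track(max(2, n %/% 2)))
    pc <- estimate_proximity(tracks, edges)
    orc <- oracle_proximity(tracks, edges)
    expect_equal(pc$t_keV_per_um, orc$t, tolerance = 1e-12)
    expect_equal(pc$out_of_range_mass_keV, orc$out, tolerance = 1e-12)
  }
})

test_that("per-track mass identity holds exactly, out-of-range included", {
  set.seed(202)
  tracks <- lapply(c(3, 17, 120), random_track, spread_um = 0.9)
  # narrow binning so much of the mass lands out of range
  pc <- estimate_proximity(tracks, bin_edges = c(0.01, 0.05, 0.2))
  expected <- mean(vapply(tracks, function(m) {
    e <- m[, "edep_keV"]
    sum(e) - sum(e^2) / sum(e)
  }, numeric(1)))
  expect_equal(sum(pc$bin_mass_keV) + pc$out_of_range_mass_keV, expected,
               tolerance = 1e-12)
})

test_that("t(x) is invariant under rotation and translation of a track", {
  set.seed(203)
  m <- random_track(60)
  th <- 0.83
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  m2 <- m
  m2[, 1:3] <- m[, 1:3] %*% rot + matrix(c(5, -2, 11), nrow(m), 3,
                                         byrow = TRUE)
  edges <- default_bin_edges()
  a <- estimate_proximity(m, edges)
  b <- estimate_proximity(m2, edges)
  expect_equal(a$t_keV_per_um, b$t_keV_per_um, tolerance = 1e-9)
})

test_that("spectrum weighting is a convex bin-wise combination", {
  set.seed(204)
  edges <- c(0, 0.1, 0.5, 1)
  a <- estimate_proximity(random_track(20), edges)
  expect_equal(weighted_proximity(list(a), 2)$t_keV_per_um, a$t_keV_per_um)
  expect_equal(weighted_proximity(list(a, a), c(0.5, 0.5))$t_keV_per_um,
               a$t_keV_per_um)

  b <- estimate_proximity(random_track(30), edges)
  w <- weighted_proximity(list(a, b), c(0.25, 0.75))
  expect_equal(sum(w$bin_mass_keV) + w$out_of_range_mass_keV,
               0.25 * (sum(a$bin_mass_keV) + a$out_of_range_mass_keV) +
                 0.75 * (sum(b$bin_mass_keV) + b$out_of_range_mass_keV))

  bad <- estimate_proximity(random_track(10), c(0, 0.2, 1))
  expect_error(weighted_proximity(list(a, bad), c(1, 1)), "bin_edges")
})

test_that("dose term adds 4 pi x^2 rho D in keV/um and is additive", {
  # a curve that is zero everywhere, one bin with geometric centre 1 um
  edges <- c(0.5, 2)
  zero <- estimate_proximity(track(rbind(c(0, 0, 0)), 1), edges)
  with_dose <- add_dose_term(zero, density_g_cm3 = 1, dose_Gy = 1)
  expect_equal(with_dose$t_keV_per_um,
               4 * pi * 1^2 * (1e-15 / 1.602176634e-16),
               tolerance = 1e-12)

  set.seed(205)
  pc <- estimate_proximity(random_track(40), default_bin_edges())
  expect_equal(add_dose_term(pc, 1, 0)$t_keV_per_um, pc$t_keV_per_um)
  once <- add_dose_term(pc, 1, 3)
  twice <- add_dose_term(add_dose_term(pc, 1, 1), 1, 2)
  expect_equal(once$t_keV_per_um, twice$t_keV_per_um, tolerance = 1e-12)
})

test_that("event pair integral matches hand evaluation and its limits", {
  a <- 0.07
  # single deposit: no pairs
  expect_equal(event_proximity_integral(track(rbind(c(0, 0, 0)), 5), a), 0)

  # two 1 keV deposits at distance a: E * (2 e^-1 / 2) = 2 e^-1
  two <- track(rbind(c(0, 0, 0), c(a, 0, 0)), c(1, 1))
  expect_equal(event_proximity_integral(two, a), 2 * exp(-1),
               tolerance = 1e-12)

  # a -> infinity recovers E * (T - sum(e^2)/T)
  set.seed(206)
  m <- random_track(25)
  e <- m[, "edep_keV"]
  total <- sum(e)
  expect_equal(event_proximity_integral(m, 1e9),
               total * (total - sum(e^2) / total), tolerance = 1e-6)
})

test_that("uncorrelated uniform deposits reproduce the dose term at small x", {
  # N equal transfers uniform in a ball correspond to a uniform energy
  # density rho*D = (N-1) e / V per deposit pair partner; at x << R the
  # empirical t(x) must approach 4 pi x^2 * (that density)
  set.seed(207)
  R <- 3
  N <- 2000
  u <- runif(N)^(1 / 3) * R
  dirs <- cbind(runif(N, -1, 1), runif(N, 0, 2 * pi))
  sz <- sqrt(1 - dirs[, 1]^2)
  pos <- cbind(sz * cos(dirs[, 2]), sz * sin(dirs[, 2]), dirs[, 1]) * u
  m <- track(pos, rep(1, N))
  edges <- c(0.1, 0.2, 0.3)
  pc <- estimate_proximity(m, edges)
  dens <- (N - 1) * 1 / (4 / 3 * pi * R^3)  # keV/um^3
  xbar <- sqrt(edges[-3] * edges[-1])
  expect_equal(pc$t_keV_per_um, 4 * pi * xbar^2 * dens, tolerance = 0.2)
})

test_that("proximity CSV round trip restores the curve", {
  set.seed(208)
  pc <- estimate_proximity(list(random_track(30), random_track(10)),
                           default_bin_edges(5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_proximity_csv(pc, path)
  back <- read_proximity_csv(path)
  expect_equal(back$bin_edges, pc$bin_edges)
  expect_equal(back$t_keV_per_um, pc$t_keV_per_um)
  expect_equal(back$n_tracks, pc$n_tracks)
  expect_equal(back$out_of_range_mass_keV, pc$out_of_range_mass_keV)
})
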