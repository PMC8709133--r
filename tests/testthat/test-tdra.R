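# analytic exponential proximity curve t(x) = A exp(-x / b) on fine log
# bins, evaluated at the geometric bin representatives
analytic_curve <- function(A, b, n_per_decade = 200) {
  edges <- 10^seq(-6, 1, by = 1 / n_per_decade)
  xbar <- sqrt(edges[-length(edges)] * edges[-1])
  trivial <- estimate_proximity(
    cbind(x_um = 0, y_um = 0, z_um = 0, edep_keV = 1), edges
  )
  trivial$t_keV_per_um <- A * exp(-xbar / b)
  trivial$bin_mass_keV <- trivial$t_keV_per_um * diff(edges)
  trivial
}

kev_per_g_to_gy <- 1.602176634e-13

test_that("quality parameter from LQ coefficients is alpha/beta", {
  expect_equal(xi_from_lq(0.150, 0.041), 3.65854, tolerance = 1e-5)
  expect_equal(xi_from_lq(0.04, 0.05), 0.8)
  expect_equal(xi_from_lq(0, 0.05), 0)
  expect_error(xi_from_lq(0.1, 0))
})

test_that("xi from a proximity curve matches the closed form", {
  # integral of A e^(-x/b) e^(-x/a) dx = A a b / (a + b), so
  # xi = A a b / (a + b) / (8 pi a^3 rho), converted keV/g -> Gy
  A <- 100
  b <- 0.05
  a <- 0.1
  cv <- analytic_curve(A, b)
  expected <- A * (a * b / (a + b)) * kev_per_g_to_gy /
    (8 * pi * a^3 * 1e-12)
  expect_equal(xi_from_proximity(cv, a), expected, tolerance = 1e-3)

  # all-zero curve
  z <- analytic_curve(0, b)
  expect_equal(xi_from_proximity(z, a), 0)

  # xi decreases as the interaction range a grows (short-range t)
  xs <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(ai)
    xi_from_proximity(cv, ai), numeric(1))
  expect_true(all(diff(xs) < 0))
})

test_that("solve_a inverts xi_from_proximity", {
  set.seed(301)
  model <- cascade_model()
  tracks <- replicate(50, generate_water_track(10, model), simplify = FALSE)
  cv <- estimate_proximity(tracks, default_bin_edges(40))

  # round trip at a realistic decay length
  a_star <- 0.122
  xi_star <- xi_from_proximity(cv, a_star)
  expect_equal(solve_a(cv, xi_star), a_star, tolerance = 1e-4)

  # analytic curve: recovered a matches the algebraic inversion
  cv2 <- analytic_curve(100, 0.05)
  a0 <- 0.1
  xi0 <- 100 * (a0 * 0.05 / (a0 + 0.05)) * kev_per_g_to_gy /
    (8 * pi * a0^3 * 1e-12)
  expect_equal(solve_a(cv2, xi0), a0, tolerance = 1e-3)

  # unbracketed target names the achievable range
  expect_error(solve_a(cv, 1e12), "achievable")
})

test_that("delta_xi matches a hand-computed three-event fixture", {
  cell <- cell_preset("Hela")
  a <- 0.1
  ev_pair <- cbind(x_um = c(0, 0.1), y_um = 0, z_um = 0, edep_keV = 1)
  ev_single <- cbind(x_um = 0, y_um = 0, z_um = 0, edep_keV = 4)
  ev_miss <- matrix(numeric(0), ncol = 4,
                    dimnames = list(NULL, colnames(ev_pair)))
  events <- list(ev_pair, ev_single, ev_miss)
  exposure <- np_exposure(n = 100, p1Gy = 0.02)

  # only the pair event contributes: E * pair sum / T = 2 e^-1 keV^2;
  # mean over the three events, then the Eq-style normalization
  mean_int <- 2 * exp(-1) / 3
  expected <- 100 * 0.02 * mean_int * kev_per_g_to_gy^2 /
    (8 * pi * a^3 * (1e-12)^2 * (4 / 3 * pi * 5.5^3))
  expect_equal(delta_xi(events, exposure, a, cell), expected,
               tolerance = 1e-12)

  # all events missing the nucleus give exactly zero
  expect_equal(delta_xi(list(ev_miss, ev_single), exposure, a, cell), 0)

  # exact linearity in n (and p1Gy)
  e2 <- np_exposure(n = 200, p1Gy = 0.02)
  expect_equal(delta_xi(events, e2, a, cell),
               2 * delta_xi(events, exposure, a, cell))
  expect_error(delta_xi(list(), exposure, a, cell), "non-empty")
})

test_that("zeta and the dose enhancement ratio follow n * p1Gy * z_bar", {
  zd <- zeta_der(np_exposure(n = 6.06e8, p1Gy = 5.04e-8, z_bar_Gy = 8.2e-4))
  expect_equal(zd$der, 1.025, tolerance = 5e-4)
  zd <- zeta_der(np_exposure(n = 6000, p1Gy = 1.95e-2, z_bar_Gy = 2.6e-3))
  expect_equal(zd$der, 1.3042, tolerance = 1e-4)
  zd <- zeta_der(np_exposure(n = 6000, p1Gy = 1.95e-2, z_bar_Gy = 0))
  expect_equal(zd$zeta, 0)
  expect_equal(zd$der, 1)
  # z_bar derived from E_bar and the nucleus mass when absent
  cell <- cell_preset("Hela")
  via_E <- zeta_der(np_exposure(n = 10, p1Gy = 0.1,
                                E_bar_keV = cell$m_nucleus_g / kev_per_g_to_gy),
                    cell)
  expect_equal(via_E$zeta, 1, tolerance = 1e-12)
})

test_that("relative lesion yield has the xi' D + D^2 + zeta D^2 form", {
  q <- quality_params(3.659, delta_xi = 0.93, zeta = 0.234)
  expect_equal(relative_yield(0, q), 0)
  expect_equal(relative_yield(2, q), 4.589 * 2 + 4 + 0.234 * 4,
               tolerance = 1e-12)
  base <- quality_params(3.659)
  D <- c(0.5, 1, 2, 5)
  expect_equal(relative_yield(D, base), 3.659 * D + D^2)
})

test_that("closed-form RBE agrees with the equal-effect root oracle", {
  # collapse: no quality change, no cross term -> R = 1 at any dose
  base <- quality_params(3.659)
  expect_equal(rbe_tdra(base, c(0.1, 1, 2, 10)), rep(1, 4),
               tolerance = 1e-12)

  q <- quality_params(3.659, delta_xi = 0.93, zeta = 0.234)
  expect_equal(rbe_tdra(q, 2), 1.175, tolerance = 5e-4)

  for (xi in c(0.8, 2.33, 3.659)) {
    for (dxi in c(0, 0.5, 1.2)) {
      for (zeta in c(0, 0.3)) {
        for (D in c(0.5, 2, 8)) {
          qq <- quality_params(xi, dxi, zeta)
          expect_equal(rbe_tdra(qq, D), oracle_rbe_tdra(xi, xi + dxi, zeta, D),
                       tolerance = 1e-9)
        }
      }
    }
  }

  # R strictly increases in xi' and zeta at fixed xi, D
  r0 <- rbe_tdra(quality_params(3, 0.2, 0.1), 2)
  expect_gt(rbe_tdra(quality_params(3, 0.3, 0.1), 2), r0)
  expect_gt(rbe_tdra(quality_params(3, 0.2, 0.2), 2), r0)
  expect_error(rbe_tdra(q, 0), "dose")
})

test_that("relative alpha increase equals delta_xi / xi identically", {
  q <- quality_params(0.150 / 0.041, delta_xi = 0.93)
  expect_identical(dalpha_ratio(q), q$delta_xi / q$xi)
  expect_equal(dalpha_ratio(q), 0.254, tolerance = 1e-3)
  expect_equal(dalpha_ratio(quality_params(0.8, 0.027)), 0.034,
               tolerance = 1e-2)
  expect_equal(dalpha_ratio(quality_params(0.8, 0)), 0)
})

test_that("scaling all deposit energies by 10 scales xi by 10", {
  set.seed(302)
  tracks <- replicate(30, random_track(20, spread_um = 0.2),
                      simplify = FALSE)
  scaled <- lapply(tracks, function(m) {
    m[, "edep_keV"] <- 10 * m[, "edep_keV"]
    m
  })
  edges <- default_bin_edges(20)
  x1 <- xi_from_proximity(estimate_proximity(tracks, edges), 0.1)
  x10 <- xi_from_proximity(estimate_proximity(scaled, edges), 0.1)
  expect_equal(x10, 10 * x1, tolerance = 1e-12)
})

test_that("exposure constants check p1Gy against mu * lambda", {
  ex <- np_exposure(n = 6000, lambda = 47.7, mu = 4.09e-4)
  expect_equal(ex$p1Gy, 47.7 * 4.09e-4)
  # printed, rounded p1Gy is accepted alongside lambda and mu
  ex <- np_exposure(n = 6000, lambda = 47.7, mu = 4.09e-4, p1Gy = 1.95e-2)
  expect_equal(ex$p1Gy, 1.95e-2)
  expect_error(np_exposure(n = 1, lambda = 47.7, mu = 4.09e-4, p1Gy = 1e-2),
               "inconsistent")
  expect_error(np_exposure(n = 1), "p1Gy")
})
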