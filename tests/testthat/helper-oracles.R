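# Independent oracles used to check the package's estimators. These are
# deliberately naive (double loops, bisection) and share no code with the
# implementation.

# O(N^2) double-loop proximity estimator over ordered pairs
oracle_proximity <- function(tracks, edges) {
  nb <- length(edges) - 1L
  mass <- numeric(nb)
  out <- 0
  for (trk in tracks) {
    eps <- trk[, "edep_keV"]
    total <- sum(eps)
    n <- nrow(trk)
    if (n < 2L) next
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt(sum((trk[i, 1:3] - trk[j, 1:3])^2))
        placed <- FALSE
        for (k in seq_len(nb)) {
          hit <- d >= edges[k] &&
            (d < edges[k + 1L] || (k == nb && d == edges[k + 1L]))
          if (hit) {
            mass[k] <- mass[k] + eps[i] * eps[j] / total
            placed <- TRUE
            break
          }
        }
        if (!placed) out <- out + eps[i] * eps[j] / total
      }
    }
  }
  list(t = mass / diff(edges) / length(tracks),
       bin_mass = mass / length(tracks),
       out = out / length(tracks))
}

# random deposit cloud with positive energies
random_track <- function(n, spread_um = 0.5) {
  m <- cbind(matrix(stats::runif(3 * n, -spread_um, spread_um), ncol = 3),
             stats::rexp(n) + 0.01)
  colnames(m) <- c("x_um", "y_um", "z_um", "edep_keV")
  m
}

# equal-effect RBE for the dual-action yield, by numeric root finding
oracle_rbe_tdra <- function(xi, xi_prime, zeta, dose_np) {
  eff <- xi_prime * dose_np + dose_np^2 + zeta * dose_np^2
  root <- stats::uniroot(function(x) xi * x + x^2 - eff,
                         interval = c(1e-12, 1e6), tol = 1e-13)$root
  root / dose_np
}

# equal-effect RBE for two LQ parameter sets, by bisection
oracle_rbe_lq <- function(alpha, beta, alpha_np, beta_np, dose_np) {
  eff <- alpha_np * dose_np + beta_np * dose_np^2
  lo <- 0
  hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (alpha * mid + beta * mid^2 < eff) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / dose_np
}

# |computed - printed| within half a unit of the printed last digit;
# `printed` is given as a string so its precision is explicit
expect_matches_printed <- function(computed, printed) {
  s <- trimws(printed)
  exp10 <- 0
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]")[[1L]]
    exp10 <- as.numeric(parts[2L])
    s <- parts[1L]
  }
  dec <- if (grepl("\\.", s)) nchar(strsplit(s, "\\.")[[1L]][2L]) else 0L
  ulp <- 10^(exp10 - dec)
  expect_lt(abs(computed - as.numeric(printed)), ulp / 2 + 1e-12)
}
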