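#' Toy Auger-cascade model
#'
#' Parameters of the synthetic track generator that emulates the output of a
#' Monte Carlo track-structure code for a single ionization of a high-Z
#' nanoparticle: one (optional) fast photoelectron plus a Poisson-distributed
#' burst of low-energy Auger electrons, each transported as a straight toy
#' track with a power-law range and energy transfers that cluster toward the
#' track end. This is deliberately toy physics: the downstream analysis only
#' needs the spatial-statistical structure of the deposit cloud (short-range
#' clustering, a point mass at zero nucleus energy), not dosimetric accuracy.
#'
#' Electron energies are exponentially distributed around the given means.
#' The range-energy law is `R = range_coeff * E^range_exp` (R in um, E in
#' keV); with the defaults, Auger electrons below ~4.4 keV stay within
#' 0.5 um of the emission point, matching the scale over which most Auger
#' energy is deposited. Self-absorption of electrons inside the
#' nanoparticle is modelled as Bernoulli thinning.
#'
#' @param n_auger mean number of Auger electrons per ionization (Poisson).
#' @param auger_energy_keV mean Auger electron energy (exponential).
#' @param photoelectron_energy_keV mean photoelectron energy (exponential).
#' @param photoelectron_prob probability that the ionization emits a fast
#'   photoelectron.
#' @param range_coeff,range_exp range-energy law coefficients
#'   (um keV^-range_exp and dimensionless).
#' @param deposits_per_electron number of discrete energy transfers per
#'   electron track (>= 1).
#' @param self_absorption_prob probability that an emitted electron is
#'   absorbed inside the nanoparticle and contributes nothing.
#' @return An object of class `cascade_model` (a validated list).
#' @export
cascade_model <- function(n_auger = 5,
                          auger_energy_keV = 2,
                          photoelectron_energy_keV = 30,
                          photoelectron_prob = 0.8,
                          range_coeff = 0.04,
                          range_exp = 1.7,
                          deposits_per_electron = 10L,
                          self_absorption_prob = 0.1) {
  stopifnot(
    n_auger >= 0, auger_energy_keV > 0, photoelectron_energy_keV > 0,
    photoelectron_prob >= 0, photoelectron_prob <= 1,
    range_coeff > 0, range_exp > 0,
    deposits_per_electron >= 1,
    self_absorption_prob >= 0, self_absorption_prob <= 1
  )
  structure(
    list(
      n_auger = n_auger,
      auger_energy_keV = auger_energy_keV,
      photoelectron_energy_keV = photoelectron_energy_keV,
      photoelectron_prob = photoelectron_prob,
      range_coeff = range_coeff,
      range_exp = range_exp,
      deposits_per_electron = as.integer(deposits_per_electron),
      self_absorption_prob = self_absorption_prob
    ),
    class = "cascade_model"
  )
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf(
    paste0("<cascade_model> photoelectron %.3g keV (p=%.2f), ",
           "Auger Poisson(%.3g) x %.3g keV,\n  range %.3g*E^%.3g um, ",
           "%d deposits/electron, self-absorption %.2f\n"),
    x$photoelectron_energy_keV, x$photoelectron_prob, x$n_auger,
    x$auger_energy_keV, x$range_coeff, x$range_exp,
    x$deposits_per_electron, x$self_absorption_prob
  ))
  invisible(x)
}

# straight toy electron track from `origin` with total energy E_keV.
# Deposits sit at path fractions (k/m)^(1/2) of the full range, so spacing
# shrinks toward the track end: the ionization density rises where real
# electron tracks cluster. Equal energy shares keep conservation exact.
.electron_track <- function(E_keV, model, origin = c(0, 0, 0)) {
  m <- model$deposits_per_electron
  R <- model$range_coeff * E_keV^model$range_exp
  dir <- .random_directions(1L)
  s <- R * sqrt(seq_len(m) / m)
  pos <- cbind(origin[1L] + dir[1L] * s,
               origin[2L] + dir[2L] * s,
               origin[3L] + dir[3L] * s)
  out <- cbind(pos, rep(E_keV / m, m))
  colnames(out) <- c("x_um", "y_um", "z_um", "edep_keV")
  out
}

#' Generate the deposit cloud of one nanoparticle ionization
#'
#' Draws the secondary-electron content of a single ionization event from a
#' [cascade_model()] and returns all surviving energy transfers in the
#' NP-local frame (NP at the origin). Energy is conserved exactly: deposit
#' energies sum to the total energy of the surviving electrons.
#'
#' @param model a [cascade_model()].
#' @return Deposit matrix (possibly 0 rows) with columns `x_um`, `y_um`,
#'   `z_um`, `edep_keV`.
#' @export
generate_cascade_event <- function(model) {
  stopifnot(inherits(model, "cascade_model"))
  energies <- numeric(0)
  if (stats::runif(1) < model$photoelectron_prob)
    energies <- stats::rexp(1L, rate = 1 / model$photoelectron_energy_keV)
  n_a <- stats::rpois(1L, model$n_auger)
  if (n_a > 0L)
    energies <- c(energies,
                  stats::rexp(n_a, rate = 1 / model$auger_energy_keV))
  if (length(energies) > 0L && model$self_absorption_prob > 0) {
    keep <- stats::runif(length(energies)) >= model$self_absorption_prob
    energies <- energies[keep]
  }
  if (length(energies) == 0L) return(empty_deposits())
  do.call(rbind, lapply(energies, .electron_track, model = model))
}

#' Generate a toy secondary-electron track in water
#'
#' Single straight toy track of a monoenergetic electron, used to build the
#' reference proximity function of the water secondary-electron population
#' (combined over an energy-weighted spectrum with
#' [weighted_proximity()]).
#'
#' @param E0_keV initial electron energy (> 0).
#' @param model a [cascade_model()] supplying the range law and the number
#'   of transfers per electron.
#' @return Deposit matrix whose energies sum exactly to `E0_keV`.
#' @export
generate_water_track <- function(E0_keV, model = cascade_model()) {
  stopifnot(inherits(model, "cascade_model"), E0_keV > 0)
  .electron_track(E0_keV, model)
}

#' Per-event nucleus energy spectrum
#'
#' Aggregates per-event energies imparted to the nucleus, including the
#' events that miss it entirely (the point mass at E = 0), into the summary
#' the TDRA cross-term needs: the zero fraction, the mean energy per
#' ionization and the mean specific energy.
#'
#' @param E_keV numeric vector of per-event nucleus energies (>= 0), zeros
#'   included.
#' @param cell a [cell_model()] providing the nucleus mass.
#' @return Object of class `energy_spectrum`: `E_keV`, `zero_fraction`,
#'   `E_bar_keV` (mean including zeros) and `z_bar_Gy` (= E_bar / m_nucleus).
#' @export
energy_spectrum <- function(E_keV, cell) {
  stopifnot(inherits(cell, "cell_model"), length(E_keV) >= 1L,
            all(E_keV >= 0))
  E_bar <- mean(E_keV)
  structure(
    list(
      E_keV = E_keV,
      zero_fraction = mean(E_keV == 0),
      E_bar_keV = E_bar,
      z_bar_Gy = E_bar * .GY_PER_KEV_PER_G / cell$m_nucleus_g
    ),
    class = "energy_spectrum"
  )
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf(
    "<energy_spectrum> %d events, zero fraction %.3f, E_bar %.4g keV, z_bar %.4g Gy\n",
    length(x$E_keV), x$zero_fraction, x$E_bar_keV, x$z_bar_Gy
  ))
  invisible(x)
}

#' Simulate nanoparticle ionization events for one placement scenario
#'
#' Runs the synthetic exposure: for each event an NP position is drawn
#' according to the scenario, an Auger-cascade deposit cloud is generated in
#' the NP frame, deposits are translated into the nucleus frame and scored
#' ([deposits_in_nucleus()]), and the nucleus energy E and specific energy
#' z = E / m_nucleus are recorded. Events whose electrons all miss the
#' nucleus contribute E = 0 and stay in the spectrum.
#'
#' @param scenario placement scenario, see [sample_np_positions()].
#' @param cell a [cell_model()].
#' @param n_events number of ionization events (>= 1).
#' @param model a [cascade_model()].
#' @param seed optional integer seed; with a fixed seed the full event list
#'   is reproducible.
#' @param np_radius_um NP radius for the membrane scenario.
#' @return Object of class `np_simulation`: `events` (list; each event has
#'   `event_id`, `np_position`, `deposits`, `nucleus_deposits`, `E_keV`,
#'   `z_Gy`), `spectrum` (an [energy_spectrum()]), plus `scenario`, `seed`,
#'   `model` and `cell`.
#' @export
simulate_exposure <- function(scenario, cell, n_events,
                              model = cascade_model(), seed = NULL,
                              np_radius_um = 0) {
  stopifnot(inherits(cell, "cell_model"), inherits(model, "cascade_model"))
  if (!(is.numeric(n_events) && length(n_events) == 1L && n_events >= 1))
    stop("n_events must be >= 1")
  n_events <- as.integer(n_events)
  if (!is.null(seed)) set.seed(seed)
  placement <- sample_np_positions(scenario, cell, n_events,
                                   np_radius_um = np_radius_um)
  k <- .GY_PER_KEV_PER_G / cell$m_nucleus_g
  events <- vector("list", n_events)
  E <- numeric(n_events)
  for (i in seq_len(n_events)) {
    pos <- placement$positions[i, ]
    dep <- generate_cascade_event(model)
    nuc <- deposits_in_nucleus(dep, pos, cell)
    Ei <- sum(nuc[, "edep_keV"])
    E[i] <- Ei
    events[[i]] <- structure(
      list(event_id = i, np_position = pos, deposits = dep,
           nucleus_deposits = nuc, E_keV = Ei, z_Gy = Ei * k),
      class = "np_event"
    )
  }
  structure(
    list(events = events, spectrum = energy_spectrum(E, cell),
         scenario = scenario, seed = seed, model = model, cell = cell),
    class = "np_simulation"
  )
}

#' @export
print.np_simulation <- function(x, ...) {
  cat(sprintf("<np_simulation> %s, %d events, seed %s\n",
              x$scenario, length(x$events),
              if (is.null(x$seed)) "none" else x$seed))
  print(x$spectrum)
  invisible(x)
}
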