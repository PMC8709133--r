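#' Default log-spaced distance bins
#'
#' Pair distances in track structure span nanometres (within one Auger
#' track) to millimetres (inter-track, dose term), so the default binning
#' is logarithmic from 1e-4 to 1e3 um.
#'
#' @param n_per_decade bins per decade (default 10).
#' @return Numeric vector of strictly increasing bin edges in um.
#' @export
default_bin_edges <- function(n_per_decade = 10) {
  10^seq(-4, 3, by = 1 / n_per_decade)
}

.validate_bin_edges <- function(bin_edges) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2L,
            all(is.finite(bin_edges)), all(diff(bin_edges) > 0),
            bin_edges[1L] >= 0)
  bin_edges
}

# bin representative used wherever t(x) is evaluated at a point: geometric
# mean of the edges (natural for log bins); arithmetic midpoint if the
# lower edge is 0.
.bin_centers <- function(bin_edges) {
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1L]
  ifelse(lo > 0, sqrt(lo * hi), hi / 2)
}

.new_proximity_curve <- function(bin_edges, bin_mass_keV, pair_counts,
                                 n_tracks, out_of_range_mass_keV) {
  widths <- diff(bin_edges)
  structure(
    list(
      bin_edges = bin_edges,
      t_keV_per_um = bin_mass_keV / widths,
      bin_mass_keV = bin_mass_keV,
      pair_counts = pair_counts,
      n_tracks = n_tracks,
      out_of_range_mass_keV = out_of_range_mass_keV
    ),
    class = "proximity_curve"
  )
}

#' Estimate the proximity function t(x) from tracks
#'
#' The proximity function `t(x) dx` is the expected energy-weighted sum over
#' pairs of energy transfers of one track at mutual distance in
#' `[x, x + dx)`: for each track with transfers of energy `e_i` at positions
#' `p_i` and total `T = sum(e_i)`, every ordered pair `i != j` contributes
#' `e_i * e_j / T` to the bin containing `|p_i - p_j|`. Bin masses are
#' averaged over tracks (per-track expectation) and divided by the bin width
#' to give `t` in keV/um. The double sum counts both orderings of a pair, so
#' the total mass carried by one track is exactly `T - sum(e_i^2) / T`.
#'
#' Pair distances that fall outside the binned range are accumulated in
#' `out_of_range_mass_keV` (and reported by `print`), never dropped, so the
#' per-track mass identity holds exactly:
#' `sum(bin_mass) + out_of_range = mean(T - sum(e^2)/T)`.
#'
#' @param tracks a single deposit matrix/data frame or a list of them (one
#'   element per track/event); columns `x_um`, `y_um`, `z_um`, `edep_keV`.
#'   Every track must contain at least one deposit; single-deposit tracks
#'   contribute zero mass.
#' @param bin_edges strictly increasing distance bin edges in um.
#' @return Object of class `proximity_curve` with `bin_edges`,
#'   `t_keV_per_um`, per-track-average `bin_mass_keV`, `pair_counts`,
#'   `n_tracks` and `out_of_range_mass_keV`.
#' @examples
#' trk <- cbind(x_um = c(0, 0.005), y_um = 0, z_um = 0, edep_keV = 1)
#' pc <- estimate_proximity(trk, bin_edges = c(0.004, 0.006))
#' pc$t_keV_per_um  # 1 keV of pair mass over a 0.002 um bin
#' @export
estimate_proximity <- function(tracks, bin_edges = default_bin_edges()) {
  bin_edges <- .validate_bin_edges(bin_edges)
  if (!is.list(tracks) || is.data.frame(tracks)) tracks <- list(tracks)
  if (length(tracks) == 0L) stop("need at least one track")
  nbins <- length(bin_edges) - 1L
  bin_mass <- numeric(nbins)
  pair_counts <- numeric(nbins)
  out_mass <- 0
  for (trk in tracks) {
    m <- as_deposit_matrix(trk)
    if (nrow(m) == 0L) stop("every track must have at least one deposit")
    if (nrow(m) == 1L) next
    eps <- m[, "edep_keV"]
    T <- sum(eps)
    d <- stats::dist(m[, 1:3, drop = FALSE])
    lt <- lower.tri(matrix(0, nrow(m), nrow(m)))
    w <- 2 * tcrossprod(eps)[lt] / T  # both orderings of each pair
    dv <- as.vector(d)
    idx <- findInterval(dv, bin_edges, rightmost.closed = TRUE)
    inside <- idx >= 1L & idx <= nbins
    if (any(inside)) {
      add <- rowsum(w[inside], idx[inside])
      at <- as.integer(rownames(add))
      bin_mass[at] <- bin_mass[at] + add[, 1L]
      cnt <- rowsum(rep(2, sum(inside)), idx[inside])
      pair_counts[at] <- pair_counts[at] + cnt[, 1L]
    }
    if (any(!inside)) out_mass <- out_mass + sum(w[!inside])
  }
  n_tracks <- length(tracks)
  .new_proximity_curve(bin_edges, bin_mass / n_tracks, pair_counts,
                       n_tracks, out_mass / n_tracks)
}

#' @export
print.proximity_curve <- function(x, ...) {
  cat(sprintf(
    "<proximity_curve> %d bins on [%.3g, %.3g] um, %d track(s)\n",
    length(x$bin_edges) - 1L, x$bin_edges[1L],
    x$bin_edges[length(x$bin_edges)], x$n_tracks
  ))
  cat(sprintf("  in-range mass %.4g keV/track, out-of-range %.4g keV/track\n",
              sum(x$bin_mass_keV), x$out_of_range_mass_keV))
  invisible(x)
}

#' Combine proximity curves with spectrum weights
#'
#' Bin-wise convex combination of proximity curves, used to build the
#' reference t(x) of a polyenergetic electron population from monoenergetic
#' curves: weights should be energy-fluence weights, `w_k` proportional to
#' `E_k * f_k` for spectrum fractions `f_k`. Weights are normalized
#' internally.
#'
#' @param curves list of `proximity_curve` objects on identical bin edges.
#' @param weights non-negative numeric vector, one per curve, not all zero.
#' @return A `proximity_curve`; `n_tracks` is the summed track count.
#' @export
weighted_proximity <- function(curves, weights) {
  stopifnot(is.list(curves), length(curves) >= 1L,
            length(weights) == length(curves), all(weights >= 0),
            sum(weights) > 0)
  lapply(curves, function(x) stopifnot(inherits(x, "proximity_curve")))
  edges <- curves[[1L]]$bin_edges
  for (cv in curves[-1L])
    if (!isTRUE(all.equal(cv$bin_edges, edges)))
      stop("all curves must share identical bin_edges")
  w <- weights / sum(weights)
  comb <- function(field)
    Reduce(`+`, Map(function(cv, wi) wi * cv[[field]], curves, w))
  .new_proximity_curve(
    edges,
    comb("bin_mass_keV"),
    comb("pair_counts"),
    sum(vapply(curves, `[[`, numeric(1), "n_tracks")),
    comb("out_of_range_mass_keV")
  )
}

#' Add the inter-track dose term to a proximity curve
#'
#' The dose-dependent proximity function is `t_D(x) = t(x) + 4 pi x^2 rho D`:
#' uncorrelated energy transfers from other primary particles contribute the
#' expected energy in a shell of radius x at uniform energy density
#' `rho * D`. The term is evaluated at each bin representative (geometric
#' mean of the edges) with `rho * D` converted to keV/um^3.
#'
#' @param curve a `proximity_curve`.
#' @param density_g_cm3 medium density (g/cm^3).
#' @param dose_Gy absorbed dose (Gy, >= 0).
#' @return A `proximity_curve` holding t_D. Additive in dose:
#'   adding D1 then D2 equals adding D1 + D2.
#' @export
add_dose_term <- function(curve, density_g_cm3 = 1.0, dose_Gy) {
  stopifnot(inherits(curve, "proximity_curve"), dose_Gy >= 0,
            density_g_cm3 > 0)
  xbar <- .bin_centers(curve$bin_edges)
  term <- 4 * pi * xbar^2 * density_g_cm3 * dose_Gy * .KEV_PER_UM3_PER_GY
  out <- curve
  out$t_keV_per_um <- curve$t_keV_per_um + term
  out$bin_mass_keV <- curve$bin_mass_keV + term * diff(curve$bin_edges)
  out
}

#' Exponentially weighted pair sum of one event
#'
#' The nanoparticle term of the TDRA quality increase needs, per ionization
#' event, the quantity `E * integral(t_ev(x) e^(-x/a) dx)` where `t_ev` is
#' the proximity function of the event's in-nucleus deposits (normalized by
#' the in-nucleus energy E). It is computed pairwise exactly, with no
#' binning, as `E * sum_{i != j} e_i e_j exp(-d_ij / a) / T` with `T = E`,
#' so the downstream quality increase carries no discretization error.
#' Events with fewer than two nucleus deposits contribute 0.
#'
#' @param event an event from [simulate_exposure()] (uses its
#'   `nucleus_deposits` and `E_keV`), or a deposit matrix/data frame that is
#'   taken to be the nucleus deposits.
#' @param a_um distance-model decay length (um, > 0).
#' @return Scalar in keV^2.
#' @export
event_proximity_integral <- function(event, a_um) {
  stopifnot(a_um > 0)
  m <- if (inherits(event, "np_event"))
    as_deposit_matrix(event$nucleus_deposits)
  else as_deposit_matrix(event)
  if (nrow(m) < 2L) return(0)
  eps <- m[, "edep_keV"]
  T <- sum(eps)
  lt <- lower.tri(matrix(0, nrow(m), nrow(m)))
  w <- 2 * tcrossprod(eps)[lt]
  d <- as.vector(stats::dist(m[, 1:3, drop = FALSE]))
  # E * (pair sum / T) with E = T, so T cancels
  sum(w * exp(-d / a_um))
}

#' Write / read a proximity curve as CSV
#'
#' Plain-text exchange format: one row per bin with columns `x_lo_um`,
#' `x_hi_um`, `t_keV_per_um`, `n_pairs`; track count and out-of-range mass
#' are kept in `#`-prefixed header comments so a round trip restores the
#' curve exactly.
#'
#' @param curve a `proximity_curve`.
#' @param path file path.
#' @return `write_proximity_csv` returns `path` invisibly;
#'   `read_proximity_csv` returns a `proximity_curve`.
#' @export
write_proximity_csv <- function(curve, path) {
  stopifnot(inherits(curve, "proximity_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# n_tracks=%.17g", curve$n_tracks),
    sprintf("# out_of_range_mass_keV=%.17g", curve$out_of_range_mass_keV)
  ), con)
  df <- data.frame(
    x_lo_um = curve$bin_edges[-length(curve$bin_edges)],
    x_hi_um = curve$bin_edges[-1L],
    t_keV_per_um = curve$t_keV_per_um,
    n_pairs = curve$pair_counts
  )
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proximity_csv
#' @export
read_proximity_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- function(key) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, "="), "", line))
  }
  df <- utils::read.csv(path, comment.char = "#")
  edges <- c(df$x_lo_um, df$x_hi_um[nrow(df)])
  .new_proximity_curve(edges, df$t_keV_per_um * diff(edges), df$n_pairs,
                       meta("n_tracks"), meta("out_of_range_mass_keV"))
}

#' Plot a proximity curve
#'
#' Log-log plot of t(x) against the bin representatives; empty bins are
#' omitted.
#'
#' @param x a `proximity_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.proximity_curve <- function(x, ...) {
  xb <- .bin_centers(x$bin_edges)
  keep <- x$t_keV_per_um > 0
  graphics::plot(xb[keep], x$t_keV_per_um[keep], log = "xy", type = "l",
                 xlab = "x (um)", ylab = "t(x) (keV/um)", ...)
  invisible(x)
}
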