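#' Spherical cell and nucleus model
#'
#' Builds the concentric-sphere cell model used throughout the package: a
#' spherical cell of radius `r_cell_um` containing a concentric spherical
#' nucleus of radius `r_nucleus_um`, filled with a medium of density
#' `density_g_cm3` (water by default). The nucleus is the sensitive target:
#' its volume and mass convert energy imparted (keV) into specific energy
#' (Gy). `eta`, the ratio of effective DNA volume to nucleus volume, is
#' carried for completeness; every quantity exported by the package is a
#' ratio in which it cancels, so it is never needed numerically.
#'
#' @param r_cell_um cell radius in micrometres.
#' @param r_nucleus_um nucleus radius in micrometres; must be smaller than
#'   the cell radius.
#' @param density_g_cm3 mass density of the medium in g/cm^3 (default 1,
#'   liquid water).
#' @param eta effective DNA volume fraction of the nucleus, in (0, 1].
#' @return An object of class `cell_model` with fields `r_cell_um`,
#'   `r_nucleus_um`, `density_g_cm3`, `eta`, and the derived
#'   `v_nucleus_um3` (um^3) and `m_nucleus_g` (g).
#' @seealso [cell_preset()] for the packaged cell lines,
#'   [sample_np_positions()], [deposits_in_nucleus()].
#' @examples
#' hela <- cell_model(8.6, 5.5)
#' hela$m_nucleus_g
#' @export
cell_model <- function(r_cell_um, r_nucleus_um, density_g_cm3 = 1.0,
                       eta = 1.0) {
  stopifnot(
    is.numeric(r_cell_um), length(r_cell_um) == 1L, is.finite(r_cell_um),
    is.numeric(r_nucleus_um), length(r_nucleus_um) == 1L,
    is.finite(r_nucleus_um)
  )
  if (!(r_nucleus_um > 0 && r_nucleus_um < r_cell_um))
    stop("need 0 < r_nucleus_um < r_cell_um")
  if (!(density_g_cm3 > 0)) stop("density_g_cm3 must be positive")
  if (!(eta > 0 && eta <= 1)) stop("eta must be in (0, 1]")
  v <- 4 / 3 * pi * r_nucleus_um^3
  structure(
    list(
      r_cell_um = r_cell_um,
      r_nucleus_um = r_nucleus_um,
      density_g_cm3 = density_g_cm3,
      eta = eta,
      v_nucleus_um3 = v,
      m_nucleus_g = density_g_cm3 * .G_PER_UM3 * v
    ),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> r_cell %.2f um, r_nucleus %.2f um, rho %.3g g/cm^3, eta %.3g\n",
    x$r_cell_um, x$r_nucleus_um, x$density_g_cm3, x$eta
  ))
  cat(sprintf("  nucleus: V = %.4g um^3, m = %.4g g\n",
              x$v_nucleus_um3, x$m_nucleus_g))
  invisible(x)
}

.np_scenarios <- c("whole_cell", "cytoplasm", "nuclear_membrane")

# isotropic unit vectors, n x 3
.random_directions <- function(n) {
  cz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(pmax(0, 1 - cz^2))
  cbind(sz * cos(phi), sz * sin(phi), cz)
}

#' Sample nanoparticle positions for a placement scenario
#'
#' Draws nanoparticle centre positions for one of the three intracellular
#' distribution scenarios: uniform in the whole cell volume, uniform in the
#' cytoplasm (the shell between nucleus and cell membrane), or uniform on
#' the nuclear membrane. Membrane placement puts NP centres at
#' `r_nucleus + np_radius`, i.e. NPs touching the membrane from outside.
#' Volume scenarios use inverse-CDF sampling of the radial coordinate, so
#' no rejection step is needed.
#'
#' @param scenario one of `"whole_cell"`, `"cytoplasm"`,
#'   `"nuclear_membrane"`.
#' @param cell a [cell_model()].
#' @param count number of positions to draw (>= 1).
#' @param np_radius_um nanoparticle radius in micrometres; only used by the
#'   membrane scenario (default 0, point NPs).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the draw is reproducible.
#' @return An object of class `np_placement`: a list with `scenario`,
#'   `np_radius_um` and `positions`, a `count` x 3 matrix of coordinates in
#'   micrometres relative to the cell centre (which is also the nucleus
#'   centre).
#' @examples
#' pl <- sample_np_positions("cytoplasm", cell_preset("Hela"), 100, seed = 1)
#' range(sqrt(rowSums(pl$positions^2)))
#' @export
sample_np_positions <- function(scenario, cell, count, np_radius_um = 0,
                                seed = NULL) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% .np_scenarios)
    stop("unknown scenario: must be one of ",
         paste(.np_scenarios, collapse = ", "))
  stopifnot(inherits(cell, "cell_model"))
  if (!(is.numeric(count) && length(count) == 1L && count >= 1))
    stop("count must be >= 1")
  count <- as.integer(count)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(count)
  r <- switch(scenario,
    whole_cell = cell$r_cell_um * u^(1 / 3),
    cytoplasm = (cell$r_nucleus_um^3 +
                   u * (cell$r_cell_um^3 - cell$r_nucleus_um^3))^(1 / 3),
    nuclear_membrane = rep(cell$r_nucleus_um + np_radius_um, count)
  )
  pos <- .random_directions(count) * r
  colnames(pos) <- c("x_um", "y_um", "z_um")
  structure(
    list(scenario = scenario, np_radius_um = np_radius_um, positions = pos),
    class = "np_placement"
  )
}

#' @export
print.np_placement <- function(x, ...) {
  cat(sprintf("<np_placement> %s, %d positions, np_radius %.4g um\n",
              x$scenario, nrow(x$positions), x$np_radius_um))
  invisible(x)
}

#' Score energy deposits inside the nucleus
#'
#' Deposits are generated in the nanoparticle-local frame (the NP at the
#' origin). Given the NP position relative to the nucleus centre, this
#' translates each deposit into the nucleus frame and keeps exactly those
#' within the nucleus radius. Positions are translated, never rotated, and
#' deposit energies and ordering are untouched, so the operation is
#' idempotent and order-preserving.
#'
#' @param deposits numeric matrix with columns `x_um`, `y_um`, `z_um`,
#'   `edep_keV` (NP-local coordinates), or a data frame with those columns.
#'   Zero rows are allowed.
#' @param np_position length-3 numeric, NP centre relative to the nucleus
#'   centre (um).
#' @param cell a [cell_model()].
#' @return The subset of rows whose translated position satisfies
#'   `|d + np_position| <= r_nucleus`, same type as the input. The returned
#'   coordinates stay NP-local.
#' @export
deposits_in_nucleus <- function(deposits, np_position, cell) {
  stopifnot(inherits(cell, "cell_model"), length(np_position) == 3L)
  m <- as_deposit_matrix(deposits)
  if (nrow(m) == 0L) return(deposits[0, , drop = FALSE])
  d2 <- (m[, 1L] + np_position[1L])^2 +
    (m[, 2L] + np_position[2L])^2 +
    (m[, 3L] + np_position[3L])^2
  keep <- d2 <= cell$r_nucleus_um^2
  deposits[keep, , drop = FALSE]
}

# coerce a deposits object (matrix or data frame with the canonical
# columns) into the internal n x 4 numeric matrix
as_deposit_matrix <- function(deposits) {
  cols <- c("x_um", "y_um", "z_um", "edep_keV")
  if (is.matrix(deposits)) {
    if (!is.null(colnames(deposits)) && all(cols %in% colnames(deposits)))
      return(deposits[, cols, drop = FALSE])
    if (ncol(deposits) == 4L) {
      colnames(deposits) <- cols
      return(deposits)
    }
    stop("deposit matrix must have 4 columns (x_um, y_um, z_um, edep_keV)")
  }
  if (is.data.frame(deposits)) {
    if (!all(cols %in% names(deposits)))
      stop("deposit data frame must have columns ",
           paste(cols, collapse = ", "))
    return(as.matrix(deposits[cols]))
  }
  stop("deposits must be a matrix or data frame")
}

# empty canonical deposit matrix
empty_deposits <- function() {
  m <- matrix(numeric(0), ncol = 4L)
  colnames(m) <- c("x_um", "y_um", "z_um", "edep_keV")
  m
}

#' Packaged cell-line presets
#'
#' Loads one of the packaged spherical cell models: `SQ20B` (cell radius
#' 10.6 um, nucleus 8.1 um), `Hela` (8.6 / 5.5 um) or `A549` (7.4 / 4.8 um,
#' radii derived from typical cell and nucleus volumes). Radii are stored in
#' `extdata/cell_presets.json`.
#'
#' @param name preset name.
#' @param density_g_cm3,eta passed to [cell_model()].
#' @return A [cell_model()].
#' @export
cell_preset <- function(name, density_g_cm3 = 1.0, eta = 1.0) {
  path <- system.file("extdata", "cell_presets.json",
                      package = "npmicrodose", mustWork = TRUE)
  presets <- jsonlite::fromJSON(path)
  if (!name %in% names(presets))
    stop("unknown cell preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  cell_model(p$r_cell_um, p$r_nucleus_um, density_g_cm3, eta)
}

#' Packaged nanoparticle presets
#'
#' Loads one of the packaged nanoparticle descriptions: `AGuIX`
#' (gadolinium-based, 3.0 nm diameter, density 1.2 g/cm^3) or `AuNP`
#' (gold, 50 nm diameter, 19.32 g/cm^3), both modelled as uniform spheres.
#'
#' @param name preset name.
#' @return A list with `name`, `diameter_nm`, `radius_um`, `density_g_cm3`.
#' @export
np_preset <- function(name) {
  path <- system.file("extdata", "np_presets.json",
                      package = "npmicrodose", mustWork = TRUE)
  presets <- jsonlite::fromJSON(path)
  if (!name %in% names(presets))
    stop("unknown NP preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  list(
    name = name,
    diameter_nm = p$diameter_nm,
    radius_um = p$diameter_nm / 2 * 1e-3,
    density_g_cm3 = p$density_g_cm3
  )
}
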