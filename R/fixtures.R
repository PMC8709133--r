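.extdata <- function(file) {
  system.file("extdata", file, package = "npmicrodose", mustWork = TRUE)
}

#' Packaged nanoparticle ionization constants
#'
#' Monte-Carlo-derived transport constants per nanoparticle type and beam:
#' `lambda` (photons entering one NP per Gy to the surrounding water), `mu`
#' (ionizations per entering photon) and `p1Gy = mu * lambda` (ionizations
#' per Gy per NP), with standard uncertainties. These are consumed as
#' constants; computing them requires a photon/electron transport code and
#' is outside this package's scope.
#'
#' @param np optional NP name filter (`"AGuIX"`, `"AuNP"`).
#' @param beam optional beam label filter (`"105kVp"`, `"220kVp"`,
#'   `"250kVp"`, `"Cs137"`, `"6MV"`).
#' @return Data frame; one row per NP/beam combination.
#' @export
ionization_params <- function(np = NULL, beam = NULL) {
  df <- utils::read.csv(.extdata("ionization_params.csv"),
                        stringsAsFactors = FALSE)
  if (!is.null(np)) df <- df[df$np == np, , drop = FALSE]
  if (!is.null(beam)) df <- df[df$beam == beam, , drop = FALSE]
  if (nrow(df) == 0L) stop("no ionization constants for np=", np,
                           ", beam=", beam)
  df
}

#' Packaged cell-irradiation experiments for the bomb model
#'
#' Published linear-quadratic fits with and without nanoparticles for the
#' packaged irradiation conditions (Hela + 50 nm AuNP at four photon
#' energies; SQ20B + AGuIX at 250 kVp; A549 + AGuIX with and without pHLIP
#' conjugation), together with the NP count per cell and, for comparison,
#' the published per-ionization kill probabilities, survival fractions at
#' 2 Gy and RBE values.
#'
#' @param id optional fixture id (e.g. `"Hela_AuNP_220kVp"`).
#' @return Data frame (all rows, or the single requested row).
#' @export
bomb_experiments <- function(id = NULL) {
  df <- utils::read.csv(.extdata("bomb_experiments.csv"),
                        stringsAsFactors = FALSE)
  if (is.null(id)) return(df)
  row <- df[df$id == id, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("unknown fixture id '", id, "'; available: ",
         paste(df$id, collapse = ", "))
  row
}

#' Packaged nucleus specific-energy summaries
#'
#' Mean specific energy to the nucleus per nanoparticle ionization
#' (`zbar_Gy`, from the Monte-Carlo nucleus energy spectra) for each
#' NP/scenario combination, with the published quality-parameter increases
#' (`dxi_lo`/`dxi_hi`, the two experimental-xi limits), relative alpha
#' increases and dose enhancement ratios at the reported and hypothetical
#' NP concentrations.
#'
#' @return Data frame keyed by `np`, `scenario` and `n_per_cell`.
#' @export
nucleus_energy_table <- function() {
  utils::read.csv(.extdata("nucleus_energy.csv"), stringsAsFactors = FALSE)
}

#' Published LQ-coefficient changes with nanoparticles
#'
#' Survey of published linear-quadratic fits (alpha, beta) with and without
#' metallic nanoparticles across cell lines, NP types and beams, packaged
#' for context and for the negative-alpha edge case (Cal33).
#'
#' @return Data frame.
#' @export
lq_literature <- function() {
  utils::read.csv(.extdata("lq_literature.csv"), stringsAsFactors = FALSE)
}

#' Experimental quality-parameter limits per cell line
#'
#' The quality parameter xi = alpha/beta derived from published survival
#' fits. For SQ20B the published fits disagree, so a two-point sensitivity
#' set spanning the literature range (0.8 to 2.33 Gy) is returned; for Hela
#' (220 kVp) the single alpha/beta value from the packaged fit.
#'
#' @param cell_line `"SQ20B"` or `"Hela"`.
#' @return Numeric vector of xi values in Gy (length 1 or 2).
#' @export
xi_limits <- function(cell_line) {
  switch(cell_line,
    SQ20B = c(0.8, 2.33),
    Hela = {
      row <- bomb_experiments("Hela_AuNP_220kVp")
      xi_from_lq(row$alpha, row$beta)
    },
    stop("no packaged xi limits for cell line '", cell_line, "'")
  )
}
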