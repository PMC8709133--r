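#' Linear-quadratic survival parameters
#'
#' @param alpha linear coefficient (Gy^-1). Negative values occur in some
#'   published fits and may be stored, but the RBE operations refuse them.
#' @param beta quadratic coefficient (Gy^-2, > 0).
#' @param sigma_alpha optional standard uncertainty of `alpha`.
#' @return Object of class `lq_params`.
#' @export
lq_params <- function(alpha, beta, sigma_alpha = NA_real_) {
  stopifnot(is.numeric(alpha), is.numeric(beta), beta > 0)
  structure(list(alpha = alpha, beta = beta, sigma_alpha = sigma_alpha),
            class = "lq_params")
}

#' @export
print.lq_params <- function(x, ...) {
  cat(sprintf("<lq_params> alpha %.4g Gy^-1, beta %.4g Gy^-2\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Bomb-model parameters
#'
#' The bomb model treats every nanoparticle ionization as an independent
#' lethal trigger: an ionization in one of the `N1` NPs outside the nucleus
#' kills the cell with probability `p1`, in one of the `N2` NPs inside with
#' probability `p2`. With `p1Gy` ionizations per Gy per NP this yields a
#' pure increase of the linear LQ coefficient,
#' `delta_alpha = p1Gy * (N1 p1 + N2 p2)`.
#'
#' An inferred `p1` larger than 1 is physically inadmissible but is stored
#' as-is with `p1_valid = FALSE` (see [infer_p1()]): it signals that the
#' measured sensitization cannot be carried by single lethal ionizations.
#'
#' @param p1Gy ionizations per Gy per NP (> 0).
#' @param N1,N2 NP counts outside / inside the nucleus (>= 0).
#' @param p1,p2 kill probabilities per ionization (>= 0).
#' @return Object of class `bomb_params` with a `p1_valid` flag
#'   (`p1 <= 1`).
#' @export
bomb_params <- function(p1Gy, N1, p1 = 0, N2 = 0, p2 = 0) {
  stopifnot(p1Gy > 0, N1 >= 0, N2 >= 0, p1 >= 0, p2 >= 0, p2 <= 1)
  structure(
    list(p1Gy = p1Gy, N1 = N1, N2 = N2, p1 = p1, p2 = p2,
         p1_valid = p1 <= 1),
    class = "bomb_params"
  )
}

#' @export
print.bomb_params <- function(x, ...) {
  cat(sprintf(
    "<bomb_params> p1Gy %.4g /Gy/NP, N1 %.4g (p1 %.4g%s), N2 %.4g (p2 %.4g)\n",
    x$p1Gy, x$N1, x$p1, if (x$p1_valid) "" else ", INVALID > 1", x$N2, x$p2
  ))
  invisible(x)
}

#' Increase in alpha under the bomb model
#'
#' `delta_alpha = p1Gy * (N1 * p1 + N2 * p2)`, exactly linear in each
#' argument.
#'
#' @param b a [bomb_params()].
#' @return `delta_alpha` in Gy^-1.
#' @export
delta_alpha_bomb <- function(b) {
  stopifnot(inherits(b, "bomb_params"))
  b$p1Gy * (b$N1 * b$p1 + b$N2 * b$p2)
}

#' Infer the per-ionization kill probability
#'
#' Inverts the bomb model for the extranuclear kill probability assuming no
#' NPs inside the nucleus: `p1 = delta_alpha / (p1Gy * N1)`. First-order
#' uncertainty propagation combines the uncertainty of `delta_alpha`
#' (typically the quadrature sum of the two alpha uncertainties) with the
#' relative uncertainty of `p1Gy` in quadrature.
#'
#' @param delta_alpha measured increase in alpha (Gy^-1). A negative value
#'   (nanoparticles made cells less sensitive) is outside the model's
#'   scope: `p1 = 0` is returned with a warning.
#' @param p1Gy ionizations per Gy per NP (> 0).
#' @param N1 NPs per cell outside the nucleus (> 0).
#' @param sigma_delta_alpha optional standard uncertainty of `delta_alpha`.
#' @param rel_sigma_p1Gy optional relative standard uncertainty of `p1Gy`.
#' @return List with `p1`, `sigma_p1` (NA when no uncertainty was given)
#'   and `p1_valid` (`p1 <= 1`).
#' @examples
#' infer_p1(0.352 - 0.150, p1Gy = 1.95e-2, N1 = 6000)  # ~1.73e-3
#' @export
infer_p1 <- function(delta_alpha, p1Gy, N1, sigma_delta_alpha = NULL,
                     rel_sigma_p1Gy = 0) {
  stopifnot(p1Gy > 0, N1 > 0, rel_sigma_p1Gy >= 0)
  if (delta_alpha < 0) {
    warning("delta_alpha < 0: nanoparticles reduced sensitivity, ",
            "outside the bomb model's scope; returning p1 = 0")
    return(list(p1 = 0, sigma_p1 = NA_real_, p1_valid = TRUE))
  }
  p1 <- delta_alpha / (p1Gy * N1)
  sigma <- NA_real_
  if (!is.null(sigma_delta_alpha) && delta_alpha > 0)
    sigma <- p1 * sqrt((sigma_delta_alpha / delta_alpha)^2 +
                         rel_sigma_p1Gy^2)
  list(p1 = p1, sigma_p1 = sigma, p1_valid = p1 <= 1)
}

#' Linear-quadratic survival fraction
#'
#' `SF(D) = exp(-alpha D - beta D^2)`; strictly decreasing in dose, alpha
#' and beta.
#'
#' @param params an [lq_params()].
#' @param dose_Gy dose (Gy, >= 0); vectorized.
#' @return Survival fractions in (0, 1].
#' @examples
#' sf_lq(lq_params(0.352, 0.041), 2)  # ~0.42
#' @export
sf_lq <- function(params, dose_Gy) {
  stopifnot(inherits(params, "lq_params"), all(dose_Gy >= 0))
  exp(-params$alpha * dose_Gy - params$beta * dose_Gy^2)
}

#' Relative biological effectiveness from two LQ parameter sets
#'
#' Equal-effect RBE: solves
#' `base$beta D^2 + base$alpha D = with_np$alpha D_NP + with_np$beta D_NP^2`
#' for the positive root `D` and returns `D / D_NP`. When the published
#' fit reports a changed beta with nanoparticles, that beta enters the
#' with-NP effect.
#'
#' @param base [lq_params()] without nanoparticles (`alpha >= 0`,
#'   `beta > 0`).
#' @param with_np [lq_params()] with nanoparticles (`alpha >= 0`).
#' @param dose_np_Gy dose with nanoparticles (Gy, > 0).
#' @return RBE (dimensionless).
#' @examples
#' rbe_lq(lq_params(0.150, 0.041), lq_params(0.352, 0.041), 2)  # ~1.56
#' @export
rbe_lq <- function(base, with_np, dose_np_Gy) {
  stopifnot(inherits(base, "lq_params"), inherits(with_np, "lq_params"),
            dose_np_Gy > 0)
  if (base$alpha < 0 || with_np$alpha < 0)
    stop("negative alpha: equal-effect RBE is not defined for fits with ",
         "alpha < 0")
  effect <- with_np$alpha * dose_np_Gy + with_np$beta * dose_np_Gy^2
  if (effect <= 0) stop("with-NP effect must be positive")
  disc <- base$alpha^2 + 4 * base$beta * effect
  D <- (-base$alpha + sqrt(disc)) / (2 * base$beta)
  D / dose_np_Gy
}

#' RBE prediction under nanoparticle concentration scaling
#'
#' The bomb model's delta_alpha is linear in the NP count, so scaling the
#' intracellular concentration by `factor` scales delta_alpha by `factor`.
#' The with-NP survival parameters are rebuilt as
#' `alpha = base$alpha + factor * delta_alpha_bomb(b)` with beta unchanged,
#' and the equal-effect RBE is evaluated at `dose_np_Gy`.
#'
#' @param b a [bomb_params()] fitted at the reference concentration.
#' @param base [lq_params()] without nanoparticles.
#' @param factor concentration multiplier (> 0).
#' @param dose_np_Gy dose with nanoparticles (Gy, > 0).
#' @return RBE at the scaled concentration.
#' @export
predict_scaling <- function(b, base, factor, dose_np_Gy) {
  stopifnot(inherits(b, "bomb_params"), factor > 0)
  d_alpha <- factor * delta_alpha_bomb(b)
  rbe_lq(base, lq_params(base$alpha + d_alpha, base$beta), dose_np_Gy)
}
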