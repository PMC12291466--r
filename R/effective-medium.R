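#' Effective-medium mixing parameters
#'
#' Parameters of the mixing rule that relates a droplet's refractive index
#' \eqn{n_p} to the volume fraction \eqn{\phi} of protein in its dense
#' phase. Two rules are supported:
#' \describe{
#'   \item{\code{"lorentz_lorenz"}}{the Lorentz-Lorenz effective-medium
#'     relation: the Lorentz-Lorenz factor \eqn{L(n) = (n^2-1)/(n^2+2)} of
#'     the droplet is the volume-fraction-weighted mean of the factors of
#'     pure protein and of the medium.}
#'   \item{\code{"linear_dndc"}}{the refractive-index-increment rule
#'     \eqn{\phi = \bar v (n_p - n_m)/(dn/dc)}, with \eqn{dn/dc} in mL/g.}
#' }
#' Defaults are conventional protein-optics values (anhydrous protein index
#' 1.60, partial specific volume 0.73 mL/g, dn/dc 0.19 mL/g), not values
#' tied to any particular dataset.
#'
#' @param medium_index \eqn{n_m}, refractive index of the buffer.
#' @param protein_index refractive index of pure (anhydrous) protein.
#' @param vbar_mL_per_g partial specific volume \eqn{\bar v}, mL/g.
#' @param rule mixing rule, \code{"lorentz_lorenz"} or \code{"linear_dndc"}.
#' @param dndc_mL_per_g refractive-index increment, mL/g (linear rule only).
#' @return object of class \code{"mixing_params"}.
#' @export
mixing_params <- function(medium_index = 1.340,
                          protein_index = 1.60,
                          vbar_mL_per_g = 0.73,
                          rule = c("lorentz_lorenz", "linear_dndc"),
                          dndc_mL_per_g = 0.19) {
  rule <- match.arg(rule)
  if (!(protein_index > medium_index && medium_index > 1)) {
    stop("require protein_index > medium_index > 1", call. = FALSE)
  }
  if (vbar_mL_per_g <= 0 || dndc_mL_per_g <= 0) {
    stop("vbar and dn/dc must be positive", call. = FALSE)
  }
  structure(list(medium_index = medium_index,
                 protein_index = protein_index,
                 vbar_mL_per_g = vbar_mL_per_g,
                 rule = rule,
                 dndc_mL_per_g = dndc_mL_per_g),
            class = "mixing_params")
}

# Lorentz-Lorenz factor L(n) = (n^2 - 1)/(n^2 + 2)
lorentz_factor <- function(n) (n^2 - 1) / (n^2 + 2)

# inverse: n(L) = sqrt((1 + 2L)/(1 - L))
lorentz_index <- function(L) sqrt((1 + 2 * L) / (1 - L))

#' Refractive index from dense-phase volume fraction
#'
#' Forward evaluation of the selected mixing rule; strictly increasing in
#' \eqn{\phi}, with \code{index_from_volume_fraction(0) == medium_index}
#' and \code{index_from_volume_fraction(1) == protein_index} for the
#' Lorentz-Lorenz rule.
#'
#' @param phi volume fraction in \[0, 1\] (vectorized).
#' @param params a [mixing_params()] object.
#' @export
index_from_volume_fraction <- function(phi, params = mixing_params()) {
  stopifnot(inherits(params, "mixing_params"))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  if (params$rule == "lorentz_lorenz") {
    L <- phi * lorentz_factor(params$protein_index) +
      (1 - phi) * lorentz_factor(params$medium_index)
    lorentz_index(L)
  } else {
    params$medium_index + phi * params$dndc_mL_per_g / params$vbar_mL_per_g
  }
}

#' Dense-phase volume fraction from refractive index
#'
#' Inverts the mixing rule: for the Lorentz-Lorenz rule the inversion is
#' algebraic in the Lorentz-Lorenz factor, so the round trip
#' \eqn{\phi \to n_p \to \phi} is exact to floating-point precision.
#' Values of \eqn{n_p} slightly below \eqn{n_m} (within \code{tol}) are
#' clamped to \eqn{\phi = 0}; values further below signal a dilute-phase
#' or corrupt record and raise an error.
#'
#' @param n_p droplet refractive index (vectorized).
#' @param params a [mixing_params()] object.
#' @param tol tolerance pad on the admissible index range.
#' @return volume fraction(s) in \[0, 1\].
#' @export
volume_fraction_from_index <- function(n_p, params = mixing_params(),
                                       tol = 1e-9) {
  stopifnot(inherits(params, "mixing_params"))
  if (any(n_p < params$medium_index - tol)) {
    stop("refractive index below the medium value: not a dense-phase droplet",
         call. = FALSE)
  }
  n_max <- index_from_volume_fraction(1, params)  # rule-specific ceiling
  if (any(n_p > n_max + tol)) {
    stop("refractive index above the pure-protein value", call. = FALSE)
  }
  phi <- if (params$rule == "lorentz_lorenz") {
    Lm <- lorentz_factor(params$medium_index)
    Lp <- lorentz_factor(params$protein_index)
    (lorentz_factor(n_p) - Lm) / (Lp - Lm)
  } else {
    params$vbar_mL_per_g * (n_p - params$medium_index) / params$dndc_mL_per_g
  }
  pmin(1, pmax(0, phi))
}

#' Mass concentration from volume fraction
#'
#' \eqn{c = 1000 \phi / \bar v} in mg/mL with \eqn{\bar v} in mL/g;
#' monotone in \eqn{\phi}.
#'
#' @param phi volume fraction in \[0, 1\] (vectorized).
#' @param params a [mixing_params()] object.
#' @export
concentration_from_phi <- function(phi, params = mixing_params()) {
  stopifnot(inherits(params, "mixing_params"))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  1000 * phi / params$vbar_mL_per_g
}

#' Mass concentration directly from refractive index
#'
#' Convenience composition of [volume_fraction_from_index()] and
#' [concentration_from_phi()], the mapping used for the secondary
#' concentration axes on population plots.
#' @inheritParams volume_fraction_from_index
#' @export
concentration_from_index <- function(n_p, params = mixing_params()) {
  concentration_from_phi(volume_fraction_from_index(n_p, params), params)
}
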