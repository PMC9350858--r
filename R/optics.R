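#' Sample an optical depth
#'
#' Free paths in a homogeneous medium follow an exponential law in optical
#' depth: `tau = -log(u)` for `u` uniform on (0, 1], so `E[tau] = 1`. The
#' physical path in a uniform medium is `tau / mu_t`. `u = 0` is rejected
#' (it would give an infinite path); the internal sampler draws on (0, 1] so
#' the case never arises in transport.
#'
#' @param u uniform deviate(s) in (0, 1].
#' @return Dimensionless optical depth(s), `-log(u)`.
#' @export
sample_optical_depth <- function(u) {
  if (any(u <= 0) || any(u > 1)) stop("u must lie in (0, 1]")
  -log(u)
}

#' Sample the Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function with
#' anisotropy `g` (the mean scattering cosine). For `|g| < 1e-6` the
#' isotropic limit `cos(theta) = 2u - 1` is used.
#'
#' @param g anisotropy in (-1, 1).
#' @param u uniform deviate(s) in \[0, 1).
#' @return Scattering cosine(s) in \[-1, 1\], with `E[cos theta] = g`.
#' @export
hg_cosine <- function(g, u) {
  cpp_hg_cosine(g, as.numeric(u))
}

#' Unpolarised Fresnel reflectance
#'
#' Mean of the s- and p-polarised intensity reflectances for light crossing
#' from index `n1` into `n2` at incidence cosine `cos_i`. Returns 1 under
#' total internal reflection. `cos_i` outside (0, 1] indicates a
#' surface-normal orientation bug upstream and is an error.
#'
#' @param n1,n2 refractive indices (>= 1) on the incident and far side.
#' @param cos_i cosine of the angle of incidence, in (0, 1].
#' @return Reflectance in \[0, 1\].
#' @examples
#' fresnel_reflectance(1, 1.5, 1)  # 0.04 at normal incidence
#' @export
fresnel_reflectance <- function(n1, n2, cos_i) {
  cpp_fresnel(n1, n2, cos_i)
}

#' Specular reflection of a direction
#'
#' `d - 2 (d . n) n` with `n` oriented against the incidence (`d . n < 0`).
#' Non-unit inputs are normalised with a warning.
#'
#' @param d incident unit direction.
#' @param n unit surface normal, oriented against `d`.
#' @return Reflected unit direction.
#' @export
reflect_direction <- function(d, n) {
  d <- check_unit(d, "d"); n <- check_unit(n, "n")
  if (sum(d * n) >= 0) stop("normal must be oriented against incidence (d . n < 0)")
  cpp_reflect(d, n)
}

#' Refraction of a direction (vector Snell law)
#'
#' Transmitted direction satisfying `n1 sin(theta_i) = n2 sin(theta_t)`.
#' Under total internal reflection there is no real solution and the `tir`
#' flag is set.
#'
#' @inheritParams reflect_direction
#' @param n1,n2 refractive indices on the incident and far side.
#' @return A list with `direction` (unit vector, or empty under TIR) and
#'   logical `tir`.
#' @export
refract_direction <- function(d, n, n1, n2) {
  d <- check_unit(d, "d"); n <- check_unit(n, "n")
  if (sum(d * n) >= 0) stop("normal must be oriented against incidence (d . n < 0)")
  cpp_refract(d, n, n1, n2)
}

check_unit <- function(v, what) {
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v))) stop(what, " must be a finite length-3 vector")
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop(what, " has zero length")
  if (abs(nv - 1) > 1e-9) {
    warning(what, " is not unit length; normalising")
    v <- v / nv
  }
  v
}
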