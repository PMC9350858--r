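#' Optical medium
#'
#' Bundle of bulk optical properties attached to a region of the scene.
#'
#' @param mu_s scattering coefficient (cm^-1, >= 0).
#' @param mu_a absorption coefficient (cm^-1, >= 0).
#' @param g scattering anisotropy, the mean cosine of the Henyey-Greenstein
#'   phase function; must lie in (-1, 1). `g = 0` is isotropic scattering.
#' @param n refractive index (>= 1).
#'
#' @return An object of class `optical_medium` with fields `mu_s`, `mu_a`,
#'   `g`, `n` and the derived extinction `mu_t = mu_s + mu_a` and single
#'   scattering `albedo = mu_s / mu_t` (0 when `mu_t = 0`).
#' @examples
#' optical_medium(mu_s = 21, mu_a = 0.23, g = 0.9, n = 1.38)
#' @export
optical_medium <- function(mu_s = 0, mu_a = 0, g = 0, n = 1) {
  stopifnot(is.numeric(mu_s), length(mu_s) == 1L, is.finite(mu_s),
            is.numeric(mu_a), length(mu_a) == 1L, is.finite(mu_a),
            is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(n), length(n) == 1L, is.finite(n))
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (abs(g) >= 1) stop("anisotropy g must lie in (-1, 1)")
  if (n < 1) stop("refractive index n must be >= 1")
  mu_t <- mu_s + mu_a
  structure(
    list(mu_s = mu_s, mu_a = mu_a, g = g, n = n,
         mu_t = mu_t, albedo = if (mu_t > 0) mu_s / mu_t else 0),
    class = "optical_medium"
  )
}

#' @export
print.optical_medium <- function(x, ...) {
  cat(sprintf(
    "<optical_medium> mu_s = %g, mu_a = %g cm^-1 (mu_t = %g, albedo = %.4g), g = %g, n = %g\n",
    x$mu_s, x$mu_a, x$mu_t, x$albedo, x$g, x$n))
  invisible(x)
}

is_medium <- function(x) inherits(x, "optical_medium")

medium_as_list <- function(m) m[c("mu_s", "mu_a", "g", "n")]
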