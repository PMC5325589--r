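#' Five-parameter Weibull peak function
#'
#' Asymmetric single-peak model used for LysoSensor emission spectra. The
#' parameterization is peak-normalized: the curve attains its maximum
#' `y0 + a` exactly at `x = x0`, which gives a testable identity independent
#' of the width and shape parameters.
#'
#' The curve is
#' \deqn{f(x) = y_0 + a \left(\frac{c-1}{c}\right)^{\frac{1-c}{c}}
#'   u^{c-1} e^{-u^c + \frac{c-1}{c}}, \quad
#'   u = \frac{x - x_0}{b} + \left(\frac{c-1}{c}\right)^{1/c}}
#' for \eqn{u > 0}, and \eqn{f(x) = y_0} otherwise (flat short-wavelength
#' tail).
#'
#' @param x Wavelengths (nm), numeric vector.
#' @param y0 Baseline intensity (a.u.).
#' @param a Peak amplitude above baseline (a.u.); the peak value is `y0 + a`.
#' @param x0 Peak position (nm).
#' @param b Width parameter (nm), must be > 0.
#' @param c Shape parameter controlling asymmetry, must be > 1.
#' @return Numeric vector of intensities, same length as `x`.
#' @examples
#' weibull5(490, y0 = 5, a = 100, x0 = 490, b = 60, c = 2.2) # == 105
#' @export
weibull5 <- function(x, y0, a, x0, b, c) {
  stop_if_not(b > 0, "weibull5: width parameter b must be > 0")
  stop_if_not(c > 1, "weibull5: shape parameter c must be > 1")
  k <- ((c - 1) / c)^(1 / c)
  u <- (x - x0) / b + k
  f <- rep(y0, length(x))
  pos <- u > 0
  if (any(pos)) {
    pref <- ((c - 1) / c)^((1 - c) / c)
    f[pos] <- y0 + a * pref * u[pos]^(c - 1) * exp(-u[pos]^c + (c - 1) / c)
  }
  f
}
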