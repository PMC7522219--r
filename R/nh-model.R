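# Non-rectangular hyperbola (NH) family: the lower root of
#   theta*y^2 - (alpha*I + ymax)*y + alpha*I*ymax = 0,  minus rd.
# ymax is the *gross* asymptote; the curve approaches it only as I -> Inf
# (for theta < 1), which is why the NH model cannot return a saturation
# irradiance for its maximum.

.check_nh_params <- function(alpha, theta, ymax, rd) {
  stopifnot(length(alpha) == 1L, length(theta) == 1L,
            length(ymax) == 1L, length(rd) == 1L)
  if (!is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a positive finite number", call. = FALSE)
  if (!is.finite(theta) || theta < 0 || theta > 1)
    stop("'theta' must lie in [0, 1]", call. = FALSE)
  if (!is.finite(ymax) || ymax <= 0)
    stop("'ymax' must be positive", call. = FALSE)
  if (!is.finite(rd) || rd < 0)
    stop("'rd' must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate the non-rectangular hyperbola light-response curve
#'
#' Computes the lower root of
#' `theta*y^2 - (alpha*i + ymax)*y + alpha*i*ymax = 0` minus `rd`, i.e.
#' \deqn{y(I) = \frac{\alpha I + y_{max} - \sqrt{(\alpha I + y_{max})^2 -
#'   4\alpha\theta y_{max} I}}{2\theta} - R_d.}
#'
#' Two limits are handled exactly: `theta = 1` collapses to the Blackman
#' form `min(alpha*i, ymax) - rd`, and `theta` below a small threshold
#' evaluates the rectangular-hyperbola limit
#' `alpha*i*ymax/(alpha*i + ymax) - rd` (avoiding 0/0).
#'
#' @param i Incident irradiance (umol photons m-2 s-1), vectorised, `>= 0`.
#' @param alpha Initial slope (umol umol-1 photons), `> 0`.
#' @param theta Convexity, dimensionless in `(0, 1]`.
#' @param ymax Gross asymptotic maximum (umol m-2 s-1), `> 0`.
#' @param rd Dark respiration rate (umol m-2 s-1), `>= 0`. Default 0.
#' @return Numeric vector of responses (umol m-2 s-1).
#' @seealso [ye_predict()], [nh_asymptote_gap()]
#' @examples
#' nh_predict(seq(0, 2000, by = 400),
#'            alpha = 0.282, theta = 0.924, ymax = 373.87)
#' @export
nh_predict <- function(i, alpha, theta, ymax, rd = 0) {
  .check_nh_params(alpha, theta, ymax, rd)
  if (any(!is.finite(i)) || any(i < 0))
    stop("'i' must be finite and non-negative", call. = FALSE)
  if (theta < .lrc_eps)
    return(alpha * i * ymax / (alpha * i + ymax) - rd)
  if (theta == 1)
    return(pmin(alpha * i, ymax) - rd)
  s <- alpha * i + ymax
  disc <- s^2 - 4 * alpha * theta * ymax * i
  (s - sqrt(pmax(disc, 0))) / (2 * theta) - rd
}

#' Light compensation point of the NH curve
#'
#' The irradiance at which the net NH curve crosses zero. Setting the lower
#' root equal to `rd` and solving gives the closed form
#' `I_c = rd * (ymax - theta*rd) / (alpha * (ymax - rd))`, which requires
#' gross capacity to exceed respiration (`ymax > rd`).
#'
#' @inheritParams nh_predict
#' @return The light compensation point (umol photons m-2 s-1).
#' @examples
#' nh_light_compensation(alpha = 0.069, theta = 0.659,
#'                       ymax = 43.30 + 3.29, rd = 3.29)
#' @export
nh_light_compensation <- function(alpha, theta, ymax, rd) {
  .check_nh_params(alpha, theta, ymax, rd)
  if (rd <= 0)
    stop("'rd' must be positive for a compensation point to exist",
         call. = FALSE)
  if (ymax <= rd)
    stop("no compensation point: respiration exceeds the asymptotic maximum",
         call. = FALSE)
  rd * (ymax - theta * rd) / (alpha * (ymax - rd))
}

#' Gap between the NH asymptote and the curve at the brightest step
#'
#' For `theta < 1` the NH curve never attains its asymptote `ymax`; this
#' returns `ymax` minus the gross model value at the largest measured
#' irradiance, quantifying how far beyond the data the reported "maximum"
#' lies. It is the mechanism by which asymptotic fits overestimate the
#' maximum of a saturating (or photoinhibited) response.
#'
#' @inheritParams nh_predict
#' @param i_max Largest measured irradiance (umol photons m-2 s-1), `> 0`.
#' @return A non-negative scalar (umol m-2 s-1); strictly positive for
#'   `theta < 1`.
#' @examples
#' nh_asymptote_gap(alpha = 0.282, theta = 0.924, ymax = 373.87, i_max = 2000)
#' @export
nh_asymptote_gap <- function(alpha, theta, ymax, i_max, rd = 0) {
  if (!is.finite(i_max) || i_max <= 0)
    stop("'i_max' must be positive", call. = FALSE)
  ymax - (nh_predict(i_max, alpha, theta, ymax, rd) + rd)
}
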