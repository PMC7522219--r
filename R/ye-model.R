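# Nonasymptotic ("Ye") light-response family:
#   y(I) = alpha * (1 - beta*I) * I / (1 + gamma*I) - rd
# alpha: initial slope; beta: photoinhibition coefficient (>= 0);
# gamma: light-saturation coefficient (may be negative as long as
# beta + gamma > 0 and the data stay inside I < -1/gamma);
# rd: dark respiration, 0 for electron-flow curves (J, JC, JO).

# Switch threshold below which gamma (or beta, or theta for the NH family)
# is treated as exactly zero and the analytic limit is used.
.lrc_eps <- 1e-10

.check_ye_params <- function(alpha, beta, gamma, rd) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L,
            length(gamma) == 1L, length(rd) == 1L)
  if (!is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a positive finite number", call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("'beta' must be non-negative", call. = FALSE)
  if (!is.finite(gamma))
    stop("'gamma' must be finite", call. = FALSE)
  if (!is.finite(rd) || rd < 0)
    stop("'rd' must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate the nonasymptotic (Ye) light-response curve
#'
#' Computes `alpha * (1 - beta*i) * i / (1 + gamma*i) - rd`, the
#' nonasymptotic light-response function with an initial slope `alpha`, a
#' photoinhibition coefficient `beta` and a light-saturation coefficient
#' `gamma`. With `rd > 0` the value is a net photosynthesis rate; with
#' `rd = 0` it is an electron-flow rate (J, JC or JO).
#'
#' `gamma` may be negative (as fitted J--I and JO--I curves sometimes
#' require) provided `beta + gamma > 0`; in that case the curve is only
#' defined for `i < -1/gamma` and irradiances at or beyond that pole are
#' rejected.
#'
#' @param i Incident irradiance (umol photons m-2 s-1), vectorised, `>= 0`.
#' @param alpha Initial slope (umol umol-1 photons), `> 0`.
#' @param beta Photoinhibition coefficient (m2 s umol-1), `>= 0`.
#' @param gamma Light-saturation coefficient (m2 s umol-1); may be negative,
#'   but `beta + gamma` must be positive.
#' @param rd Dark respiration rate (umol m-2 s-1), `>= 0`. Default 0.
#' @return Numeric vector of responses (umol m-2 s-1), same length as `i`.
#' @seealso [ye_derived()], [ye_light_compensation()], [nh_predict()]
#' @examples
#' ye_predict(seq(0, 2000, by = 400),
#'            alpha = 0.059, beta = 1.40e-4, gamma = 5.76e-4, rd = 3.76)
#' @export
ye_predict <- function(i, alpha, beta, gamma, rd = 0) {
  .check_ye_params(alpha, beta, gamma, rd)
  if (any(!is.finite(i)) || any(i < 0))
    stop("'i' must be finite and non-negative", call. = FALSE)
  denom <- 1 + gamma * i
  if (any(denom <= 0))
    stop("curve undefined: 1 + gamma*i <= 0 at some irradiance ",
         "(validity window is i < ", format(-1 / gamma), ")", call. = FALSE)
  alpha * (1 - beta * i) * i / denom - rd
}

#' Closed-form derived quantities of the Ye curve
#'
#' Returns the interior maximum of the curve, the saturation irradiance at
#' which it is attained, and (for net-photosynthesis curves with `rd > 0`)
#' the light compensation point:
#' \deqn{I_{sat} = \frac{\sqrt{(\beta+\gamma)/\beta} - 1}{\gamma}, \qquad
#'       y_{max} = \alpha\left(\frac{\sqrt{\beta+\gamma} -
#'                 \sqrt{\beta}}{\gamma}\right)^2 - R_d.}
#'
#' Degenerate limits are handled analytically: for `gamma ~ 0` the curve is
#' the parabola limit with `i_sat = 1/(2 beta)`, `y_max = alpha/(4 beta) - rd`;
#' for `beta = 0` (no photoinhibition) the curve is a saturating hyperbola
#' with no finite interior maximum, reported as the asymptote
#' `alpha/gamma - rd` with `i_sat = Inf` and `asymptotic = TRUE`.
#'
#' @inheritParams ye_predict
#' @return A list with components `y_max`, `i_sat`, `i_c` (`NA` unless
#'   `rd > 0` and a compensation point exists) and the logical `asymptotic`.
#' @examples
#' ye_derived(alpha = 0.221, beta = 2.54e-4, gamma = 1.67e-5) # JC-I curve
#' @export
ye_derived <- function(alpha, beta, gamma, rd = 0) {
  .check_ye_params(alpha, beta, gamma, rd)
  if (beta + gamma <= 0)
    stop("'beta + gamma' must be positive (finite interior maximum)",
         call. = FALSE)
  if (abs(gamma) < .lrc_eps) {
    # beta + gamma > 0 guarantees beta > 0 here
    out <- list(y_max = alpha / (4 * beta) - rd,
                i_sat = 1 / (2 * beta),
                i_c = NA_real_, asymptotic = FALSE)
  } else if (beta < .lrc_eps) {
    out <- list(y_max = alpha / gamma - rd,
                i_sat = Inf,
                i_c = NA_real_, asymptotic = TRUE)
  } else {
    out <- list(y_max = alpha * ((sqrt(beta + gamma) - sqrt(beta)) / gamma)^2 - rd,
                i_sat = (sqrt((beta + gamma) / beta) - 1) / gamma,
                i_c = NA_real_, asymptotic = FALSE)
  }
  if (rd > 0) {
    ic <- tryCatch(ye_light_compensation(alpha, beta, gamma, rd),
                   error = function(e) NA_real_)
    out$i_c <- ic
  }
  out
}

#' Light compensation point of the Ye curve
#'
#' Solves `ye_predict(i) = 0` for the smaller positive root, i.e. the
#' irradiance at which gross assimilation first balances respiration.
#' Clearing the denominator gives the quadratic
#' `alpha*beta*I^2 - (alpha - rd*gamma)*I + rd = 0`; the smaller positive
#' root (below saturation) is the physiological compensation point. For
#' `beta = 0` the equation is linear-fractional and the root is
#' `rd / (alpha - rd*gamma)`.
#'
#' @inheritParams ye_predict
#' @return The light compensation point (umol photons m-2 s-1).
#' @examples
#' ye_light_compensation(alpha = 0.059, beta = 1.40e-4,
#'                       gamma = 5.76e-4, rd = 3.76)
#' @export
ye_light_compensation <- function(alpha, beta, gamma, rd) {
  .check_ye_params(alpha, beta, gamma, rd)
  if (rd <= 0)
    stop("'rd' must be positive: a curve through the origin has no ",
         "compensation point", call. = FALSE)
  b <- alpha - rd * gamma
  if (beta < .lrc_eps) {
    if (b <= 0)
      stop("no compensation point: respiration exceeds attainable assimilation",
           call. = FALSE)
    return(rd / b)
  }
  a <- alpha * beta
  disc <- b^2 - 4 * a * rd
  if (disc < 0)
    stop("no compensation point: respiration exceeds attainable assimilation",
         call. = FALSE)
  roots <- (b + c(-1, 1) * sqrt(disc)) / (2 * a)
  roots <- roots[roots > 0]
  if (!length(roots))
    stop("no compensation point: both roots non-positive", call. = FALSE)
  min(roots)
}
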