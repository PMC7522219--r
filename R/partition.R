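# PSII electron flow from fluorescence, and its split into the
# RuBP-carboxylation (JC) and RuBP-oxygenation (JO) streams.

#' Respiration specification
#'
#' Couples dark respiration `r_d` to day respiration `r_day`. By the usual
#' convention `r_day = 0.5 * r_d` unless `r_day` is given explicitly; the
#' 0.5 factor is a cited convention, not a law, so either member may be
#' supplied on its own.
#'
#' @param r_d Dark respiration rate (umol m-2 s-1), `>= 0`.
#' @param r_day Day respiration rate (umol m-2 s-1), `>= 0`; defaults to
#'   `0.5 * r_d`.
#' @return A list of class `"respiration_spec"` with elements `r_d` and
#'   `r_day`.
#' @examples
#' respiration_spec(r_d = 4)        # r_day = 2
#' respiration_spec(r_day = 1.5)    # r_d unknown
#' @export
respiration_spec <- function(r_d = NULL, r_day = NULL) {
  if (is.null(r_d) && is.null(r_day))
    stop("supply 'r_d' or 'r_day'", call. = FALSE)
  if (!is.null(r_d) && (!is.finite(r_d) || r_d < 0))
    stop("'r_d' must be non-negative", call. = FALSE)
  if (is.null(r_day)) r_day <- 0.5 * r_d
  if (!is.finite(r_day) || r_day < 0)
    stop("'r_day' must be non-negative", call. = FALSE)
  structure(list(r_d = if (is.null(r_d)) NA_real_ else r_d, r_day = r_day),
            class = "respiration_spec")
}

#' Total PSII electron transport rate from fluorescence
#'
#' `J = phi_psii * i * psii_fraction * absorptance`, the standard estimate
#' of linear electron flow from the effective PSII quantum yield. The
#' default `psii_fraction = 0.5` (fraction of absorbed photons reaching
#' PSII) and `absorptance = 0.84` (leaf absorptance) are the conventional
#' C3 leaf values; both are species-dependent in general use and therefore
#' exposed.
#'
#' @param phi_psii Effective PSII quantum yield, in `[0, 1]`, vectorised.
#' @param i Incident irradiance (umol photons m-2 s-1), `>= 0`, vectorised.
#' @param psii_fraction Fraction of absorbed quanta partitioned to PSII,
#'   in `(0, 1]`.
#' @param absorptance Leaf absorptance, in `(0, 1]`.
#' @return Electron flow (umol e- m-2 s-1).
#' @examples
#' compute_j(0.5, 1000)  # 210
#' @export
compute_j <- function(phi_psii, i, psii_fraction = 0.5, absorptance = 0.84) {
  if (any(!is.finite(phi_psii)) || any(phi_psii < 0) || any(phi_psii > 1))
    stop("'phi_psii' must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(i)) || any(i < 0))
    stop("'i' must be non-negative", call. = FALSE)
  if (length(psii_fraction) != 1L || !is.finite(psii_fraction) ||
      psii_fraction <= 0 || psii_fraction > 1)
    stop("'psii_fraction' must lie in (0, 1]", call. = FALSE)
  if (length(absorptance) != 1L || !is.finite(absorptance) ||
      absorptance <= 0 || absorptance > 1)
    stop("'absorptance' must lie in (0, 1]", call. = FALSE)
  phi_psii * i * psii_fraction * absorptance
}

#' Partition total electron flow into carboxylation and oxygenation streams
#'
#' From total PSII electron flow `j` and net assimilation `a_n`,
#' \deqn{J_C = \tfrac{1}{3}\,[J + 8(A_n + R_{day})], \qquad
#'       J_O = \tfrac{2}{3}\,[J - 4(A_n + R_{day})],}
#' which sum to `j` identically. The split assumes electron sinks other
#' than RuBP carboxylation and oxygenation are negligible or constant; a
#' negative `j_o` diagnoses a violation of that assumption (or inconsistent
#' inputs) and is returned as-is with a warning, never clipped.
#'
#' @param j Total electron flow (umol e- m-2 s-1), `>= 0`, vectorised.
#' @param a_n Net photosynthesis (umol CO2 m-2 s-1), vectorised.
#' @param resp A [respiration_spec()], or a number taken as `r_day`.
#' @return A data frame with columns `j_c` and `j_o` (`j_c + j_o == j`).
#' @examples
#' partition_j(j = 300, a_n = 30, resp = respiration_spec(r_d = 4))
#' @export
partition_j <- function(j, a_n, resp) {
  if (is.numeric(resp)) resp <- respiration_spec(r_day = resp)
  stopifnot(inherits(resp, "respiration_spec"))
  if (any(!is.finite(j)) || any(j < 0))
    stop("'j' must be non-negative", call. = FALSE)
  if (any(!is.finite(a_n)))
    stop("'a_n' must be finite", call. = FALSE)
  gross <- a_n + resp$r_day
  j_c <- (j + 8 * gross) / 3
  j_o <- 2 * (j - 4 * gross) / 3
  if (any(j_o < 0))
    warning(sum(j_o < 0), " step(s) with negative j_o: J < 4*(A_n + R_day), ",
            "inputs inconsistent or alternative electron sinks not negligible",
            call. = FALSE)
  if (any(j_c < 0))
    warning(sum(j_c < 0), " step(s) with negative j_c", call. = FALSE)
  data.frame(j_c = j_c, j_o = j_o)
}

#' Populate electron-flow columns on a table of light steps
#'
#' For each measurement step, computes total electron flow `j` from
#' `phi_psii` (unless a `j` column is already present) and splits it into
#' `j_c` and `j_o` via [partition_j()]. Steps lacking both `phi_psii` and
#' `j` are passed through unchanged with a warning.
#'
#' @param steps Data frame with columns `i`, `a_n` and `phi_psii` (or `j`).
#' @param resp A [respiration_spec()].
#' @inheritParams compute_j
#' @return `steps` with `j`, `j_c`, `j_o` columns filled where possible.
#' @examples
#' steps <- data.frame(i = c(1000, 500), a_n = c(25, 18),
#'                     phi_psii = c(0.5, 0.62))
#' partition_steps(steps, respiration_spec(r_d = 4))
#' @export
partition_steps <- function(steps, resp, psii_fraction = 0.5,
                            absorptance = 0.84) {
  if (!is.data.frame(steps) || nrow(steps) == 0L)
    stop("'steps' must be a non-empty data frame", call. = FALSE)
  if (!all(c("i", "a_n") %in% names(steps)))
    stop("'steps' needs columns 'i' and 'a_n'", call. = FALSE)
  stopifnot(inherits(resp, "respiration_spec"))
  if (!"j" %in% names(steps)) steps$j <- NA_real_
  has_phi <- "phi_psii" %in% names(steps)
  need_j <- is.na(steps$j)
  if (has_phi) {
    fill <- need_j & !is.na(steps$phi_psii)
    steps$j[fill] <- compute_j(steps$phi_psii[fill], steps$i[fill],
                               psii_fraction, absorptance)
  }
  ok <- !is.na(steps$j)
  if (any(!ok))
    warning(sum(!ok), " step(s) lack both 'phi_psii' and 'j'; passed through",
            call. = FALSE)
  steps$j_c <- NA_real_
  steps$j_o <- NA_real_
  if (any(ok)) {
    part <- partition_j(steps$j[ok], steps$a_n[ok], resp)
    steps$j_c[ok] <- part$j_c
    steps$j_o[ok] <- part$j_o
  }
  steps
}
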