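# Synthetic gas-exchange / fluorescence datasets with the structure of a
# descending-light-step measurement campaign: n leaf replicates, an initial
# linear rise, saturation, mild post-saturation decline, Gaussian noise.

#' Standard descending light-step designs
#'
#' The measurement designs emulated by the generator: 15 steps from 2000
#' down to 0 umol m-2 s-1 (`"soybean"`), or the same sequence capped at
#' 1800 (`"wheat"`, matching lower seasonal light availability).
#'
#' @param design `"soybean"` or `"wheat"`.
#' @return Numeric vector of irradiances in descending order.
#' @examples
#' light_steps("soybean")
#' @export
light_steps <- function(design = c("soybean", "wheat")) {
  design <- match.arg(design)
  steps <- c(2000, 1800, 1600, 1400, 1200, 1000, 800, 600, 400, 200,
             150, 100, 80, 50, 0)
  if (design == "wheat") steps <- steps[steps <= 1800]
  steps
}

#' Reference parameter catalog for the two-species dataset
#'
#' Named ground-truth parameter sets for wheat (*Triticum aestivum*) and
#' soybean (*Glycine max*) light-response curves — the replicate-mean
#' fitted coefficients of each response family — used as simulation truths
#' and fixtures throughout the package. Ye entries carry
#' `(alpha, beta, gamma, rd)`; NH entries `(alpha, theta, ymax, rd)` with
#' `ymax` the gross asymptote.
#'
#' The wheat J--I Ye entry is deliberately absent: its published
#' coefficients are internally inconsistent (the printed photoinhibition
#' coefficient would force J negative well inside the measured light
#' range), so they cannot serve as a simulation truth.
#'
#' @return Named list; each element has `model`, `species`, `response`,
#'   `design` and `params`.
#' @examples
#' names(fixture_table1())
#' fixture_table1()$gmax_jc$params
#' @export
fixture_table1 <- function() {
  ye <- function(species, response, design, alpha, beta, gamma, rd = 0)
    list(model = "ye", species = species, response = response,
         design = design,
         params = c(alpha = alpha, beta = beta, gamma = gamma, rd = rd))
  nh <- function(species, response, design, alpha, theta, ymax, rd = 0)
    list(model = "nh", species = species, response = response,
         design = design,
         params = c(alpha = alpha, theta = theta, ymax = ymax, rd = rd))
  list(
    taes_an = ye("T. aestivum", "an", "wheat",
                 0.077, 1.31e-4, 1.02e-3, 3.60),
    gmax_an = ye("G. max", "an", "soybean",
                 0.059, 1.40e-4, 5.76e-4, 3.76),
    gmax_j = ye("G. max", "j", "soybean", 0.299, 3.07e-4, -1.50e-4),
    taes_jc = ye("T. aestivum", "jc", "wheat", 0.266, 2.07e-4, 3.75e-4),
    gmax_jc = ye("G. max", "jc", "soybean", 0.221, 2.54e-4, 1.67e-5),
    taes_jo = ye("T. aestivum", "jo", "wheat", 0.062, 3.45e-4, -1.98e-4),
    gmax_jo = ye("G. max", "jo", "soybean", 0.087, 4.12e-4, -3.71e-4),
    taes_an_nh = nh("T. aestivum", "an", "wheat",
                    0.069, 0.659, 43.30 + 3.29, 3.29),
    gmax_an_nh = nh("G. max", "an", "soybean",
                    0.055, 0.644, 47.74 + 3.58, 3.58),
    gmax_j_nh = nh("G. max", "j", "soybean", 0.282, 0.924, 373.87))
}

.valid_ye_truth <- function(p, i_max) {
  p[["alpha"]] > 0 && p[["beta"]] >= 0 &&
    p[["beta"]] + p[["gamma"]] > 0 &&
    1 + p[["gamma"]] * i_max > 0 && p[["rd"]] >= 0
}

# multiplicative lognormal jitter preserving sign, redrawn until valid
.jitter_params <- function(p, jitter, i_max, max_tries = 100) {
  if (jitter <= 0) return(p)
  for (k in seq_len(max_tries)) {
    q <- p * stats::rlnorm(length(p), 0, jitter)
    if (.valid_ye_truth(q, i_max)) return(q)
  }
  stop("could not draw valid jittered parameters in ", max_tries,
       " attempts", call. = FALSE)
}

#' Simulate net-photosynthesis light-response curves
#'
#' Generates an `n_replicates`-leaf dataset from a Ye-model truth at the
#' given light steps. Per replicate, the truth parameters are jittered
#' multiplicatively (lognormal, sd `replicate_jitter`, redrawn while
#' invalid) to emulate between-leaf biological variation, the curve is
#' evaluated at the steps, and homoscedastic Gaussian measurement noise is
#' added with sd `noise_sd` times the maximum of the noiseless curve
#' (`noise_mode = "relative"`, the default) or `noise_sd` itself
#' (`"absolute"`).
#'
#' @param truth Named vector `c(alpha, beta, gamma, rd)` of Ye parameters
#'   (see [fixture_table1()] for references).
#' @param steps Irradiance sequence; default [light_steps()]`("soybean")`.
#' @param n_replicates Number of leaf replicates. Default 3.
#' @param noise_sd Gaussian noise sd (relative to the curve maximum by
#'   default). Default 0.02.
#' @param noise_mode `"relative"` or `"absolute"`.
#' @param replicate_jitter Lognormal sd of between-replicate parameter
#'   variation. Default 0.
#' @param seed Optional integer seed; a fixed seed makes the dataset
#'   reproducible.
#' @param response_col Name of the generated response column (default
#'   `"a_n"`; use e.g. `"j"` to generate an electron-flow curve from a
#'   zero-offset truth).
#' @return Data frame with columns `replicate`, `i`, and the response.
#' @examples
#' simulate_an_curves(fixture_table1()$gmax_an$params, seed = 1)
#' @export
simulate_an_curves <- function(truth, steps = light_steps("soybean"),
                               n_replicates = 3, noise_sd = 0.02,
                               noise_mode = c("relative", "absolute"),
                               replicate_jitter = 0, seed = NULL,
                               response_col = "a_n") {
  noise_mode <- match.arg(noise_mode)
  stopifnot(is.numeric(truth),
            all(c("alpha", "beta", "gamma", "rd") %in% names(truth)))
  if (anyDuplicated(steps) || any(steps < 0))
    stop("light steps must be unique and non-negative", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  i_max <- max(steps)
  if (!.valid_ye_truth(truth, i_max))
    stop("invalid truth parameters for the requested light range",
         call. = FALSE)
  out <- lapply(seq_len(n_replicates), function(r) {
    p <- .jitter_params(truth, replicate_jitter, i_max)
    y <- ye_predict(steps, p[["alpha"]], p[["beta"]], p[["gamma"]],
                    p[["rd"]])
    sdev <- if (noise_mode == "relative") noise_sd * max(abs(y))
            else noise_sd
    y <- y + stats::rnorm(length(steps), 0, sdev)
    df <- data.frame(replicate = paste0("rep", r), i = steps)
    df[[response_col]] <- y
    df
  })
  do.call(rbind, out)
}

#' Add fluorescence yields consistent with an electron-flow truth
#'
#' Given a Ye-model truth for the total electron flow (J--I) and an
#' existing gas-exchange dataset, generates the effective PSII quantum
#' yield each replicate would have shown: the J curve is evaluated at each
#' step and inverted through `J = phi_psii * i * psii_fraction *
#' absorptance`, so that [compute_j()] on the generated yields reproduces
#' the noiseless J truth exactly when `noise_sd = 0`. At `i = 0` (where the
#' inversion is singular) the yield of the smallest positive step is used.
#' Yields are clipped to `[0, 1]` with a warning; a clipping rate above 10%
#' signals a truth/step mismatch loudly.
#'
#' @param j_truth Named vector `c(alpha, beta, gamma, rd)` of the J--I Ye
#'   truth (`rd` must be 0).
#' @param an_data Dataset from [simulate_an_curves()] (columns `replicate`,
#'   `i`).
#' @param noise_sd Gaussian noise sd on the yield, relative to its maximum.
#' @param seed Optional integer seed.
#' @inheritParams compute_j
#' @return `an_data` with a `phi_psii` column appended.
#' @examples
#' fx <- fixture_table1()
#' an <- simulate_an_curves(fx$gmax_an$params, noise_sd = 0, seed = 1)
#' fl <- simulate_fluorescence(fx$gmax_j$params, an, noise_sd = 0)
#' head(fl)
#' @export
simulate_fluorescence <- function(j_truth, an_data, noise_sd = 0,
                                  seed = NULL, psii_fraction = 0.5,
                                  absorptance = 0.84) {
  stopifnot(is.data.frame(an_data),
            all(c("replicate", "i") %in% names(an_data)))
  if (!is.null(seed)) set.seed(seed)
  i <- an_data$i
  j <- ye_predict(i, j_truth[["alpha"]], j_truth[["beta"]],
                  j_truth[["gamma"]], 0)
  phi <- rep(NA_real_, length(i))
  pos <- i > 0
  phi[pos] <- j[pos] / (psii_fraction * absorptance * i[pos])
  if (any(!pos)) {
    i_min_pos <- min(i[pos])
    ref <- j[match(i_min_pos, i)] / (psii_fraction * absorptance * i_min_pos)
    phi[!pos] <- ref
  }
  if (noise_sd > 0)
    phi <- phi + stats::rnorm(length(phi), 0, noise_sd * max(phi))
  clipped <- phi < 0 | phi > 1
  if (any(clipped)) {
    rate <- mean(clipped)
    phi <- pmin(pmax(phi, 0), 1)
    if (rate > 0.10)
      warning(sprintf(paste0("%.0f%% of generated yields clipped to [0, 1]: ",
                             "J truth and light steps are inconsistent"),
                      100 * rate), call. = FALSE)
    else
      warning(sum(clipped), " generated yield(s) clipped to [0, 1]",
              call. = FALSE)
  }
  an_data$phi_psii <- phi
  an_data
}
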