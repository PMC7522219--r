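# Per-replicate nonlinear least-squares fitting of the Ye and NH families,
# by Levenberg-Marquardt with box bounds and a deterministic multi-start.

.response_col <- c(an = "a_n", j = "j", jc = "j_c", jo = "j_o")

#' Coefficient of determination and error sums of squares
#'
#' `r_squared = 1 - SSE/SST` with `SSE = sum((obs - pred)^2)` and
#' `SST = sum((obs - mean(obs))^2)`.
#'
#' @param observed,predicted Numeric vectors of equal length `>= 2`.
#' @return A list with `r_squared`, `sse`, `sst`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))  # r2 = 0.5
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  if (length(observed) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0)
    stop("degenerate data: all observed values are equal (SST = 0)",
         call. = FALSE)
  list(r_squared = 1 - sse / sst, sse = sse, sst = sst)
}

# Initial-slope candidates: the low-light secant (exact on noiseless
# data) plus gross-maximum-based guesses that survive noise in the two
# dimmest steps.
.alpha_starts <- function(i, y, rd0) {
  ord <- order(i)
  secant <- (y[ord][2] - y[ord][1]) / (i[ord][2] - i[ord][1])
  ygross <- max(y) + rd0
  i_at_max <- max(i[which.max(y)], min(i[i > 0]))
  cand <- c(secant, 2 * ygross / i_at_max, 4 * ygross / i_at_max)
  unique(pmin(pmax(cand, 5e-3), 1))
}

# Run nls.lm over a deterministic list of starts; return the best solution.
.lm_multistart <- function(starts, resid_fn, lower, upper) {
  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxfev = 10000, maxiter = 1000)
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    # non-convergence surfaces through the `converged` flag, not conditions
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                           upper = upper, control = ctrl)),
      error = function(e) NULL)
    if (is.null(res)) next
    dev <- sum(res$fvec^2)
    if (is.null(best) || dev < best$dev)
      best <- list(par = res$par, dev = dev, info = res$info)
  }
  if (is.null(best))
    stop("optimization failed from every start", call. = FALSE)
  best
}

.fit_ye_engine <- function(i, y, free_rd, rd_fixed) {
  imax <- max(i)
  rd0 <- if (any(i == 0)) max(0.05, -y[i == 0][1]) else max(0.05, -min(y))
  alpha0s <- .alpha_starts(i, y, if (free_rd) rd0 else rd_fixed)
  gamma_lo <- -1 / (1.05 * imax)
  gamma0s <- c(-1e-4, 1e-5, 5e-4, 2e-3)
  gamma0s <- gamma0s[gamma0s > gamma_lo]
  grid <- expand.grid(alpha = alpha0s, gamma = gamma0s)
  if (free_rd) {
    lower <- c(alpha = 1e-6, beta = 0, gamma = gamma_lo, rd = 0)
    upper <- c(alpha = 1, beta = 0.02, gamma = 0.05, rd = 20)
    starts <- lapply(seq_len(nrow(grid)), function(k)
      c(alpha = grid$alpha[k], beta = 1e-4, gamma = grid$gamma[k],
        rd = min(rd0, 20)))
    rfun <- function(p) y - (p[["alpha"]] * (1 - p[["beta"]] * i) * i /
                               (1 + p[["gamma"]] * i) - p[["rd"]])
  } else {
    lower <- c(alpha = 1e-6, beta = 0, gamma = gamma_lo)
    upper <- c(alpha = 1, beta = 0.02, gamma = 0.05)
    starts <- lapply(seq_len(nrow(grid)), function(k)
      c(alpha = grid$alpha[k], beta = 1e-4, gamma = grid$gamma[k]))
    rfun <- function(p) y - (p[["alpha"]] * (1 - p[["beta"]] * i) * i /
                               (1 + p[["gamma"]] * i) - rd_fixed)
  }
  best <- .lm_multistart(starts, rfun, lower, upper)
  par <- best$par
  if (!free_rd) par <- c(par, rd = rd_fixed)
  names(par) <- c("alpha", "beta", "gamma", "rd")
  list(par = par, converged = best$info %in% 1:3)
}

.fit_nh_engine <- function(i, y, free_rd, rd_fixed) {
  rd0 <- if (any(i == 0)) max(0.05, -y[i == 0][1]) else max(0.05, -min(y))
  alpha0s <- .alpha_starts(i, y, if (free_rd) rd0 else rd_fixed)
  ygross_max <- max(y) + if (free_rd) rd0 else rd_fixed
  ymax0 <- 1.05 * max(ygross_max, 1e-3)
  ymax_hi <- 10 * max(abs(y))
  grid <- expand.grid(alpha = alpha0s, theta = c(0.5, 0.9))
  if (free_rd) {
    lower <- c(alpha = 1e-6, theta = 1e-6, ymax = 1e-8, rd = 0)
    upper <- c(alpha = 1, theta = 1, ymax = ymax_hi, rd = 20)
    starts <- lapply(seq_len(nrow(grid)), function(k)
      c(alpha = grid$alpha[k], theta = grid$theta[k], ymax = ymax0,
        rd = min(rd0, 20)))
    rfun <- function(p) {
      s <- p[["alpha"]] * i + p[["ymax"]]
      disc <- pmax(s^2 - 4 * p[["alpha"]] * p[["theta"]] * p[["ymax"]] * i, 0)
      y - ((s - sqrt(disc)) / (2 * p[["theta"]]) - p[["rd"]])
    }
  } else {
    lower <- c(alpha = 1e-6, theta = 1e-6, ymax = 1e-8)
    upper <- c(alpha = 1, theta = 1, ymax = ymax_hi)
    starts <- lapply(seq_len(nrow(grid)), function(k)
      c(alpha = grid$alpha[k], theta = grid$theta[k], ymax = ymax0))
    rfun <- function(p) {
      s <- p[["alpha"]] * i + p[["ymax"]]
      disc <- pmax(s^2 - 4 * p[["alpha"]] * p[["theta"]] * p[["ymax"]] * i, 0)
      y - ((s - sqrt(disc)) / (2 * p[["theta"]]) - rd_fixed)
    }
  }
  best <- .lm_multistart(starts, rfun, lower, upper)
  par <- best$par
  if (!free_rd) par <- c(par, rd = rd_fixed)
  names(par) <- c("alpha", "theta", "ymax", "rd")
  list(par = par, converged = best$info %in% 1:3)
}

.derived_from_params <- function(model, par, i_max) {
  if (model == "ye") {
    d <- tryCatch(
      ye_derived(par[["alpha"]], par[["beta"]], par[["gamma"]], par[["rd"]]),
      error = function(e) list(y_max = NA_real_, i_sat = NA_real_,
                               i_c = NA_real_, asymptotic = NA))
    list(y_max = d$y_max, i_sat = d$i_sat, i_c = d$i_c,
         asymptotic = d$asymptotic)
  } else {
    ic <- if (par[["rd"]] > 0 && par[["ymax"]] > par[["rd"]])
      nh_light_compensation(par[["alpha"]], par[["theta"]], par[["ymax"]],
                            par[["rd"]])
    else NA_real_
    list(y_max = par[["ymax"]] - par[["rd"]], i_sat = NA_real_, i_c = ic,
         asymptotic = TRUE,
         asymptote_gap = nh_asymptote_gap(par[["alpha"]], par[["theta"]],
                                          par[["ymax"]], i_max, par[["rd"]]))
  }
}

#' Fit a light-response model to one replicate curve
#'
#' Estimates the Ye (nonasymptotic) or NH (non-rectangular hyperbola)
#' parameters for one of the four response families — net photosynthesis
#' (`"an"`), total PSII electron flow (`"j"`), or its carboxylation
#' (`"jc"`) and oxygenation (`"jo"`) streams — by bounded
#' Levenberg-Marquardt least squares with a deterministic multi-start
#' (both families have shallow valleys for which a single start is not
#' reliable). Electron-flow curves pass through the origin, so their
#' respiration offset is fixed at 0; for `"an"` the dark respiration is a
#' free parameter unless pinned with `fix_rd`.
#'
#' Derived quantities (curve maximum, saturation irradiance, light
#' compensation point) are propagated from the estimates: for the Ye model
#' via the closed forms of [ye_derived()]; for the NH model the reported
#' maximum is the (net) asymptote itself and the saturation irradiance is
#' undefined, the asymptotic form having none.
#'
#' @param data Data frame holding one replicate's steps.
#' @param model `"ye"` or `"nh"`.
#' @param response One of `"an"`, `"j"`, `"jc"`, `"jo"`; picks the default
#'   response column (`a_n`, `j`, `j_c`, `j_o`) and the respiration
#'   handling.
#' @param fix_rd Optional non-negative value pinning the dark respiration
#'   of an `"an"` fit (e.g. the measured exchange at I = 0).
#' @param i_col,y_col Column names for irradiance and response; `y_col`
#'   defaults from `response`.
#' @return An object of class `"lrc_fit"`: a list with elements `model`,
#'   `response`, `params` (named vector), `derived`, `fitted`, `residuals`,
#'   `r_squared`, `sse`, `sst`, `converged`, `n_obs`, `data`, `replicate`
#'   and `call`. Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @examples
#' steps <- data.frame(i = c(2000, 1500, 1000, 600, 300, 150, 50, 0))
#' steps$a_n <- ye_predict(steps$i, 0.059, 1.40e-4, 5.76e-4, 3.76)
#' fit <- fit_lrc(steps, model = "ye", response = "an")
#' coef(fit)
#' summary(fit)
#' @export
fit_lrc <- function(data, model = c("ye", "nh"),
                    response = c("an", "j", "jc", "jo"),
                    fix_rd = NULL, i_col = "i", y_col = NULL) {
  model <- match.arg(model)
  response <- match.arg(response)
  if (is.null(y_col)) y_col <- .response_col[[response]]
  if (!is.data.frame(data))
    stop("'data' must be a data frame", call. = FALSE)
  if (!all(c(i_col, y_col) %in% names(data)))
    stop("'data' must have columns '", i_col, "' and '", y_col, "'",
         call. = FALSE)
  keep <- is.finite(data[[i_col]]) & is.finite(data[[y_col]])
  i <- data[[i_col]][keep]
  y <- data[[y_col]][keep]
  if (any(i < 0)) stop("irradiances must be non-negative", call. = FALSE)
  if (anyDuplicated(i)) stop("irradiance levels must be unique", call. = FALSE)
  if (length(unique(i)) < 5L)
    stop("need at least 5 distinct irradiance levels", call. = FALSE)

  free_rd <- response == "an" && is.null(fix_rd)
  rd_fixed <- if (response == "an") {
    if (is.null(fix_rd)) NA_real_ else {
      if (!is.finite(fix_rd) || fix_rd < 0)
        stop("'fix_rd' must be non-negative", call. = FALSE)
      fix_rd
    }
  } else 0

  eng <- if (model == "ye") .fit_ye_engine(i, y, free_rd, rd_fixed)
         else .fit_nh_engine(i, y, free_rd, rd_fixed)
  par <- eng$par
  pred <- if (model == "ye")
    ye_predict(i, par[["alpha"]], par[["beta"]], par[["gamma"]], par[["rd"]])
  else
    nh_predict(i, par[["alpha"]], par[["theta"]], par[["ymax"]], par[["rd"]])
  gof <- goodness_of_fit(y, pred)

  structure(list(
    model = model, response = response, params = par,
    derived = .derived_from_params(model, par, max(i)),
    fitted = pred, residuals = y - pred,
    r_squared = gof$r_squared, sse = gof$sse, sst = gof$sst,
    converged = eng$converged, n_obs = length(i),
    n_par = if (model == "ye") 3L + free_rd else 3L + free_rd,
    data = data.frame(i = i, y = y),
    replicate = if ("replicate" %in% names(data))
      as.character(data$replicate[keep][1]) else NA_character_,
    call = match.call()), class = "lrc_fit")
}

#' Fit every replicate of a dataset independently
#'
#' Splits `data` by its replicate column and applies [fit_lrc()] to each
#' replicate curve, preserving order. A failing replicate does not abort
#' the rest: its slot carries the error message (class `"lrc_fit_error"`).
#'
#' @inheritParams fit_lrc
#' @param replicate_col Name of the replicate identifier column.
#' @param ... Passed on to [fit_lrc()].
#' @return A list of `lrc_fit` objects of class `"lrc_fit_list"`.
#' @examples
#' sim <- simulate_an_curves(fixture_table1()$gmax_an$params,
#'                           n_replicates = 3, noise_sd = 0, seed = 1)
#' fits <- fit_replicates(sim, model = "ye", response = "an")
#' summary(fits)
#' @export
fit_replicates <- function(data, model = c("ye", "nh"),
                           response = c("an", "j", "jc", "jo"),
                           replicate_col = "replicate", ...) {
  model <- match.arg(model)
  response <- match.arg(response)
  if (!is.data.frame(data) || nrow(data) == 0L)
    stop("'data' must be a non-empty data frame", call. = FALSE)
  if (!replicate_col %in% names(data))
    stop("no replicate column '", replicate_col, "'", call. = FALSE)
  ids <- unique(data[[replicate_col]])
  fits <- lapply(ids, function(id) {
    sub <- data[data[[replicate_col]] == id, , drop = FALSE]
    tryCatch(fit_lrc(sub, model = model, response = response, ...),
             error = function(e) structure(
               list(replicate = as.character(id),
                    message = conditionMessage(e)),
               class = "lrc_fit_error"))
  })
  names(fits) <- as.character(ids)
  structure(fits, class = "lrc_fit_list", model = model, response = response)
}
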