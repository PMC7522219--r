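# S3 methods for lrc_fit and lrc_fit_list.

.model_label <- c(ye = "Ye (nonasymptotic)", nh = "non-rectangular hyperbola")
.response_label <- c(an = "A_n-I", j = "J-I", jc = "J_C-I", jo = "J_O-I")

#' @export
print.lrc_fit <- function(x, digits = 4, ...) {
  cat(.model_label[[x$model]], "fit,", .response_label[[x$response]],
      "curve", if (!is.na(x$replicate)) paste0("(replicate ", x$replicate, ")"),
      "\n")
  cat("Coefficients:\n")
  print(signif(x$params, digits))
  d <- x$derived
  cat("Maximum:", format(signif(d$y_max, digits)),
      if (isTRUE(d$asymptotic)) "(asymptote)" else
        paste("at I_sat =", format(signif(d$i_sat, digits))), "\n")
  if (!is.na(d$i_c))
    cat("Light compensation point:", format(signif(d$i_c, digits)), "\n")
  cat("R-squared:", format(signif(x$r_squared, digits)),
      " SSE:", format(signif(x$sse, digits)),
      " n =", x$n_obs,
      if (!x$converged) " [did not converge]", "\n")
  invisible(x)
}

#' @export
summary.lrc_fit <- function(object, ...) {
  sigma <- sqrt(object$sse / max(object$n_obs - object$n_par, 1))
  structure(list(fit = object, sigma = sigma), class = "summary.lrc_fit")
}

#' @export
print.summary.lrc_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("Residual standard deviation:", format(signif(x$sigma, digits)), "\n")
  invisible(x)
}

#' @export
coef.lrc_fit <- function(object, ...) object$params

#' @export
fitted.lrc_fit <- function(object, ...) object$fitted

#' @export
residuals.lrc_fit <- function(object, ...) object$residuals

#' Predict from a fitted light-response curve
#'
#' @param object An `lrc_fit`.
#' @param newdata Optional data frame with an `i` column, or a numeric
#'   vector of irradiances; defaults to the fitted irradiances.
#' @param ... Unused.
#' @return Predicted responses (umol m-2 s-1).
#' @export
predict.lrc_fit <- function(object, newdata = NULL, ...) {
  i <- if (is.null(newdata)) object$data$i
       else if (is.data.frame(newdata)) newdata$i
       else as.numeric(newdata)
  p <- object$params
  if (object$model == "ye")
    ye_predict(i, p[["alpha"]], p[["beta"]], p[["gamma"]], p[["rd"]])
  else
    nh_predict(i, p[["alpha"]], p[["theta"]], p[["ymax"]], p[["rd"]])
}

#' Plot a fitted light-response curve
#'
#' Measured steps as points, the fitted model as a line.
#'
#' @param x An `lrc_fit`.
#' @param n Number of grid points for the fitted line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lrc_fit <- function(x, n = 200, ...) {
  grid <- seq(0, max(x$data$i), length.out = n)
  ylab <- switch(x$response,
                 an = expression(A[n] ~ (mu * mol ~ m^-2 ~ s^-1)),
                 j = expression(J ~ (mu * mol ~ e^"-" ~ m^-2 ~ s^-1)),
                 jc = expression(J[C] ~ (mu * mol ~ e^"-" ~ m^-2 ~ s^-1)),
                 jo = expression(J[O] ~ (mu * mol ~ e^"-" ~ m^-2 ~ s^-1)))
  graphics::plot(x$data$i, x$data$y,
                 xlab = expression(I ~ (mu * mol ~ photons ~ m^-2 ~ s^-1)),
                 ylab = ylab, ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' Simulate new response vectors from a fitted curve
#'
#' Draws Gaussian noise with the residual standard deviation around the
#' fitted values, the same error model the synthetic-data generator uses.
#'
#' @param object An `lrc_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, one row per fitted step.
#' @export
simulate.lrc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$sse / max(object$n_obs - object$n_par, 1))
  out <- replicate(nsim, object$fitted +
                     stats::rnorm(object$n_obs, 0, sigma))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.lrc_fit_list <- function(x, ...) {
  cat(length(x), "replicate fit(s),", .model_label[[attr(x, "model")]],
      "model,", .response_label[[attr(x, "response")]], "curve\n")
  print(summary(x), ...)
  invisible(x)
}

#' Tabulate per-replicate parameter and derived-quantity estimates
#'
#' @param object An `lrc_fit_list` from [fit_replicates()].
#' @param ... Unused.
#' @return A data frame, one row per replicate (failed replicates carry
#'   `NA`s and the error message).
#' @export
summary.lrc_fit_list <- function(object, ...) {
  rows <- lapply(seq_along(object), function(k) {
    f <- object[[k]]
    if (inherits(f, "lrc_fit_error"))
      return(data.frame(replicate = names(object)[k], alpha = NA_real_,
                        y_max = NA_real_, i_sat = NA_real_, i_c = NA_real_,
                        rd = NA_real_, r_squared = NA_real_, sse = NA_real_,
                        converged = FALSE, error = f$message))
    data.frame(replicate = names(object)[k],
               alpha = f$params[["alpha"]],
               y_max = f$derived$y_max,
               i_sat = f$derived$i_sat,
               i_c = f$derived$i_c,
               rd = f$params[["rd"]],
               r_squared = f$r_squared, sse = f$sse,
               converged = f$converged, error = NA_character_)
  })
  do.call(rbind, rows)
}

#' @export
print.respiration_spec <- function(x, ...) {
  cat("Respiration: r_d =", format(x$r_d), " r_day =", format(x$r_day), "\n")
  invisible(x)
}
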