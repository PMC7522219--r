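# Independent oracles and random-case generators used across the suite.
# These deliberately avoid the closed forms they check.

# Brute-force maximum of the Ye curve on a fine irradiance grid.
grid_argmax_ye <- function(alpha, beta, gamma, rd = 0, upper, step = 0.1) {
  grid <- seq(0, upper, by = step)
  y <- alpha * (1 - beta * grid) * grid / (1 + gamma * grid) - rd
  k <- which.max(y)
  list(i = grid[k], y = y[k])
}

# Simple bisection root finder (for compensation-point cross-checks).
bisect_zero <- function(f, lo, hi, tol = 1e-10, maxit = 200) {
  flo <- f(lo); fhi <- f(hi)
  stopifnot(flo * fhi <= 0)
  for (k in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (flo * fm <= 0) { hi <- mid; fhi <- fm } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

# Random valid Ye parameter draws (physiologically plausible envelopes;
# negative gamma included). Returns a data frame of n rows.
draw_ye_params <- function(n, rd_range = c(0, 0)) {
  out <- data.frame(alpha = numeric(0), beta = numeric(0),
                    gamma = numeric(0), rd = numeric(0))
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out))
    cand <- data.frame(
      alpha = runif(m, 0.03, 0.35),
      beta = runif(m, 5e-5, 1e-3),
      gamma = runif(m, -1e-4, 2e-3),
      rd = runif(m, rd_range[1], rd_range[2]))
    ok <- cand$beta + cand$gamma > 2e-5
    out <- rbind(out, cand[ok, ])
  }
  out[seq_len(n), ]
}

# Random valid NH parameter draws (theta kept off both bounds).
draw_nh_params <- function(n, rd_range = c(0, 0)) {
  data.frame(alpha = runif(n, 0.03, 0.35),
             theta = runif(n, 0.3, 0.97),
             ymax = runif(n, 20, 400),
             rd = runif(n, rd_range[1], rd_range[2]))
}

# Noiseless single-replicate curve data frame from a Ye truth.
ye_curve_data <- function(p, steps = light_steps("soybean"),
                          col = "a_n") {
  d <- data.frame(replicate = "rep1", i = steps)
  d[[col]] <- ye_predict(steps, p[["alpha"]], p[["beta"]], p[["gamma"]],
                         p[["rd"]])
  d
}

nh_curve_data <- function(p, steps = light_steps("soybean"),
                          col = "a_n") {
  d <- data.frame(replicate = "rep1", i = steps)
  d[[col]] <- nh_predict(steps, p[["alpha"]], p[["theta"]], p[["ymax"]],
                         p[["rd"]])
  d
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = paste0("relative difference ",
                             format(max(abs(actual - expected) /
                                          pmax(abs(expected), 1e-300))),
                             " exceeds ", format(tol)))
}
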