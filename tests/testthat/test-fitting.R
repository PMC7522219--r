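fx <- fixture_table1()

test_that("goodness_of_fit computes 1 - SSE/SST", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g$sse, 1)
  expect_equal(g$sst, 2)
  expect_equal(g$r_squared, 0.5)
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r_squared, 1)
  expect_equal(g$sse, 0)
  # predicting the mean gives r2 = 0
  g <- goodness_of_fit(c(1, 2, 3), rep(2, 3))
  expect_equal(g$r_squared, 0)
  expect_error(goodness_of_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(goodness_of_fit(1:3, 1:4), "equal length")
})

test_that("Ye fit recovers a noiseless truth at the measured steps", {
  p <- fx$gmax_an$params
  fit <- fit_lrc(ye_curve_data(p), model = "ye", response = "an")
  expect_true(fit$converged)
  expect_rel_equal(coef(fit), p, 1e-4)
  # derived quantities propagate from the estimates
  expect_rel_equal(fit$derived$y_max,
                   ye_derived(p[["alpha"]], p[["beta"]], p[["gamma"]],
                              p[["rd"]])$y_max, 1e-3)
  # perfect linear data: r2 = 1 to numerical precision
  d <- data.frame(i = c(0, 50, 100, 200, 400, 800),
                  a_n = 0.1 * c(0, 50, 100, 200, 400, 800) - 1)
  fit <- fit_lrc(d, model = "ye", response = "an")
  expect_gte(fit$r_squared, 1 - 1e-10)
})

test_that("electron-flow fits pin the offset at zero", {
  p <- fx$gmax_jc$params
  fit <- fit_lrc(ye_curve_data(p, col = "j_c"), model = "ye",
                 response = "jc")
  expect_identical(unname(coef(fit)[["rd"]]), 0)
  expect_rel_equal(coef(fit)[c("alpha", "beta", "gamma")],
                   p[c("alpha", "beta", "gamma")], 1e-4)
  expect_rel_equal(fit$derived$y_max,
                   ye_derived(p[["alpha"]], p[["beta"]], p[["gamma"]])$y_max,
                   1e-3)
})

test_that("fix_rd pins the respiration of a net-photosynthesis fit", {
  p <- fx$gmax_an$params
  fit <- fit_lrc(ye_curve_data(p), model = "ye", response = "an",
                 fix_rd = 3.76)
  expect_identical(unname(coef(fit)[["rd"]]), 3.76)
  expect_rel_equal(coef(fit), p, 1e-4)
})

test_that("NH fit recovers a noiseless truth and flags the asymptote", {
  p <- fx$gmax_j_nh$params
  fit <- fit_lrc(nh_curve_data(p, col = "j"), model = "nh", response = "j")
  expect_rel_equal(coef(fit)[c("alpha", "theta", "ymax")],
                   p[c("alpha", "theta", "ymax")], 1e-4)
  expect_true(is.na(fit$derived$i_sat))
  expect_true(fit$derived$asymptotic)
  expect_gt(fit$derived$asymptote_gap, 0)
})

test_that("theta converges to its upper bound on Blackman-like data", {
  steps <- light_steps("soybean")
  d <- data.frame(i = steps, j = pmin(0.3 * steps, 250))
  fit <- fit_lrc(d, model = "nh", response = "j")
  expect_equal(unname(coef(fit)[["theta"]]), 1, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
})

test_that("NH fitted maximum overshoots a photoinhibited Ye truth", {
  p <- fx$gmax_an$params
  true_max <- ye_derived(p[["alpha"]], p[["beta"]], p[["gamma"]],
                         p[["rd"]])$y_max
  fit <- fit_lrc(ye_curve_data(p), model = "nh", response = "an")
  expect_gt(fit$derived$y_max, true_max)
})

test_that("stored goodness-of-fit is consistent with stored residuals", {
  p <- fx$taes_an$params
  d <- ye_curve_data(p, steps = light_steps("wheat"))
  set.seed(2)
  d$a_n <- d$a_n + rnorm(nrow(d), 0, 0.5)
  for (m in c("ye", "nh")) {
    fit <- fit_lrc(d, model = m, response = "an")
    sse <- sum(fit$residuals^2)
    sst <- sum((fit$data$y - mean(fit$data$y))^2)
    expect_equal(fit$sse, sse, tolerance = 1e-12)
    expect_equal(fit$r_squared, 1 - sse / sst, tolerance = 1e-12)
    expect_equal(fitted(fit) + residuals(fit), fit$data$y)
  }
})

test_that("both models re-find random noiseless truths (multi-start)", {
  set.seed(31)
  yes <- draw_ye_params(15, rd_range = c(0.5, 5))
  for (k in seq_len(nrow(yes))) {
    p <- unlist(yes[k, ])
    fit <- fit_lrc(ye_curve_data(p), model = "ye", response = "an")
    expect_rel_equal(coef(fit), p, 1e-4)
  }
  nhs <- draw_nh_params(15, rd_range = c(0.5, 5))
  for (k in seq_len(nrow(nhs))) {
    p <- unlist(nhs[k, ])
    fit <- fit_lrc(nh_curve_data(p), model = "nh", response = "an")
    expect_rel_equal(coef(fit), p, 1e-4)
  }
})

test_that("fit_lrc validates its input table", {
  expect_error(fit_lrc(data.frame(i = 1:3, a_n = 1:3), "ye", "an"),
               "at least 5")
  expect_error(fit_lrc(data.frame(i = c(0, 0, 100, 200, 300),
                                  a_n = 1:5), "ye", "an"), "unique")
  expect_error(fit_lrc(data.frame(x = 1:6, a_n = 1:6), "ye", "an"),
               "columns")
})

test_that("fit_replicates fits each curve independently, keeping order", {
  p <- fx$gmax_an$params
  one <- ye_curve_data(p)
  d <- do.call(rbind, lapply(1:3, function(r)
    transform(one, replicate = paste0("leaf", r))))
  fits <- fit_replicates(d, model = "ye", response = "an")
  expect_s3_class(fits, "lrc_fit_list")
  expect_named(fits, paste0("leaf", 1:3))
  cf <- sapply(fits, coef)
  expect_equal(cf[, 1], cf[, 2])
  expect_equal(cf[, 1], cf[, 3])
  # a broken replicate yields an error record, not an abort
  bad <- data.frame(replicate = "leaf4", i = c(0, 50), a_n = c(-3, 1))
  fits <- fit_replicates(rbind(d, bad), model = "ye", response = "an")
  expect_s3_class(fits$leaf4, "lrc_fit_error")
  expect_false(summary(fits)$converged[4])
  expect_error(fit_replicates(data.frame(), "ye", "an"), "non-empty")
})

test_that("fit methods print, predict, plot and simulate coherently", {
  p <- fx$gmax_an$params
  fit <- fit_lrc(ye_curve_data(p), model = "ye", response = "an")
  expect_output(print(fit), "Ye")
  expect_output(print(summary(fit)), "Residual standard deviation")
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, 0), -coef(fit)[["rd"]])
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_equal(dim(sims), c(fit$n_obs, 2L))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})
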