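test_that("observed extrema: maximum, dark exchange, interpolated i_c", {
  steps <- data.frame(i = c(0, 50, 100, 200), a_n = c(-4, -1, 2, 8))
  o <- observed_extrema(steps)
  expect_equal(o$y_obs_max, 8)
  expect_equal(o$i_at_max, 200)
  expect_equal(o$r_d_obs, 4)
  # linear interpolation between (50, -1) and (100, 2): 50 + 50/3
  expect_equal(o$i_c_obs, 50 + 50 / 3)
  # monotone curve peaking at the brightest step
  steps <- data.frame(i = c(100, 400, 800, 1600), a_n = c(5, 12, 18, 21))
  o <- suppressWarnings(observed_extrema(steps))
  expect_equal(o$i_at_max, 1600)
  expect_true(is.na(o$r_d_obs))
  # all-negative curve has no observable compensation point
  expect_warning(o <- observed_extrema(
    data.frame(i = c(0, 50, 100), a_n = c(-4, -3, -2))), "no sign change")
  expect_true(is.na(o$i_c_obs))
})

test_that("observed maximum cannot exceed the continuous Ye maximum", {
  set.seed(17)
  pars <- draw_ye_params(50)
  steps <- light_steps("soybean")
  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    y <- ye_predict(steps, p$alpha, p$beta, p$gamma)
    d <- ye_derived(p$alpha, p$beta, p$gamma)
    expect_lte(max(y), d$y_max)
  }
})

# Independent brute-force one-way ANOVA F from raw sums of squares.
anova_oracle <- function(values) {
  all_v <- unlist(values)
  grand <- mean(all_v)
  ssb <- sum(vapply(values, function(v)
    length(v) * (mean(v) - grand)^2, numeric(1)))
  ssw <- sum(vapply(values, function(v)
    sum((v - mean(v))^2), numeric(1)))
  dfb <- length(values) - 1
  dfw <- length(all_v) - length(values)
  (ssb / dfb) / (ssw / dfw)
}

test_that("one-way ANOVA matches brute-force sums of squares", {
  # hand-computed instance: third group shifted by 10
  # SSB = 3[(2-16/3)^2 + (2-16/3)^2 + (12-16/3)^2] = 200, SSW = 6,
  # F = (200/2)/(6/6) = 100 with df (2, 6)
  vals <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(11, 12, 13))
  res <- groups_anova(vals)
  expect_equal(res$f_statistic, 100)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$f_statistic, anova_oracle(vals))
  # shifted group carries its own letter; identical groups share one
  expect_equal(res$groups$letter[res$groups$label == "c"], "a")
  expect_equal(res$groups$letter[res$groups$label == "a"],
               res$groups$letter[res$groups$label == "b"])
  expect_false(res$groups$letter[3] %in% res$groups$letter[1:2])
  # random instances against the oracle
  set.seed(23)
  for (k in 1:20) {
    vals <- lapply(1:3, function(g) rnorm(sample(3:6, 1), mean = g))
    names(vals) <- c("x", "y", "z")
    res <- groups_anova(vals)
    expect_equal(res$f_statistic, anova_oracle(vals), tolerance = 1e-10)
  }
})

test_that("identical groups give F = 0, p = 1, one shared letter", {
  res <- groups_anova(list(Ye = c(1, 2, 3), NH = c(1, 2, 3),
                           Obs = c(1, 2, 3)))
  expect_equal(res$f_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(unique(res$groups$letter), "a")
})

test_that("two-group ANOVA reduces to the pooled-variance t-test", {
  set.seed(29)
  x <- rnorm(5, 10); y <- rnorm(6, 12)
  res <- groups_anova(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate and undersized groups are rejected", {
  expect_error(groups_anova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
  expect_error(groups_anova(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(groups_anova(list(a = c(1, 2))), "2 groups")
})

test_that("comparison table mirrors the fitted-vs-observed layout", {
  fx <- fixture_table1()
  sim <- simulate_an_curves(fx$gmax_an$params, n_replicates = 3,
                            noise_sd = 0.02, seed = 42)
  cmp <- compare_models(sim, response = "an")
  tab <- cmp$table
  expect_setequal(unique(tab$quantity), c("y_max", "i_sat", "i_c", "r_d",
                                          "sse"))
  # NH contributes no saturation irradiance (asymptotic model)
  expect_false("NH" %in% tab$group[tab$quantity == "i_sat"])
  expect_setequal(tab$group[tab$quantity == "y_max"], c("Ye", "NH", "Obs"))
  # the headline pattern: asymptotic maximum above the observed one,
  # nonasymptotic maximum in close agreement (shared Tukey letter)
  ym <- tab[tab$quantity == "y_max", ]
  expect_gt(ym$mean[ym$group == "NH"], ym$mean[ym$group == "Obs"])
  expect_equal(ym$letter[ym$group == "Ye"], ym$letter[ym$group == "Obs"])
  expect_output(print(cmp), "comparison")
})

test_that("comparison works single-model and degrades on noiseless data", {
  fx <- fixture_table1()
  sim <- simulate_an_curves(fx$gmax_an$params, n_replicates = 3,
                            noise_sd = 0, seed = 1)
  cmp <- suppressWarnings(
    compare_models(sim, response = "an", models = "ye"))
  ym <- cmp$table[cmp$table$quantity == "y_max", ]
  expect_setequal(ym$group, c("Ye", "Obs"))
  # noiseless replicates are identical: Ye maxima equal across replicates
  expect_lt(ym$se[ym$group == "Ye"], 1e-6)
  expect_error(compare_models(sim[sim$replicate == "rep1", ], "an"),
               "2 replicates")
})
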