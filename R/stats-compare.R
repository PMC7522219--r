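# Replicate summaries, observed extrema, one-way ANOVA with Tukey letters,
# and the model-vs-observation intercomparison table.

#' Observed extrema of a measured light-response curve
#'
#' Extracts the model-free "observed" quantities that the fitted ones are
#' compared against: the largest measured response and the irradiance of
#' that step; and, for net-photosynthesis curves, the measured dark
#' exchange (`r_d_obs = -y` at `i = 0`, when that step exists) and the
#' observed light compensation point, obtained by linear interpolation of
#' the zero crossing between the two steps bracketing `y = 0`.
#'
#' @param steps Data frame with irradiance and response columns.
#' @param i_col,y_col Column names (defaults `i`, `a_n`).
#' @param net Logical; compute `r_d_obs` and `i_c_obs` (only meaningful for
#'   net-photosynthesis curves). Default `TRUE` when `y_col` is `"a_n"`.
#' @return List with `y_obs_max`, `i_at_max`, and (for net curves)
#'   `r_d_obs` and `i_c_obs` (`NA` when the I = 0 step or a sign change is
#'   absent, the latter with a warning).
#' @examples
#' observed_extrema(data.frame(i = c(0, 50, 100, 200),
#'                             a_n = c(-4, -1, 2, 8)))
#' @export
observed_extrema <- function(steps, i_col = "i", y_col = "a_n",
                             net = identical(y_col, "a_n")) {
  if (!is.data.frame(steps) || nrow(steps) == 0L)
    stop("'steps' must be a non-empty data frame", call. = FALSE)
  if (!all(c(i_col, y_col) %in% names(steps)))
    stop("missing column(s)", call. = FALSE)
  i <- steps[[i_col]]
  y <- steps[[y_col]]
  keep <- is.finite(i) & is.finite(y)
  i <- i[keep]; y <- y[keep]
  k <- which.max(y)
  out <- list(y_obs_max = y[k], i_at_max = i[k])
  if (net) {
    out$r_d_obs <- if (any(i == 0)) -y[i == 0][1] else NA_real_
    ord <- order(i)
    io <- i[ord]; yo <- y[ord]
    cross <- which(yo[-length(yo)] < 0 & yo[-1] >= 0)
    if (length(cross)) {
      k <- cross[1]
      out$i_c_obs <- io[k] + (0 - yo[k]) * (io[k + 1] - io[k]) /
        (yo[k + 1] - yo[k])
    } else {
      warning("no sign change: observed light compensation point undefined",
              call. = FALSE)
      out$i_c_obs <- NA_real_
    }
  }
  out
}

# Homogeneous-subset letters from a symmetric "not significantly different"
# matrix: each maximal clique of consecutive mean-ordered groups gets one
# letter (valid because Tukey NS sets on ordered means are intervals).
.subset_letters <- function(ns, means) {
  g <- length(means)
  ord <- order(means, decreasing = TRUE)
  ranges <- list()
  for (a in seq_len(g)) {
    b <- a
    while (b < g && all(ns[ord[a:(b + 1)], ord[a:(b + 1)]]))
      b <- b + 1
    ranges[[length(ranges) + 1L]] <- a:b
  }
  # drop ranges contained in another
  keep <- vapply(seq_along(ranges), function(k)
    !any(vapply(seq_along(ranges), function(m)
      m != k && all(ranges[[k]] %in% ranges[[m]]), logical(1))), logical(1))
  ranges <- ranges[keep]
  letters_out <- rep("", g)
  for (k in seq_along(ranges))
    letters_out[ord[ranges[[k]]]] <- paste0(letters_out[ord[ranges[[k]]]],
                                            letters[k])
  letters_out
}

#' One-way ANOVA across labelled groups with Tukey letters
#'
#' Classical one-way ANOVA over two or more groups of replicate values,
#' followed by pairwise Tukey HSD at `alpha`; groups sharing a letter are
#' not significantly different. Used to compare fitted (Ye, NH) and
#' observed values of each derived quantity across replicates.
#'
#' @param values A named list of numeric vectors, each of length `>= 2`.
#' @param alpha Significance level for the Tukey letters. Default 0.05.
#' @return A list of class `"lrc_anova"`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `groups` (data frame with label, n, mean, se,
#'   letter), and the Tukey `p_adj` matrix.
#' @examples
#' groups_anova(list(Ye = c(1, 2, 3), NH = c(11, 12, 13), Obs = c(1, 2, 3)))
#' @export
groups_anova <- function(values, alpha = 0.05) {
  if (!is.list(values) || length(values) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    names(values) <- paste0("group", seq_along(values))
  n <- vapply(values, length, integer(1))
  if (any(n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  all_v <- unlist(values, use.names = FALSE)
  if (stats::var(all_v) == 0)
    stop("degenerate data: total variance is zero", call. = FALSE)
  df <- data.frame(value = all_v,
                   group = factor(rep(names(values), n),
                                  levels = names(values)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- stats::anova(fit)
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  means <- vapply(values, mean, numeric(1))
  ses <- vapply(values, function(v) stats::sd(v) / sqrt(length(v)),
                numeric(1))
  # pairwise Tukey HSD "not significantly different" matrix
  g <- length(values)
  ns <- matrix(TRUE, g, g, dimnames = list(names(values), names(values)))
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  p_adj <- matrix(NA_real_, g, g, dimnames = dimnames(ns))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    pa <- tk[r, "p adj"]
    p_adj[pair[1], pair[2]] <- p_adj[pair[2], pair[1]] <- pa
    # NaN p arises with zero within-group variance: any mean difference
    # is then trivially significant
    sig <- if (is.na(pa)) abs(diff(means[pair])) > 1e-12 else pa < alpha
    if (sig)
      ns[pair[1], pair[2]] <- ns[pair[2], pair[1]] <- FALSE
  }
  letter <- .subset_letters(ns, means)
  structure(list(
    f_statistic = f, df_between = tab$Df[1], df_within = tab$Df[2],
    p_value = p,
    groups = data.frame(label = names(values), n = n, mean = means,
                        se = ses, letter = letter, row.names = NULL),
    p_adj = p_adj), class = "lrc_anova")
}

#' @export
print.lrc_anova <- function(x, digits = 4, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      format(signif(x$f_statistic, digits)),
      ", p = ", format(signif(x$p_value, digits)), "\n", sep = "")
  print(x$groups, digits = digits)
  invisible(x)
}

.cmp_quantities <- list(
  y_max = "maximum response", i_sat = "saturation irradiance",
  i_c = "light compensation point", r_d = "dark respiration",
  sse = "residual sum of squares")

#' Model-versus-observation intercomparison across replicates
#'
#' Fits the requested models to every replicate curve, extracts each
#' derived quantity per replicate together with its observed counterpart,
#' and runs a one-way ANOVA with Tukey letters across the groups — the
#' standard fitted-vs-measured comparison layout. For `"an"` curves the
#' quantities are the maximum, the saturation irradiance, the light
#' compensation point, the dark respiration and the residual SS; for
#' electron-flow curves, the maximum, the saturation irradiance and the
#' residual SS. The NH model contributes no saturation irradiance (its
#' maximum is an asymptote); the observed saturation irradiance is the
#' irradiance of the largest measured step, and the observed compensation
#' point is interpolated ([observed_extrema()]).
#'
#' @inheritParams fit_replicates
#' @param models Character vector, subset of `c("ye", "nh")`.
#' @param fix_rd Optional pinned dark respiration passed to [fit_lrc()].
#' @param alpha Significance level for Tukey letters.
#' @return An object of class `"lrc_comparison"`: `table` (long data frame
#'   with quantity, group, n, mean, se, letter), `anova` (per-quantity
#'   [groups_anova()] results), `fits` (per-model `lrc_fit_list`s), and
#'   metadata.
#' @examples
#' sim <- simulate_an_curves(fixture_table1()$gmax_an$params,
#'                           n_replicates = 3, noise_sd = 0.02, seed = 42)
#' cmp <- compare_models(sim, response = "an")
#' cmp$table
#' @export
compare_models <- function(data, response = c("an", "j", "jc", "jo"),
                           models = c("ye", "nh"), replicate_col = "replicate",
                           fix_rd = NULL, alpha = 0.05, ...) {
  response <- match.arg(response)
  models <- match.arg(models, c("ye", "nh"), several.ok = TRUE)
  if (!replicate_col %in% names(data))
    stop("no replicate column '", replicate_col, "'", call. = FALSE)
  ids <- unique(data[[replicate_col]])
  if (length(ids) < 2L) stop("need at least 2 replicates", call. = FALSE)
  y_col <- .response_col[[response]]

  fits <- lapply(models, function(m)
    fit_replicates(data, model = m, response = response,
                   replicate_col = replicate_col, fix_rd = fix_rd, ...))
  names(fits) <- models

  obs <- lapply(ids, function(id) {
    sub <- data[data[[replicate_col]] == id, , drop = FALSE]
    observed_extrema(sub, y_col = y_col, net = response == "an")
  })

  label <- c(ye = "Ye", nh = "NH")
  pull <- function(m, what) {
    v <- vapply(fits[[m]], function(f) {
      if (inherits(f, "lrc_fit_error")) return(NA_real_)
      switch(what,
             y_max = f$derived$y_max, i_sat = f$derived$i_sat,
             i_c = f$derived$i_c, r_d = f$params[["rd"]], sse = f$sse)
    }, numeric(1))
    v
  }
  pull_obs <- function(what) vapply(obs, function(o)
    switch(what, y_max = o$y_obs_max, i_sat = o$i_at_max,
           i_c = if (is.null(o$i_c_obs)) NA_real_ else o$i_c_obs,
           r_d = if (is.null(o$r_d_obs)) NA_real_ else o$r_d_obs,
           sse = NA_real_), numeric(1))

  quantities <- if (response == "an") c("y_max", "i_sat", "i_c", "r_d", "sse")
                else c("y_max", "i_sat", "sse")
  tab_rows <- list()
  anovas <- list()
  for (q in quantities) {
    grp <- list()
    for (m in models) {
      v <- pull(m, q)
      if (sum(is.finite(v)) >= 2L) grp[[label[[m]]]] <- v[is.finite(v)]
    }
    v <- pull_obs(q)
    if (sum(is.finite(v)) >= 2L) grp[["Obs"]] <- v[is.finite(v)]
    if (!length(grp)) next
    an <- if (length(grp) >= 2L)
      tryCatch(groups_anova(grp, alpha = alpha), error = function(e) NULL)
    else NULL
    anovas[[q]] <- an
    for (gname in names(grp)) {
      v <- grp[[gname]]
      tab_rows[[length(tab_rows) + 1L]] <- data.frame(
        quantity = q, group = gname, n = length(v), mean = mean(v),
        se = stats::sd(v) / sqrt(length(v)),
        letter = if (!is.null(an))
          an$groups$letter[an$groups$label == gname] else NA_character_,
        f_statistic = if (!is.null(an)) an$f_statistic else NA_real_,
        p_value = if (!is.null(an)) an$p_value else NA_real_)
    }
  }
  structure(list(table = do.call(rbind, tab_rows), anova = anovas,
                 fits = fits, response = response, models = models,
                 n_replicates = length(ids)),
            class = "lrc_comparison")
}

#' @export
print.lrc_comparison <- function(x, digits = 4, ...) {
  cat("Model-vs-observation comparison,", .response_label[[x$response]],
      "curve,", x$n_replicates, "replicates\n")
  tab <- x$table
  tab$mean <- signif(tab$mean, digits)
  tab$se <- signif(tab$se, digits)
  tab$f_statistic <- signif(tab$f_statistic, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
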