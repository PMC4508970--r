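#' Fit the interaction regression comparing two variant classes
#'
#' Ordinary least squares on the stacked data
#' `f = beta0 + beta1 * G + beta2 * D + beta3 * G * D + e`, where `f` is a
#' response (for example the proportion of alt homozygotes falling in ROH),
#' `G` the genome ROH coverage, and `D` an indicator separating the two
#' groups being compared (1 for the focal group, e.g. deleterious). A
#' two-tailed t-test on beta2 tests an intercept difference between the
#' two groups' separate regressions, and on beta3 a slope difference.
#' Rows with missing response or covariate are dropped (count reported).
#'
#' @param data A data frame.
#' @param response,coverage,indicator Columns (tidy-eval) holding f, G and
#'   the 0/1 indicator.
#' @return An object of class `roh_interaction`: the underlying `lm` plus
#'   the coefficient table (beta0-beta3 with SE, t, two-tailed p), the
#'   per-group Pearson correlation of (G, f), `n` and `n_dropped`. Use
#'   [tidy()] / [glance()] to extract results.
#' @examples
#' d <- tibble::tibble(g = rep(seq(0, 1, 0.1), 2),
#'                     d = rep(0:1, each = 11))
#' d$f <- 0.1 + 0.8 * d$g + 0.3 * d$g * d$d
#' tidy(fit_interaction_model(d, f, g, d))
#' @export
fit_interaction_model <- function(data, response, coverage, indicator) {
  df <- tibble::tibble(
    f = dplyr::pull(data, {{ response }}),
    g = dplyr::pull(data, {{ coverage }}),
    d = dplyr::pull(data, {{ indicator }})
  )
  if (any(df$g < 0 | df$g > 1, na.rm = TRUE))
    stop("coverage proportions must lie in [0, 1]")
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  df <- df[keep, ]
  for (dd in unique(df$d)) {
    if (sum(df$d == dd) < 5)
      stop("need at least 5 observations per indicator group")
  }
  if (stats::var(df$g) == 0)
    stop("coverage is constant; the model is rank-deficient")
  fit <- stats::lm(f ~ g * d, data = df)
  cf <- summary(fit)$coefficients
  coef_tbl <- tibble::tibble(
    term = c("beta0", "beta1", "beta2", "beta3"),
    estimate = unname(cf[, 1]), std.error = unname(cf[, 2]),
    statistic = unname(cf[, 3]), p.value = unname(cf[, 4])
  )
  by_group <- purrr::map_dfr(sort(unique(df$d)), function(dd) {
    sub <- df[df$d == dd, ]
    r <- pearson_with_test(sub$g, sub$f)
    dplyr::mutate(r, d = dd, .before = 1)
  })
  structure(list(fit = fit, coefficients = coef_tbl, group_cor = by_group,
                 n = nrow(df), n_dropped = n_dropped),
            class = "roh_interaction")
}

#' @export
print.roh_interaction <- function(x, ...) {
  cat("Interaction regression f ~ G * D  (n =", x$n, ")\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_interaction_model
#' @param x An `roh_interaction` object.
#' @param ... Unused.
#' @export
tidy.roh_interaction <- function(x, ...) x$coefficients

#' @rdname fit_interaction_model
#' @method glance roh_interaction
#' @export
glance.roh_interaction <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, n = x$n, n_dropped = x$n_dropped)
}

#' Interaction regressions between all pairings of ROH size classes
#'
#' For one functional class, compares the per-size-class proportions
#' f\[i, j\] across individuals between every pairing of size classes
#' (L vs M, L vs S, M vs S), fitting [fit_interaction_model()] with the
#' indicator marking the larger class of the pairing and G the coverage of
#' the respective class.
#'
#' @param f_tbl Output of [roh_proportions()].
#' @param profiles Output of [coverage_profile()].
#' @param func_class Functional class to analyse (default "deleterious").
#' @return Named list of `roh_interaction` fits
#'   (`L_vs_M`, `L_vs_S`, `M_vs_S`).
#' @export
pairwise_sizeclass_model <- function(f_tbl, profiles,
                                     func_class = "deleterious") {
  f_tbl <- dplyr::filter(f_tbl, .data$func_class == !!func_class,
                         .data$roh_class %in% c("S", "M", "L"))
  gcol <- c(S = "g_s", M = "g_m", L = "g_l")
  long <- f_tbl |>
    dplyr::left_join(profiles, by = "sample") |>
    dplyr::mutate(g = dplyr::case_when(
      .data$roh_class == "S" ~ .data$g_s,
      .data$roh_class == "M" ~ .data$g_m,
      .data$roh_class == "L" ~ .data$g_l
    ))
  pairings <- list(L_vs_M = c("L", "M"), L_vs_S = c("L", "S"),
                   M_vs_S = c("M", "S"))
  purrr::map(pairings, function(pr) {
    sub <- long[long$roh_class %in% pr, ]
    sub$d <- as.integer(sub$roh_class == pr[1])
    fit_interaction_model(sub, f, g, d)
  })
}

#' Expected change in homozygote counts from fitted regression lines
#'
#' Given the slopes and intercepts of the separate inside-ROH and
#' outside-ROH regressions of homozygote counts on genome ROH coverage G,
#' computes the expected count changes for an increase of `delta_g` in
#' coverage, and the baseline count of a non-inbred individual (G ~ 0,
#' the outside-ROH intercept). Components are rounded half-away-from-zero;
#' the net change is computed from the unrounded components and then
#' rounded (`net_from = "rounded"` sums the rounded components instead).
#'
#' @param slope_in,intercept_in Inside-ROH regression line.
#' @param slope_out,intercept_out Outside-ROH regression line.
#' @param delta_g Coverage increase (e.g. 0.10 for ten percentage points).
#' @param net_from `"unrounded"` (default) or `"rounded"`.
#' @return One-row tibble: `change_in`, `change_out`, `net`, `baseline`.
#' @examples
#' predict_counts(1568.76, -57.63, -98.67, 693.63, 0.10)
#' @export
predict_counts <- function(slope_in, intercept_in = NA_real_,
                           slope_out, intercept_out = NA_real_,
                           delta_g, net_from = c("unrounded", "rounded")) {
  net_from <- match.arg(net_from)
  stopifnot(is.finite(slope_in), is.finite(slope_out), is.finite(delta_g))
  ci <- round_half_away(slope_in * delta_g)
  co <- round_half_away(slope_out * delta_g)
  net <- if (net_from == "unrounded") {
    round_half_away(slope_in * delta_g + slope_out * delta_g)
  } else {
    ci + co
  }
  tibble::tibble(change_in = ci, change_out = co, net = net,
                 baseline = round_half_away(intercept_out))
}

#' Round half away from zero
#'
#' Commercial rounding: 0.5 rounds to 1, -0.5 to -1 (unlike base R's
#' round-half-to-even).
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Pearson correlation with a two-tailed t-test
#'
#' Sample Pearson correlation computed from the textbook sums, with the
#' exact t-based two-tailed test: t = r * sqrt((n-2) / (1-r^2)) on n-2
#' degrees of freedom. Pairs with a missing member are dropped; zero
#' variance in either variable yields a missing r.
#'
#' @param x,y Numeric vectors of equal length (n >= 3 after NA removal).
#' @return One-row tibble: `r`, `statistic`, `p.value`, `n`.
#' @export
pearson_with_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0) {
    return(tibble::tibble(r = NA_real_, statistic = NA_real_,
                          p.value = NA_real_, n = n))
  }
  r <- sum(sx * sy) / sqrt(vx * vy)
  if (abs(r) >= 1) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(r = r, statistic = tstat, p.value = p, n = n)
}

#' Split individuals into low- and high-ROH groups
#'
#' Individuals with genome ROH coverage below the cutoff are "low",
#' the rest "high"; a tie at exactly the cutoff goes to "high".
#'
#' @param profiles Output of [coverage_profile()].
#' @param cutoff Coverage cutoff (default 0.20).
#' @return The input with a `roh_group` factor column ("low"/"high").
#' @export
split_low_high <- function(profiles, cutoff = 0.20) {
  stopifnot(nrow(profiles) > 0)
  dplyr::mutate(profiles,
                roh_group = factor(ifelse(.data$g_r < cutoff, "low", "high"),
                                   levels = c("low", "high")))
}

#' Welch two-sample t-test between two groups of individuals
#'
#' Two-tailed Welch (unequal variance) t-test, the default breed-contrast
#' test of the package. Degenerate zero-variance inputs are handled:
#' identical constant groups give t = 0, p = 1.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @return One-row tibble: `estimate` (mean difference a - b),
#'   `statistic`, `df`, `p.value`.
#' @export
breed_ttest <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(tibble::tibble(estimate = 0, statistic = 0,
                            df = NA_real_, p.value = 1))
    }
    return(tibble::tibble(estimate = mean(values_a) - mean(values_b),
                          statistic = Inf * sign(mean(values_a) - mean(values_b)),
                          df = NA_real_, p.value = 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  tibble::tibble(estimate = unname(diff(rev(tt$estimate))),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value)
}
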