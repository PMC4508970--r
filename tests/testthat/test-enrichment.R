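test_that("identical groups give exactly zero interaction terms", {
  d <- tibble::tibble(g = rep(seq(0.1, 0.5, length.out = 8), 2),
                      f = rep(seq(0.2, 0.6, length.out = 8), 2),
                      d = rep(0:1, each = 8))
  td <- tidy(suppressWarnings(fit_interaction_model(d, f, g, d)))
  expect_equal(td$estimate[td$term == "beta2"], 0, tolerance = 1e-12)
  expect_equal(td$estimate[td$term == "beta3"], 0, tolerance = 1e-12)
})

test_that("noiseless lines are recovered to machine precision", {
  g <- seq(0, 1, length.out = 11)
  d <- tibble::tibble(g = rep(g, 2), d = rep(0:1, each = 11))
  d$f <- ifelse(d$d == 0, 0.1 + 0.8 * d$g, 0.1 + 1.1 * d$g)
  td <- tidy(suppressWarnings(fit_interaction_model(d, f, g, d)))
  expect_equal(td$estimate, c(0.1, 0.8, 0, 0.3), tolerance = 1e-10)
})

test_that("coefficients, SEs and p-values match the normal-equations oracle", {
  set.seed(14)
  n <- 30
  df <- tibble::tibble(g = runif(2 * n), d = rep(0:1, each = n))
  df$f <- 0.2 + 0.5 * df$g + 0.05 * df$d + 0.3 * df$g * df$d +
    rnorm(2 * n, 0, 0.05)
  df$f <- pmin(pmax(df$f, 0), 1)
  td <- tidy(fit_interaction_model(df, f, g, d))
  X <- cbind(1, df$g, df$d, df$g * df$d)
  want <- oracle_ols(df$f, X)
  expect_equal(td$estimate, want$beta, tolerance = 1e-12)
  expect_equal(td$std.error, want$se, tolerance = 1e-12)
  expect_equal(td$statistic, want$t, tolerance = 1e-12)
  expect_equal(td$p.value, want$p, tolerance = 1e-12)
})

test_that("degenerate designs are rejected", {
  d <- tibble::tibble(g = rep(0.3, 20), f = runif(20), d = rep(0:1, 10))
  expect_error(fit_interaction_model(d, f, g, d), "constant")
  small <- tibble::tibble(g = runif(6), f = runif(6),
                          d = c(0, 0, 0, 0, 0, 1))
  expect_error(fit_interaction_model(small, f, g, d), "at least 5")
  bad <- tibble::tibble(g = c(runif(10), 1.5), f = runif(11),
                        d = rep(0:1, c(5, 6)))
  expect_error(fit_interaction_model(bad, f, g, d), "\\[0, 1\\]")
})

test_that("worked count predictions from the printed fitted lines", {
  pred <- predict_counts(slope_in = 1568.76, intercept_in = -57.63,
                         slope_out = -98.67, intercept_out = 693.63,
                         delta_g = 0.10)
  expect_equal(pred$change_in, 157)
  expect_equal(pred$change_out, -10)
  expect_equal(pred$net, 147)
  expect_equal(pred$baseline, 694)
  # rounded-components convention differs where the fractions disagree
  pred2 <- predict_counts(slope_in = 1568.76, slope_out = -98.67,
                          delta_g = 0.10, net_from = "rounded")
  expect_equal(pred2$net, 147)
  expect_equal(round_half_away(c(0.5, -0.5, 2.4, -2.5)), c(1, -1, 2, -3))
})

test_that("pearson_with_test matches cor.test and handles degeneracy", {
  x <- seq(1, 10)
  expect_equal(pearson_with_test(x, 2 * x + 1)$r, 1)
  set.seed(3)
  for (k in 1:5) {
    x <- rnorm(25); y <- 0.3 * x + rnorm(25)
    got <- pearson_with_test(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
    hand <- oracle_pearson(x, y)
    expect_equal(got$r, hand$r, tolerance = 1e-12)
    expect_equal(got$p.value, hand$p, tolerance = 1e-12)
  }
  expect_true(is.na(pearson_with_test(rep(1, 10), rnorm(10))$r))
  expect_error(pearson_with_test(1:2, 1:2), "at least 3")
})

test_that("null x-y pairs give small r and uniform p-values", {
  set.seed(99)
  n_rep <- 200
  p <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    x <- rnorm(50); y <- rnorm(50)
    p[k] <- pearson_with_test(x, y)$p.value
  }
  big <- pearson_with_test(rnorm(1000), rnorm(1000))
  expect_lt(abs(big$r), 0.1)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("low/high ROH split uses a strict cutoff with ties going high", {
  pr <- tibble::tibble(sample = c("a", "b", "c"),
                       g_s = 0, g_m = 0, g_l = 0,
                       g_r = c(0.05, 0.35, 0.20))
  got <- split_low_high(pr)
  expect_equal(as.character(got$roh_group), c("low", "high", "high"))
})

test_that("breed t-test is Welch and matches the textbook formula", {
  same <- c(1, 2, 3, 4)
  id <- breed_ttest(same, same)
  expect_equal(id$statistic, 0)
  expect_equal(id$p.value, 1)
  # constant identical groups
  expect_equal(breed_ttest(c(2, 2), c(2, 2))$p.value, 1)

  set.seed(6)
  a <- rnorm(15, 1, 2); b <- rnorm(30, 0, 1)
  got <- breed_ttest(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$statistic, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p.value, want$p, tolerance = 1e-12)
})

test_that("rejection rate tracks analytic Welch power", {
  set.seed(17)
  n1 <- 15; n2 <- 30; diff <- 2; s1 <- 2; s2 <- 2
  n_rep <- 300
  rej <- 0
  for (k in seq_len(n_rep)) {
    if (breed_ttest(rnorm(n1, diff, s1), rnorm(n2, 0, s2))$p.value < 0.05)
      rej <- rej + 1
  }
  sedm <- sqrt(s1^2 / n1 + s2^2 / n2)
  df <- sedm^4 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  tc <- stats::qt(0.975, df)
  power <- 1 - stats::pt(tc, df, ncp = diff / sedm) +
    stats::pt(-tc, df, ncp = diff / sedm)
  mc_se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(rej / n_rep - power), 4 * mc_se)
})

test_that("three size-class pairings are fitted; identical inputs null out", {
  f_tbl <- tidyr::expand_grid(sample = paste0("I", 1:12),
                              roh_class = c("S", "M", "L"),
                              func_class = "deleterious")
  prof <- tibble::tibble(sample = paste0("I", 1:12),
                         g_s = runif(12, 0, 0.3))
  prof$g_m <- prof$g_s  # identical coverage in every class
  prof$g_l <- prof$g_s
  f_tbl$f <- rep(0.1 + 0.9 * prof$g_s, each = 3)
  fits <- suppressWarnings(pairwise_sizeclass_model(f_tbl, prof))
  expect_named(fits, c("L_vs_M", "L_vs_S", "M_vs_S"))
  for (ft in fits) {
    td <- tidy(ft)
    expect_equal(td$estimate[3], 0, tolerance = 1e-10)
    expect_equal(td$estimate[4], 0, tolerance = 1e-10)
  }
})

test_that("planted medium-tract enrichment turns the L-vs-M slope negative", {
  lay <- demo_layout()
  params <- sim_params(n_pops = 1, n_per_pop = 16,
                       tract_freq_mult = c(S = 3, M = 3, L = 0.3),
                       seed = 55)
  co <- simulate_cohort(lay, params)
  roh <- classify_roh(co$truth_tracts |>
                        dplyr::mutate(length = end - start))
  prof <- coverage_profile(roh, lay, co$samples$sample)
  f <- roh_proportions(partition_genotypes(co, roh))
  fits <- pairwise_sizeclass_model(f, prof)
  td <- tidy(fits$L_vs_M)
  expect_lt(td$estimate[td$term == "beta3"], 0)
})
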