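# small helper: panel data frame for DID fits without the DEA stage
did_df <- function(seed = 1, delta = 0.03, n_prov = 30, ...) {
  p <- generate_panel(synthetic_config(seed = seed, delta = delta, ...))
  with_true_outcome(p)
}

test_that("TWFE equals the hand-computed 2x2 double difference exactly", {
  df <- data.frame(province = rep(c("ctl", "trt"), each = 2),
                   year = rep(1:2, 2),
                   mrae = c(0.80, 0.82, 0.80, 0.90),
                   du_dt = c(0, 0, 0, 1))
  fit <- fit_twfe_did(df, did_spec())
  expect_equal(fit$alpha1, 0.08, tolerance = 1e-12)
})

test_that("constant outcome gives a zero policy coefficient", {
  df <- did_df(seed = 3)
  df$mrae <- 0.9
  fit <- fit_twfe_did(df, did_spec(controls = control_cols()))
  expect_equal(fit$alpha1, 0, tolerance = 1e-12)
})

test_that("two-way demeaning reproduces dummy-variable least squares", {
  df <- did_df(seed = 8)
  spec <- did_spec(controls = control_cols())
  fit <- fit_twfe_did(df, spec)
  lmfit <- stats::lm(mrae ~ du_dt + lnPGDP + lnPOP + Gov + Idu + lnPat +
                       factor(province) + factor(year), data = df)
  sm <- summary(lmfit)$coefficients
  expect_equal(fit$alpha1, unname(sm["du_dt", 1]), tolerance = 1e-8)
  expect_equal(fit$se_alpha1, unname(sm["du_dt", 2]), tolerance = 1e-8)
  expect_equal(fit$p_alpha1, unname(sm["du_dt", 4]), tolerance = 1e-6)
  expect_equal(unname(fit$beta["Gov"]), unname(sm["Gov", 1]),
               tolerance = 1e-8)
  expect_equal(fit$n_obs, 390L)
})

test_that("cluster-by-unit standard errors match the sandwich estimator", {
  skip_if_not_installed("sandwich")
  df <- did_df(seed = 9)
  spec <- did_spec(controls = control_cols(),
                   se_type = "cluster_by_unit")
  fit <- fit_twfe_did(df, spec)
  lmfit <- stats::lm(mrae ~ du_dt + lnPGDP + lnPOP + Gov + Idu + lnPat +
                       factor(province) + factor(year), data = df)
  V <- sandwich::vcovCL(lmfit, cluster = df$province)
  expect_equal(fit$se_alpha1, sqrt(V["du_dt", "du_dt"]), tolerance = 1e-6)
})

test_that("adding a constant to the outcome moves only the intercept", {
  df <- did_df(seed = 10)
  spec <- did_spec(controls = control_cols())
  f1 <- fit_twfe_did(df, spec)
  df2 <- df; df2$mrae <- df2$mrae + 5
  f2 <- fit_twfe_did(df2, spec)
  expect_equal(f1$alpha1, f2$alpha1, tolerance = 1e-10)
  expect_equal(f2$alpha0 - f1$alpha0, 5, tolerance = 1e-9)
})

test_that("rank deficiency is reported with the offending column", {
  df <- did_df(seed = 11)
  df$dup <- df$lnPGDP
  spec <- did_spec(controls = c("lnPGDP", "dup"))
  err <- expect_error(fit_twfe_did(df, spec), class = "collinearity_error")
  expect_match(conditionMessage(err), "dup")
})

test_that("event study recovers a step effect: leads near 0, lags near delta", {
  set.seed(123)
  est <- replicate(40, {
    df <- did_df(seed = sample.int(1e6, 1), delta = 0.05)
    fit <- fit_event_study(df, did_spec(controls = control_cols()))
    fit$coefficients$estimate
  })
  m <- rowMeans(est)
  names(m) <- fit_event_study(did_df(seed = 1, delta = 0.05),
                              did_spec())$coefficients$term
  expect_true(all(abs(m[paste0("before_", 1:6)]) < 0.015))
  expect_true(all(abs(m[paste0("after_", 1:6)] - 0.05) < 0.015))
})

test_that("event study flags empty event-time cells", {
  # only two pre-periods: deep lead bins are empty
  df <- did_df(seed = 13, years = 2013:2018,
               batches = list("2015" = 4, "2016" = 7))
  err <- expect_error(fit_event_study(df, did_spec()),
                      class = "degenerate_design_error")
  expect_match(conditionMessage(err), "before_")
})

test_that("forcing the identity permutation reproduces the benchmark", {
  df <- did_df(seed = 14)
  truth <- panel_truth(generate_panel(synthetic_config(seed = 14)))$treated
  provs <- unique(df$province)
  byv <- stats::setNames(rep(NA_integer_, length(provs)), provs)
  byv[names(truth)] <- as.integer(truth)
  pl <- placebo_test(df, did_spec(controls = control_cols()),
                     assignments = list(byv))
  expect_equal(pl$perm_coefs[1], pl$benchmark_coef, tolerance = 1e-12)
  expect_equal(pl$empirical_p, 1)
})

test_that("placebo permutations keep batch sizes and are reproducible", {
  df <- did_df(seed = 15)
  p1 <- placebo_test(df, did_spec(), n_perm = 8, seed = 99)
  p2 <- placebo_test(df, did_spec(), n_perm = 8, seed = 99)
  expect_identical(p1$perm_coefs, p2$perm_coefs)
  expect_equal(length(p1$perm_coefs), 8L)
  expect_true(p1$empirical_p >= 0 && p1$empirical_p <= 1)
})

test_that("a single all-province subgroup reproduces the full-panel fit", {
  df <- did_df(seed = 16)
  spec <- did_spec(controls = control_cols())
  full <- fit_twfe_did(df, spec)
  provs <- unique(df$province)
  sub <- subgroup_did(df, spec,
                      stats::setNames(rep("all", length(provs)), provs))
  expect_equal(sub$all$alpha1, full$alpha1, tolerance = 1e-12)
})

test_that("median splits partition provinces with ties to the low group", {
  df <- did_df(seed = 17)
  g <- split_by_median(df, "mrae")
  expect_setequal(names(g), unique(df$province))
  expect_equal(sort(unique(unname(g))), c("high", "low"))
  avg <- tapply(df$mrae, df$province, mean)
  med <- stats::median(avg)
  expect_true(all(g[avg <= med] == "low"))
  expect_true(all(g[avg > med] == "high"))
})

test_that("subgroups without treated or control provinces are inestimable", {
  df <- did_df(seed = 18)
  treated <- unique(df$province[!is.na(df$batch_year)])
  g <- stats::setNames(ifelse(unique(df$province) %in% treated,
                              "T", "C"), unique(df$province))
  expect_error(subgroup_did(df, did_spec(), g),
               class = "inestimable_subgroup_error")
})

test_that("VIF matches its closed form and flags near-collinearity", {
  set.seed(19)
  n <- 200
  df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- compute_vif(df, c("a", "b", "c"))
  expect_true(all(abs(v - 1) < 0.1))   # independent draws: VIF near 1
  df$d <- df$a + rnorm(n, sd = 0.02)
  v2 <- compute_vif(df, c("a", "b", "d"))
  r2 <- summary(stats::lm(d ~ a + b, df))$r.squared
  expect_equal(unname(v2["d"]), 1 / (1 - r2), tolerance = 1e-9)
  expect_gt(v2["d"], 10)               # screening threshold
  skip_if_not_installed("car")
  lmfit <- stats::lm(rnorm(n) ~ a + b + d, df)
  expect_equal(unname(v2[c("a", "b", "d")]),
               unname(car::vif(lmfit)[c("a", "b", "d")]),
               tolerance = 1e-6)
})
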