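test_that("generation is deterministic given the seed", {
  p1 <- small_synth(seed = 42)
  p2 <- small_synth(seed = 42)
  expect_equal(as.data.frame(p1), as.data.frame(p2), tolerance = 1e-15)
  expect_equal(panel_truth(p1)$treated, panel_truth(p2)$treated)
})

test_that("default configuration reproduces the study dimensions", {
  p <- generate_panel(synthetic_config(seed = 5))
  expect_equal(nrow(p), 390L)
  tr <- panel_truth(p)
  expect_equal(length(tr$treated), 11L)
  expect_equal(as.integer(table(tr$treated)[c("2015", "2016")]), c(4L, 7L))
  # the treated draw follows the pilot batches' regional composition
  rg <- region_grouping(p)[names(tr$treated)]
  expect_equal(as.integer(table(rg)[c("East", "Central", "West")]),
               c(4L, 2L, 5L))
  expect_equal(nrow(validate_panel(p)), 0L)
})

test_that("a noiseless common-technology panel puts every unit on the frontier", {
  p <- generate_panel(synthetic_config(
    n_provinces = 10, years = 2009:2012,
    region_sizes = c(East = 4, Central = 3, West = 3), batches = list(),
    delta = 0, inefficiency_scale = 0, noise_sd = 0,
    group_tech_gap = c(East = 1, Central = 1, West = 1), seed = 3))
  m <- meta_efficiencies(p)
  expect_true(all(abs(m$efficiency - 1) < 1e-7))
})

test_that("toy instances have the advertised efficient sets", {
  toy <- generate_dea_toy(2, c(N = 2, M = 1, I = 1), type = "dominant",
                          seed = 1)
  ref <- reference_technology(toy$X, toy$Y, toy$B)
  e <- sapply(1:2, function(j) efficiency_from_solution(
    solve_sbm_ddf(toy$X[, j], toy$Y[, j], toy$B[, j], ref)))
  expect_equal(e[1], 1)
  expect_lt(e[2], 1)
  # all units on a common ray are efficient under CRS
  ray <- generate_dea_toy(5, c(N = 2, M = 2, I = 1), type = "ray", seed = 2)
  refr <- reference_technology(ray$X, ray$Y, ray$B)
  er <- sapply(1:5, function(j) efficiency_from_solution(
    solve_sbm_ddf(ray$X[, j], ray$Y[, j], ray$B[, j], refr)))
  expect_true(all(abs(er - 1) < 1e-8))
})

test_that("dominated units are never efficient", {
  set.seed(77)
  for (rep in 1:5) {
    toy <- generate_dea_toy(6, c(N = 2, M = 2, I = 1), type = "random")
    dom <- dominated_units(toy$X, toy$Y, toy$B)
    ref <- reference_technology(toy$X, toy$Y, toy$B)
    for (j in which(dom)) {
      expect_lt(efficiency_from_solution(
        solve_sbm_ddf(toy$X[, j], toy$Y[, j], toy$B[, j], ref)),
        1 - 1e-9)
    }
  }
})

test_that("a deeper group technology gap lowers that group's mean TGR", {
  mean_tgr <- sapply(c(1, 0.85, 0.7), function(a) {
    p <- generate_panel(synthetic_config(
      n_provinces = 15, years = 2013:2016,
      region_sizes = c(East = 5, Central = 5, West = 5),
      batches = list(),
      group_tech_gap = c(East = 1, Central = a, West = 1), seed = 50))
    tg <- technology_gap_ratio(meta_efficiencies(p),
                               group_efficiencies(p))
    mean(tg$tgr[region_grouping(p)[tg$province] == "Central"])
  })
  expect_lt(mean_tgr[2], mean_tgr[1])
  expect_lt(mean_tgr[3], mean_tgr[2])
  # with a common technology the gap is only frontier sampling error
  expect_gt(mean_tgr[1], 0.9)
})

test_that("the full DEA-then-DID pipeline recovers the true effect", {
  # scaled-down panel chosen to keep the share of frontier units near
  # the default configuration's (~1/3), since frontier censoring is
  # what attenuates a DEA-scored effect
  set.seed(321)
  alphas <- replicate(150, {
    p <- generate_panel(synthetic_config(
      n_provinces = 16, years = 2012:2019,
      region_sizes = c(East = 6, Central = 5, West = 5),
      batches = list("2015" = 3, "2016" = 3),
      delta = 0.03, seed = sample.int(1e6, 1)))
    df <- with_outcome(p, meta_efficiencies(p))
    dft <- with_true_outcome(p)
    c(dea = fit_twfe_did(df, did_spec(controls = control_cols()))$alpha1,
      true = fit_twfe_did(dft, did_spec(controls = control_cols()))$alpha1)
  })
  # true-efficiency route is unbiased; the DEA route carries a small
  # downward attenuation because units already on the frontier cannot
  # show the gain (score ceiling at 1).  Recovery must stay within a
  # third of the effect, and the censoring loss must stay small.
  expect_lt(abs(mean(alphas["true", ]) - 0.03),
            0.25 * stats::sd(alphas["true", ]))
  expect_lt(abs(mean(alphas["dea", ]) - 0.03), 0.01)
  atten <- mean(alphas["true", ] - alphas["dea", ])
  expect_lt(abs(atten), 0.01)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_provinces = 5,
                                region_sizes = c(East = 3, Central = 3,
                                                 West = 3)),
               class = "config_error")
  expect_error(synthetic_config(batches = list("2015" = 40)),
               class = "config_error")
  expect_error(synthetic_config(delta = 0.9), class = "config_error")
  expect_error(synthetic_config(group_tech_gap = c(East = 1.5, Central = 1,
                                                   West = 1)),
               class = "config_error")
})
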