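# Hand-derived toy: A = (x=1, y=2, b=1), B = (x=2, y=1, b=2), CRS,
# direction = own observed values.  Evaluating B: the objective
# 1/2*s_x/2 + 1/4*s_y/1 + 1/4*s_b/2 reduces to 1/2 + lambda_A/8 -
# lambda_B/2 with lambda_A <= 2 binding, so inefficiency(B) = 3/4.
# Evaluating A the objective is maximised at lambda = (1, 0) with all
# slacks zero, so A is efficient.

test_that("two-DMU toy matches the hand-solved LP", {
  X <- matrix(c(1, 2), 1); Y <- matrix(c(2, 1), 1); B <- matrix(c(1, 2), 1)
  ref <- reference_technology(X, Y, B, rts = "CRS")
  solB <- solve_sbm_ddf(2, 1, 2, ref)
  expect_equal(solB$inefficiency, 0.75, tolerance = 1e-9)
  expect_equal(efficiency_from_solution(solB), 0.25, tolerance = 1e-9)
  solA <- solve_sbm_ddf(1, 2, 1, ref)
  expect_equal(solA$inefficiency, 0, tolerance = 1e-9)
  expect_equal(efficiency_from_solution(solA), 1)
})

test_that("self-referenced DMU is efficient with zero slacks", {
  set.seed(7)
  for (rts in c("CRS", "VRS")) {
    x <- exp(rnorm(3)); y <- exp(rnorm(2)); b <- exp(rnorm(2))
    ref <- reference_technology(cbind(x), cbind(y), cbind(b), rts = rts)
    sol <- solve_sbm_ddf(x, y, b, ref)
    expect_equal(sol$inefficiency, 0, tolerance = 1e-9)
    expect_equal(sol$lambda, 1, tolerance = 1e-9)
    expect_true(all(abs(c(sol$s_x, sol$s_y, sol$s_b)) < 1e-8))
  }
})

test_that("LP objective matches the vertex-enumeration oracle", {
  set.seed(202)
  for (rep in 1:12) {
    J <- sample(3:6, 1)
    inst <- random_sbm_instance(J)
    j0 <- sample(J, 1)
    sol <- solve_sbm_ddf(inst$X[, j0], inst$Y[, j0], inst$B[, j0],
                         reference_technology(inst$X, inst$Y, inst$B))
    ora <- sbm_oracle(inst$X[, j0], inst$Y[, j0], inst$B[, j0],
                      inst$X, inst$Y, inst$B)
    expect_equal(sol$inefficiency, ora, tolerance = 1e-6)
  }
})

test_that("enlarging the reference set never increases efficiency", {
  set.seed(33)
  inst <- random_sbm_instance(8)
  sub <- 1:4
  for (j0 in 1:4) {
    refS <- reference_technology(inst$X[, sub, drop = FALSE],
                                 inst$Y[, sub, drop = FALSE],
                                 inst$B[, sub, drop = FALSE])
    refL <- reference_technology(inst$X, inst$Y, inst$B)
    eS <- efficiency_from_solution(
      solve_sbm_ddf(inst$X[, j0], inst$Y[, j0], inst$B[, j0], refS))
    eL <- efficiency_from_solution(
      solve_sbm_ddf(inst$X[, j0], inst$Y[, j0], inst$B[, j0], refL))
    expect_lte(eL, eS + 1e-9)
  }
})

test_that("CRS scores are invariant to rescaling one variable's units", {
  set.seed(44)
  inst <- random_sbm_instance(6)
  ref1 <- reference_technology(inst$X, inst$Y, inst$B)
  X2 <- inst$X; X2[1, ] <- X2[1, ] * 1000   # e.g. currency unit change
  ref2 <- reference_technology(X2, inst$Y, inst$B)
  for (j0 in 1:6) {
    e1 <- efficiency_from_solution(
      solve_sbm_ddf(inst$X[, j0], inst$Y[, j0], inst$B[, j0], ref1))
    e2 <- efficiency_from_solution(
      solve_sbm_ddf(X2[, j0], inst$Y[, j0], inst$B[, j0], ref2))
    expect_equal(e1, e2, tolerance = 1e-7)
  }
})

test_that("a strictly dominant unit is efficient, identical units all are", {
  toy <- generate_dea_toy(5, c(N = 2, M = 2, I = 1), type = "dominant",
                          seed = 9)
  ref <- reference_technology(toy$X, toy$Y, toy$B)
  e1 <- efficiency_from_solution(
    solve_sbm_ddf(toy$X[, 1], toy$Y[, 1], toy$B[, 1], ref))
  expect_equal(e1, 1)
  # identical columns: everyone sits on the frontier
  Xi <- matrix(rep(c(1, 2), 4), 2); Yi <- matrix(rep(c(3, 1), 4), 2)
  Bi <- matrix(rep(0.5, 4), 1)
  refi <- reference_technology(Xi, Yi, Bi)
  for (j in 1:4) {
    expect_equal(efficiency_from_solution(
      solve_sbm_ddf(Xi[, j], Yi[, j], Bi[, j], refi)), 1)
  }
})

test_that("VRS scores are at least CRS scores", {
  set.seed(55)
  inst <- random_sbm_instance(6)
  for (j0 in 1:6) {
    eC <- efficiency_from_solution(solve_sbm_ddf(
      inst$X[, j0], inst$Y[, j0], inst$B[, j0],
      reference_technology(inst$X, inst$Y, inst$B, rts = "CRS")))
    eV <- efficiency_from_solution(solve_sbm_ddf(
      inst$X[, j0], inst$Y[, j0], inst$B[, j0],
      reference_technology(inst$X, inst$Y, inst$B, rts = "VRS")))
    expect_gte(eV, eC - 1e-9)
  }
})

test_that("score_all returns one in-range score per unit-period", {
  p <- small_synth(seed = 12, n_prov = 6, years = 2013:2015,
                   batches = list())
  tab <- score_all(p, frontier_scope("meta"))
  expect_equal(nrow(tab), 18L)
  expect_true(all(tab$efficiency >= 0 & tab$efficiency <= 1))
  # deterministic
  tab2 <- score_all(p, frontier_scope("meta"))
  expect_identical(tab$efficiency, tab2$efficiency)
})

test_that("dimension and positivity violations are rejected", {
  ref <- reference_technology(matrix(1), matrix(1), matrix(1))
  expect_error(solve_sbm_ddf(c(1, 2), 1, 1, ref), class = "dimension_error")
  expect_error(solve_sbm_ddf(-1, 1, 1, ref), class = "dea_input_error")
  expect_error(reference_technology(matrix(0), matrix(1), matrix(1)),
               class = "technology_error")
  expect_error(direction_vector(0, 1, 1), class = "direction_error")
})
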