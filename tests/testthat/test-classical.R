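test_that("soft thresholding shrinks toward zero", {
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.1, 0.2), 0)
  v <- c(-2, 0, 1.5)
  expect_equal(soft_threshold(v, 0), v)
  expect_error(soft_threshold(1, -1), "non-negative")
})

test_that("FISTA with zero data and a sparse prior returns zero", {
  toy <- fx_toy_problem()
  prob <- inverse_problem(toy$W, numeric(20), normalize = FALSE)
  r <- adfista(prob, lambda = 0.5)
  expect_true(all(r$x == 0))
})

test_that("unregularized FISTA solves non-negative least squares", {
  toy <- fx_toy_problem()
  nn <- pracma::lsqnonneg(toy$W, as.vector(toy$y))$x
  for (norm in c(TRUE, FALSE)) {
    prob <- inverse_problem(toy$W, toy$y, normalize = norm)
    r <- suppressMessages(adfista(prob, lambda = 0, tol = 1e-12,
                                  max_iter = 30000))
    expect_lt(rel_l2(r$x, nn), 1e-4)
  }
})

test_that("objective decreases and the fixed-budget variant matches", {
  toy <- fx_toy_problem()
  prob <- inverse_problem(toy$W, toy$y)
  rt <- suppressMessages(t_fista(prob, lambda = 0.05, iterations = 300))
  ra <- suppressMessages(adfista(prob, lambda = 0.05, tol = 0,
                                 max_iter = 300))
  expect_identical(rt$x, ra$x)
  expect_equal(rt$iterations, 300)
  # objective traces over seeded small problems end below their start
  for (sd in 1:20) {
    toy2 <- fx_toy_problem(15, 8, seed = sd)
    r <- suppressMessages(t_fista(inverse_problem(toy2$W, toy2$y),
                                  lambda = 0.1, iterations = 50))
    tr <- r$objective_trace
    expect_lte(tr[length(tr)], tr[1])
  }
})

test_that("MLEM converges on a noiseless toy with a monotone likelihood", {
  set.seed(11)
  W <- matrix(0.3 * runif(900), 30, 30) + 5 * diag(30)
  x_true <- pmax(rnorm(30) + 0.5, 0)
  y <- W %*% x_true
  r <- admlem(inverse_problem(W, y), iterations = 800)
  expect_lt(rel_l2(r$x, x_true), 0.01)
  expect_false(is.unsorted(r$objective_trace))
  expect_true(all(r$x >= 0))
  # negative measurements are clipped with a message
  expect_message(admlem(inverse_problem(W, y - 2), iterations = 5),
                 "clipping")
})

test_that("MAP-ICD reduces to least squares as the prior vanishes", {
  toy <- fx_toy_problem()
  nn <- pracma::lsqnonneg(toy$W, as.vector(toy$y))$x
  prob <- inverse_problem(toy$W, toy$y, normalize = FALSE)
  r <- map_gmrf_icd(prob, sweeps = 3000, tol = 1e-14, sigma2 = 1, p2 = 1e12)
  expect_lt(rel_l2(r$x, nn), 1e-3)
})

test_that("ICD sweeps never increase the objective at fixed hyperparameters", {
  toy <- fx_toy_problem()
  prob <- inverse_problem(toy$W, toy$y)
  r <- map_gmrf_icd(prob, sweeps = 40, sigma2 = 1, p2 = 0.5)
  expect_true(all(diff(r$objective_trace) <= 1e-9))
  expect_true(all(r$x >= 0))
  # alternating hyperparameter estimation stays finite and converges
  r2 <- map_gmrf_icd(prob, sweeps = 40)
  expect_true(all(is.finite(r2$settings$hyper)))
})

test_that("the GMRF prior ignores constant shifts", {
  toy <- fx_toy_problem()
  prob <- inverse_problem(toy$W, toy$y)
  nb <- cbxlct:::gmrf_neighbors(prob)
  x <- runif(10)
  expect_equal(cbxlct:::gmrf_prior_energy(x, nb),
               cbxlct:::gmrf_prior_energy(x + 7, nb))
})

test_that("solvers are deterministic given the problem and settings", {
  toy <- fx_toy_problem()
  prob <- inverse_problem(toy$W, toy$y)
  expect_identical(suppressMessages(t_fista(prob))$x,
                   suppressMessages(t_fista(prob))$x)
  expect_identical(admlem(prob, iterations = 50)$x,
                   admlem(prob, iterations = 50)$x)
  expect_identical(map_gmrf_icd(prob, sweeps = 5)$x,
                   map_gmrf_icd(prob, sweeps = 5)$x)
})
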