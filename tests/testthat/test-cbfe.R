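test_that("coin-toss coordinate ascent converges to the exact Beta posterior", {
  fit <- cbfe_coordinate_ascent(list(model = "beta_bernoulli", a = 1, b = 1, y = c(1, 1, 0)))
  expect_equal(fit$posterior$a, 3)
  expect_equal(fit$posterior$b, 2)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) <= 1e-9))
  expect_length(fit$diagnostics, 0L)
  # final free energy equals minus the exact log evidence
  log_evidence <- lbeta(3, 2) - lbeta(1, 1)
  expect_equal(fit$trace[length(fit$trace)], -log_evidence, tolerance = 1e-12)
  # cross-check the parametric posterior against grid enumeration
  ct <- coin_toss(data = c(1, 1, 0))
  bf <- brute_force(ct$graph, coin_toss_tables(ct$graph, 401L))
  grid <- as.numeric(names(bf$marginals[[1]]))
  grid_mean <- sum(grid * bf$marginals[[1]])
  expect_equal(grid_mean, fit$posterior$a / (fit$posterior$a + fit$posterior$b),
               tolerance = 1e-3)
})

test_that("zero observations leave the prior untouched", {
  fit <- cbfe_coordinate_ascent(list(model = "beta_bernoulli", a = 1, b = 1, y = numeric(0)))
  expect_equal(fit$posterior$a, 1)
  expect_equal(fit$posterior$b, 1)
  expect_equal(fit$trace[length(fit$trace)], 0, tolerance = 1e-12) # evidence of nothing
})

test_that("functional-form tags are honored and unsupported models refused", {
  ct <- coin_toss(data = c(1, 0))
  tags <- apply_functional_form(ct$graph, build_constraint_set(ffc("theta", "Beta")))
  fit <- cbfe_coordinate_ascent(list(model = "beta_bernoulli", a = 1, b = 1, y = c(1, 0)),
                                graph = ct$graph, family_tags = tags)
  expect_equal(fit$posterior$a, 2)
  bad_tags <- stats::setNames("Gamma", names(tags))
  expect_error(cbfe_coordinate_ascent(list(model = "beta_bernoulli", y = c(1, 0)),
                                      family_tags = bad_tags),
               class = "ffg_not_supported")
  expect_error(cbfe_coordinate_ascent(list(model = "dirichlet_process", y = 1)),
               class = "ffg_not_supported")
})

test_that("Gaussian mean with known precision recovers the exact conjugate posterior", {
  set.seed(7)
  y <- rnorm(12, 2, 1)
  tau <- 1.7; m0 <- -1; v0 <- 4
  fit <- cbfe_coordinate_ascent(list(model = "normal_known_precision",
                                     m0 = m0, v0 = v0, tau = tau, y = y))
  v_exact <- 1 / (1 / v0 + length(y) * tau)
  m_exact <- v_exact * (m0 / v0 + tau * sum(y))
  expect_equal(fit$posterior$mean, m_exact, tolerance = 1e-12)
  expect_equal(fit$posterior$var, v_exact, tolerance = 1e-12)
  expect_true(all(diff(fit$trace) <= 1e-9))
  # exact log evidence: p(y) is multivariate normal, covariance v0*J + I/tau
  n <- length(y)
  S <- v0 * matrix(1, n, n) + diag(n) / tau
  log_evidence <- -0.5 * as.numeric(n * log(2 * pi) + determinant(S)$modulus +
                                      t(y - m0) %*% solve(S, y - m0))
  expect_equal(fit$trace[length(fit$trace)], -log_evidence, tolerance = 1e-9)
})

test_that("Normal-Gamma mean field matches the textbook fixed point and is monotone", {
  set.seed(11)
  y <- rnorm(25, 1.5, 0.7)
  spec <- list(model = "normal_gamma", m0 = 0, v0 = 10, a0 = 2, b0 = 1, y = y)
  fit <- cbfe_coordinate_ascent(spec, max_iters = 200)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) <= 1e-9))
  expect_length(fit$diagnostics, 0L)

  # independent oracle: iterate the standard coupled updates to convergence
  n <- length(y); m <- 0; v <- 10; a <- 2; b <- 1
  for (i in 1:500) {
    et <- a / b
    v <- 1 / (1 / 10 + n * et)
    m <- v * (0 / 10 + et * sum(y))
    a <- 2 + n / 2
    b <- 1 + 0.5 * sum((y - m)^2 + v)
  }
  expect_equal(fit$posterior$mu$mean, m, tolerance = 1e-6)
  expect_equal(fit$posterior$mu$var, v, tolerance = 1e-6)
  expect_equal(fit$posterior$tau$shape, a, tolerance = 1e-6)
  expect_equal(fit$posterior$tau$rate, b, tolerance = 1e-6)

  # with no data the optimum is the prior
  fit0 <- cbfe_coordinate_ascent(list(model = "normal_gamma", m0 = 0, v0 = 10,
                                      a0 = 2, b0 = 1, y = numeric(0)))
  expect_equal(fit0$posterior$mu$mean, 0)
  expect_equal(fit0$posterior$tau$shape, 2)
})

test_that("converged coin beliefs satisfy normalization and marginalization on the grid", {
  fit <- cbfe_coordinate_ascent(list(model = "beta_bernoulli", a = 1, b = 1, y = c(1, 1, 0)))
  grid_size <- 201L
  grid <- (seq_len(grid_size) - 0.5) / grid_size
  q <- dbeta(grid, fit$posterior$a, fit$posterior$b)
  q <- q / sum(q)
  ct <- coin_toss(data = c(1, 1, 0))
  g <- ct$graph
  theta <- fg_variables(g)$id[fg_variables(g)$name == "theta"]
  node <- list()
  for (fid in ls(g$factors)) {
    node[[fid]] <- list(blocks = list("out"), q = list(q), vars = list(theta),
                        domains = stats::setNames(list(grid), theta))
  }
  belief <- structure(list(edge = stats::setNames(list(stats::setNames(q, grid)), theta),
                           node = node), class = "ffg_belief")
  expect_length(check_constraints(belief, tol = 1e-8), 0L)
})

test_that("the trace tidier exposes iterations and free energies", {
  fit <- cbfe_coordinate_ascent(list(model = "beta_bernoulli", a = 1, b = 1, y = c(1, 0, 0)))
  tr <- tidy_trace(fit)
  expect_s3_class(tr, "tbl_df")
  expect_equal(tr$iteration[1], 0L)
  expect_equal(tr$free_energy, fit$trace)
})
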