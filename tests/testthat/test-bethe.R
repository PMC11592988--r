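test_that("enumeration normalizes a single factor and reports zero log evidence", {
  g <- fg_new("m")
  root <- fg_root(g)
  s <- fg_add_variable(g, root, "s", "random")
  fid <- fg_add_factor(g, root, "prior", c(i1 = s))
  tabs <- list(factor_table(fid, domains = list(i1 = c(0, 1)), table = c(0.2, 0.8)))
  bf <- brute_force(g, tabs)
  expect_equal(unname(bf$marginals[[s]]), c(0.2, 0.8))
  expect_equal(bf$log_evidence, 0, tolerance = 1e-14)
})

test_that("enumeration matches an independent nested-loop oracle on the example graph", {
  set.seed(20)
  e4 <- eq4_graph()
  g <- e4$graph
  doms <- lapply(e4$vars, function(v) c(0, 1))
  tabs <- list()
  for (nm in names(e4$factors)) {
    fid <- e4$factors[[nm]]
    f <- g$factors[[fid]]
    k <- length(f$interfaces)
    tabs[[fid]] <- factor_table(fid,
      domains = stats::setNames(rep(list(c(0, 1)), k), names(f$interfaces)),
      table = array(runif(2^k, 0.05, 1), rep(2L, k)))
  }
  bf <- brute_force(g, tabs)
  oracle <- oracle_enumerate(
    lapply(tabs, function(ft) {
      fid <- ft$factor_id
      list(vars = unname(g$factors[[fid]]$interfaces), table = ft$table)
    }),
    stats::setNames(rep(list(2L), 4L), unname(e4$vars)))
  for (v in unname(e4$vars)) {
    expect_equal(unname(bf$marginals[[v]]), oracle$marginals[[v]], tolerance = 1e-12)
  }
  expect_equal(bf$log_evidence, oracle$log_evidence, tolerance = 1e-12)
})

test_that("enumeration clamps data, respects the cap, and handles the coin grid", {
  ct <- coin_toss(data = c(1, 1, 0))
  tabs <- coin_toss_tables(ct$graph, grid_size = 201L)
  bf <- brute_force(ct$graph, tabs)
  theta_belief <- bf$marginals[[1]]
  grid <- as.numeric(names(theta_belief))
  # posterior is Beta(3, 2): mode 2/3, mean 0.6
  expect_equal(grid[which.max(theta_belief)], 2 / 3, tolerance = 0.01)
  expect_equal(sum(grid * theta_belief), 0.6, tolerance = 0.01)
  expect_error(brute_force(ct$graph, tabs, cap = 10), class = "ffg_state_space_too_large")
})

test_that("sum-product on trees reproduces exact marginals, evidence and the Bethe identity", {
  for (s in 1:60) {
    n <- sample(2:8, 1)
    rd <- random_discrete_model(n, max_domain = 4, seed = s)
    bf <- brute_force(rd$graph, rd$tables)
    bp <- sum_product(rd$graph, rd$tables)
    expect_true(bp$converged)
    for (v in names(bf$marginals)) {
      expect_lt(tv(bf$marginals[[v]], bp$belief$edge[[v]]), 1e-10)
    }
    expect_equal(bp$log_evidence, bf$log_evidence, tolerance = 1e-9)
    fe <- bethe_free_energy(rd$graph, rd$tables, bp$belief)
    expect_equal(fe$total, -bf$log_evidence, tolerance = 1e-9)
  }
})

test_that("closing the box: directional message products equal exact edge marginals", {
  for (s in c(3, 7, 21)) {
    rd <- random_discrete_model(7, max_domain = 3, seed = s)
    bf <- brute_force(rd$graph, rd$tables)
    bp <- sum_product(rd$graph, rd$tables)
    for (fid in names(bp$network$factors)) {
      f <- bp$network$factors[[fid]]
      for (v in f$vars) {
        fwd <- bp$messages[[paste(v, fid, sep = "|")]]
        bwd <- bp$messages[[paste(fid, v, sep = "|")]]
        prod <- fwd * bwd
        expect_lt(tv(prod / sum(prod), bf$marginals[[v]]), 1e-10)
      }
    }
  }
})

test_that("a single prior factor yields the normalized factor as belief", {
  g <- fg_new("m")
  root <- fg_root(g)
  s <- fg_add_variable(g, root, "s", "random")
  fid <- fg_add_factor(g, root, "prior", c(i1 = s))
  tabs <- list(factor_table(fid, domains = list(i1 = 1:3), table = c(1, 2, 1)))
  bp <- sum_product(g, tabs)
  expect_equal(unname(bp$belief$edge[[s]]), c(0.25, 0.5, 0.25))
  fe <- bethe_free_energy(g, tabs, bp$belief)
  expect_equal(fe$total, -log(4), tolerance = 1e-12)
})

test_that("damped flooding approximates exact marginals on a weakly coupled cycle", {
  rd <- random_discrete_model(5, max_domain = 2, seed = 13, cycle = TRUE)
  bf <- brute_force(rd$graph, rd$tables)
  bp <- sum_product(rd$graph, rd$tables, max_sweeps = 500, tol = 1e-12)
  expect_true(bp$converged)
  for (v in names(bf$marginals)) {
    expect_lt(tv(bf$marginals[[v]], bp$belief$edge[[v]]), 0.05)
  }
  expect_error(sum_product(rd$graph, rd$tables, schedule = "tree"),
               class = "ffg_not_a_tree")
})

test_that("free energy reports +Inf with a diagnostic on support mismatch", {
  g <- fg_new("m")
  root <- fg_root(g)
  s <- fg_add_variable(g, root, "s", "random")
  fid <- fg_add_factor(g, root, "prior", c(i1 = s))
  tabs <- list(factor_table(fid, domains = list(i1 = c(0, 1)), table = c(1, 0)))
  belief <- structure(list(
    edge = stats::setNames(list(c(`0` = 0.5, `1` = 0.5)), s),
    node = stats::setNames(list(list(blocks = list("i1"), q = list(c(0.5, 0.5)),
                                     vars = list(s),
                                     domains = stats::setNames(list(c(0, 1)), s))), fid)),
    class = "ffg_belief")
  fe <- bethe_free_energy(g, tabs, belief)
  expect_equal(fe$total, Inf)
  expect_match(fe$diagnostics, "SupportMismatch")
})

test_that("KL divergence is nonnegative, zero iff equal, and support-checked", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-14)
  expect_gt(kl_divergence(c(0.9, 0.1), c(0.5, 0.5)), 0)
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), class = "ffg_support_mismatch")
  expect_error(kl_divergence(c(1), c(0.5, 0.5)), class = "ffg_support_mismatch")
})

test_that("the free-energy decomposition F[q] = KL(q||posterior) - log evidence holds", {
  set.seed(31)
  for (s in 1:5) {
    rd <- random_discrete_model(4, max_domain = 3, seed = s)
    bf <- brute_force(rd$graph, rd$tables, return_joint = TRUE)
    for (rep in 1:3) {
      q <- array(runif(length(bf$joint), 0.01, 1), dim = dim(bf$joint))
      q <- q / sum(q)
      F <- vfe(q, bf)
      kl <- kl_divergence(as.numeric(q), as.numeric(bf$joint))
      expect_equal(F, kl - bf$log_evidence, tolerance = 1e-9)
    }
    # at the exact posterior the KL term vanishes
    expect_equal(vfe(bf$joint, bf), -bf$log_evidence, tolerance = 1e-9)
  }
})

test_that("constraint checks pass at BP fixed points and flag broken beliefs", {
  rd <- random_discrete_model(6, seed = 17)
  bp <- sum_product(rd$graph, rd$tables)
  expect_length(check_constraints(bp$belief), 0L)

  scaled <- bp$belief
  v1 <- names(scaled$edge)[1]
  scaled$edge[[v1]] <- scaled$edge[[v1]] * 2
  expect_match(check_constraints(scaled), "normalization", all = FALSE)

  skewed <- bp$belief
  f1 <- names(skewed$node)[[1]]
  q <- skewed$node[[f1]]$q[[1]]
  q <- q^2 / sum(q^2)
  skewed$node[[f1]]$q[[1]] <- q
  expect_match(check_constraints(skewed), "marginalization", all = FALSE)
})
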