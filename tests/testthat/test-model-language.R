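reg <- node_registry()

test_that("compound unrolling is innermost-first, left-to-right", {
  # y ~ Normal(x, exp(kappa * z + omega))
  stmt <- fg_stmt("y", fg_call("Normal", fg_ref("x"),
                               fg_call("exp", fg_call("+", fg_call("*", fg_ref("kappa"), fg_ref("z")),
                                                      fg_ref("omega")))))
  out <- unroll_compound(stmt, reg)
  expect_length(out, 4L)
  expect_equal(vapply(out, function(s) s$rhs$label, character(1)),
               c("*", "+", "exp", "Normal"))
  expect_equal(vapply(out[1:3], function(s) s$lhs$name, character(1)),
               c("y_tmp_0", "y_tmp_1", "y_tmp_2"))
  expect_equal(out[[4]]$lhs$name, "y")

  # already primitive: returned as-is
  prim <- fg_stmt("theta", fg_call("Beta", 1, 1))
  expect_length(unroll_compound(prim, reg), 1L)

  # left-to-right among siblings
  stmt2 <- fg_stmt("y", fg_call("Normal", fg_call("exp", fg_ref("a")),
                                fg_call("exp", fg_ref("b"))))
  out2 <- unroll_compound(stmt2, reg)
  expect_equal(vapply(out2, function(s) s$rhs$label, character(1)),
               c("exp", "exp", "Normal"))
  expect_equal(out2[[1]]$rhs$args[[1]]$name, "a")
  expect_equal(out2[[2]]$rhs$args[[1]]$name, "b")

  expect_error(unroll_compound(fg_stmt("y", fg_call("Mystery", 1)), reg),
               class = "ffg_unknown_label")
})

test_that("a Beta statement materializes one factor and two constants besides the lhs", {
  g <- fg_new("m")
  res <- materialize_statement(g, fg_root(g), reg, fg_stmt("theta", fg_call("Beta", 1, 1)))
  expect_false(res$folded)
  vars <- fg_variables(g)
  expect_equal(nrow(vars), 3L)
  expect_equal(sum(vars$kind == "constant"), 2L)
  expect_equal(nrow(fg_factors(g)), 1L)
  f <- g$factors[[res$factor_id]]
  expect_equal(names(f$interfaces), c("out", "a", "b"))
})

test_that("deterministic calls with known arguments fold to a bound value", {
  g <- fg_new("m")
  res <- materialize_statement(g, fg_root(g), reg, fg_stmt("a", fg_call("norm", c(1, 2, 3))))
  expect_true(res$folded)
  expect_equal(res$value, sqrt(14), tolerance = 1e-15)
  expect_equal(nrow(fg_variables(g)), 0L) # folding creates no nodes
  expect_equal(nrow(fg_factors(g)), 0L)

  # the folded value is usable downstream and reified as a constant there
  res2 <- materialize_statement(g, fg_root(g), reg,
                                fg_stmt("x", fg_call("Bernoulli", fg_ref("a"))))
  cst <- g$vars[[res2$constant_ids]]
  expect_equal(cst$value, sqrt(14))
})

test_that("deterministic relations with a random argument materialize a factor", {
  g <- fg_new("m")
  root <- fg_root(g)
  materialize_statement(g, root, reg, fg_stmt("x", fg_call("Beta", 1, 1)))
  res <- materialize_statement(g, root, reg,
                               fg_stmt("w", fg_call("exp", fg_ref("x")), relation = ":="))
  expect_false(res$folded)
  f <- g$factors[[res$factor_id]]
  expect_true(f$deterministic)
  expect_equal(names(f$interfaces), c("out", "in"))
  expect_equal(unname(f$interfaces[["in"]]), unname(g$ctxs[[root]]$bindings[["x"]]))
  expect_error(materialize_statement(g, root, reg,
                                     fg_stmt("q", fg_call("exp", fg_ref("nope")))),
               class = "ffg_unresolvable_reference")
})

test_that("indexed variables are created on first touch and are idempotent", {
  g <- fg_new("m")
  root <- fg_root(g)
  a <- get_or_create_indexed(g, root, "x", 0L)
  b <- get_or_create_indexed(g, root, "x", 0L)
  expect_identical(a, b)
  c3 <- get_or_create_indexed(g, root, "x", 3L)
  c1 <- get_or_create_indexed(g, root, "x", 1L)
  expect_false(c3 == c1)
  # sparse: only the touched indices exist
  vars <- fg_variables(g)
  expect_setequal(vars$index[vars$name == "x"], c(0L, 3L, 1L))
  expect_error(get_or_create_indexed(g, root, "x", -1L), class = "ffg_invalid_index")
})

test_that("model definitions reject duplicate interfaces and have no side effects", {
  expect_error(define_model("m", c("a", "a"), function(m, a) NULL),
               class = "ffg_duplicate_interface")
  calls <- 0L
  def <- define_model("m", "a", function(m, a) calls <<- calls + 1L)
  expect_equal(calls, 0L)
  materialize_model(def)
  expect_equal(calls, 1L)
})

test_that("submodel invocation binds the missing interface to the lhs", {
  gcv_def <- gcv()
  parent <- define_model("outer", character(0), function(m) {
    tilde(m, "x0", fg_call("Normal", 0, 1))
    tilde(m, "z0", fg_call("Normal", 0, 1))
    tilde(m, "k", fg_call("Normal", 0, 1))
    tilde(m, "w", fg_call("Normal", 0, 1))
    tilde(m, "x_next", submodel(gcv_def, x = fg_ref("x0"), z = fg_ref("z0"),
                                kappa = fg_ref("k"), omega = fg_ref("w")))
  })
  g <- materialize_model(parent)
  ctxs <- fg_contexts(g)
  child <- ctxs$id[ctxs$model == "gcv"]
  expect_length(child, 1L)
  bound <- g$ctxs[[child]]$interface_bindings[["y"]]
  root <- g$root
  expect_identical(bound, g$ctxs[[root]]$bindings[["x_next"]])
})

test_that("invocation errors: supplied-but-lhs, several missing, unknown interface", {
  gcv_def <- gcv()
  base <- define_model("outer", character(0), function(m) {
    for (nm in c("a", "b", "c", "d", "e")) tilde(m, nm, fg_call("Normal", 0, 1))
    full <- list(y = fg_ref("a"), x = fg_ref("b"), z = fg_ref("c"),
                 kappa = fg_ref("d"), omega = fg_ref("e"))
    expect_error(tilde(m, "t", do.call(submodel, c(list(gcv_def), full))),
                 class = "ffg_no_missing_interface")
    expect_error(tilde(m, "t", submodel(gcv_def, x = fg_ref("b"))),
                 class = "ffg_multiple_missing_interfaces")
    expect_error(do.call(invoke, c(list(m, gcv_def), full, list(nope = fg_ref("a")))),
                 class = "ffg_unknown_interface")
  })
  materialize_model(base, validate = FALSE)
})

test_that("repeated invocations get distinct context paths and never collide", {
  gcv_def <- gcv()
  outer <- define_model("outer", character(0), function(m) {
    for (nm in c("x0", "z0", "k", "w")) tilde(m, nm, fg_call("Normal", 0, 1))
    tilde(m, "a", submodel(gcv_def, x = fg_ref("x0"), z = fg_ref("z0"),
                           kappa = fg_ref("k"), omega = fg_ref("w")))
    tilde(m, "b", submodel(gcv_def, x = fg_ref("x0"), z = fg_ref("z0"),
                           kappa = fg_ref("k"), omega = fg_ref("w")))
  })
  g <- materialize_model(outer)
  ctxs <- fg_contexts(g)
  paths <- ctxs$path[ctxs$model == "gcv"]
  expect_setequal(paths, c("outer/gcv:0", "outer/gcv:1"))
  expect_length(fg_validate(g), 0L)
})

test_that("materializing the coin model yields the hand-counted graph", {
  ct <- coin_toss(data = c(1, 1, 0))
  f <- fg_factors(ct$graph)
  expect_equal(sum(f$label == "Beta"), 1L)
  expect_equal(sum(f$label == "Bernoulli"), 3L)
  v <- fg_variables(ct$graph)
  expect_equal(nrow(v), 6L)
  expect_equal(sum(v$kind == "data"), 3L)
  expect_equal(sum(v$kind == "constant"), 2L)

  # n = 0: prior only
  ct0 <- coin_toss(0)
  expect_equal(nrow(fg_factors(ct0$graph)), 1L)
  expect_equal(nrow(fg_variables(ct0$graph)), 3L)
})

test_that("an empty-bodied model with one interface yields one variable, no factors", {
  def <- define_model("empty", "a", function(m, a) NULL)
  g <- materialize_model(def)
  expect_equal(nrow(fg_variables(g)), 1L)
  expect_equal(nrow(fg_factors(g)), 0L)
})

test_that("unbound gcv materializes the four-factor controlled-variance subgraph", {
  g <- materialize_model(gcv())
  expect_setequal(fg_factors(g)$label, c("*", "+", "exp", "Normal"))
  expect_equal(nrow(fg_factors(g)), 4L)
  d <- fg_factors(g)
  expect_equal(unname(sort(d$degree)), c(2L, 3L, 3L, 3L))
})

test_that("compound materialization equals its hand-unrolled primitive sequence", {
  # unrolling soundness: same multiset of (label, degree), same variable count
  g1 <- materialize_model(gcv_compound())
  g2 <- materialize_model(gcv())
  expect_identical(label_degree_signature(g1), label_degree_signature(g2))
  expect_equal(nrow(fg_variables(g1)), nrow(fg_variables(g2)))
})

test_that("after materialization no deterministic factor has all-constant inputs", {
  # folding soundness over several zoo graphs
  graphs <- list(
    materialize_model(gcv()),
    materialize_model(hgf(3, 2), list(y = fg_vector(2), xi = 1, kappa = 1, omega = 0)),
    hierarchical_ssm(3)$graph
  )
  for (g in graphs) {
    for (fid in ls(g$factors)) {
      f <- g$factors[[fid]]
      if (!f$deterministic) next
      inputs <- f$interfaces[setdiff(names(f$interfaces), "out")]
      kinds <- vapply(inputs, function(v) g$vars[[v]]$kind, character(1))
      expect_true(any(kinds != "constant"),
                  label = sprintf("deterministic factor %s folded too late", fid))
    }
  }
})
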