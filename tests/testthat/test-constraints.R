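test_that("plugin payloads are namespaced and target-checked", {
  ct <- coin_toss(data = c(1, 0))
  g <- ct$graph
  theta <- fg_variables(g)$id[fg_variables(g)$name == "theta"]
  attach_payload(g, "forms", theta, list(form = "Beta"))
  expect_equal(get_payload(g, "forms", theta)$form, "Beta")
  expect_error(attach_payload(g, "forms", "v999", list()), class = "ffg_unknown_target")
  # two plugins on the same node are independent
  attach_payload(g, "other", theta, list(note = 1))
  expect_equal(get_payload(g, "forms", theta)$form, "Beta")
  expect_equal(get_payload(g, "other", theta)$note, 1)
  expect_warning(attach_payload(g, "forms", theta, list(form = "Gamma")),
                 class = "ffg_payload_overwrite")
})

test_that("constraint sets validate partitions and detect conflicts", {
  cs <- build_constraint_set(fc(c("x", "y", "z"), list("x", "y", "z")))
  expect_length(cs$entries, 1L)
  expect_length(cs$entries[[1]]$partition, 3L)

  expect_error(fc(c("x", "y"), list("x")), class = "ffg_malformed_partition")
  expect_error(fc(c("x", "y"), list(c("x", "y"), "y")), class = "ffg_malformed_partition")
  expect_error(fc(c("x"), list(character(0), "x")), class = "ffg_malformed_partition")

  expect_error(
    build_constraint_set(fc(c("x", "y"), list("x", "y")),
                         fc(c("x", "y"), list(c("x", "y")))),
    class = "ffg_conflicting_constraints")
  # compatible overlap is fine
  build_constraint_set(fc(c("x", "y"), list("x", "y")),
                       fc(c("y", "z"), list("y", "z")))
})

test_that("scope patterns match every invocation of a submodel, counters ignored", {
  g <- materialize_model(hgf(3, 3), list(y = fg_vector(3), xi = 1))
  cs <- build_constraint_set(fc(c("omega", "kappa", "u"),
                                list("omega", "kappa", "u"), scope = "gcv"))
  sc <- resolve_scopes(cs, g)
  matched <- names(Filter(Negate(is.null), sc$map))
  ctxs <- fg_contexts(g)
  gcv_ctxs <- ctxs$id[ctxs$model == "gcv"]
  expect_setequal(matched, gcv_ctxs)
  expect_length(gcv_ctxs, 6L) # one direct + one inside gcv_lm per timestep
  expect_length(sc$diagnostics, 0L)

  # hierarchical ssm: the ssm scope matches both invocations
  mod <- hierarchical_ssm(2)
  sc2 <- resolve_scopes(build_constraint_set(fc(c("precision"), list("precision"), scope = "ssm")),
                        mod$graph)
  ssm_ctxs <- fg_contexts(mod$graph)
  expect_setequal(names(Filter(Negate(is.null), sc2$map)),
                  ssm_ctxs$id[ssm_ctxs$model == "ssm"])

  # absent submodel: warning-level diagnostic, not fatal
  sc3 <- resolve_scopes(build_constraint_set(fc("a", list("a"), scope = "absent")), g)
  expect_match(sc3$diagnostics, "UnmatchedScope")
})

test_that("empty constraints reproduce the Bethe default: one joint block per factor", {
  e4 <- eq4_graph()
  lf <- apply_factorization(e4$graph, build_constraint_set(list()))
  for (fid in names(lf)) {
    expect_length(lf[[fid]], 1L)
    expect_setequal(lf[[fid]][[1]], names(e4$graph$factors[[fid]]$interfaces))
  }
})

test_that("the state-space constraint splits the likelihood factor in every step context", {
  T <- 5L
  mod <- hierarchical_ssm(T)
  lf <- apply_factorization(mod$graph, mod$constraints)
  fs <- fg_factors(mod$graph)
  targets <- fs$id[fs$label == "NormalMeanPrecision"]
  expect_length(targets, 2L * T) # both chains
  for (fid in targets) {
    blocks <- lapply(lf[[fid]], sort)
    expect_setequal(vapply(blocks, paste, character(1), collapse = ","),
                    c("mean,out", "precision"))
  }
  # non-likelihood factors inside ssm_step split only around x_next
  trans <- fs$id[fs$label == "NormalMeanVariance"]
  for (fid in trans) {
    expect_true(list("out") %in% lapply(lf[[fid]], identity) ||
                  any(vapply(lf[[fid]], function(b) identical(b, "out"), logical(1))))
  }
})

test_that("the mean-field constraint isolates omega, kappa and u in every gcv context", {
  g <- materialize_model(hgf(3, 2), list(y = fg_vector(2), xi = 1))
  cs <- build_constraint_set(fc(c("omega", "kappa", "u"),
                                list("omega", "kappa", "u"), scope = "gcv"))
  lf <- apply_factorization(g, cs)
  ctxs <- fg_contexts(g)
  gcv_ctxs <- ctxs$id[ctxs$model == "gcv"]
  for (cid in gcv_ctxs) {
    for (fid in ls(g$factors)) {
      f <- g$factors[[fid]]
      if (f$ctx != cid) next
      for (iface in names(f$interfaces)) {
        vname <- g$vars[[f$interfaces[[iface]]]]$name
        if (vname %in% c("omega", "kappa", "u")) {
          blk <- Find(function(b) iface %in% b, lf[[fid]])
          expect_length(blk, 1L)
        }
      }
    }
  }
})

test_that("constraints naming unresolvable or constant variables are rejected", {
  mod <- hierarchical_ssm(2)
  expect_error(
    apply_factorization(mod$graph,
                        build_constraint_set(fc("ghost", list("ghost"), scope = "ssm_step"))),
    class = "ffg_unknown_constraint_variable")
  g <- materialize_model(hgf(3, 1), list(y = fg_vector(1), xi = 1, kappa = 1, omega = 0))
  expect_error(
    apply_factorization(g, build_constraint_set(
      fc(c("omega", "u"), list("omega", "u"), scope = "gcv"))),
    class = "ffg_constraint_on_constant")
})

test_that("resolved partitions equal the brute-force lattice meet", {
  mod <- hierarchical_ssm(2)
  lf <- apply_factorization(mod$graph, mod$constraints)
  for (fid in names(lf)) {
    f <- mod$graph$factors[[fid]]
    ifaces <- names(f$interfaces)
    in_step <- mod$graph$ctxs[[f$ctx]]$model_name == "ssm_step"
    induced <- list(list(ifaces)) # Bethe default
    if (in_step && f$label == "NormalMeanPrecision") {
      # the FC groups (x_next -> mean, y -> out) against precision
      induced <- c(induced, list(list(c("out", "mean"), "precision")))
    } else if (in_step && f$label == "NormalMeanVariance") {
      # only x_next (this factor's out) is mentioned; the rest stay together
      induced <- c(induced, list(list("out", c("mean", "var"))))
    }
    expect_identical(canon_partition(lf[[fid]]), oracle_meet(induced, ifaces),
                     label = sprintf("factor %s (%s)", fid, f$label))
  }
})

test_that("applying a constraint set twice is idempotent", {
  mod <- hierarchical_ssm(3)
  lf1 <- apply_factorization(mod$graph, mod$constraints)
  lf2 <- apply_factorization(mod$graph, mod$constraints)
  expect_identical(unclass(lf1)[order(names(lf1))], unclass(lf2)[order(names(lf2))])
})

test_that("functional-form constraints tag variables as plugin payloads", {
  ct <- coin_toss(data = c(1, 1, 0))
  cs <- build_constraint_set(ffc("theta", "Beta"))
  tags <- apply_functional_form(ct$graph, cs)
  theta <- fg_variables(ct$graph)$id[fg_variables(ct$graph)$name == "theta"]
  expect_equal(unname(tags[theta]), "Beta")
  expect_equal(get_payload(ct$graph, "variational_constraints", theta)$form, "Beta")

  expect_length(apply_functional_form(ct$graph, build_constraint_set(list())), 0L)
  expect_error(apply_functional_form(ct$graph, build_constraint_set(ffc("theta", "Frobnitz"))),
               class = "ffg_unknown_family")
})

test_that("constraint documents parse from YAML with nested scopes", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "constraints:",
    "  - q: [theta]",
    "    form: Beta",
    "  - scope: ssm_step",
    "    constraints:",
    "      - q: [x_next, y, precision]",
    "        factorization: [[x_next, y], [precision]]"
  ), path)
  cs <- read_constraints(path)
  expect_length(cs$entries, 2L)
  expect_s3_class(cs$entries[[1]], "ffg_ffc")
  expect_equal(cs$entries[[2]]$scope, "ssm_step")
  expect_length(cs$entries[[2]]$partition, 2L)
})
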