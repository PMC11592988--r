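# Executable model fixtures: the coin-toss model, the
# Gaussian-with-Controlled-Variance (GCV) family and the hierarchical
# Gaussian filter built from it, a Bayesian neural network constructed from
# neuron submodels, and the hierarchical state-space model with its
# constraint fixture.

#' Coin-toss model: `theta ~ Beta(1, 1)`, `y_i ~ Bernoulli(theta)`
#'
#' @param n Number of tosses (unobserved `y`), or
#' @param data 0/1 vector of observed tosses (overrides `n`).
#' @return List with `definition` (an `ffg_model`) and `graph` (materialized).
#' @export
coin_toss <- function(n = 0L, data = NULL) {
  def <- define_model("coin_toss", "y", function(m, y) {
    tilde(m, "theta", fg_call("Beta", 1, 1))
    nn <- if (is_vecref(y)) vec_length(y) else 0L
    for (i in seq_len(nn)) {
      tilde(m, at(y, i - 1L), fg_call("Bernoulli", fg_ref("theta")))
    }
  })
  binding <- if (!is.null(data)) list(y = fg_data(data)) else list(y = fg_vector(n))
  graph <- materialize_model(def, binding)
  list(definition = def, graph = graph)
}

#' Discrete tables for a coin-toss graph on a probability grid
#'
#' Discretizes the latent probability onto a midpoint grid so the enumeration
#' oracle and sum-product can run on the (continuous) coin model.
#'
#' @param graph A [coin_toss()] graph.
#' @param grid_size Number of grid points (default 201).
#' @return List of [factor_table()]s.
#' @export
coin_toss_tables <- function(graph, grid_size = 201L) {
  grid <- (seq_len(grid_size) - 0.5) / grid_size
  tables <- list()
  for (fid in sort_ids(ls(graph$factors))) {
    f <- graph$factors[[fid]]
    if (f$label == "Beta") {
      a <- graph$vars[[f$interfaces[["a"]]]]$value
      b <- graph$vars[[f$interfaces[["b"]]]]$value
      tables[[fid]] <- factor_table(fid,
        domains = list(out = grid, a = a, b = b),
        table = array(stats::dbeta(grid, a, b), c(grid_size, 1L, 1L)))
    } else if (f$label == "Bernoulli") {
      tables[[fid]] <- factor_table(fid,
        domains = list(out = c(0, 1), p = grid),
        table = outer(c(0, 1), grid, function(y, p) p^y * (1 - p)^(1 - y)))
    } else {
      ffg_stop("not_supported", "unexpected factor label '%s' in coin graph", f$label)
    }
  }
  tables
}

#' Gaussian-with-Controlled-Variance model, `y ~ N(x, exp(kappa * z + omega))`
#'
#' `gcv()` uses named deterministic (`:=`) statements; `gcv_compound()`
#' builds the same graph from a single compound statement. Interfaces are
#' `(y, x, z, kappa, omega)`.
#'
#' @return An `ffg_model`.
#' @export
gcv <- function() {
  define_model("gcv", c("y", "x", "z", "kappa", "omega"),
               function(m, y, x, z, kappa, omega) {
    det_assign(m, "u", fg_call("+", fg_call("*", kappa, z), omega))
    det_assign(m, "s", fg_call("exp", fg_ref("u")))
    tilde(m, y, fg_call("Normal", x, fg_ref("s")))
  })
}

#' @rdname gcv
#' @export
gcv_compound <- function() {
  define_model("gcv", c("y", "x", "z", "kappa", "omega"),
               function(m, y, x, z, kappa, omega) {
    tilde(m, y, fg_call("Normal", x,
                        fg_call("exp", fg_call("+", fg_call("*", kappa, z), omega))))
  })
}

#' GCV state transition chained with a Gaussian likelihood
#'
#' `x_next ~ gcv(x = x_prev, z, kappa, omega)`; `y ~ N(x_next, 1)`.
#' Interfaces `(y, x_prev, x_next, z, kappa, omega)`.
#'
#' @return An `ffg_model`.
#' @export
gcv_lm <- function() {
  gcv_def <- gcv()
  define_model("gcv_lm", c("y", "x_prev", "x_next", "z", "kappa", "omega"),
               function(m, y, x_prev, x_next, z, kappa, omega) {
    tilde(m, x_next, submodel(gcv_def, x = x_prev, z = z, kappa = kappa, omega = omega))
    tilde(m, y, fg_call("Normal", fg_ref("x_next"), 1))
  })
}

#' Hierarchical Gaussian filter built from gcv/gcv_lm submodels
#'
#' Layer `depth` (top) evolves as a Gaussian random walk with variance `xi`;
#' every intermediate layer is a gcv transition controlled by the layer
#' above; the bottom layer is a gcv_lm producing the observation. Per time
#' step this creates one top-layer transition, `depth - 2` gcv invocations
#' and one gcv_lm invocation.
#'
#' @param depth Number of layers (>= 2; the customary default is 3).
#' @param T Number of time steps (>= 1).
#' @return An `ffg_model` with interfaces `(y, xi, kappa, omega)`.
#' @export
hgf <- function(depth = 3L, T = 1L) {
  if (depth < 2L) ffg_stop("invalid_params", "hgf needs depth >= 2")
  if (T < 1L) ffg_stop("invalid_params", "hgf needs T >= 1")
  gcv_def <- gcv(); gcv_lm_def <- gcv_lm()
  layer_name <- function(j) if (j == 1L) "x" else paste0("z", j)
  define_model("hgf", c("y", "xi", "kappa", "omega"),
               function(m, y, xi, kappa, omega) {
    for (j in seq_len(depth)) {
      tilde(m, at(layer_name(j), 0L), fg_call("Normal", 0, 1))
    }
    top <- layer_name(depth)
    for (t in seq_len(T)) {
      tilde(m, at(top, t), fg_call("Normal", at(top, t - 1L), xi))
      if (depth > 2L) {
        for (j in seq(depth - 1L, 2L)) {
          tilde(m, at(layer_name(j), t),
                submodel(gcv_def, x = at(layer_name(j), t - 1L),
                         z = at(layer_name(j + 1L), t),
                         kappa = kappa, omega = omega))
        }
      }
      tilde(m, at("x", t),
            submodel(gcv_lm_def, x_prev = at("x", t - 1L),
                     z = at(layer_name(2L), t), y = at(y, t - 1L),
                     kappa = kappa, omega = omega))
    }
  })
}

#' Hand-flattened hierarchical Gaussian filter
#'
#' The same statements as [hgf()] with the gcv/gcv_lm bodies inlined in the
#' root context — the nesting-equivalence reference: both builds must yield
#' identical multisets of (factor label, degree) pairs.
#'
#' @inheritParams hgf
#' @return An `ffg_model`.
#' @export
hgf_flat <- function(depth = 3L, T = 1L) {
  layer_name <- function(j) if (j == 1L) "x" else paste0("z", j)
  define_model("hgf_flat", c("y", "xi", "kappa", "omega"),
               function(m, y, xi, kappa, omega) {
    for (j in seq_len(depth)) {
      tilde(m, at(layer_name(j), 0L), fg_call("Normal", 0, 1))
    }
    top <- layer_name(depth)
    inline_gcv <- function(out_ref, x_ref, z_ref, tag) {
      det_assign(m, paste0("u_", tag), fg_call("+", fg_call("*", kappa, z_ref), omega))
      det_assign(m, paste0("s_", tag), fg_call("exp", fg_ref(paste0("u_", tag))))
      tilde(m, out_ref, fg_call("Normal", x_ref, fg_ref(paste0("s_", tag))))
    }
    for (t in seq_len(T)) {
      tilde(m, at(top, t), fg_call("Normal", at(top, t - 1L), xi))
      if (depth > 2L) {
        for (j in seq(depth - 1L, 2L)) {
          inline_gcv(at(layer_name(j), t), at(layer_name(j), t - 1L),
                     at(layer_name(j + 1L), t), sprintf("l%d_t%d", j, t))
        }
      }
      inline_gcv(at("x", t), at("x", t - 1L), at(layer_name(2L), t),
                 sprintf("lm_t%d", t))
      tilde(m, at(y, t - 1L), fg_call("Normal", at("x", t), 1))
    }
  })
}

#' Building blocks for a Bayesian neural network
#'
#' `neural_dot(d)`: output `~ tanh(dot(input, w))` over `d`-vectors.
#' `neuron(d)`: `d` standard-normal weight priors plus a neural_dot.
#' `dense(n, d)`: `n` neurons sharing one `d`-dimensional input.
#' `bnn(layer_sizes)`: a chain of dense layers (graph construction only; no
#' training).
#'
#' @param d Input dimension.
#' @return An `ffg_model`.
#' @export
neural_dot <- function(d) {
  define_model("neural_dot", c("out", "input", "w"), function(m, out, input, w) {
    refs <- c(lapply(seq_len(d) - 1L, function(i) at(input, i)),
              lapply(seq_len(d) - 1L, function(i) at(w, i)))
    tilde(m, out, fg_call("tanh", do.call(fg_call, c(list("dot"), refs))))
  })
}

#' @rdname neural_dot
#' @export
neuron <- function(d) {
  nd <- neural_dot(d)
  define_model("neuron", c("out", "input"), function(m, out, input) {
    w <- local_vec(m, "w", d)
    for (i in seq_len(d) - 1L) {
      tilde(m, at(w, i), fg_call("Normal", 0, 1))
    }
    tilde(m, out, submodel(nd, input = input, w = w))
  })
}

#' @rdname neural_dot
#' @param n Number of neurons in the layer.
#' @export
dense <- function(n, d) {
  neuron_def <- neuron(d)
  define_model("dense", c("out", "input"), function(m, out, input) {
    for (j in seq_len(n) - 1L) {
      tilde(m, at(out, j), submodel(neuron_def, input = input))
    }
  })
}

#' @rdname neural_dot
#' @param layer_sizes Positive integers: input dimension followed by the
#'   width of each layer. The default gives the customary four-layer
#'   perceptron.
#' @export
bnn <- function(layer_sizes = c(2L, 3L, 3L, 3L, 1L)) {
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    ffg_stop("invalid_params", "layer_sizes must be >= 2 positive integers")
  }
  n_layers <- length(layer_sizes) - 1L
  defs <- lapply(seq_len(n_layers), function(l) dense(layer_sizes[l + 1L], layer_sizes[l]))
  define_model("bnn", c("out", "input"), function(m, out, input) {
    prev <- input
    for (l in seq_len(n_layers)) {
      target <- if (l == n_layers) out else local_vec(m, paste0("h", l), layer_sizes[l + 1L])
      invoke(m, defs[[l]], out = target, input = prev)
      prev <- target
    }
  })
}

#' Hierarchical state-space model
#'
#' A random walk with drift where the drift is itself a random walk: the
#' `ssm` submodel is invoked twice (once generating the drift sequence, once
#' the observed states, fed by the drift) and invokes `ssm_step` on every
#' data point. In each step two Gaussian variables are summed, a Gaussian
#' transition is applied, and an observation with Gamma-distributed precision
#' is emitted.
#'
#' @param T Number of time steps.
#' @param data Optional numeric observations of length `T`.
#' @return List with `definition`, `graph`, and `constraints` (the
#'   factorization constraint `q(x_next, y, precision) =
#'   q(x_next, y) q(precision)` scoped to every ssm_step context).
#' @export
hierarchical_ssm <- function(T = 1L, data = NULL) {
  if (T < 1L) ffg_stop("invalid_params", "T must be >= 1")
  ssm_step_def <- define_model("ssm_step", c("x_prev", "u", "x_next", "y", "precision"),
                               function(m, x_prev, u, x_next, y, precision) {
    det_assign(m, "mean", fg_call("+", x_prev, u))
    tilde(m, x_next, fg_call("Normal", mean = fg_ref("mean"), var = 0.1))
    tilde(m, y, fg_call("Normal", mean = x_next, precision = precision))
  })
  ssm_def <- define_model("ssm", c("x", "u", "y", "precision"),
                          function(m, x, u, y, precision) {
    nn <- vec_length(y)
    for (t in seq_len(nn) - 1L) {
      tilde(m, at(x, t + 1L),
            submodel(ssm_step_def, x_prev = at(x, t), u = at(u, t),
                     y = at(y, t), precision = precision))
    }
  })
  def <- define_model("hierarchical_ssm", "y", function(m, y) {
    nn <- vec_length(y)
    tilde(m, "drift_precision", fg_call("Gamma", 2, 2))
    tilde(m, "obs_precision", fg_call("Gamma", 2, 2))
    dw <- local_vec(m, "drift_walk", nn + 1L)
    hs <- local_vec(m, "hidden_state", nn + 1L)
    drift <- local_vec(m, "hidden_state_drift", nn)
    tilde(m, at(dw, 0L), fg_call("Normal", 0, 1))
    tilde(m, at(hs, 0L), fg_call("Normal", 0, 1))
    zeros <- const_vec(m, "zero", rep(0, nn))
    invoke(m, ssm_def, x = dw, u = zeros, y = drift,
           precision = fg_ref("drift_precision"))
    invoke(m, ssm_def, x = hs, u = drift, y = y,
           precision = fg_ref("obs_precision"))
  })
  binding <- if (!is.null(data)) list(y = fg_data(data)) else list(y = fg_vector(T))
  graph <- materialize_model(def, binding)
  list(definition = def, graph = graph, constraints = ssm_constraints())
}

#' Constraint fixture for the hierarchical state-space model
#'
#' In the variational posterior the next state/observation pair is assumed
#' independent of the observation precision in every step:
#' `q(x_next, y, precision) = q(x_next, y) q(precision)`.
#'
#' @return An `ffg_constraint_set`.
#' @export
ssm_constraints <- function() {
  build_constraint_set(fc(c("x_next", "y", "precision"),
                          list(c("x_next", "y"), "precision"),
                          scope = "ssm_step"))
}

#' The four-variable example factorization
#'
#' Builds the graph of `p(s1, s2, s3, s4) = fa(s1) fb(s1, s2, s3) fc(s2, s4)
#' fd(s3) fe(s4)`.
#'
#' @return List with `graph`, `vars` (named ids s1..s4), `factors` (named ids
#'   fa..fe).
#' @export
eq4_graph <- function() {
  g <- fg_new("eq4")
  root <- fg_root(g)
  s <- vapply(1:4, function(i) fg_add_variable(g, root, paste0("s", i), "random"),
              character(1))
  names(s) <- paste0("s", 1:4)
  mk <- function(label, vars) {
    fg_add_factor(g, root, label, stats::setNames(s[vars], paste0("i", seq_along(vars))))
  }
  f <- c(fa = mk("fa", "s1"), fb = mk("fb", c("s1", "s2", "s3")),
         fc = mk("fc", c("s2", "s4")), fd = mk("fd", "s3"), fe = mk("fe", "s4"))
  list(graph = g, vars = s, factors = f)
}

#' Random discrete factor-graph model (test fixture generator)
#'
#' Generates a random tree-structured (or optionally single-cycle) discrete
#' factor graph with random positive tables: unary factors on every variable
#' plus pairwise factors along a random spanning tree.
#'
#' @param n_vars Number of latent variables (>= 1).
#' @param max_domain Maximum domain size (>= 2).
#' @param seed Integer seed.
#' @param cycle If `TRUE`, add one extra pairwise factor closing a cycle
#'   (requires `n_vars >= 3`).
#' @return List with `graph` and `tables`.
#' @export
random_discrete_model <- function(n_vars, max_domain = 3L, seed = 1L, cycle = FALSE) {
  set.seed(seed)
  g <- fg_new("random_discrete")
  root <- fg_root(g)
  dom_sizes <- sample(2:max_domain, n_vars, replace = TRUE)
  vars <- vapply(seq_len(n_vars), function(i) {
    fg_add_variable(g, root, paste0("x", i), "random")
  }, character(1))
  tables <- list()
  add_unary <- function(i) {
    fid <- fg_add_factor(g, root, "prior", stats::setNames(vars[i], "i1"))
    tables[[fid]] <<- factor_table(fid, domains = list(i1 = seq_len(dom_sizes[i])),
                                   table = stats::runif(dom_sizes[i], 0.1, 1))
  }
  add_pair <- function(i, j) {
    fid <- fg_add_factor(g, root, "pair",
                         stats::setNames(vars[c(i, j)], c("i1", "i2")))
    tables[[fid]] <<- factor_table(fid,
      domains = list(i1 = seq_len(dom_sizes[i]), i2 = seq_len(dom_sizes[j])),
      table = array(stats::runif(dom_sizes[i] * dom_sizes[j], 0.1, 1),
                    c(dom_sizes[i], dom_sizes[j])))
  }
  for (i in seq_len(n_vars)) add_unary(i)
  if (n_vars > 1L) {
    for (i in 2:n_vars) add_pair(sample.int(i - 1L, 1L), i)
    if (cycle && n_vars >= 3L) {
      pick <- sample.int(n_vars, 2L)
      add_pair(pick[1L], pick[2L])
    }
  }
  list(graph = g, tables = tables)
}
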