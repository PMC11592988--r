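# Reference inference for discrete models: exact enumeration, sum-product
# belief propagation, Bethe free energy, and the normalization /
# marginalization constraint checks that make the Bethe family a valid
# variational family.

#' Attach a discrete table to a factor
#'
#' @param factor_id Factor id in the graph.
#' @param domains Named list, interface name -> finite value vector.
#' @param table Nonnegative numeric array; `dim(table)` must match the domain
#'   sizes in interface order (a vector is accepted for a single interface).
#' @return An `ffg_factor_table`.
#' @export
factor_table <- function(factor_id, domains, table) {
  sizes <- vapply(domains, length, integer(1))
  tab <- as.array(table)
  if (length(sizes) == 1L) dim(tab) <- sizes
  if (!identical(unname(dim(tab)), unname(sizes))) {
    ffg_stop("table_shape", "table shape (%s) does not match domain sizes (%s)",
             paste(dim(tab), collapse = "x"), paste(sizes, collapse = "x"))
  }
  if (any(tab < 0) || all(tab == 0)) {
    ffg_stop("table_values", "table must be nonnegative and not all zero")
  }
  structure(list(factor_id = factor_id, domains = domains, table = tab),
            class = "ffg_factor_table")
}

# Compile graph + tables into a clamped discrete network: per factor, the
# table is conditioned on constant/data interfaces, leaving latent interfaces
# only. Latent variable domains are cross-checked across factors.
compile_network <- function(graph, tables) {
  if (!is.null(names(tables)) && all(nzchar(names(tables)))) {
    tabmap <- tables
  } else {
    tabmap <- stats::setNames(tables, vapply(tables, function(t) t$factor_id, character(1)))
  }
  factors <- list()
  var_domains <- list()
  for (fid in sort_ids(ls(graph$factors))) {
    f <- graph$factors[[fid]]
    ft <- tabmap[[fid]]
    if (is.null(ft)) ffg_stop("missing_table", "no discrete table for factor %s (%s)", fid, f$label)
    ifaces <- names(f$interfaces)
    if (!setequal(names(ft$domains), ifaces)) {
      ffg_stop("table_shape", "table for %s names interfaces {%s}, factor has {%s}",
               fid, paste(names(ft$domains), collapse = ","), paste(ifaces, collapse = ","))
    }
    doms <- ft$domains[ifaces]
    tab <- ft$table
    if (!identical(names(ft$domains), ifaces)) {
      tab <- aperm(tab, match(ifaces, names(ft$domains)))
    }
    keep <- logical(length(ifaces))
    index <- vector("list", length(ifaces))
    for (k in seq_along(ifaces)) {
      vid <- f$interfaces[[k]]
      v <- graph$vars[[vid]]
      if (v$kind == "random") {
        keep[k] <- TRUE
        index[[k]] <- seq_along(doms[[k]])
        prev <- var_domains[[vid]]
        if (is.null(prev)) {
          var_domains[[vid]] <- doms[[k]]
        } else if (!identical(prev, doms[[k]])) {
          ffg_stop("domain_mismatch", "inconsistent domains for variable %s", vid)
        }
      } else {
        pos <- match(v$value, doms[[k]])
        if (is.na(pos)) {
          ffg_stop("domain_mismatch", "clamped value %s of %s outside table domain", v$value, vid)
        }
        index[[k]] <- pos
      }
    }
    red <- do.call(`[`, c(list(tab), index, list(drop = FALSE)))
    lat_vars <- unname(f$interfaces[keep])
    if (anyDuplicated(lat_vars)) {
      ffg_stop("not_supported", "factor %s touches a latent variable through several interfaces", fid)
    }
    red <- array(red, dim = vapply(which(keep), function(k) length(doms[[k]]), integer(1)))
    factors[[fid]] <- list(id = fid, vars = lat_vars, ifaces = ifaces[keep],
                           table = red, label = f$label)
  }
  list(factors = factors, var_domains = var_domains,
       latent = names(var_domains))
}

#' Exact marginals and log evidence by enumeration
#'
#' Brute-force enumeration of the clamped joint distribution; the independent
#' oracle everything else is checked against. Data and constant nodes are
#' clamped to their values before summation.
#'
#' @param graph An `ffg` graph.
#' @param tables List of [factor_table()]s covering every factor.
#' @param cap Maximum joint state count (error beyond it).
#' @param return_joint Also return the normalized joint and the unnormalized
#'   log joint over latent states.
#' @return List with `marginals` (named list variable id -> named probability
#'   vector), `log_evidence`, `vars`, `domains`, and optionally `joint`,
#'   `log_unnorm`.
#' @export
brute_force <- function(graph, tables, cap = 1e7, return_joint = FALSE) {
  net <- compile_network(graph, tables)
  vars <- net$latent
  dims <- vapply(vars, function(v) length(net$var_domains[[v]]), integer(1))
  n_states <- prod(dims)
  if (length(vars) == 0L) {
    lz <- sum(vapply(net$factors, function(f) log(as.numeric(f$table)), numeric(1)))
    return(list(marginals = list(), log_evidence = lz, vars = character(0), domains = list()))
  }
  if (n_states > cap) {
    ffg_stop("state_space_too_large", "%g joint states exceed cap %g", n_states, cap)
  }
  strides <- c(1, cumprod(dims))[seq_along(dims)]
  idx <- lapply(seq_along(vars), function(j) {
    ((seq_len(n_states) - 1L) %/% strides[j]) %% dims[j] + 1L
  })
  names(idx) <- vars
  logw <- numeric(n_states)
  for (f in net$factors) {
    if (length(f$vars) == 0L) {
      logw <- logw + log(as.numeric(f$table))
      next
    }
    pos <- idx[f$vars]
    cell <- pos[[1L]]
    if (length(f$vars) > 1L) {
      fd <- dim(f$table)
      mult <- 1L
      cell <- rep(1L, n_states)
      for (k in seq_along(f$vars)) {
        cell <- cell + (pos[[k]] - 1L) * mult
        mult <- mult * fd[k]
      }
    }
    logw <- logw + log(as.numeric(f$table)[cell])
  }
  mx <- max(logw)
  if (!is.finite(mx)) ffg_stop("table_values", "all joint states have zero probability")
  w <- exp(logw - mx)
  z <- sum(w)
  log_evidence <- mx + log(z)
  p <- w / z
  marginals <- stats::setNames(vector("list", length(vars)), vars)
  for (j in seq_along(vars)) {
    m <- vapply(seq_len(dims[j]), function(s) sum(p[idx[[j]] == s]), numeric(1))
    names(m) <- as.character(net$var_domains[[vars[j]]])
    marginals[[j]] <- m
  }
  out <- list(marginals = marginals, log_evidence = log_evidence,
              vars = vars, domains = net$var_domains[vars])
  if (return_joint) {
    out$joint <- array(p, dim = dims)
    out$log_unnorm <- array(logw, dim = dims)
  }
  out
}

# --- sum-product -------------------------------------------------------------

msg_key <- function(from, to) paste(from, to, sep = "|")

# product of incoming factor->variable messages, excluding `except`
var_incoming <- function(msgs, v, nbs, dom_len, except = NULL) {
  out <- rep(1, dom_len)
  for (f in nbs) {
    if (!is.null(except) && f == except) next
    m <- msgs[[msg_key(f, v)]]
    if (!is.null(m)) out <- out * m
  }
  out
}

factor_to_var <- function(f, v, msgs, domlens) {
  k <- match(v, f$vars)
  tab <- f$table
  nd <- length(f$vars)
  if (nd == 1L) return(as.numeric(tab))
  for (j in seq_len(nd)) {
    if (j == k) next
    m <- msgs[[msg_key(f$vars[j], f$id)]]
    if (is.null(m)) m <- rep(1, domlens[[f$vars[j]]])
    tab <- tab * array(rep(m, each = prod(dim(tab)[seq_len(j - 1L)])),
                       dim = dim(tab))
  }
  apply(tab, k, sum)
}

#' Sum-product belief propagation
#'
#' Exact on acyclic graphs with a two-pass leaf-to-root-to-leaf schedule
#' (stationary points of the Bethe free energy coincide with belief
#' propagation fixed points); cyclic graphs use damped flooding.
#'
#' @param graph An `ffg` graph.
#' @param tables List of [factor_table()]s.
#' @param schedule `"auto"` (default; tree schedule when acyclic),
#'   `"tree"`, or `"flooding"`.
#' @param max_sweeps Sweep budget for flooding.
#' @param tol Convergence tolerance on the maximum message update.
#' @param damping Damping weight on the previous message (flooding only;
#'   default 0.5).
#' @return An `ffg_bp_result`: `belief` (an `ffg_belief`), `messages`,
#'   `converged`, `iterations`, `log_evidence` (trees only, else `NA`).
#' @export
sum_product <- function(graph, tables, schedule = c("auto", "tree", "flooding"),
                        max_sweeps = 100L, tol = 1e-12, damping = 0.5) {
  schedule <- match.arg(schedule)
  net <- compile_network(graph, tables)
  vars <- net$latent
  domlens <- lapply(net$var_domains, length)
  facs <- Filter(function(f) length(f$vars) > 0L, net$factors)
  var_nbs <- stats::setNames(lapply(vars, function(v) {
    vapply(Filter(function(f) v %in% f$vars, facs), function(f) f$id, character(1))
  }), vars)
  fmap <- stats::setNames(facs, vapply(facs, function(f) f$id, character(1)))

  # acyclicity via union-find over the bipartite incidence
  parent <- stats::setNames(c(vars, names(fmap)), c(vars, names(fmap)))
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  acyclic <- TRUE
  for (f in facs) for (v in f$vars) {
    rv <- find(v); rf <- find(f$id)
    if (rv == rf) acyclic <- FALSE else parent[[rv]] <- rf
  }
  if (schedule == "tree" && !acyclic) {
    ffg_stop("not_a_tree", "tree schedule requested on a cyclic graph")
  }
  use_tree <- (schedule == "tree") || (schedule == "auto" && acyclic)

  msgs <- new.env(parent = emptyenv())
  log_scale <- 0
  send_vf <- function(v, f, damp = 0) {
    m <- var_incoming(msgs, v, var_nbs[[v]], domlens[[v]], except = f)
    s <- sum(m)
    if (s <= 0) m <- rep(1 / length(m), length(m)) else m <- m / s
    old <- msgs[[msg_key(v, f)]]
    if (!is.null(old) && damp > 0) m <- damp * old + (1 - damp) * m
    delta <- if (is.null(old)) Inf else max(abs(m - old))
    assign(msg_key(v, f), m, envir = msgs)
    if (s > 0) log_scale <<- log_scale + log(s)
    delta
  }
  send_fv <- function(f, v, damp = 0) {
    m <- factor_to_var(fmap[[f]], v, msgs, domlens)
    s <- sum(m)
    if (s <= 0) m <- rep(1 / length(m), length(m)) else m <- m / s
    old <- msgs[[msg_key(f, v)]]
    if (!is.null(old) && damp > 0) m <- damp * old + (1 - damp) * m
    delta <- if (is.null(old)) Inf else max(abs(m - old))
    assign(msg_key(f, v), m, envir = msgs)
    if (s > 0) log_scale <<- log_scale + log(s)
    delta
  }

  converged <- TRUE
  iterations <- 1L
  log_evidence <- NA_real_
  if (use_tree) {
    # BFS forest over the bipartite graph; upward then downward pass
    nodes <- c(vars, names(fmap))
    visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
    log_evidence <- 0
    for (root in vars) {
      if (visited[[root]]) next
      order <- character(0); par <- list()
      queue <- root; visited[[root]] <- TRUE; par[[root]] <- NA_character_
      while (length(queue) > 0L) {
        x <- queue[1L]; queue <- queue[-1L]
        order <- c(order, x)
        nbs <- if (x %in% vars) var_nbs[[x]] else fmap[[x]]$vars
        for (nb in nbs) {
          if (!visited[[nb]]) {
            visited[[nb]] <- TRUE
            par[[nb]] <- x
            queue <- c(queue, nb)
          }
        }
      }
      log_scale <- 0
      for (x in rev(order)) { # upward
        p <- par[[x]]
        if (is.na(p)) next
        if (x %in% vars) send_vf(x, p) else send_fv(x, p)
      }
      bel <- var_incoming(msgs, root, var_nbs[[root]], domlens[[root]])
      log_evidence <- log_evidence + log_scale + log(sum(bel))
      for (x in order) { # downward
        nbs <- if (x %in% vars) var_nbs[[x]] else fmap[[x]]$vars
        for (nb in nbs) {
          if (identical(par[[x]], nb)) next
          if (x %in% vars) send_vf(x, nb) else send_fv(x, nb)
        }
      }
    }
    # isolated factor components (no latent vars) contribute directly
    for (f in net$factors) {
      if (length(f$vars) == 0L) log_evidence <- log_evidence + log(as.numeric(f$table))
    }
  } else {
    # flooding with damping
    for (v in vars) for (f in var_nbs[[v]]) {
      assign(msg_key(v, f), rep(1 / domlens[[v]], domlens[[v]]), envir = msgs)
    }
    converged <- FALSE
    for (it in seq_len(max_sweeps)) {
      delta <- 0
      for (f in facs) for (v in f$vars) delta <- max(delta, send_fv(f$id, v, damp = damping))
      for (v in vars) for (f in var_nbs[[v]]) delta <- max(delta, send_vf(v, f, damp = damping))
      iterations <- it
      if (delta < tol) { converged <- TRUE; break }
    }
  }

  belief <- beliefs_from_messages(net, msgs, var_nbs, domlens)
  structure(list(belief = belief, messages = as.list(msgs), converged = converged,
                 iterations = iterations, log_evidence = log_evidence,
                 network = net),
            class = "ffg_bp_result")
}

beliefs_from_messages <- function(net, msgs, var_nbs, domlens) {
  edge <- stats::setNames(lapply(net$latent, function(v) {
    b <- var_incoming(msgs, v, var_nbs[[v]], domlens[[v]])
    b <- b / sum(b)
    names(b) <- as.character(net$var_domains[[v]])
    b
  }), net$latent)
  node <- list()
  for (f in net$factors) {
    if (length(f$vars) == 0L) next
    tab <- f$table
    nd <- length(f$vars)
    for (j in seq_len(nd)) {
      m <- msgs[[msg_key(f$vars[j], f$id)]]
      if (is.null(m)) m <- rep(1, domlens[[f$vars[j]]])
      tab <- tab * array(rep(m, each = prod(dim(tab)[seq_len(j - 1L)])), dim = dim(tab))
    }
    tab <- tab / sum(tab)
    node[[f$id]] <- list(blocks = list(f$ifaces), q = list(tab),
                         vars = list(f$vars),
                         domains = net$var_domains[f$vars])
  }
  structure(list(edge = edge, node = node), class = "ffg_belief")
}

#' Edge beliefs as a tibble
#' @param belief An `ffg_belief`.
#' @export
tidy_beliefs <- function(belief) {
  rows <- lapply(names(belief$edge), function(v) {
    b <- belief$edge[[v]]
    tibble::tibble(variable = v, value = names(b), probability = unname(b))
  })
  do.call(rbind, rows)
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' @param q,p Nonnegative vectors on the same domain (normalized internally).
#' @return KL(q || p) in nats; `>= 0`, zero iff `q == p`.
#' @export
kl_divergence <- function(q, p) {
  if (length(q) != length(p)) ffg_stop("support_mismatch", "q and p live on different domains")
  q <- q / sum(q); p <- p / sum(p)
  if (any(q > 0 & p == 0)) ffg_stop("support_mismatch", "q has mass where p is zero")
  s <- q > 0
  sum(q[s] * (log(q[s]) - log(p[s])))
}

#' Variational free energy of a joint candidate distribution
#'
#' `F[q] = E_q[log q - log p(x, z)]`, computed against the clamped
#' unnormalized joint from [brute_force()]. Equals
#' `KL(q || posterior) - log evidence`.
#'
#' @param q Array over latent states, dimensions ordered as
#'   `enumeration$vars`.
#' @param enumeration Result of `brute_force(..., return_joint = TRUE)`.
#' @return Scalar free energy in nats.
#' @export
vfe <- function(q, enumeration) {
  if (is.null(enumeration$log_unnorm)) {
    ffg_stop("support_mismatch", "enumeration must be computed with return_joint = TRUE")
  }
  q <- as.numeric(q) / sum(q)
  lw <- as.numeric(enumeration$log_unnorm)
  if (length(q) != length(lw)) ffg_stop("support_mismatch", "q has the wrong number of states")
  s <- q > 0
  if (any(s & !is.finite(lw))) return(Inf)
  sum(q[s] * (log(q[s]) - lw[s]))
}

#' Bethe free energy of a belief set
#'
#' Node terms are local free energies `F[q_a] = sum q_a log(q_a / f_a)`; edge
#' terms are entropies with the degree-based counting correction,
#' `(d_i - 1) H[q_i]`. At belief-propagation fixed points on acyclic graphs
#' the total equals minus the log evidence.
#'
#' @param graph An `ffg` graph.
#' @param tables List of [factor_table()]s.
#' @param belief An `ffg_belief` (node beliefs may be block-factorized per a
#'   local factorization).
#' @param local_factorization Optional `ffg_local_factorization`; defaults to
#'   the block structure carried by `belief`.
#' @return An `ffg_fe_report`: `node_terms`, `edge_terms`, `total`,
#'   `diagnostics` (support mismatches reported with a `+Inf` term).
#' @export
bethe_free_energy <- function(graph, tables, belief, local_factorization = NULL) {
  net <- compile_network(graph, tables)
  diagnostics <- character(0)
  node_terms <- numeric(0)
  for (f in net$factors) {
    if (length(f$vars) == 0L) {
      node_terms[f$id] <- -log(as.numeric(f$table))
      next
    }
    nb <- belief$node[[f$id]]
    if (is.null(nb)) ffg_stop("support_mismatch", "belief missing for factor %s", f$id)
    qa <- block_joint(nb, f)
    fa <- as.numeric(f$table)
    qv <- as.numeric(qa)
    s <- qv > 0
    if (any(s & fa == 0)) {
      diagnostics <- c(diagnostics, sprintf(
        "SupportMismatch: factor %s has belief mass on zero-probability cells", f$id))
      node_terms[f$id] <- Inf
      next
    }
    node_terms[f$id] <- sum(qv[s] * (log(qv[s]) - log(fa[s])))
  }
  degree <- stats::setNames(rep(0L, length(net$latent)), net$latent)
  for (f in net$factors) for (v in f$vars) degree[v] <- degree[v] + 1L
  edge_terms <- numeric(0)
  for (v in net$latent) {
    qi <- belief$edge[[v]]
    if (is.null(qi)) ffg_stop("support_mismatch", "belief missing for variable %s", v)
    s <- qi > 0
    H <- -sum(qi[s] * log(qi[s]))
    edge_terms[v] <- (degree[v] - 1L) * H
  }
  total <- sum(node_terms) + sum(edge_terms)
  structure(list(node_terms = node_terms, edge_terms = edge_terms,
                 total = total, diagnostics = diagnostics),
            class = "ffg_fe_report")
}

# joint array over a factor's latent interfaces from (possibly blocked) node
# beliefs: the product of block beliefs, axes ordered as f$vars
block_joint <- function(nb, f) {
  dims <- vapply(f$vars, function(v) length(nb$domains[[v]]), integer(1))
  idx <- arrayInd(seq_len(prod(dims)), .dim = dims)
  out <- rep(1, nrow(idx))
  for (bi in seq_along(nb$q)) {
    bvars <- nb$vars[[bi]]
    q <- as.numeric(nb$q[[bi]])
    pos <- match(bvars, f$vars)
    bdims <- dims[pos]
    strides <- c(1, cumprod(bdims))[seq_along(bdims)]
    lin <- as.vector((idx[, pos, drop = FALSE] - 1) %*% strides) + 1L
    out <- out * q[lin]
  }
  array(out, dim = dims)
}

#' @export
print.ffg_fe_report <- function(x, ...) {
  cat(sprintf("<ffg_fe_report> total = %.6f nats (%d node terms, %d edge terms)\n",
              x$total, length(x$node_terms), length(x$edge_terms)))
  if (length(x$diagnostics)) cat(paste0("  ", x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}

#' Glance at a free-energy report
#' @param x An `ffg_fe_report`.
#' @export
glance_fe <- function(x) {
  tibble::tibble(total = x$total,
                 energy_nodes = sum(x$node_terms),
                 entropy_edges = sum(x$edge_terms),
                 n_diagnostics = length(x$diagnostics))
}

#' Check normalization and marginalization constraints of a belief set
#'
#' Verifies that every belief sums to one and that every block marginal of a
#' node belief matches the corresponding edge belief, within `tol`. These are
#' the constraints that make Bethe-family optimization return a valid
#' distribution.
#'
#' @param belief An `ffg_belief`.
#' @param local_factorization Unused placeholder for interface symmetry; the
#'   block structure is carried by the belief itself.
#' @param tol Numeric tolerance.
#' @return Character vector of diagnostics; empty iff all constraints hold.
#' @export
check_constraints <- function(belief, local_factorization = NULL, tol = 1e-8) {
  diags <- character(0)
  for (v in names(belief$edge)) {
    s <- sum(belief$edge[[v]])
    if (abs(s - 1) > tol) {
      diags <- c(diags, sprintf("normalization: edge belief of %s sums to %.6g", v, s))
    }
  }
  for (fid in names(belief$node)) {
    nb <- belief$node[[fid]]
    for (bi in seq_along(nb$q)) {
      q <- as.array(nb$q[[bi]])
      s <- sum(q)
      if (abs(s - 1) > tol) {
        diags <- c(diags, sprintf("normalization: node belief block %d of %s sums to %.6g",
                                  bi, fid, s))
      }
      bvars <- nb$vars[[bi]]
      for (k in seq_along(bvars)) {
        v <- bvars[k]
        marg <- if (length(bvars) == 1L) as.numeric(q) else apply(q, k, sum)
        qi <- belief$edge[[v]]
        if (is.null(qi)) next
        if (max(abs(marg - unname(qi))) > tol) {
          diags <- c(diags, sprintf(
            "marginalization: block marginal of %s onto %s deviates from edge belief (max %.3g)",
            fid, v, max(abs(marg - unname(qi)))))
        }
      }
    }
  }
  diags
}
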