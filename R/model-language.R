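#' Define a reusable model
#'
#' A model definition is a named builder with an ordered interface list. The
#' body is a function receiving a builder (see [tilde()]) and one handle per
#' interface; it has no side effects except through the builder, so the same
#' definition can be materialized as a standalone graph or invoked as a
#' submodel any number of times.
#'
#' @param name Model name (used as context label).
#' @param interfaces Character vector of interface names (unique, ordered).
#' @param body `function(m, <interface handles...>)`.
#' @return An `ffg_model`.
#' @export
define_model <- function(name, interfaces, body) {
  if (anyDuplicated(interfaces)) {
    ffg_stop("duplicate_interface", "interface names of model '%s' must be unique", name)
  }
  if (!is.function(body)) ffg_stop("invalid_model", "model body must be a function")
  structure(list(name = name, interfaces = interfaces, body = body), class = "ffg_model")
}

#' @export
print.ffg_model <- function(x, ...) {
  cat(sprintf("<ffg_model> %s(%s)\n", x$name, paste(x$interfaces, collapse = ", ")))
  invisible(x)
}

new_builder <- function(graph, ctx, registry) {
  structure(list(graph = graph, ctx = ctx, registry = registry), class = "ffg_builder")
}

# --- reference resolution --------------------------------------------------

binding_key <- function(name, index) {
  if (is.null(index) || is.na(index)) name else sprintf("%s[%d]", name, index)
}

is_vecref <- function(x) inherits(x, "ffg_vecref")

new_vecref <- function(name, ctx, length = NA_integer_) {
  structure(list(name = name, ctx = ctx, length = as.integer(length)), class = "ffg_vecref")
}

#' Index into a vector variable handle
#'
#' Indices are 0-based throughout the data model and the builder API, in step
#' with the serialization format.
#'
#' @param h A vector handle (or a base name).
#' @param i 0-based index.
#' @return An `ffg_ref`.
#' @export
at <- function(h, i) {
  if (is_vecref(h)) return(fg_ref(h$name, i))
  if (is_ref(h)) return(fg_ref(h$name, i))
  fg_ref(h, i)
}

#' Length of a vector interface handle
#' @export
vec_length <- function(h) {
  if (is_vecref(h)) return(h$length)
  ffg_stop("not_a_vector", "handle is not a vector interface")
}

# Resolve (name, index) in a context. Follows vector-handle bindings to the
# owning context. Returns a variable id, a folded value, or NULL.
resolve_var <- function(graph, ctx_id, name, index = NA_integer_, create = FALSE) {
  ctx <- resolve_ctx(graph, ctx_id)
  b <- ctx$bindings[[name]]
  if (!is.na(index)) {
    if (is_vecref(b) && !(identical(b$ctx, ctx_id) && identical(b$name, name))) {
      return(resolve_var(graph, b$ctx, b$name, index, create = create))
    }
    key <- binding_key(name, index)
    hit <- ctx$bindings[[key]]
    if (!is.null(hit)) return(hit)
    if (!create) return(NULL)
    id <- fg_add_variable(graph, ctx_id, name, kind = "random", index = index)
    assign(key, id, envir = ctx$bindings)
    return(id)
  }
  if (!is.null(b)) {
    if (is_vecref(b)) return(b)
    return(b) # var id or list(value = ...)
  }
  if (!create) return(NULL)
  id <- fg_add_variable(graph, ctx_id, name, kind = "random")
  assign(name, id, envir = ctx$bindings)
  id
}

#' Get or create an indexed variable
#'
#' Idempotent: the first touch of `name[index]` creates a random variable
#' node; later touches return the same id. This implements `new`-style vector
#' variable creation, where a state and the observation it explains can be
#' introduced on the same line.
#'
#' @param graph An `ffg` graph.
#' @param context Context id.
#' @param name Base name.
#' @param index 0-based index.
#' @return Variable id.
#' @export
get_or_create_indexed <- function(graph, context, name, index) {
  index <- as.integer(index)
  if (is.na(index) || index < 0L) ffg_stop("invalid_index", "index must be >= 0")
  resolve_var(graph, context, name, index, create = TRUE)
}

# Resolve an rhs argument to list(type = "value"/"var", ...). Indexed names
# are auto-created; unbound scalar names are an error.
resolve_rhs_arg <- function(graph, ctx_id, arg) {
  if (is_literal(arg)) return(list(type = "value", value = arg))
  if (is_vecref(arg)) {
    ffg_stop("unresolvable_reference", "vector handle '%s' used where a scalar is required", arg$name)
  }
  if (!is_ref(arg)) ffg_stop("invalid_statement", "rhs arguments must be literals or references")
  r <- resolve_var(graph, ctx_id, arg$name, arg$index, create = !is.na(arg$index))
  if (is.null(r)) {
    ffg_stop("unresolvable_reference", "'%s' is not bound in this context", arg$name)
  }
  if (is.list(r) && !is_vecref(r) && !is.null(r$value)) return(list(type = "value", value = r$value))
  if (is_vecref(r)) {
    ffg_stop("unresolvable_reference", "'%s' is a vector; index it with at()", arg$name)
  }
  list(type = "var", id = r)
}

new_constant <- function(graph, ctx_id, value) {
  ctx <- resolve_ctx(graph, ctx_id)
  nm <- paste0("const_", ctx$const_counter)
  ctx$const_counter <- ctx$const_counter + 1L
  id <- fg_add_variable(graph, ctx_id, nm, kind = "constant", value = value)
  assign(nm, id, envir = ctx$bindings)
  id
}

# --- statement materialization ---------------------------------------------

#' Materialize a primitive statement
#'
#' Stochastic node types always create one factor node, the left-hand-side
#' variable (if absent), and one constant variable node per literal argument.
#' Deterministic node types whose arguments are all known at construction
#' time are folded: no nodes are created and the left-hand side is bound in
#' the context to the evaluator's result. A deterministic type with at least
#' one random (or data) argument is materialized as a deterministic factor
#' node.
#'
#' @param graph An `ffg` graph.
#' @param context Context id.
#' @param registry An `ffg_registry`.
#' @param statement A primitive `ffg_statement` (see [unroll_compound()]).
#' @return A list: `folded` flag, plus either `value` or
#'   `factor_id`/`lhs_id`/`constant_ids`.
#' @export
materialize_statement <- function(graph, context, registry, statement) {
  if (!stmt_is_primitive(statement)) {
    ffg_stop("compound_statement", "statement must be primitive; unroll it first")
  }
  ctx <- resolve_ctx(graph, context)
  rhs <- statement$rhs
  res <- resolve_alias(registry, rhs$label, rhs$kwargs)
  label <- res$label
  entry <- registry_entry(registry, label)
  pos_names <- function(n) {
    nm <- entry$arg_names
    if (is.null(nm) || length(nm) < n) paste0("in", seq_len(n)) else nm[seq_len(n)]
  }
  if (!identical(label, rhs$label)) {
    # alias rule fired: arguments already in the target's positional order
    args <- c(rhs$args, res$args)
    iface_names <- pos_names(length(args))
  } else {
    args <- c(rhs$args, res$args)
    iface_names <- c(pos_names(length(rhs$args)), names(res$args))
  }

  resolved <- lapply(args, function(a) resolve_rhs_arg(graph, context, a))
  known <- vapply(resolved, function(r) r$type == "value" ||
                    graph$vars[[r$id]]$kind == "constant", logical(1))
  if (length(known) == 0L) known <- logical(0)

  if (entry$kind == "deterministic" && all(known)) {
    vals <- lapply(resolved, function(r) {
      if (r$type == "value") r$value else graph$vars[[r$id]]$value
    })
    value <- do.call(entry$evaluator, vals)
    key <- binding_key(statement$lhs$name, statement$lhs$index)
    if (!is.null(ctx$bindings[[key]])) {
      ffg_stop("duplicate_name", "'%s' is already bound; cannot rebind folded result", key)
    }
    assign(key, list(value = value), envir = ctx$bindings)
    return(list(folded = TRUE, value = value))
  }

  # left-hand side variable (created if absent)
  lhs <- statement$lhs
  lhs_id <- resolve_var(graph, context, lhs$name, lhs$index, create = TRUE)
  if (is.list(lhs_id) || is_vecref(lhs_id)) {
    ffg_stop("unresolvable_reference", "lhs '%s' does not resolve to a variable node", lhs$name)
  }

  const_ids <- character(0)
  arg_ids <- character(length(resolved))
  for (k in seq_along(resolved)) {
    r <- resolved[[k]]
    if (r$type == "value") {
      cid <- new_constant(graph, context, r$value)
      const_ids <- c(const_ids, cid)
      arg_ids[k] <- cid
    } else {
      arg_ids[k] <- r$id
    }
  }
  interfaces <- c(stats::setNames(lhs_id, "out"), stats::setNames(arg_ids, iface_names))
  fid <- fg_add_factor(graph, context, label, interfaces,
                       deterministic = entry$kind == "deterministic")
  list(folded = FALSE, factor_id = fid, lhs_id = lhs_id, constant_ids = const_ids)
}

# --- builder surface --------------------------------------------------------

#' Record a tilde statement
#'
#' The central builder operation: `lhs ~ rhs`. Compound right-hand sides are
#' unrolled innermost-first, left-to-right into anonymous intermediates named
#' `<lhs>_tmp_<k>`. If `rhs` is a submodel invocation (see [submodel()]),
#' the missing interface is bound to `lhs`.
#'
#' @param m A builder (passed to model bodies).
#' @param lhs Variable name, `ffg_ref`, or `NULL` for a submodel invocation
#'   with all interfaces supplied.
#' @param rhs An `ffg_call` or a [submodel()] invocation.
#' @param relation `"~"` (stochastic) or `":="` (deterministic alias).
#' @return The lhs variable id (invisible), or the folded value.
#' @export
tilde <- function(m, lhs, rhs, relation = "~") {
  if (inherits(rhs, "ffg_submodel_call")) {
    ctx <- invoke_submodel(m$graph, m$ctx, rhs$def, rhs$kwargs, lhs = lhs)
    return(invisible(ctx))
  }
  if (is.character(lhs)) lhs <- fg_ref(lhs)
  stmt <- fg_stmt(lhs, rhs, relation)
  ctx <- resolve_ctx(m$graph, m$ctx)
  stmts <- unroll_compound(stmt, m$registry, counter = ctx$tmp_counters)
  out <- NULL
  for (s in stmts) out <- materialize_statement(m$graph, m$ctx, m$registry, s)
  if (out$folded) out$value else invisible(out$lhs_id)
}

#' Deterministic assignment (`:=`), an alias of the tilde operator
#' @rdname tilde
#' @export
det_assign <- function(m, lhs, rhs) tilde(m, lhs, rhs, relation = ":=")

#' Reference a submodel invocation on the right-hand side of a tilde
#'
#' @param def An `ffg_model`.
#' @param ... Named interface bindings (all but at most one interface).
#' @return An `ffg_submodel_call`.
#' @export
submodel <- function(def, ...) {
  structure(list(def = def, kwargs = list(...)), class = "ffg_submodel_call")
}

#' Create a vector of constant nodes and return its handle
#'
#' @param m Builder.
#' @param name Base name for the constant vector.
#' @param values Numeric vector.
#' @return An `ffg_vecref` handle over the created constants.
#' @export
const_vec <- function(m, name, values) {
  ctx <- resolve_ctx(m$graph, m$ctx)
  for (i in seq_along(values)) {
    id <- fg_add_variable(m$graph, m$ctx, name, kind = "constant",
                          value = values[i], index = i - 1L)
    assign(binding_key(name, i - 1L), id, envir = ctx$bindings)
  }
  h <- new_vecref(name, m$ctx, length(values))
  assign(name, h, envir = ctx$bindings)
  h
}

#' Declare a local vector of random variables
#'
#' Registers a vector handle in the current context; elements are created
#' lazily on first touch (see [get_or_create_indexed()]).
#'
#' @param m Builder.
#' @param name Base name.
#' @param length Number of addressable elements (0-based indices).
#' @return An `ffg_vecref` handle.
#' @export
local_vec <- function(m, name, length) {
  ctx <- resolve_ctx(m$graph, m$ctx)
  h <- new_vecref(name, m$ctx, length)
  assign(name, h, envir = ctx$bindings)
  h
}

#' Invoke a submodel with all interfaces supplied
#'
#' @param m Builder.
#' @param def An `ffg_model`.
#' @param ... Named interface bindings covering every interface.
#' @return The child context id, invisibly.
#' @export
invoke <- function(m, def, ...) {
  invisible(invoke_submodel(m$graph, m$ctx, def, list(...), lhs = NULL,
                            registry = m$registry))
}

#' Invoke a model definition as a submodel
#'
#' Creates a child context (with an invocation counter so repeated
#' invocations never collide), binds the supplied interfaces to parent-scope
#' variables, binds the single missing interface to `lhs` when given, and
#' executes the body against the child context. All nodes created by the body
#' carry the child path.
#'
#' @param graph An `ffg` graph.
#' @param parent_context Parent context id.
#' @param modeldef An `ffg_model`.
#' @param kwargs Named list of interface bindings: `ffg_ref`, vector handles,
#'   or numeric literals (which become constant nodes in the parent scope).
#' @param lhs Optional lhs reference bound to the missing interface.
#' @param registry Registry used by the body (defaults to the standard one).
#' @return The child context id.
#' @export
invoke_submodel <- function(graph, parent_context, modeldef, kwargs, lhs = NULL,
                            registry = NULL) {
  if (is.null(registry)) registry <- builder_registry(graph)
  ifaces <- modeldef$interfaces
  kw <- names(kwargs)
  if (length(kwargs) > 0L && (is.null(kw) || any(!nzchar(kw)))) {
    ffg_stop("unknown_interface", "submodel interfaces must be supplied by name")
  }
  unknown <- setdiff(kw, ifaces)
  if (length(unknown) > 0L) {
    ffg_stop("unknown_interface", "model '%s' has no interface(s): %s",
             modeldef$name, paste(unknown, collapse = ", "))
  }
  missing <- setdiff(ifaces, kw)
  if (!is.null(lhs)) {
    if (length(missing) == 0L) {
      ffg_stop("no_missing_interface", "all interfaces of '%s' supplied but an lhs was given", modeldef$name)
    }
    if (length(missing) > 1L) {
      ffg_stop("multiple_missing_interfaces", "interfaces {%s} of '%s' are unbound",
               paste(missing, collapse = ", "), modeldef$name)
    }
  } else if (length(missing) > 0L) {
    ffg_stop("multiple_missing_interfaces", "interfaces {%s} of '%s' are unbound and no lhs was given",
             paste(missing, collapse = ", "), modeldef$name)
  }

  parent <- resolve_ctx(graph, parent_context)
  cnt <- parent$submodel_counters[[modeldef$name]]
  if (is.null(cnt)) cnt <- 0L
  assign(modeldef$name, cnt + 1L, envir = parent$submodel_counters)
  child_id <- new_context(graph, modeldef$name, parent = parent_context, counter = cnt)
  child <- resolve_ctx(graph, child_id)

  bind_iface <- function(iface, value) {
    if (is_vecref(value)) {
      assign(iface, value, envir = child$bindings)
      assign(iface, value, envir = child$interface_bindings)
      return(new_vecref(iface, child_id, value$length))
    }
    if (is.numeric(value) && length(value) == 1L) {
      vid <- new_constant(graph, parent_context, value)
    } else if (is_ref(value)) {
      r <- resolve_var(graph, parent_context, value$name, value$index,
                       create = !is.na(value$index))
      if (is.null(r)) {
        ffg_stop("unresolvable_reference", "'%s' is not bound in the parent scope", value$name)
      }
      if (is_vecref(r)) {
        assign(iface, r, envir = child$bindings)
        assign(iface, r, envir = child$interface_bindings)
        return(new_vecref(iface, child_id, r$length))
      }
      if (is.list(r) && !is.null(r$value)) {
        vid <- new_constant(graph, parent_context, r$value)
      } else {
        vid <- r
      }
    } else {
      ffg_stop("unknown_interface", "unsupported binding for interface '%s'", iface)
    }
    assign(iface, vid, envir = child$bindings)
    assign(iface, vid, envir = child$interface_bindings)
    fg_ref(iface)
  }

  handles <- stats::setNames(vector("list", length(ifaces)), ifaces)
  for (iface in ifaces) {
    if (iface %in% kw) {
      handles[[iface]] <- bind_iface(iface, kwargs[[iface]])
    } else {
      # missing interface: bound to the lhs variable (created in parent if absent)
      if (is.character(lhs)) lhs <- fg_ref(lhs)
      vid <- resolve_var(graph, parent_context, lhs$name, lhs$index, create = TRUE)
      assign(iface, vid, envir = child$bindings)
      assign(iface, vid, envir = child$interface_bindings)
      handles[[iface]] <- fg_ref(iface)
    }
  }

  mb <- new_builder(graph, child_id, registry)
  do.call(modeldef$body, c(list(mb), handles))
  child_id
}

# A graph remembers the registry used to build it so nested invocations and
# later inspection share node-type knowledge.
builder_registry <- function(graph) {
  if (is.null(graph$registry)) graph$registry <- node_registry()
  graph$registry
}

#' Materialize a model definition into a factor graph
#'
#' @param modeldef An `ffg_model`.
#' @param bindings Named list over interfaces. Each entry is a numeric scalar
#'   or vector (constants), [fg_data()] (observations; one data node per
#'   element), or [fg_vector()] (an unbound random vector of known length).
#'   Interfaces absent from `bindings` become single unbound random
#'   variables.
#' @param registry Node-type registry (defaults to the standard registry).
#' @param validate Run [fg_validate()] on the result (default `TRUE`).
#' @return A validated `ffg` graph.
#' @export
materialize_model <- function(modeldef, bindings = list(), registry = node_registry(),
                              validate = TRUE) {
  unknown <- setdiff(names(bindings), modeldef$interfaces)
  if (length(unknown) > 0L) {
    ffg_stop("unknown_interface", "model '%s' has no interface(s): %s",
             modeldef$name, paste(unknown, collapse = ", "))
  }
  graph <- fg_new(modeldef$name)
  graph$registry <- registry
  root <- graph$root
  ctx <- resolve_ctx(graph, root)
  handles <- stats::setNames(vector("list", length(modeldef$interfaces)),
                             modeldef$interfaces)
  for (iface in modeldef$interfaces) {
    b <- bindings[[iface]]
    if (is.null(b)) {
      id <- fg_add_variable(graph, root, iface, kind = "random")
      assign(iface, id, envir = ctx$bindings)
      handles[[iface]] <- fg_ref(iface)
    } else if (inherits(b, "ffg_data_binding")) {
      vals <- b$values
      if (length(vals) == 1L) {
        id <- fg_add_variable(graph, root, iface, kind = "data", value = vals)
        assign(iface, id, envir = ctx$bindings)
        handles[[iface]] <- fg_ref(iface)
      } else {
        for (i in seq_along(vals)) {
          id <- fg_add_variable(graph, root, iface, kind = "data",
                                value = vals[i], index = i - 1L)
          assign(binding_key(iface, i - 1L), id, envir = ctx$bindings)
        }
        h <- new_vecref(iface, root, length(vals))
        assign(iface, h, envir = ctx$bindings)
        handles[[iface]] <- h
      }
    } else if (inherits(b, "ffg_vector_binding")) {
      h <- new_vecref(iface, root, b$n)
      assign(iface, h, envir = ctx$bindings)
      handles[[iface]] <- h
    } else if (is.numeric(b) && length(b) == 1L) {
      id <- fg_add_variable(graph, root, iface, kind = "constant", value = b)
      assign(iface, id, envir = ctx$bindings)
      handles[[iface]] <- fg_ref(iface)
    } else if (is.numeric(b)) {
      for (i in seq_along(b)) {
        id <- fg_add_variable(graph, root, iface, kind = "constant",
                              value = b[i], index = i - 1L)
        assign(binding_key(iface, i - 1L), id, envir = ctx$bindings)
      }
      h <- new_vecref(iface, root, length(b))
      assign(iface, h, envir = ctx$bindings)
      handles[[iface]] <- h
    } else {
      ffg_stop("unknown_interface", "unsupported binding for interface '%s'", iface)
    }
  }
  mb <- new_builder(graph, root, registry)
  do.call(modeldef$body, c(list(mb), handles))
  if (validate) {
    diags <- fg_validate(graph)
    if (length(diags) > 0L) {
      ffg_stop("invalid_graph", "materialized graph fails validation: %s",
               paste(diags, collapse = "; "))
    }
  }
  graph
}

#' Mark a binding as observed data
#' @param values Numeric vector (one data node per element) or scalar.
#' @export
fg_data <- function(values) structure(list(values = values), class = "ffg_data_binding")

#' Mark a binding as an unbound random vector of known length
#' @param n Number of elements the body may address (0-based indices).
#' @export
fg_vector <- function(n) structure(list(n = as.integer(n)), class = "ffg_vector_binding")
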