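#' Create an empty Forney-style factor graph
#'
#' A Forney-style factor graph (FFG) is a bipartite graph whose vertices are
#' factor functions and whose variables connect the factors that share them.
#' The graph carries a tree of naming contexts recording submodel nesting, so
#' that the same model definition can be invoked repeatedly without name
#' collisions ("closing the box").
#'
#' The object is an environment (reference semantics): builder operations
#' mutate it in place, as graph construction is inherently stateful.
#'
#' @param model_name Name of the root model; used as the root context label.
#' @return An object of class `ffg`.
#' @export
fg_new <- function(model_name = "model") {
  g <- new.env(parent = emptyenv())
  g$vars <- new.env(parent = emptyenv())      # var id -> record
  g$factors <- new.env(parent = emptyenv())   # factor id -> record
  g$ctxs <- new.env(parent = emptyenv())      # ctx id -> context environment
  g$adj <- new.env(parent = emptyenv())       # var id -> character vector of factor ids
  g$key_index <- new.env(parent = emptyenv()) # (name,index,path) key -> var id
  g$payloads <- new.env(parent = emptyenv())  # plugin name -> env(target id -> payload)
  g$counters <- new.env(parent = emptyenv())
  g$counters$var <- 0L
  g$counters$factor <- 0L
  g$counters$ctx <- 0L
  class(g) <- "ffg"
  g$root <- new_context(g, model_name, parent = NULL, counter = 0L)
  g
}

new_context <- function(graph, model_name, parent, counter) {
  graph$counters$ctx <- graph$counters$ctx + 1L
  id <- paste0("c", graph$counters$ctx)
  ctx <- new.env(parent = emptyenv())
  ctx$id <- id
  ctx$model_name <- model_name
  ctx$counter <- counter
  ctx$parent <- parent # parent ctx id or NULL
  label <- if (is.null(parent)) model_name else paste0(model_name, ":", counter)
  ctx$path <- if (is.null(parent)) label else c(graph$ctxs[[parent]]$path, label)
  ctx$bindings <- new.env(parent = emptyenv())           # local key -> var id or list(value=)
  ctx$interface_bindings <- new.env(parent = emptyenv()) # interface name -> var id / id vector
  ctx$tmp_counters <- new.env(parent = emptyenv())       # lhs base name -> next k
  ctx$const_counter <- 0L
  ctx$submodel_counters <- new.env(parent = emptyenv())  # model name -> next invocation index
  assign(id, ctx, envir = graph$ctxs)
  id
}

#' @export
fg_root <- function(graph) graph$root

var_key <- function(name, index, path) {
  idx <- if (is.null(index) || is.na(index)) "" else as.character(as.integer(index))
  paste(name, idx, paste(path, collapse = "/"), sep = "\r")
}

resolve_ctx <- function(graph, context) {
  ctx <- graph$ctxs[[context]]
  if (is.null(ctx)) ffg_stop("unknown_context", "unknown context id '%s'", context)
  ctx
}

#' Add a variable node
#'
#' @param graph An `ffg` graph.
#' @param context Context id the variable belongs to.
#' @param name Base name (nonempty string).
#' @param kind One of `"random"`, `"constant"`, `"data"`.
#' @param value Numeric value; required for `constant`/`data`, forbidden for
#'   `random`.
#' @param index Optional 0-based integer index for vector variables.
#' @return The fresh variable node id (character).
#' @export
fg_add_variable <- function(graph, context, name,
                            kind = c("random", "constant", "data"),
                            value = NULL, index = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    ffg_stop("invalid_name", "variable name must be a nonempty string")
  }
  if (!is.null(index)) {
    index <- as.integer(index)
    if (is.na(index) || index < 0L) ffg_stop("invalid_index", "index must be a nonnegative integer")
  }
  ctx <- resolve_ctx(graph, context)
  if (kind == "random" && !is.null(value)) {
    ffg_stop("unexpected_value", "random variable '%s' must not carry a value", name)
  }
  if (kind != "random" && is.null(value)) {
    ffg_stop("missing_value", "%s variable '%s' requires a value", kind, name)
  }
  key <- var_key(name, index, ctx$path)
  if (!is.null(graph$key_index[[key]])) {
    ffg_stop("duplicate_name", "variable '%s'%s already exists in context path %s",
             name, if (is.null(index)) "" else sprintf("[%d]", index),
             paste(ctx$path, collapse = "/"))
  }
  graph$counters$var <- graph$counters$var + 1L
  id <- paste0("v", graph$counters$var)
  rec <- list(id = id, name = name,
              index = if (is.null(index)) NA_integer_ else index,
              path = ctx$path, ctx = ctx$id, kind = kind, value = value)
  assign(id, rec, envir = graph$vars)
  assign(id, character(0), envir = graph$adj)
  assign(key, id, envir = graph$key_index)
  id
}

#' Add a factor node
#'
#' Connects an ordered, named set of interfaces to existing variable nodes.
#' Bipartiteness is preserved by construction: adjacency exists only between
#' factors and variables.
#'
#' @param graph An `ffg` graph.
#' @param context Context id the factor belongs to.
#' @param label Node-type label (e.g. `"Beta"`, `"exp"`).
#' @param interfaces Named character vector: interface name -> variable id.
#' @param deterministic Whether the factor expresses a deterministic relation.
#' @return The fresh factor node id.
#' @export
fg_add_factor <- function(graph, context, label, interfaces, deterministic = FALSE) {
  ctx <- resolve_ctx(graph, context)
  if (length(interfaces) == 0L) {
    ffg_stop("empty_interfaces", "factor '%s' must have at least one interface", label)
  }
  nms <- names(interfaces)
  if (is.null(nms) || any(!nzchar(nms))) {
    ffg_stop("empty_interfaces", "all interfaces of '%s' must be named", label)
  }
  if (anyDuplicated(nms)) {
    ffg_stop("duplicate_interface", "interface names of '%s' must be unique", label)
  }
  for (vid in interfaces) {
    if (is.null(graph$vars[[vid]])) {
      ffg_stop("unknown_variable", "factor '%s' references unknown variable id '%s'", label, vid)
    }
  }
  graph$counters$factor <- graph$counters$factor + 1L
  id <- paste0("f", graph$counters$factor)
  rec <- list(id = id, label = label, deterministic = isTRUE(deterministic),
              interfaces = interfaces, path = ctx$path, ctx = ctx$id)
  assign(id, rec, envir = graph$factors)
  for (vid in unique(interfaces)) {
    assign(vid, c(graph$adj[[vid]], id), envir = graph$adj)
  }
  id
}

#' Markov blanket of a factor subset
#'
#' Returns the boundary-crossing variables of a group of factors: exactly the
#' variables adjacent to at least one factor inside and at least one factor
#' outside the subset. Conditioned on its Markov blanket, the group's
#' interior is independent of the exterior, which is what lets a subgraph be
#' "closed into a box" and treated as a single composite node.
#'
#' @param graph An `ffg` graph.
#' @param factor_subset Character vector of factor ids.
#' @return Character vector of variable ids (sorted).
#' @export
fg_markov_blanket <- function(graph, factor_subset) {
  all_f <- ls(graph$factors)
  unknown <- setdiff(factor_subset, all_f)
  if (length(unknown) > 0L) {
    ffg_stop("unknown_factor", "unknown factor id(s): %s", paste(unknown, collapse = ", "))
  }
  inside <- unique(factor_subset)
  blanket <- character(0)
  for (vid in ls(graph$adj)) {
    nb <- graph$adj[[vid]]
    if (any(nb %in% inside) && any(!(nb %in% inside))) blanket <- c(blanket, vid)
  }
  sort(blanket)
}

#' Validate graph invariants
#'
#' Checks the structural invariants of the data model: bipartiteness, no
#' dangling references, value presence matching variable kind, uniqueness of
#' (name, index, path), nonempty factor interfaces, and an acyclic context
#' tree. Returns diagnostics rather than raising, so a partially broken graph
#' can still be inspected.
#'
#' @param graph An `ffg` graph.
#' @return Character vector of diagnostics; empty iff all invariants hold.
#' @export
fg_validate <- function(graph) {
  diags <- character(0)
  var_ids <- ls(graph$vars)
  factor_ids <- ls(graph$factors)
  for (vid in var_ids) {
    v <- graph$vars[[vid]]
    if (v$kind == "random" && !is.null(v$value)) {
      diags <- c(diags, sprintf("variable %s: random but carries a value", vid))
    }
    if (v$kind != "random" && is.null(v$value)) {
      diags <- c(diags, sprintf("variable %s: kind %s without a value", vid, v$kind))
    }
    if (is.null(graph$ctxs[[v$ctx]])) {
      diags <- c(diags, sprintf("variable %s: unknown context %s", vid, v$ctx))
    }
  }
  seen_keys <- new.env(parent = emptyenv())
  for (vid in var_ids) {
    v <- graph$vars[[vid]]
    key <- var_key(v$name, v$index, v$path)
    if (!is.null(seen_keys[[key]])) {
      diags <- c(diags, sprintf("variables %s and %s share (name,index,path)", seen_keys[[key]], vid))
    }
    assign(key, vid, envir = seen_keys)
  }
  for (fid in factor_ids) {
    f <- graph$factors[[fid]]
    if (length(f$interfaces) == 0L) {
      diags <- c(diags, sprintf("factor %s: empty interfaces", fid))
    }
    for (vid in f$interfaces) {
      if (is.null(graph$vars[[vid]])) {
        diags <- c(diags, sprintf("factor %s: dangling reference to %s", fid, vid))
      }
    }
  }
  # bipartiteness: adjacency lists may only name factor nodes, keyed by variables
  for (vid in ls(graph$adj)) {
    if (is.null(graph$vars[[vid]])) {
      diags <- c(diags, sprintf("adjacency key %s is not a variable node", vid))
    }
    for (nb in graph$adj[[vid]]) {
      if (is.null(graph$factors[[nb]])) {
        diags <- c(diags, sprintf("bipartiteness violated: %s adjacent to non-factor %s", vid, nb))
      }
    }
  }
  # edge count symmetry between the two incidence representations
  n_from_factors <- sum(vapply(factor_ids, function(fid) {
    sum(!is.na(match(graph$factors[[fid]]$interfaces, var_ids)))
  }, integer(1)))
  n_from_adj <- sum(vapply(ls(graph$adj), function(vid) {
    sum(!is.na(match(graph$adj[[vid]], factor_ids)))
  }, integer(1)))
  if (n_from_factors != n_from_adj) {
    diags <- c(diags, sprintf("edge count mismatch: %d from factors, %d from adjacency",
                              n_from_factors, n_from_adj))
  }
  # context tree acyclicity
  for (cid in ls(graph$ctxs)) {
    seen <- character(0)
    cur <- cid
    while (!is.null(cur)) {
      if (cur %in% seen) {
        diags <- c(diags, sprintf("context %s: cycle in parent chain", cid))
        break
      }
      seen <- c(seen, cur)
      cur <- graph$ctxs[[cur]]$parent
    }
  }
  diags
}

#' Degree of a variable (number of incident factor edges)
#' @export
fg_degree <- function(graph, var_id) {
  nb <- graph$adj[[var_id]]
  if (is.null(nb)) ffg_stop("unknown_variable", "unknown variable id '%s'", var_id)
  # a factor touching the same variable through k interfaces contributes k edges
  sum(vapply(unique(nb), function(fid) {
    sum(graph$factors[[fid]]$interfaces == var_id)
  }, integer(1)))
}

#' Variables of a graph as a tibble
#' @export
fg_variables <- function(graph) {
  ids <- sort_ids(ls(graph$vars))
  tibble::tibble(
    id = ids,
    name = vapply(ids, function(i) graph$vars[[i]]$name, character(1)),
    index = vapply(ids, function(i) graph$vars[[i]]$index, integer(1)),
    kind = vapply(ids, function(i) graph$vars[[i]]$kind, character(1)),
    path = vapply(ids, function(i) paste(graph$vars[[i]]$path, collapse = "/"), character(1)),
    degree = vapply(ids, function(i) fg_degree(graph, i), integer(1))
  )
}

#' Factors of a graph as a tibble
#' @export
fg_factors <- function(graph) {
  ids <- sort_ids(ls(graph$factors))
  tibble::tibble(
    id = ids,
    label = vapply(ids, function(i) graph$factors[[i]]$label, character(1)),
    deterministic = vapply(ids, function(i) graph$factors[[i]]$deterministic, logical(1)),
    degree = vapply(ids, function(i) length(graph$factors[[i]]$interfaces), integer(1)),
    path = vapply(ids, function(i) paste(graph$factors[[i]]$path, collapse = "/"), character(1))
  )
}

#' Contexts of a graph as a tibble
#' @export
fg_contexts <- function(graph) {
  ids <- sort_ids(ls(graph$ctxs))
  tibble::tibble(
    id = ids,
    model = vapply(ids, function(i) graph$ctxs[[i]]$model_name, character(1)),
    counter = vapply(ids, function(i) graph$ctxs[[i]]$counter, integer(1)),
    parent = vapply(ids, function(i) {
      p <- graph$ctxs[[i]]$parent
      if (is.null(p)) NA_character_ else p
    }, character(1)),
    path = vapply(ids, function(i) paste(graph$ctxs[[i]]$path, collapse = "/"), character(1))
  )
}

# numeric sort for ids like "v10" so tables list nodes in creation order
sort_ids <- function(ids) {
  if (length(ids) == 0L) return(ids)
  ids[order(as.integer(sub("^[a-z]+", "", ids)))]
}

#' @export
print.ffg <- function(x, ...) {
  cat(sprintf("<ffg> %d variables, %d factors, %d contexts (root model '%s')\n",
              length(ls(x$vars)), length(ls(x$factors)), length(ls(x$ctxs)),
              x$ctxs[[x$root]]$model_name))
  invisible(x)
}
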