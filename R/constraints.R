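# Variational-constraints plugin: factorization constraints (FCs) and
# functional-form constraints (FFCs), scoped to submodels, resolved into
# per-factor local factorizations. Together with the normalization and
# marginalization constraints enforced by the engine, these define a
# Constrained Bethe Free Energy.

CONSTRAINT_PLUGIN <- "variational_constraints"

#' Factorization constraint
#'
#' Declares a split of the joint variational belief over named variables,
#' e.g. `q(x, y, z) = q(x) q(y) q(z)` is `fc(c("x","y","z"),
#' list("x","y","z"))`. Within every factor whose interfaces touch the
#' mentioned variables, interfaces in different blocks are placed in separate
#' belief blocks.
#'
#' @param variables Character vector of variable names (in the declaring
#'   scope).
#' @param partition List of character vectors: disjoint nonempty blocks whose
#'   union equals `variables`.
#' @param scope Character vector of submodel names; the constraint applies in
#'   every context whose model-name path ends with this sequence. Empty means
#'   the root scope.
#' @return An `ffg_fc`.
#' @export
fc <- function(variables, partition, scope = character(0)) {
  blocks <- lapply(partition, as.character)
  flat <- unlist(blocks)
  if (length(blocks) == 0L || any(lengths(blocks) == 0L)) {
    ffg_stop("malformed_partition", "partition blocks must be nonempty")
  }
  if (anyDuplicated(flat)) {
    ffg_stop("malformed_partition", "partition blocks must be disjoint")
  }
  if (!setequal(flat, variables)) {
    ffg_stop("malformed_partition", "partition must cover exactly the constrained variables")
  }
  structure(list(type = "fc", variables = as.character(variables),
                 partition = blocks, scope = as.character(scope)),
            class = c("ffg_fc", "ffg_constraint"))
}

#' Functional-form constraint
#'
#' Restricts the variational marginal of one variable to a named distribution
#' family, e.g. `q(x) :: Beta` is `ffc("x", "Beta")`.
#'
#' @param variable Variable name in the declaring scope.
#' @param family Distribution-family label (must be a registered node type).
#' @param scope As in [fc()].
#' @return An `ffg_ffc`.
#' @export
ffc <- function(variable, family, scope = character(0)) {
  structure(list(type = "ffc", variable = as.character(variable),
                 family = as.character(family), scope = as.character(scope)),
            class = c("ffg_ffc", "ffg_constraint"))
}

#' Build a validated constraint set
#'
#' Accepts constraint entries created with [fc()]/[ffc()], or a nested
#' document (parsed YAML/JSON) with `scope` blocks; see
#' [read_constraints()]. Two FCs conflict when one places a pair of
#' variables in the same block and the other separates them.
#'
#' @param ... Constraint entries, or a single list of entries.
#' @return An `ffg_constraint_set`.
#' @export
build_constraint_set <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1L]]) &&
      !inherits(entries[[1L]], "ffg_constraint")) {
    entries <- entries[[1L]]
  }
  for (e in entries) {
    if (!inherits(e, "ffg_constraint")) {
      ffg_stop("malformed_partition", "constraint entries must be created with fc() or ffc()")
    }
  }
  fcs <- Filter(function(e) e$type == "fc", entries)
  if (length(fcs) > 1L) {
    for (i in seq_len(length(fcs) - 1L)) {
      for (j in seq(i + 1L, length(fcs))) {
        a <- fcs[[i]]; b <- fcs[[j]]
        if (!identical(a$scope, b$scope)) next
        shared <- intersect(a$variables, b$variables)
        if (length(shared) < 2L) next
        for (u in shared) for (v in shared) {
          if (u >= v) next
          sep_a <- block_of(a, u) != block_of(a, v)
          sep_b <- block_of(b, u) != block_of(b, v)
          if (sep_a != sep_b) {
            ffg_stop("conflicting_constraints",
                     "constraints disagree on whether q(%s) and q(%s) factorize", u, v)
          }
        }
      }
    }
  }
  structure(list(entries = entries), class = "ffg_constraint_set")
}

block_of <- function(fc, var) {
  for (k in seq_along(fc$partition)) if (var %in% fc$partition[[k]]) return(k)
  NA_integer_
}

#' @export
print.ffg_constraint_set <- function(x, ...) {
  cat(sprintf("<ffg_constraint_set> %d entries\n", length(x$entries)))
  for (e in x$entries) {
    sc <- if (length(e$scope)) paste0("[", paste(e$scope, collapse = "/"), "] ") else ""
    if (e$type == "fc") {
      rhs <- paste(vapply(e$partition, function(b) sprintf("q(%s)", paste(b, collapse = ",")),
                          character(1)), collapse = "")
      cat(sprintf("  %sq(%s) = %s\n", sc, paste(e$variables, collapse = ","), rhs))
    } else {
      cat(sprintf("  %sq(%s) :: %s\n", sc, e$variable, e$family))
    }
  }
  invisible(x)
}

# model-name path of a context, counters stripped
ctx_model_path <- function(graph, ctx_id) {
  ctx <- graph$ctxs[[ctx_id]]
  sub(":[0-9]+$", "", ctx$path)
}

scope_matches <- function(scope, model_path) {
  n <- length(scope)
  if (n == 0L) return(length(model_path) == 1L) # root only
  if (length(model_path) < n) return(FALSE)
  identical(tail(model_path, n), scope)
}

#' Resolve constraint scopes against a graph's context tree
#'
#' An entry with scope pattern `P` applies to every context whose model-name
#' path (invocation counters ignored) ends with `P`; unscoped entries apply
#' to the root context only.
#'
#' @param constraint_set An `ffg_constraint_set`.
#' @param graph An `ffg` graph.
#' @return A list with `map` (named list: context id -> integer indices of
#'   applicable entries) and `diagnostics` (character; one warning-level
#'   entry per scope pattern matching no context).
#' @export
resolve_scopes <- function(constraint_set, graph) {
  ctx_ids <- ls(graph$ctxs)
  paths <- lapply(ctx_ids, function(c) ctx_model_path(graph, c))
  map <- stats::setNames(vector("list", length(ctx_ids)), ctx_ids)
  diagnostics <- character(0)
  for (k in seq_along(constraint_set$entries)) {
    e <- constraint_set$entries[[k]]
    hit <- FALSE
    for (i in seq_along(ctx_ids)) {
      if (scope_matches(e$scope, paths[[i]])) {
        map[[ctx_ids[i]]] <- c(map[[ctx_ids[i]]], k)
        hit <- TRUE
      }
    }
    if (!hit) {
      diagnostics <- c(diagnostics, sprintf(
        "UnmatchedScope: pattern '%s' matches no context",
        if (length(e$scope)) paste(e$scope, collapse = "/") else "<root>"))
    }
  }
  list(map = map, diagnostics = diagnostics)
}

# Resolve a constraint variable name to the set of variable ids it denotes in
# a context: the scalar binding and/or every indexed element of that base
# name, following interface bindings to the owning scope.
resolve_constraint_var <- function(graph, ctx_id, name) {
  ctx <- graph$ctxs[[ctx_id]]
  b <- ctx$bindings[[name]]
  ids <- character(0)
  if (is_vecref(b)) {
    owner <- graph$ctxs[[b$ctx]]
    keys <- ls(owner$bindings)
    el <- keys[startsWith(keys, paste0(b$name, "["))]
    ids <- unlist(lapply(el, function(k) owner$bindings[[k]]), use.names = FALSE)
  } else if (is.character(b)) {
    ids <- b
  } else if (is.list(b) && !is.null(b$value)) {
    ffg_stop("constraint_on_constant",
             "'%s' is a construction-time constant; beliefs range over latent variables", name)
  }
  keys <- ls(ctx$bindings)
  el <- keys[startsWith(keys, paste0(name, "["))]
  ids <- unique(c(ids, unlist(lapply(el, function(k) {
    v <- ctx$bindings[[k]]
    if (is.character(v)) v else NULL
  }), use.names = FALSE)))
  ids
}

#' Resolve factorization constraints to per-factor local factorizations
#'
#' The default local belief is the full joint over each factor's interfaces
#' (the Bethe family). Every applicable FC induces, on each factor whose
#' interface variables it mentions, a partition grouping mentioned interfaces
#' by FC block with all unmentioned interfaces in one remaining cell; the
#' result per factor is the coarsest partition refined by all induced
#' partitions (the lattice meet).
#'
#' @param graph An `ffg` graph.
#' @param constraint_set An `ffg_constraint_set`.
#' @param attach Store the result as a graph-global payload of the
#'   variational-constraints plugin (default `TRUE`).
#' @return An `ffg_local_factorization`: named list factor id -> list of
#'   character vectors of interface names.
#' @export
apply_factorization <- function(graph, constraint_set, attach = TRUE) {
  sc <- resolve_scopes(constraint_set, graph)
  lf <- list()
  for (fid in sort_ids(ls(graph$factors))) {
    f <- graph$factors[[fid]]
    part <- list(names(f$interfaces)) # Bethe default: one joint block
    ks <- sc$map[[f$ctx]]
    for (k in ks) {
      e <- constraint_set$entries[[k]]
      if (e$type != "fc") next
      # map each constrained name to variable ids in the factor's context
      id_blocks <- lapply(e$partition, function(block) {
        unlist(lapply(block, function(nm) {
          ids <- resolve_constraint_var(graph, f$ctx, nm)
          if (length(ids) == 0L) {
            ffg_stop("unknown_constraint_variable",
                     "constraint variable '%s' does not resolve in scope '%s'",
                     nm, paste(ctx_model_path(graph, f$ctx), collapse = "/"))
          }
          for (id in ids) {
            if (graph$vars[[id]]$kind == "constant") {
              ffg_stop("constraint_on_constant",
                       "constraint variable '%s' is a constant node", nm)
            }
          }
          ids
        }), use.names = FALSE)
      })
      cell_of <- vapply(f$interfaces, function(vid) {
        for (bi in seq_along(id_blocks)) if (vid %in% id_blocks[[bi]]) return(bi)
        0L # unmentioned
      }, integer(1))
      if (!any(cell_of > 0L)) next # FC mentions none of this factor's variables
      induced <- split(names(f$interfaces), cell_of)
      part <- partition_meet(part, unname(induced))
    }
    lf[[fid]] <- part
  }
  out <- structure(lf, class = "ffg_local_factorization",
                   diagnostics = sc$diagnostics)
  if (attach) {
    attach_payload(graph, CONSTRAINT_PLUGIN, "graph",
                   list(local_factorization = unclass(lf)), quiet = TRUE)
  }
  out
}

# coarsest common refinement of two partitions of the same ground set
partition_meet <- function(p, q) {
  out <- list()
  for (a in p) for (b in q) {
    cell <- intersect(a, b)
    if (length(cell) > 0L) out[[length(out) + 1L]] <- cell
  }
  out
}

#' Resolve functional-form constraints to per-variable family tags
#'
#' Tags are attached as payloads of the variational-constraints plugin;
#' variables without an FFC stay untagged (free-form).
#'
#' @param graph An `ffg` graph.
#' @param constraint_set An `ffg_constraint_set`.
#' @param registry Registry in which families must be registered (defaults to
#'   the graph's builder registry).
#' @return Named character vector: variable id -> family label.
#' @export
apply_functional_form <- function(graph, constraint_set, registry = NULL) {
  if (is.null(registry)) registry <- builder_registry(graph)
  sc <- resolve_scopes(constraint_set, graph)
  tags <- character(0)
  for (cid in names(sc$map)) {
    for (k in sc$map[[cid]]) {
      e <- constraint_set$entries[[k]]
      if (e$type != "ffc") next
      if (!is_registered(registry, e$family)) {
        ffg_stop("unknown_family", "family '%s' is not registered", e$family)
      }
      ids <- resolve_constraint_var(graph, cid, e$variable)
      if (length(ids) == 0L) {
        ffg_stop("unknown_constraint_variable",
                 "constraint variable '%s' does not resolve in its scope", e$variable)
      }
      for (id in ids) {
        if (graph$vars[[id]]$kind != "random") {
          ffg_stop("constraint_on_constant",
                   "functional form on non-latent variable '%s'", e$variable)
        }
        attach_payload(graph, CONSTRAINT_PLUGIN, id, list(form = e$family), quiet = TRUE)
        tags[id] <- e$family
      }
    }
  }
  tags
}

#' Read a constraint document (YAML or JSON)
#'
#' The document is a list of entries; each entry is either a constraint
#' (`q`: variables, `factorization`: list of blocks — or `form`: family for
#' an FFC with `q` of length one) or a nested scope block (`scope`: submodel
#' name or path, `constraints`: entries). Nesting prefixes the scope path.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return An `ffg_constraint_set`.
#' @export
read_constraints <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    # keep YAML-1.1 boolean-ish scalars like "y"/"n" as variable names
    keep <- function(truth) function(x) {
      if (tolower(x) %in% c("true", "false")) truth else x
    }
    yaml::read_yaml(path, handlers = list("bool#yes" = keep(TRUE),
                                          "bool#no" = keep(FALSE)))
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  build_constraint_set(parse_constraint_doc(doc, scope = character(0)))
}

parse_constraint_doc <- function(doc, scope) {
  if (!is.null(doc$constraints) && is.null(doc$scope)) {
    doc <- doc$constraints
  }
  out <- list()
  for (e in doc) {
    if (!is.null(e$scope)) {
      child <- c(scope, unlist(e$scope))
      out <- c(out, parse_constraint_doc(e$constraints, child))
    } else if (!is.null(e$form)) {
      out <- c(out, list(ffc(unlist(e$q), unlist(e$form), scope = scope)))
    } else if (!is.null(e$factorization)) {
      blocks <- lapply(e$factorization, unlist)
      out <- c(out, list(fc(unlist(e$q), blocks, scope = scope)))
    } else {
      ffg_stop("malformed_partition", "unrecognized constraint entry")
    }
  }
  out
}
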