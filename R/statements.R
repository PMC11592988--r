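#' Build a call expression
#'
#' Expression trees are the right-hand sides of tilde statements. Arguments
#' may be literals (numeric scalars or vectors), variable references created
#' with [fg_ref()], or nested calls (compound statements, which the builder
#' unrolls).
#'
#' @param label Node-type label.
#' @param ... Positional (unnamed) and keyword (named) arguments.
#' @return An `ffg_call` expression.
#' @export
fg_call <- function(label, ...) {
  args <- list(...)
  nms <- names(args)
  if (is.null(nms)) nms <- rep("", length(args))
  structure(list(label = label,
                 args = unname(args[!nzchar(nms)]),
                 kwargs = args[nzchar(nms)]),
            class = "ffg_call")
}

#' Reference a variable by (name, index)
#'
#' @param name Base variable name.
#' @param index Optional 0-based index for vector variables.
#' @return An `ffg_ref`.
#' @export
fg_ref <- function(name, index = NULL) {
  structure(list(name = name,
                 index = if (is.null(index)) NA_integer_ else as.integer(index)),
            class = "ffg_ref")
}

is_call <- function(x) inherits(x, "ffg_call")
is_ref <- function(x) inherits(x, "ffg_ref")
is_literal <- function(x) is.numeric(x)

#' Construct a statement
#'
#' A statement relates a left-hand-side variable to a call expression either
#' stochastically (`"~"`) or deterministically (`":="`). The deterministic
#' relation is an alias of the stochastic one: both materialize through the
#' same operation, and the relation flag is recorded for rendering only.
#'
#' @param lhs An `ffg_ref` or a variable name.
#' @param rhs An `ffg_call`.
#' @param relation `"~"` or `":="`.
#' @return An `ffg_statement`.
#' @export
fg_stmt <- function(lhs, rhs, relation = c("~", ":=")) {
  relation <- match.arg(relation)
  if (is.character(lhs)) lhs <- fg_ref(lhs)
  if (!is_ref(lhs)) ffg_stop("invalid_statement", "statement lhs must be a name or fg_ref")
  if (!is_call(rhs)) ffg_stop("invalid_statement", "statement rhs must be an fg_call")
  structure(list(lhs = lhs, rhs = rhs, relation = relation), class = "ffg_statement")
}

stmt_is_primitive <- function(stmt) {
  flat <- function(a) !is_call(a)
  all(vapply(stmt$rhs$args, flat, logical(1))) &&
    all(vapply(stmt$rhs$kwargs, flat, logical(1)))
}

check_labels_registered <- function(expr, registry) {
  if (!is_call(expr)) return(invisible(NULL))
  if (!is_registered(registry, expr$label) && is.null(registry$aliases[[expr$label]])) {
    ffg_stop("unknown_label", "node type '%s' is not registered", expr$label)
  }
  for (a in expr$args) check_labels_registered(a, registry)
  for (a in expr$kwargs) check_labels_registered(a, registry)
  invisible(NULL)
}

#' Unroll a compound statement into primitive statements
#'
#' Nested calls on the right-hand side are lifted into anonymous intermediate
#' variables named `<lhs>_tmp_<k>`, evaluated innermost-first and
#' left-to-right; the final statement binds the original left-hand side. The
#' anonymous counter is per-context so repeated statements with the same
#' left-hand side never collide.
#'
#' @param statement An `ffg_statement`.
#' @param registry An `ffg_registry`; every label in the tree must be
#'   registered (or have alias rules).
#' @param counter Optional environment carrying per-name counters; a fresh
#'   one (starting at 0) is used when omitted.
#' @return List of primitive `ffg_statement`s.
#' @export
unroll_compound <- function(statement, registry, counter = NULL) {
  if (is.null(counter)) counter <- new.env(parent = emptyenv())
  check_labels_registered(statement$rhs, registry)
  base <- statement$lhs$name
  out <- list()
  next_tmp <- function() {
    k <- counter[[base]]
    if (is.null(k)) k <- 0L
    assign(base, k + 1L, envir = counter)
    paste0(base, "_tmp_", k)
  }
  flatten_arg <- function(a) {
    if (!is_call(a)) return(a)
    flat <- flatten_call(a)
    tmp <- next_tmp()
    out[[length(out) + 1L]] <<- fg_stmt(fg_ref(tmp), flat, statement$relation)
    fg_ref(tmp)
  }
  flatten_call <- function(cl) {
    cl$args <- lapply(cl$args, flatten_arg)
    cl$kwargs <- lapply(cl$kwargs, flatten_arg)
    cl
  }
  top <- flatten_call(statement$rhs)
  out[[length(out) + 1L]] <- fg_stmt(statement$lhs, top, statement$relation)
  out
}

#' @export
print.ffg_statement <- function(x, ...) {
  fmt <- function(e) {
    if (is_ref(e)) {
      if (is.na(e$index)) e$name else sprintf("%s[%d]", e$name, e$index)
    } else if (is_call(e)) {
      parts <- c(vapply(e$args, fmt, character(1)),
                 if (length(e$kwargs)) paste0(names(e$kwargs), " = ",
                                              vapply(e$kwargs, fmt, character(1))))
      sprintf("%s(%s)", e$label, paste(parts, collapse = ", "))
    } else {
      paste(format(e), collapse = ",")
    }
  }
  cat(fmt(x$lhs), x$relation, fmt(x$rhs), "\n")
  invisible(x)
}
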