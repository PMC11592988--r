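#' Node-type registry
#'
#' The builder decides, per statement, whether to materialize a factor node
#' (stochastic node types, or deterministic ones with unresolved arguments)
#' or to evaluate the relation at construction time (deterministic folding).
#' That decision is driven by this registry, which inference backends can
#' extend with their own node types.
#'
#' @param populate If `TRUE` (default) the registry is pre-populated with the
#'   standard node types (`Beta`, `Bernoulli`, `Gamma`, the four `Normal`
#'   parameterizations with keyword aliasing, and the deterministic
#'   primitives `+`, `*`, `exp`, `tanh`, `dot`, `norm`).
#' @return An object of class `ffg_registry`.
#' @export
node_registry <- function(populate = TRUE) {
  reg <- new.env(parent = emptyenv())
  reg$types <- new.env(parent = emptyenv())   # label -> entry
  reg$aliases <- new.env(parent = emptyenv()) # source label -> list of rules
  class(reg) <- "ffg_registry"
  if (populate) populate_default_registry(reg)
  reg
}

#' Register a node type
#'
#' @param registry An `ffg_registry`.
#' @param label Node-type label.
#' @param kind `"stochastic"` or `"deterministic"`.
#' @param evaluator For deterministic types, a numeric function used for
#'   construction-time folding.
#' @param arg_names Optional interface names for positional arguments
#'   (defaults to `in1`, `in2`, ... and the output interface is always
#'   `out`).
#' @param overwrite Allow re-registration of an existing label.
#' @return The registry, invisibly.
#' @export
register_node_type <- function(registry, label, kind = c("stochastic", "deterministic"),
                               evaluator = NULL, arg_names = NULL, overwrite = FALSE) {
  kind <- match.arg(kind)
  if (!overwrite && !is.null(registry$types[[label]])) {
    ffg_stop("duplicate_label", "node type '%s' is already registered", label)
  }
  if (kind == "deterministic" && !is.function(evaluator)) {
    ffg_stop("evaluator_missing", "deterministic node type '%s' requires an evaluator", label)
  }
  entry <- list(label = label, kind = kind, evaluator = evaluator, arg_names = arg_names)
  assign(label, entry, envir = registry$types)
  invisible(registry)
}

#' Register a keyword-alias rule
#'
#' Maps a generic node label plus a keyword set to a concrete node type, e.g.
#' `Normal(mean = , var = )` to `NormalMeanVariance` with the keywords placed
#' in the stated positional order. This lets users write against a single
#' intuitive name while backends see concrete parameterizations.
#'
#' @param registry An `ffg_registry`.
#' @param source_label Generic label the user writes.
#' @param keywords Character vector; both the keyword set and the positional
#'   order of the target's arguments.
#' @param target_label Concrete node-type label (must be registered).
#' @return The registry, invisibly.
#' @export
register_alias_rule <- function(registry, source_label, keywords, target_label) {
  if (anyDuplicated(keywords)) {
    ffg_stop("malformed_alias", "alias keywords must be distinct")
  }
  rules <- registry$aliases[[source_label]]
  if (is.null(rules)) rules <- list()
  for (r in rules) {
    if (setequal(r$keywords, keywords)) {
      ffg_stop("duplicate_alias", "an alias for '%s' with this keyword set already exists", source_label)
    }
  }
  rules[[length(rules) + 1L]] <- list(keywords = keywords, target = target_label)
  assign(source_label, rules, envir = registry$aliases)
  invisible(registry)
}

#' Resolve a (label, keyword arguments) pair to a concrete node type
#'
#' @param registry An `ffg_registry`.
#' @param label Label as written in the statement.
#' @param kwargs Named list of keyword arguments (may be empty).
#' @return A list with `label` (concrete), `args` (ordered positional
#'   argument list).
#' @export
resolve_alias <- function(registry, label, kwargs = list()) {
  rules <- registry$aliases[[label]]
  if (length(kwargs) == 0L) {
    if (is.null(registry$types[[label]]) && is.null(rules)) {
      ffg_stop("unknown_label", "node type '%s' is not registered", label)
    }
    return(list(label = label, args = list()))
  }
  kw <- names(kwargs)
  if (is.null(kw) || any(!nzchar(kw))) {
    ffg_stop("malformed_alias", "keyword arguments must all be named")
  }
  if (is.null(rules)) {
    if (is.null(registry$types[[label]])) {
      ffg_stop("unknown_label", "node type '%s' is not registered", label)
    }
    # no alias rules: keywords are taken as the factor's interface names directly
    return(list(label = label, args = kwargs))
  }
  hits <- Filter(function(r) setequal(r$keywords, kw), rules)
  if (length(hits) == 0L) {
    ffg_stop("unknown_keyword_set", "no alias of '%s' accepts keywords {%s}",
             label, paste(sort(kw), collapse = ", "))
  }
  if (length(hits) > 1L) {
    ffg_stop("ambiguous_alias", "multiple aliases of '%s' match keywords {%s}",
             label, paste(sort(kw), collapse = ", "))
  }
  rule <- hits[[1L]]
  list(label = rule$target, args = unname(kwargs[rule$keywords]))
}

registry_entry <- function(registry, label) {
  e <- registry$types[[label]]
  if (is.null(e)) ffg_stop("unknown_label", "node type '%s' is not registered", label)
  e
}

#' @export
is_registered <- function(registry, label) !is.null(registry$types[[label]])

populate_default_registry <- function(reg) {
  register_node_type(reg, "Beta", "stochastic", arg_names = c("a", "b"))
  register_node_type(reg, "Bernoulli", "stochastic", arg_names = "p")
  register_node_type(reg, "Gamma", "stochastic", arg_names = c("shape", "rate"))
  register_node_type(reg, "Categorical", "stochastic", arg_names = "p")
  register_node_type(reg, "NormalMeanVariance", "stochastic", arg_names = c("mean", "var"))
  register_node_type(reg, "NormalMeanPrecision", "stochastic", arg_names = c("mean", "precision"))
  register_node_type(reg, "NormalWeightedMeanVariance", "stochastic", arg_names = c("xi", "var"))
  register_node_type(reg, "NormalWeightedMeanPrecision", "stochastic", arg_names = c("xi", "precision"))
  # generic Normal: positional call means (mean, variance)
  register_node_type(reg, "Normal", "stochastic", arg_names = c("mean", "var"))
  register_alias_rule(reg, "Normal", c("mean", "var"), "NormalMeanVariance")
  register_alias_rule(reg, "Normal", c("mean", "precision"), "NormalMeanPrecision")
  register_alias_rule(reg, "Normal", c("xi", "var"), "NormalWeightedMeanVariance")
  register_alias_rule(reg, "Normal", c("xi", "precision"), "NormalWeightedMeanPrecision")
  # Greek spellings seen in the modelling literature (nu = weighted mean, tau = precision)
  register_alias_rule(reg, "Normal", c("nu", "tau"), "NormalWeightedMeanPrecision")

  register_node_type(reg, "+", "deterministic", evaluator = function(...) Reduce(`+`, list(...)))
  register_node_type(reg, "*", "deterministic", evaluator = function(...) Reduce(`*`, list(...)))
  register_node_type(reg, "exp", "deterministic", evaluator = exp, arg_names = "in")
  register_node_type(reg, "tanh", "deterministic", evaluator = tanh, arg_names = "in")
  register_node_type(reg, "dot", "deterministic", evaluator = function(...) {
    xs <- unlist(list(...))
    h <- length(xs) %/% 2L
    sum(xs[seq_len(h)] * xs[h + seq_len(h)])
  })
  register_node_type(reg, "norm", "deterministic", evaluator = function(...) {
    sqrt(sum(unlist(list(...))^2))
  })
  reg
}

#' @export
print.ffg_registry <- function(x, ...) {
  cat(sprintf("<ffg_registry> %d node types, %d aliased labels\n",
              length(ls(x$types)), length(ls(x$aliases))))
  invisible(x)
}
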