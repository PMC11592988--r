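# JSON graph documents: a lossless, versioned exchange format so a model can
# be built in one process and inspected, constrained or executed in another.

FORMAT_VERSION <- "1.0"

serialize_binding <- function(b) {
  if (is_vecref(b)) {
    list(type = "vec", name = b$name, ctx = b$ctx, length = b$length)
  } else if (is.character(b)) {
    list(type = "var", id = b)
  } else if (is.list(b) && !is.null(b$value)) {
    list(type = "value", value = b$value)
  } else {
    ffg_stop("schema_violation", "unserializable binding")
  }
}

deserialize_binding <- function(s) {
  switch(s$type,
         vec = new_vecref(s$name, s$ctx, s$length %||% NA_integer_),
         var = s$id,
         value = list(value = unlist(s$value)),
         ffg_stop("schema_violation", "unknown binding type '%s'", s$type))
}

#' Serialize a factor graph to a JSON document
#'
#' The document is lossless: variables, factors, the full context tree
#' (including bindings and counters), plugin payloads, and optional discrete
#' tables round-trip with identical ids.
#'
#' @param graph An `ffg` graph (must pass [fg_validate()]).
#' @param tables Optional list of [factor_table()]s to embed.
#' @param file Optional path; when given the JSON is written there.
#' @return The document as a list (invisibly when `file` is given).
#' @export
to_json <- function(graph, tables = NULL, file = NULL) {
  diags <- fg_validate(graph)
  if (length(diags) > 0L) {
    ffg_stop("invalid_graph", "refusing to serialize an invalid graph: %s",
             paste(diags, collapse = "; "))
  }
  doc <- list(
    format_version = FORMAT_VERSION,
    root = graph$root,
    counters = list(var = graph$counters$var, factor = graph$counters$factor,
                    ctx = graph$counters$ctx),
    variables = lapply(sort_ids(ls(graph$vars)), function(id) {
      v <- graph$vars[[id]]
      list(id = v$id, name = v$name,
           index = if (is.na(v$index)) NULL else v$index,
           ctx = v$ctx, kind = v$kind, value = v$value)
    }),
    factors = lapply(sort_ids(ls(graph$factors)), function(id) {
      f <- graph$factors[[id]]
      list(id = f$id, label = f$label, deterministic = f$deterministic,
           interfaces = as.list(f$interfaces), ctx = f$ctx)
    }),
    contexts = lapply(sort_ids(ls(graph$ctxs)), function(id) {
      ctx <- graph$ctxs[[id]]
      list(id = ctx$id, model_name = ctx$model_name, counter = ctx$counter,
           parent = ctx$parent,
           bindings = stats::setNames(
             lapply(ls(ctx$bindings), function(k) serialize_binding(ctx$bindings[[k]])),
             ls(ctx$bindings)),
           interface_bindings = stats::setNames(
             lapply(ls(ctx$interface_bindings),
                    function(k) serialize_binding(ctx$interface_bindings[[k]])),
             ls(ctx$interface_bindings)),
           const_counter = ctx$const_counter,
           tmp_counters = as.list(ctx$tmp_counters),
           submodel_counters = as.list(ctx$submodel_counters))
    }),
    payloads = stats::setNames(lapply(ls(graph$payloads), function(p) {
      ns <- graph$payloads[[p]]
      stats::setNames(lapply(ls(ns), function(t) ns[[t]]), ls(ns))
    }), ls(graph$payloads))
  )
  if (!is.null(tables)) {
    doc$tables <- lapply(tables, function(ft) {
      list(factor_id = ft$factor_id,
           domains = ft$domains,
           dim = dim(ft$table),
           values = as.numeric(ft$table))
    })
  }
  if (!is.null(file)) {
    jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(doc))
  }
  doc
}

#' Parse a JSON graph document
#'
#' @param doc A document list, or a path to a JSON file.
#' @return List with `graph` (an `ffg`) and `tables` (possibly `NULL`).
#' @export
from_json <- function(doc) {
  if (is.character(doc) && length(doc) == 1L) {
    doc <- jsonlite::read_json(doc, simplifyVector = FALSE)
  }
  fv <- doc$format_version
  if (is.null(fv)) ffg_stop("schema_violation", "document lacks format_version")
  if (sub("\\..*$", "", fv) != sub("\\..*$", "", FORMAT_VERSION)) {
    ffg_stop("version_mismatch", "document format %s is incompatible with %s",
             fv, FORMAT_VERSION)
  }
  for (field in c("root", "variables", "factors", "contexts")) {
    if (is.null(doc[[field]])) ffg_stop("schema_violation", "document lacks '%s'", field)
  }
  g <- new.env(parent = emptyenv())
  g$vars <- new.env(parent = emptyenv())
  g$factors <- new.env(parent = emptyenv())
  g$ctxs <- new.env(parent = emptyenv())
  g$adj <- new.env(parent = emptyenv())
  g$key_index <- new.env(parent = emptyenv())
  g$payloads <- new.env(parent = emptyenv())
  g$counters <- new.env(parent = emptyenv())
  g$counters$var <- as.integer(doc$counters$var %||% 0L)
  g$counters$factor <- as.integer(doc$counters$factor %||% 0L)
  g$counters$ctx <- as.integer(doc$counters$ctx %||% 0L)
  g$root <- doc$root
  class(g) <- "ffg"

  ctxs <- doc$contexts[order(vapply(doc$contexts, function(c) {
    as.integer(sub("^c", "", c$id))
  }, integer(1)))]
  for (c in ctxs) {
    ctx <- new.env(parent = emptyenv())
    ctx$id <- c$id
    ctx$model_name <- c$model_name
    ctx$counter <- as.integer(c$counter)
    ctx$parent <- c$parent
    label <- if (is.null(c$parent)) c$model_name else paste0(c$model_name, ":", c$counter)
    ctx$path <- if (is.null(c$parent)) label else c(g$ctxs[[c$parent]]$path, label)
    ctx$bindings <- new.env(parent = emptyenv())
    for (k in names(c$bindings)) {
      assign(k, deserialize_binding(c$bindings[[k]]), envir = ctx$bindings)
    }
    ctx$interface_bindings <- new.env(parent = emptyenv())
    for (k in names(c$interface_bindings)) {
      assign(k, deserialize_binding(c$interface_bindings[[k]]), envir = ctx$interface_bindings)
    }
    ctx$tmp_counters <- new.env(parent = emptyenv())
    for (k in names(c$tmp_counters)) assign(k, as.integer(c$tmp_counters[[k]]), envir = ctx$tmp_counters)
    ctx$const_counter <- as.integer(c$const_counter %||% 0L)
    ctx$submodel_counters <- new.env(parent = emptyenv())
    for (k in names(c$submodel_counters)) {
      assign(k, as.integer(c$submodel_counters[[k]]), envir = ctx$submodel_counters)
    }
    assign(ctx$id, ctx, envir = g$ctxs)
  }
  for (v in doc$variables) {
    ctx <- g$ctxs[[v$ctx]]
    if (is.null(ctx)) ffg_stop("schema_violation", "variable %s references unknown context", v$id)
    idx <- if (is.null(v$index)) NA_integer_ else as.integer(v$index)
    rec <- list(id = v$id, name = v$name, index = idx, path = ctx$path,
                ctx = v$ctx, kind = v$kind,
                value = if (is.null(v$value)) NULL else unlist(v$value))
    assign(v$id, rec, envir = g$vars)
    assign(v$id, character(0), envir = g$adj)
    assign(var_key(v$name, idx, ctx$path), v$id, envir = g$key_index)
  }
  for (f in doc$factors) {
    ctx <- g$ctxs[[f$ctx]]
    interfaces <- unlist(f$interfaces)
    for (vid in interfaces) {
      if (is.null(g$vars[[vid]])) {
        ffg_stop("schema_violation", "factor %s references unknown variable %s", f$id, vid)
      }
    }
    rec <- list(id = f$id, label = f$label, deterministic = isTRUE(f$deterministic),
                interfaces = interfaces, path = ctx$path, ctx = f$ctx)
    assign(f$id, rec, envir = g$factors)
    for (vid in unique(interfaces)) assign(vid, c(g$adj[[vid]], f$id), envir = g$adj)
  }
  for (p in names(doc$payloads)) {
    for (t in names(doc$payloads[[p]])) {
      attach_payload(g, p, t, doc$payloads[[p]][[t]], quiet = TRUE)
    }
  }
  tables <- NULL
  if (!is.null(doc$tables)) {
    tables <- list()
    for (ft in doc$tables) {
      domains <- lapply(ft$domains, unlist)
      tab <- array(unlist(ft$values), dim = unlist(ft$dim))
      tables[[ft$factor_id]] <- factor_table(ft$factor_id, domains, tab)
    }
  }
  diags <- fg_validate(g)
  if (length(diags) > 0L) {
    ffg_stop("schema_violation", "document decodes to an invalid graph: %s",
             paste(diags, collapse = "; "))
  }
  list(graph = g, tables = tables)
}
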