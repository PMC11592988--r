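#' Attach a plugin payload to a graph element
#'
#' Payloads are namespaced by plugin name: a plugin cannot read (or clobber)
#' another plugin's payloads. Inference backends use this to store the extra
#' information they need — the variational-constraints plugin stores
#' functional-form tags and resolved local factorizations this way.
#'
#' @param graph An `ffg` graph.
#' @param plugin_name Plugin namespace.
#' @param target A variable id, factor id, or `"graph"` for graph-global.
#' @param payload Any serializable R object.
#' @param quiet Suppress the overwrite warning.
#' @return The graph, invisibly.
#' @export
attach_payload <- function(graph, plugin_name, target, payload, quiet = FALSE) {
  if (!identical(target, "graph") &&
      is.null(graph$vars[[target]]) && is.null(graph$factors[[target]])) {
    ffg_stop("unknown_target", "no graph element with id '%s'", target)
  }
  ns <- graph$payloads[[plugin_name]]
  if (is.null(ns)) {
    ns <- new.env(parent = emptyenv())
    assign(plugin_name, ns, envir = graph$payloads)
  }
  if (!is.null(ns[[target]]) && !quiet) {
    ffg_warn("payload_overwrite", "plugin '%s' overwrites its payload on '%s'",
             plugin_name, target)
  }
  assign(target, payload, envir = ns)
  invisible(graph)
}

#' Retrieve a plugin payload
#'
#' @inheritParams attach_payload
#' @return The payload, or `NULL` if none is attached.
#' @export
get_payload <- function(graph, plugin_name, target) {
  ns <- graph$payloads[[plugin_name]]
  if (is.null(ns)) return(NULL)
  ns[[target]]
}

#' List all payloads of a plugin
#'
#' @inheritParams attach_payload
#' @return Named list target id -> payload.
#' @export
list_payloads <- function(graph, plugin_name) {
  ns <- graph$payloads[[plugin_name]]
  if (is.null(ns)) return(list())
  stats::setNames(lapply(ls(ns), function(t) ns[[t]]), ls(ns))
}
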