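#' Render a factor graph as DOT text
#'
#' Factors are drawn as squares and variables as circles; each submodel
#' context becomes a dotted cluster, visualizing "closing the box". With
#' `strict_ffg = TRUE`, variables shared by more than two factors are drawn
#' as equality nodes (small squares labelled `=`), the classical expansion
#' that keeps every edge binary in a Forney-style drawing.
#'
#' @param graph An `ffg` graph.
#' @param edge_labels Label each edge with its interface name.
#' @param strict_ffg Render degree > 2 variables as equality nodes.
#' @return A single string of DOT source.
#' @export
to_dot <- function(graph, edge_labels = FALSE, strict_ffg = FALSE) {
  esc <- function(x) gsub('"', '\\\\"', x)
  lines <- c("graph ffg {", "  node [fontsize=10];")
  var_label <- function(v) {
    nm <- if (is.na(v$index)) v$name else sprintf("%s[%d]", v$name, v$index)
    if (v$kind != "random") nm <- sprintf("%s=%s", nm, paste(format(v$value), collapse = ","))
    nm
  }
  # group node declarations by context for clustering
  ctx_nodes <- list()
  push <- function(cid, line) {
    ctx_nodes[[cid]] <<- c(ctx_nodes[[cid]], line)
  }
  for (vid in sort_ids(ls(graph$vars))) {
    v <- graph$vars[[vid]]
    shape <- if (strict_ffg && fg_degree(graph, vid) > 2L) {
      sprintf('  "%s" [shape=square, label="=", xlabel="%s"];', vid, esc(var_label(v)))
    } else {
      sprintf('  "%s" [shape=circle, label="%s"];', vid, esc(var_label(v)))
    }
    push(v$ctx, shape)
  }
  for (fid in sort_ids(ls(graph$factors))) {
    f <- graph$factors[[fid]]
    style <- if (f$deterministic) ", style=dashed" else ""
    push(f$ctx, sprintf('  "%s" [shape=box, label="%s"%s];', fid, esc(f$label), style))
  }
  # context tree -> nested clusters
  children <- list()
  for (cid in ls(graph$ctxs)) {
    p <- graph$ctxs[[cid]]$parent
    if (!is.null(p)) children[[p]] <- c(children[[p]], cid)
  }
  emit_ctx <- function(cid, indent) {
    pad <- strrep(" ", indent)
    out <- character(0)
    ctx <- graph$ctxs[[cid]]
    is_root <- is.null(ctx$parent)
    if (!is_root) {
      out <- c(out, sprintf('%ssubgraph "cluster_%s" {', pad, cid),
               sprintf('%s  style=dotted; label="%s:%d";', pad, esc(ctx$model_name), ctx$counter))
    }
    out <- c(out, paste0(pad, ctx_nodes[[cid]]))
    for (ch in sort_ids(children[[cid]] %||% character(0))) {
      out <- c(out, emit_ctx(ch, indent + 2L))
    }
    if (!is_root) out <- c(out, paste0(pad, "}"))
    out
  }
  lines <- c(lines, emit_ctx(graph$root, 2L))
  for (fid in sort_ids(ls(graph$factors))) {
    f <- graph$factors[[fid]]
    for (k in seq_along(f$interfaces)) {
      lbl <- if (edge_labels) sprintf(' [label="%s"]', esc(names(f$interfaces)[k])) else ""
      lines <- c(lines, sprintf('  "%s" -- "%s"%s;', fid, f$interfaces[[k]], lbl))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
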