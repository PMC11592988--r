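# Independent oracles used across the suite. These deliberately avoid the
# package's own enumeration/message-passing code paths.

# nested-loop enumeration over a list of factors given as
# list(vars = <var ids>, table = <array>), domains as named list of sizes
oracle_enumerate <- function(factor_list, dom_sizes) {
  vars <- names(dom_sizes)
  grid <- do.call(expand.grid, lapply(dom_sizes, seq_len))
  w <- rep(1, nrow(grid))
  for (f in factor_list) {
    idx <- as.matrix(grid[, f$vars, drop = FALSE])
    strides <- c(1, cumprod(dim(as.array(f$table))))[seq_along(f$vars)]
    lin <- as.vector((idx - 1) %*% strides) + 1L
    w <- w * as.numeric(f$table)[lin]
  }
  z <- sum(w)
  marginals <- lapply(vars, function(v) {
    vapply(seq_len(dom_sizes[[v]]), function(s) sum(w[grid[[v]] == s]), numeric(1)) / z
  })
  names(marginals) <- vars
  list(marginals = marginals, log_evidence = log(z))
}

# total variation distance
tv <- function(a, b) 0.5 * sum(abs(unname(a) - unname(b)))

# multiset signature of a graph: sorted (factor label, degree) pairs
label_degree_signature <- function(graph) {
  f <- fg_factors(graph)
  sort(paste(f$label, f$degree))
}

# brute-force coarsest common refinement over a small ground set, via
# enumeration of all partitions (Bell-number search; fine for <= 5 elements)
all_partitions <- function(els) {
  if (length(els) == 0L) return(list(list()))
  first <- els[1L]
  rest <- all_partitions(els[-1L])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(first, q[[k]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

partition_refines <- function(p, q) {
  all(vapply(p, function(cell) {
    any(vapply(q, function(big) all(cell %in% big), logical(1)))
  }, logical(1)))
}

canon_partition <- function(p) {
  sorted <- lapply(p, sort)
  sorted[order(vapply(sorted, function(b) b[1L], character(1)))]
}

oracle_meet <- function(parts, ground) {
  cands <- all_partitions(ground)
  ok <- Filter(function(c) all(vapply(parts, function(p) partition_refines(c, p), logical(1))), cands)
  sizes <- vapply(ok, length, integer(1))
  best <- ok[sizes == min(sizes)]
  stopifnot(length(best) >= 1L)
  canon_partition(best[[1L]])
}
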