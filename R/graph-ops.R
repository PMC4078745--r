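# Structural operations: unrolling, skeletons, v-structures, observational
# equivalence, ancestor closure.

#' Unroll a process graph into its time-indexed causal structure
#'
#' Replicates every process over a finite time window and instantiates every
#' lagged edge `src -> dst (lag d)` as `src@t -> dst@(t+d)` for all t with
#' `t + d < window`.  The result is the microscopic (DAG) representation of
#' the dynamics over that window, with all edges pointing forward in time.
#'
#' @param g a [process_graph()].
#' @param window positive integer number of time slices; must be at least
#'   `max(lag) + 1` so every edge is instantiated at least once.
#' @return a [causal_structure()]; attributes `processes`, `window` and
#'   `latent` (the unrolled latent node names) record the provenance.
#' @export
unroll <- function(g, window) {
  if (!inherits(g, "process_graph")) stop("invalid-argument: need a process_graph")
  window <- as.integer(window)
  max_lag <- if (nrow(g$edges)) max(g$edges$lag) else 1L
  if (length(window) != 1L || is.na(window) || window < max_lag + 1L) {
    stop("invalid-argument: window must be >= max edge lag + 1")
  }
  times <- 0:(window - 1L)
  nodes <- as.vector(t(outer(g$nodes, times, node_at)))
  edges <- edge_frame()
  if (nrow(g$edges)) {
    pieces <- lapply(seq_len(nrow(g$edges)), function(i) {
      e <- g$edges[i, ]
      t0 <- 0:(window - 1L - e$lag)
      if (length(t0) < 1L || t0[1L] > window - 1L - e$lag) return(NULL)
      edge_frame(node_at(e$src, t0), node_at(e$dst, t0 + e$lag))
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces)) edges <- do.call(rbind, pieces)
  }
  s <- causal_structure(nodes, edges, check = FALSE)
  attr(s, "processes") <- g$nodes
  attr(s, "window") <- window
  attr(s, "latent") <- as.vector(t(outer(g$latent, times, node_at)))
  s
}

#' Skeleton of a graph
#'
#' The links of a graph without regard to direction or edge type: one
#' undirected edge per adjacent node pair.
#'
#' @param g a causal structure, pattern, embedded pattern or mixed macro graph.
#' @return a list of class `graph_skeleton` with elements `nodes` and
#'   `pairs` (a two-column matrix of canonically ordered node pairs).
#' @export
skeleton <- function(g) {
  e <- graph_edges(g)
  if (nrow(e)) {
    a <- pmin(e$src, e$dst)
    b <- pmax(e$src, e$dst)
    pr <- unique(cbind(a, b))
    pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  } else {
    pr <- matrix(character(0), ncol = 2L)
  }
  dimnames(pr) <- list(NULL, c("a", "b"))
  structure(list(nodes = sort(graph_nodes(g)), pairs = pr),
            class = "graph_skeleton")
}

#' @export
print.graph_skeleton <- function(x, ...) {
  cat(sprintf("Skeleton: %d nodes, %d links\n", length(x$nodes), nrow(x$pairs)))
  invisible(x)
}

adjacency_pairs <- function(g) {
  sk <- skeleton(g)
  if (!nrow(sk$pairs)) return(character(0))
  pair_key(sk$pairs[, 1L], sk$pairs[, 2L])
}

#' V-structures of a causal structure
#'
#' All triples `a -> c <- b` whose outer nodes are non-adjacent, the invariant
#' that distinguishes observationally equivalent DAGs.  Each collider is
#' reported once, canonically ordered as `(min(a,b), c, max(a,b))`.
#'
#' @param s a [causal_structure()].
#' @return data.frame with columns `a`, `c`, `b`, sorted lexicographically.
#' @export
v_structures <- function(s) {
  e <- graph_edges(s)
  out <- data.frame(a = character(0), c = character(0), b = character(0),
                    stringsAsFactors = FALSE)
  if (!nrow(e)) return(out)
  adj <- adjacency_pairs(s)
  par_by <- split(e$src, e$dst)
  rows <- list()
  for (c_node in names(par_by)) {
    pa <- sort(unique(par_by[[c_node]]))
    if (length(pa) < 2L) next
    cmb <- utils::combn(pa, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      if (!(pair_key(a, b) %in% adj)) {
        rows[[length(rows) + 1L]] <- data.frame(a = a, c = c_node, b = b,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(out$a, out$c, out$b), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Observational equivalence of two causal structures
#'
#' Two DAGs are observationally equivalent iff they have the same skeleton
#' and the same v-structures: they then admit exactly the same conditional
#' independencies, so no observational data can tell them apart.
#'
#' @param s1,s2 [causal_structure()] objects over the same node set.
#' @return logical.
#' @export
observationally_equivalent <- function(s1, s2) {
  if (!setequal(graph_nodes(s1), graph_nodes(s2))) {
    stop("invalid-argument: structures must share the same node set")
  }
  sk1 <- skeleton(s1); sk2 <- skeleton(s2)
  if (!identical(sk1$pairs, sk2$pairs)) return(FALSE)
  v1 <- v_structures(s1); v2 <- v_structures(s2)
  identical(v1, v2)
}

#' Ancestor closure
#'
#' All nodes from which a target can be attained by following directed paths
#' forwards (equivalently, following arrows backwards from the targets).
#' Targets are included in the closure.
#'
#' @param s a [causal_structure()].
#' @param targets character vector of node names.
#' @return character vector of node names (sorted).
#' @export
ancestors <- function(s, targets) {
  stopifnot_nodes(targets, graph_nodes(s))
  e <- graph_edges(s)
  par_by <- split(e$src, e$dst)
  seen <- unique(as.character(targets))
  queue <- seen
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (p in par_by[[v]] %||% character(0)) {
      if (!(p %in% seen)) {
        seen <- c(seen, p)
        queue <- c(queue, p)
      }
    }
  }
  sort(seen)
}
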