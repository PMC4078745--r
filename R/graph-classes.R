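# Graph containers used throughout the package.
#
# All graph flavors share one internal layout: a character vector of node
# names plus an edge data.frame with columns src, dst, type (and lag for
# process graphs).  The edge-type alphabet differs per flavor:
#   causal_structure : directed
#   pattern          : directed | undirected
#   embedded_pattern : undirected | potential | genuine | bidirectional
#   mixed_macro_graph: directed | bidirectional
# For d-separation every edge is reduced to a pair of endpoint marks
# (tail/head); see dsep.R.

GRAPH_EDGE_TYPES <- c("directed", "undirected", "potential", "genuine",
                      "bidirectional")

#' Ground-truth description of interacting dynamic processes
#'
#' A process graph is the macroscopic description of a dynamic system: one
#' node per process, directed edges annotated with a positive time lag, and a
#' subset of processes flagged as latent (unobserved).  Instantaneous
#' (lag-zero) ground-truth edges are disallowed: same-time dependence between
#' observed signals can only arise downstream, from latent drivers or from
#' aggregation in the observation map.
#'
#' @param nodes character vector of process identifiers.
#' @param edges data.frame with columns `src`, `dst`, `lag` (positive
#'   integers). Self-edges (autocausal links) are allowed and expected.
#' @param latent character vector, subset of `nodes`, flagged unobserved.
#' @return an object of class `process_graph`.
#' @export
#' @examples
#' g <- process_graph(c("X", "Y"),
#'                    edge_lags(src = c("Y", "X", "Y"),
#'                              dst = c("X", "X", "Y"), lag = 1))
#' unroll(g, 3)
process_graph <- function(nodes, edges = edge_lags(), latent = character(0)) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("invalid-argument: duplicated process ids")
  edges <- edge_lags(edges$src, edges$dst, edges$lag)
  stopifnot_nodes(c(edges$src, edges$dst), nodes, "process")
  stopifnot_nodes(latent, nodes, "latent process")
  if (nrow(edges) && any(edges$lag < 1L)) {
    stop("invalid-argument: process-graph edge lags must be >= 1")
  }
  key <- paste(edges$src, edges$dst, edges$lag)
  if (anyDuplicated(key)) stop("invalid-argument: duplicated lagged edge")
  structure(list(nodes = nodes, edges = edges,
                 latent = as.character(latent)),
            class = "process_graph")
}

#' Build the lagged edge table of a process graph
#'
#' @param src,dst character vectors of process identifiers.
#' @param lag integer vector of positive lags (recycled).
#' @return data.frame with columns `src`, `dst`, `lag`.
#' @export
edge_lags <- function(src = character(0), dst = character(0), lag = integer(0)) {
  n <- max(length(src), length(dst))
  edge_frame(src, dst, lag = as.integer(rep_len(lag, n)))
}

#' Time-unrolled causal structure
#'
#' The microscopic representation of a dynamic system: a directed acyclic
#' graph whose nodes are (process, time-index) pairs named `"<process>@<t>"`.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `src`, `dst`.
#' @param check logical; verify acyclicity (default `TRUE`).
#' @return an object of class `causal_structure`.
#' @export
causal_structure <- function(nodes, edges = edge_frame(), check = TRUE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("invalid-argument: duplicated nodes")
  edges <- edge_frame(edges$src, edges$dst)
  stopifnot_nodes(c(edges$src, edges$dst), nodes)
  if (nrow(edges) && any(edges$src == edges$dst)) {
    stop("invalid-argument: self-loops are not allowed in a causal structure")
  }
  if (anyDuplicated(paste(edges$src, edges$dst))) {
    stop("invalid-argument: duplicated edge")
  }
  if (check && !is_acyclic_edges(nodes, edges)) {
    stop("invalid-argument: causal structure must be acyclic")
  }
  edges$type <- rep("directed", nrow(edges))
  structure(list(nodes = nodes, edges = edges), class = "causal_structure")
}

new_typed_graph <- function(nodes, edges, allowed, class) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("invalid-argument: duplicated nodes")
  edges <- edge_frame(edges$src, edges$dst, type = as.character(edges$type))
  stopifnot_nodes(c(edges$src, edges$dst), nodes)
  bad <- setdiff(edges$type, allowed)
  if (length(bad)) {
    stop(sprintf("invalid-argument: edge type(s) %s not allowed for %s",
                 paste(bad, collapse = ", "), class))
  }
  if (anyDuplicated(pair_key(edges$src, edges$dst))) {
    stop("invalid-argument: at most one edge per node pair")
  }
  structure(list(nodes = nodes, edges = edges), class = class)
}

#' Partially directed pattern (IC algorithm output)
#'
#' Represents a Markov equivalence class of DAGs: directed edges are shared by
#' every member, undirected edges are reversible.  The directed part must be
#' acyclic.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `src`, `dst`, `type`
#'   (`"directed"` or `"undirected"`).
#' @return an object of class `pattern`.
#' @export
pattern <- function(nodes, edges = edge_frame(type = character(0))) {
  g <- new_typed_graph(nodes, edges, c("directed", "undirected"), "pattern")
  dir <- g$edges[g$edges$type == "directed", , drop = FALSE]
  if (!is_acyclic_edges(g$nodes, dir)) {
    stop("invalid-argument: directed part of a pattern must be acyclic")
  }
  g
}

#' Hybrid embedded pattern (IC* algorithm output)
#'
#' A hybrid acyclic graph over observed variables whose edge alphabet encodes
#' what can be concluded in the presence of latent variables: `undirected`
#' (link yet to be resolved), `potential` (dashed arrow: a direct cause or a
#' latent common driver), `genuine` (solid arrow: certain causal connection)
#' and `bidirectional` (certain latent common driver).  The hierarchy is
#' undirected > potential > {genuine, bidirectional}.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame with columns `src`, `dst`, `type`.
#' @return an object of class `embedded_pattern`.
#' @export
embedded_pattern <- function(nodes, edges = edge_frame(type = character(0))) {
  g <- new_typed_graph(nodes, edges,
                       c("undirected", "potential", "genuine", "bidirectional"),
                       "embedded_pattern")
  dir <- g$edges[g$edges$type %in% c("potential", "genuine"), , drop = FALSE]
  if (!is_acyclic_edges(g$nodes, dir)) {
    stop("invalid-argument: no directed cycle through arrowheads is allowed")
  }
  g
}

#' Macroscopic mixed graph over processes (ICG* algorithm output)
#'
#' One node per process; a directed edge marks Granger causality that no
#' conditioning set cancels, a bidirectional edge marks instantaneous
#' causality that no conditioning set cancels, i.e. at least one latent
#' common driver.  A pair carrying a bidirectional edge carries no directed
#' edge (the algorithm's later steps skip such pairs).
#'
#' @param nodes character vector of process names.
#' @param edges data.frame with columns `src`, `dst`, `type`
#'   (`"directed"` or `"bidirectional"`).
#' @param instantaneous optional data.frame (`src`, `dst`) of unresolved
#'   instantaneous-dependence annotations for summaries.
#' @return an object of class `mixed_macro_graph`.
#' @export
mixed_macro_graph <- function(nodes, edges = edge_frame(type = character(0)),
                              instantaneous = NULL) {
  nodes <- as.character(nodes)
  edges <- edge_frame(edges$src, edges$dst, type = as.character(edges$type))
  stopifnot_nodes(c(edges$src, edges$dst), nodes)
  bad <- setdiff(edges$type, c("directed", "bidirectional"))
  if (length(bad)) {
    stop("invalid-argument: mixed macro graphs allow directed/bidirectional edges")
  }
  # at most one record per unordered pair and type; directed pairs may carry
  # both orientations, but never alongside a bidirectional edge
  key <- pair_key(edges$src, edges$dst)
  if (anyDuplicated(paste(key, edges$type, edges$src))) {
    stop("invalid-argument: duplicated edge record")
  }
  bidi <- unique(key[edges$type == "bidirectional"])
  if (any(key[edges$type == "directed"] %in% bidi)) {
    stop("invalid-argument: directed and bidirectional edges cannot share a pair")
  }
  g <- structure(list(nodes = nodes, edges = edges), class = "mixed_macro_graph")
  if (!is.null(instantaneous)) g$instantaneous <- instantaneous
  g
}

graph_nodes <- function(g) g$nodes
graph_edges <- function(g) g$edges

#' @export
print.process_graph <- function(x, ...) {
  cat(sprintf("Process graph: %d processes, %d lagged edges",
              length(x$nodes), nrow(x$edges)))
  if (length(x$latent)) cat(sprintf(", latent: %s", paste(x$latent, collapse = ", ")))
  cat("\n")
  if (nrow(x$edges)) {
    cat(paste(sprintf("  %s -> %s (lag %d)", x$edges$src, x$edges$dst,
                      x$edges$lag), collapse = "\n"), "\n")
  }
  invisible(x)
}

format_typed_edge <- function(e) {
  glyph <- c(directed = "->", undirected = "--", potential = "..>",
             genuine = "=>", bidirectional = "<->")
  sprintf("  %s %s %s", e$src, glyph[e$type], e$dst)
}

print_typed <- function(x, label) {
  cat(sprintf("%s: %d nodes, %d edges\n", label, length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) cat(paste(format_typed_edge(x$edges), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.causal_structure <- function(x, ...) print_typed(x, "Causal structure")

#' @export
print.pattern <- function(x, ...) print_typed(x, "Pattern")

#' @export
print.embedded_pattern <- function(x, ...) print_typed(x, "Embedded pattern")

#' @export
print.mixed_macro_graph <- function(x, ...) print_typed(x, "Mixed macroscopic graph")
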