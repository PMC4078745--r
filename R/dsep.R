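# d-separation on directed and hybrid graphs.
#
# Every edge is reduced to a pair of endpoint marks (tail/head):
#   directed, potential, genuine : tail at src, head at dst
#   undirected                   : tail at both ends
#   bidirectional                : head at both ends
# A collider on a path is a node receiving head marks from both path
# neighbours, whatever the edge styles; undirected and dashed tails never
# contribute an arrowhead.  The separation test is a memoized reachability
# walk over (node, arrival-mark) states, equivalent to enumerating all paths
# (the explicit enumerator is kept as a small-instance oracle in the tests).

edge_marks <- function(g) {
  e <- graph_edges(g)
  type <- e$type %||% rep("directed", nrow(e))
  msrc <- ifelse(type == "bidirectional", "head", "tail")
  mdst <- ifelse(type == "undirected", "tail", "head")
  data.frame(src = e$src, dst = e$dst, msrc = msrc, mdst = mdst,
             stringsAsFactors = FALSE)
}

# Ancestors of S via arrow-following edges (tail at source, head at target),
# S included.  Used for the collider-opening clause.
mark_ancestors <- function(marks, S) {
  dir <- marks[marks$msrc == "tail" & marks$mdst == "head", , drop = FALSE]
  par_by <- split(dir$src, dir$dst)
  seen <- unique(S)
  queue <- seen
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (p in par_by[[v]] %||% character(0)) {
      if (!(p %in% seen)) { seen <- c(seen, p); queue <- c(queue, p) }
    }
  }
  seen
}

# Core reachability.  a, b, S: character vectors of node names.
# start_head_only: the first edge of the path must carry a head mark at its
# a-side endpoint; end_head_only: only arrivals at b through a head mark
# count as active paths.  Returns TRUE iff a and b are separated by S.
#
# Undirected edges are handled at the level of sections (maximal undirected
# runs of a path): a section entered by arrowheads at both ends is a
# collider -- open only if it touches S or an ancestor of S -- while any
# section with a tail end is a non-collider, blocked as soon as it contains
# a conditioning node.  For runs of length one this is the textbook collider
# definition; the section view is what makes the reading of patterns (whose
# undirected edges stand for either orientation) agree with every member of
# the equivalence class.  Traversal state per node: the mark the current
# section was entered with, plus, for head-entered sections, whether the
# section so far touches S / an ancestor of S.
dsep_reach <- function(g, a, b, S, start_head_only = FALSE,
                       end_head_only = FALSE) {
  nodes <- graph_nodes(g)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  S <- unique(as.character(S))
  stopifnot_nodes(c(a, b, S), nodes)
  if (!length(a) || !length(b)) stop("invalid-argument: empty endpoint set")
  if (length(intersect(a, b))) stop("invalid-argument: endpoint sets overlap")
  if (length(intersect(c(a, b), S))) {
    stop("invalid-argument: endpoints may not appear in the conditioning set")
  }
  marks <- edge_marks(g)
  if (!nrow(marks)) return(TRUE)
  und <- marks$msrc == "tail" & marks$mdst == "tail"
  anS <- mark_ancestors(marks, S)
  inc <- split(seq_len(nrow(marks)), factor(marks$src, levels = nodes))
  inc2 <- split(seq_len(nrow(marks)), factor(marks$dst, levels = nodes))
  incident <- lapply(nodes, function(v) c(inc[[v]], inc2[[v]]))
  names(incident) <- nodes

  other_end <- function(i, v) if (marks$src[i] == v) marks$dst[i] else marks$src[i]
  mark_at <- function(i, v) if (marks$src[i] == v) marks$msrc[i] else marks$mdst[i]

  # states: entry mark "tail", or head-entered section flags
  # "head00" (no S, no an(S) touched), "head01" (an(S)), "head11" (S, an(S))
  states <- c("tail", "head00", "head01", "head11")
  seen <- matrix(FALSE, nrow = length(nodes), ncol = length(states),
                 dimnames = list(nodes, states))
  queue_v <- character(0); queue_m <- character(0)
  push <- function(v, m) {
    if (!seen[v, m]) {
      seen[v, m] <<- TRUE
      queue_v <<- c(queue_v, v); queue_m <<- c(queue_m, m)
    }
  }
  head_state <- function(w, tS, tA) {
    tS <- tS || (w %in% S)
    tA <- tA || (w %in% anS)
    if (tS) "head11" else if (tA) "head01" else "head00"
  }
  # state at w after traversing edge i out of a section/state at v
  arrive <- function(i, w, from_head_section, tS, tA) {
    if (und[i]) {
      if (from_head_section) head_state(w, tS, tA) else "tail"
    } else if (mark_at(i, w) == "head") head_state(w, FALSE, FALSE)
    else "tail"
  }
  for (v0 in a) {
    for (i in incident[[v0]]) {
      if (start_head_only && mark_at(i, v0) != "head") next
      w <- other_end(i, v0)
      if (w %in% b) {
        mw <- mark_at(i, w)
        if (!end_head_only || mw == "head") return(FALSE)
        next
      }
      if (w %in% a) next
      push(w, arrive(i, w, FALSE, FALSE, FALSE))
    }
  }

  while (length(queue_v)) {
    v <- queue_v[[1L]]; m_in <- queue_m[[1L]]
    queue_v <- queue_v[-1L]; queue_m <- queue_m[-1L]
    in_head <- m_in != "tail"
    tS <- m_in == "head11"
    tA <- m_in %in% c("head01", "head11")
    for (i in incident[[v]]) {
      m_out <- mark_at(i, v)
      if (und[i]) {
        # stay within (or enter the continuation of) an undirected section
        ok <- if (in_head) TRUE else !(v %in% S)
      } else if (in_head) {
        # leaving a head-entered section
        ok <- if (m_out == "head") tA else !tS
      } else {
        # ordinary non-collider passage
        ok <- !(v %in% S)
      }
      if (!ok) next
      w <- other_end(i, v)
      if (w %in% b) {
        if (und[i]) {
          if (!end_head_only && !(in_head && tS)) return(FALSE)
        } else {
          if (!end_head_only || mark_at(i, w) == "head") return(FALSE)
        }
        next
      }
      if (w %in% a) next
      push(w, arrive(i, w, in_head && und[i], tS, tA))
    }
  }
  TRUE
}

#' d-separation
#'
#' Decides whether every path between `a` and `b` is blocked by `S`: a path
#' is blocked if it contains a non-collider that belongs to `S`, or a
#' collider that neither belongs to `S` nor is an ancestor of a node in `S`.
#' Works on causal structures, patterns, embedded patterns and mixed
#' macroscopic graphs; on hybrid graphs a collider is any pair of
#' head-to-head arrowheads of whatever edge style, and undirected or dashed
#' tails count as non-collider ends.  Head-to-head meetings are judged at the
#' level of undirected sections (maximal undirected runs of a path): a
#' section entered by arrowheads at both ends is a collider, which is what
#' makes the reading of a pattern -- whose undirected edges stand for either
#' orientation -- agree with every member of its equivalence class.  In a
#' compatible model, separation implies conditional independence; under
#' stability (faithfulness) the implication becomes an equivalence.
#'
#' @param g a graph object.
#' @param a,b node names (sets allowed; the query is whether every `a` node
#'   is separated from every `b` node).
#' @param S conditioning node set (default empty), disjoint from `a`, `b`.
#' @return logical.
#' @export
#' @examples
#' chain <- causal_structure(c("X", "Z", "Y"),
#'                           edge_frame(c("X", "Z"), c("Z", "Y")))
#' d_separated(chain, "X", "Y", "Z")
d_separated <- function(g, a, b, S = character(0)) {
  dsep_reach(g, a, b, S)
}

#' d-separation by ancestral pruning
#'
#' The graphical-manipulation procedure for checking all paths at once on a
#' DAG: (1) keep only the ancestors of `a`, `b` and `S`; (2) delete every
#' edge coming out of a node in `S`; (3) `a` and `b` are separated iff no
#' path connects them in what remains, ignoring edge directions.
#'
#' @inheritParams d_separated
#' @return logical.
#' @export
d_separated_pruned <- function(g, a, b, S = character(0)) {
  if (!inherits(g, "causal_structure")) {
    stop("invalid-argument: the pruning procedure is defined for DAGs only")
  }
  nodes <- graph_nodes(g)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  S <- unique(as.character(S))
  stopifnot_nodes(c(a, b, S), nodes)
  if (length(intersect(c(a, b), S)) || length(intersect(a, b))) {
    stop("invalid-argument: endpoints must be disjoint from each other and S")
  }
  keep <- ancestors(g, c(a, b, S))
  e <- graph_edges(g)
  e <- e[e$src %in% keep & e$dst %in% keep, , drop = FALSE]
  e <- e[!(e$src %in% S), , drop = FALSE]
  # undirected connectivity from a
  nb <- split(c(e$dst, e$src), c(e$src, e$dst))
  seen <- a
  queue <- a
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in nb[[v]] %||% character(0)) {
      if (w %in% b) return(FALSE)
      if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
    }
  }
  TRUE
}

#' Graphical sufficient condition for Granger non-causality
#'
#' On a macroscopic mixed graph, if `X` is d-separated from `Y` by `S` on
#' every path that ends with an arrowhead pointing at `Y`, then the transfer
#' entropy from `X` to `Y` given `S` vanishes in every compatible model
#' (an equivalence under stability).
#'
#' @param g a [mixed_macro_graph()].
#' @param X,Y process names.
#' @param S conditioning process set.
#' @return logical: `TRUE` means the graph certifies `T_{X->Y|S} = 0`.
#' @export
granger_noncausal_graphical <- function(g, X, Y, S = character(0)) {
  dsep_reach(g, X, Y, S, end_head_only = TRUE)
}

#' Graphical sufficient condition for instantaneous non-causality
#'
#' As [granger_noncausal_graphical()], but only paths carrying an arrowhead
#' at both ends matter: if all of them are blocked by `S`, the instantaneous
#' causality between `X` and `Y` given `S` vanishes.  Paths with arrowheads
#' at both ends are precisely the signature of latent common drivers.
#'
#' @inheritParams granger_noncausal_graphical
#' @return logical: `TRUE` means the graph certifies `T_{X.Y|S} = 0`.
#' @export
instantaneous_noncausal_graphical <- function(g, X, Y, S = character(0)) {
  dsep_reach(g, X, Y, S, start_head_only = TRUE, end_head_only = TRUE)
}
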