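# Structure-learning algorithms: IC, IC*, the temporal simplification of IC
# for dynamic processes, and ICG* for processes with latent drivers.
#
# All conditioning-set searches run in increasing cardinality and
# lexicographic order within a cardinality; the first separating set wins.
# This fixes the output deterministically without affecting correctness.

# Step 1 shared by IC and IC*: skeleton plus the witness sets S_ab.
ic_skeleton <- function(oracle, variables, max_cond) {
  variables <- sort(variables)
  sepsets <- list()
  adj <- matrix(FALSE, length(variables), length(variables),
                dimnames = list(variables, variables))
  pairs <- if (length(variables) >= 2L) utils::combn(variables, 2L) else
    matrix(character(0), 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    found <- NULL
    for (S in subsets_in_order(setdiff(variables, c(a, b)), max_cond)) {
      if (oracle$query(a, b, S)) { found <- S; break }
    }
    if (is.null(found)) {
      adj[a, b] <- adj[b, a] <- TRUE
    } else {
      sepsets[[pair_key(a, b)]] <- found
    }
  }
  list(variables = variables, adj = adj, sepsets = sepsets)
}

# v-structure triples (a, c, b): a, b non-adjacent with common neighbour c
# and c outside the witness set S_ab.
ic_colliders <- function(sk) {
  vars <- sk$variables
  out <- list()
  if (length(vars) < 3L) return(out)
  pairs <- utils::combn(vars, 2L)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    if (sk$adj[a, b]) next
    common <- vars[sk$adj[a, ] & sk$adj[b, ]]
    S <- sk$sepsets[[pair_key(a, b)]]
    if (is.null(S)) next   # non-adjacent pairs always carry a witness set
    for (cc in common) {
      if (!(cc %in% S)) out[[length(out) + 1L]] <- c(a, cc, b)
    }
  }
  out
}

#' IC algorithm (inductive causation)
#'
#' Recovers the pattern of the Markov equivalence class compatible with an
#' independence oracle, assuming no latent variables: (1) link two variables
#' iff no conditioning set separates them; (2) orient `a -> c <- b` for every
#' non-adjacent pair whose witness set excludes the common neighbour;
#' (3) orient as many remaining edges as possible subject to creating no new
#' v-structure and no directed cycle (the Meek completion rules R1-R4).
#'
#' @param oracle a `ci_oracle` (see [ci_oracle_graphical()],
#'   [ci_oracle_list()]).
#' @param variables variables to analyse; defaults to `oracle$variables`.
#' @param max_cond cap on the conditioning-set cardinality searched
#'   (default: unrestricted).
#' @return a [pattern()].
#' @export
ic <- function(oracle, variables = oracle$variables, max_cond = Inf) {
  sk <- ic_skeleton(oracle, variables, max_cond)
  vars <- sk$variables
  # orientation matrix: 0 no edge, 1 undirected, 2 oriented tail->head
  g <- matrix(0L, length(vars), length(vars), dimnames = list(vars, vars))
  g[sk$adj] <- 1L
  orient <- function(from, to) {
    if (g[to, from] == 2L) {
      stop(sprintf(paste("inference-error: conflicting orientations for edge",
                         "%s - %s; the oracle is inconsistent with a DAG"),
                   from, to))
    }
    changed <- g[from, to] != 2L || g[to, from] != 0L
    g[from, to] <<- 2L; g[to, from] <<- 0L
    changed
  }
  for (tr in ic_colliders(sk)) {
    orient(tr[1L], tr[2L]); orient(tr[3L], tr[2L])
  }
  # Meek completion
  und <- function() which(g == 1L & t(g) == 1L, arr.ind = TRUE)
  has_dir_path <- function(from, to) {
    seen <- from; queue <- from
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nxt <- vars[g[v, ] == 2L]
      if (to %in% nxt) return(TRUE)
      new <- setdiff(nxt, seen)
      seen <- c(seen, new); queue <- c(queue, new)
    }
    FALSE
  }
  repeat {
    changed <- FALSE
    uu <- und()
    for (k in seq_len(nrow(uu))) {
      i <- vars[uu[k, 1L]]; j <- vars[uu[k, 2L]]
      if (g[i, j] != 1L || g[j, i] != 1L) next
      adj_j <- g[j, ] > 0L | g[, j] > 0L
      # R1: w -> i, w and j non-adjacent  =>  i -> j
      r1 <- any(g[, i] == 2L & !adj_j & vars != j)
      # R2: directed path i -> ... -> j  =>  i -> j
      r2 <- has_dir_path(i, j)
      # R3: i - w1, i - w2, w1 -> j, w2 -> j, w1 and w2 non-adjacent
      w_to_j <- vars[g[, j] == 2L]
      w_und_i <- vars[g[i, ] == 1L & g[, i] == 1L]
      r3 <- FALSE
      cand <- intersect(w_to_j, w_und_i)
      if (length(cand) >= 2L) {
        cmb <- utils::combn(cand, 2L)
        for (q in seq_len(ncol(cmb))) {
          if (g[cmb[1L, q], cmb[2L, q]] == 0L && g[cmb[2L, q], cmb[1L, q]] == 0L) {
            r3 <- TRUE; break
          }
        }
      }
      # R4: i - w, w -> l, l -> j, w and j non-adjacent, i adjacent l
      r4 <- FALSE
      for (w in w_und_i) {
        ls <- vars[g[w, ] == 2L]
        for (l in ls) {
          if (g[l, j] == 2L && g[w, j] == 0L && g[j, w] == 0L &&
              (g[i, l] > 0L || g[l, i] > 0L)) { r4 <- TRUE; break }
        }
        if (r4) break
      }
      if (r1 || r2 || r3 || r4) {
        orient(i, j)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  edges <- edge_frame(type = character(0))
  rows <- list()
  for (i in vars) for (j in vars) {
    if (g[i, j] == 2L) rows[[length(rows) + 1L]] <-
        edge_frame(i, j, type = "directed")
    else if (g[i, j] == 1L && i < j) rows[[length(rows) + 1L]] <-
        edge_frame(i, j, type = "undirected")
  }
  if (length(rows)) edges <- do.call(rbind, rows)
  pattern(vars, edges)
}

#' IC* algorithm (inductive causation with latent variables)
#'
#' Recovers the embedded pattern of the dependency class when latent
#' variables are not excluded.  Steps 1-2 parallel IC except that the
#' collider orientations become dashed arrows (potential causes: a direct
#' cause or a latent common driver); an edge receiving arrowheads at both
#' ends becomes bidirectional (certain common driver).  Two rules are then
#' applied to a fixed point: 3R1 upgrades `c -> b` to a genuine (solid)
#' cause whenever `a` and `b` are non-adjacent with common neighbour `c`,
#' the `a`-`c` link carries an arrowhead into `c` and the `c`-`b` link does
#' not (any alternative would create a new v-structure); 3R2 excludes
#' directed cycles by downgrading a link one step in the hierarchy
#' (bidirectional/genuine to potential, potential to undirected).
#'
#' @inheritParams ic
#' @return an [embedded_pattern()].
#' @export
ic_star <- function(oracle, variables = oracle$variables, max_cond = Inf) {
  sk <- ic_skeleton(oracle, variables, max_cond)
  vars <- sk$variables
  # head[u, v]: edge u - v carries an arrowhead at v; solid[u, v] (symmetric):
  # the link is a genuine (solid) connection oriented towards its head.
  head_ <- matrix(FALSE, length(vars), length(vars), dimnames = list(vars, vars))
  solid <- matrix(FALSE, length(vars), length(vars), dimnames = list(vars, vars))
  adj <- sk$adj
  for (tr in ic_colliders(sk)) {
    head_[tr[1L], tr[2L]] <- TRUE
    head_[tr[3L], tr[2L]] <- TRUE
  }
  arrow_of <- function() which(head_ & !t(head_), arr.ind = TRUE)
  repeat {
    changed <- FALSE
    # 3R1
    pairs <- if (length(vars) >= 2L) utils::combn(vars, 2L) else
      matrix(character(0), 2L)
    for (j in seq_len(ncol(pairs))) {
      for (ab in list(pairs[, j], rev(pairs[, j]))) {
        a <- ab[[1L]]; b <- ab[[2L]]
        if (adj[a, b]) next
        for (cc in vars[adj[a, ] & adj[b, ]]) {
          if (head_[a, cc] && !head_[b, cc] &&
              !(solid[cc, b] && head_[cc, b])) {
            head_[cc, b] <- TRUE
            solid[cc, b] <- TRUE
            changed <- TRUE
          }
        }
      }
    }
    # 3R2: no directed cycle through arrowhead-oriented links
    repeat {
      ar <- arrow_of()
      if (!nrow(ar)) break
      dir_edges <- edge_frame(vars[ar[, 1L]], vars[ar[, 2L]])
      cyc <- find_directed_cycle(vars, dir_edges)
      if (is.null(cyc)) break
      downgraded <- FALSE
      for (q in seq_len(nrow(cyc))) {
        u <- cyc$src[q]; v <- cyc$dst[q]
        if (!solid[u, v]) {           # potential -> undirected
          head_[u, v] <- FALSE
          downgraded <- TRUE; changed <- TRUE
          break
        }
      }
      if (!downgraded) {              # genuine -> potential
        u <- cyc$src[1L]; v <- cyc$dst[1L]
        solid[u, v] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rows <- list()
  pairs <- if (length(vars) >= 2L) utils::combn(vars, 2L) else
    matrix(character(0), 2L)
  for (j in seq_len(ncol(pairs))) {
    u <- pairs[1L, j]; v <- pairs[2L, j]
    if (!adj[u, v]) next
    type <- if (head_[u, v] && head_[v, u]) "bidirectional"
    else if (head_[u, v]) if (solid[u, v]) "genuine" else "potential"
    else if (head_[v, u]) if (solid[v, u]) "genuine" else "potential"
    else "undirected"
    src <- if (head_[v, u] && !head_[u, v]) v else u
    dst <- setdiff(c(u, v), src)
    if (type %in% c("undirected", "bidirectional")) { src <- u; dst <- v }
    rows[[length(rows) + 1L]] <- edge_frame(src, dst, type = type)
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    edge_frame(type = character(0))
  embedded_pattern(vars, edges)
}

# Find one directed cycle (as its edge list) or NULL.
find_directed_cycle <- function(nodes, edges) {
  if (!nrow(edges)) return(NULL)
  out_by <- split(edges$dst, edges$src)
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 active 2 done
  stack_path <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    color[[v]] <<- 1L
    stack_path <<- c(stack_path, v)
    for (w in out_by[[v]] %||% character(0)) {
      if (!is.null(result)) break
      if (color[[w]] == 1L) {
        cyc_nodes <- c(stack_path[which(stack_path == w):length(stack_path)], w)
        result <<- edge_frame(cyc_nodes[-length(cyc_nodes)], cyc_nodes[-1L])
        break
      }
      if (color[[w]] == 0L) visit(w)
    }
    color[[v]] <<- 2L
    stack_path <<- stack_path[-length(stack_path)]
  }
  for (v in nodes) if (color[[v]] == 0L) visit(v)
  result
}

#' Temporal IC for latent-free dynamic processes
#'
#' For dynamic processes without latent variables, temporal precedence makes
#' the IC algorithm collapse to Step 1 with a fixed conditioning set: the
#' lagged link `V_{j,i} -> V_{j',i+d}` exists iff conditioning on the whole
#' observed past except `V_{j,i}` fails to separate the two nodes, and every
#' arrowhead follows from time order.  The reconstruction is a complete DAG,
#' unique within its equivalence class.
#'
#' @param oracle a `ci_oracle` over time-indexed nodes (names
#'   `"<process>@<t>"`), typically `ci_oracle_graphical(unroll(g, window))`.
#' @param processes character vector of process names.
#' @param max_lag largest lag tested.
#' @param window number of time slices used (`>= max_lag + 1`).
#' @return a [causal_structure()] over the window, with the recovered
#'   [process_graph()] in attribute `process_graph`.
#' @export
temporal_ic <- function(oracle, processes, max_lag, window) {
  window <- as.integer(window)
  if (window < max_lag + 1L) {
    stop("invalid-argument: window must be >= max_lag + 1")
  }
  if (length(oracle$latent %||% character(0))) {
    stop("invalid-argument: temporal IC assumes no latent processes")
  }
  top <- window - 1L
  past_nodes <- as.vector(outer(processes, 0:(top - 1L), node_at))
  rows <- list()
  for (d in seq_len(max_lag)) {
    for (src in processes) for (dst in processes) {
      if (d == 0L) next
      src_node <- node_at(src, top - d)
      dst_node <- node_at(dst, top)
      S <- setdiff(past_nodes, src_node)
      if (!oracle$query(src_node, dst_node, S)) {
        rows[[length(rows) + 1L]] <- edge_lags(src, dst, d)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else edge_lags()
  pg <- process_graph(processes, edges)
  s <- unroll(pg, window)
  attr(s, "process_graph") <- pg
  s
}

#' ICG* algorithm (inductive causation with latent variables using Granger
#' causality)
#'
#' Structure learning for dynamic processes at the macroscopic scale, with
#' explicit latent-common-driver detection.  Step 1: link `a <-> b`
#' (bidirectional) iff no conditioning set of observed processes cancels the
#' instantaneous causality between them -- possible only if latent common
#' drivers exist, given that every latent process is autocausal.  Steps 2-3:
#' for the remaining pairs, link `a -> b` iff no conditioning set cancels
#' the Granger causality from `a` to `b`, and likewise for `b -> a`.
#'
#' @param oracle a `granger_oracle` (see [granger_oracle_graphical()],
#'   [granger_oracle_gaussian()]).
#' @param processes processes to analyse; defaults to `oracle$processes`.
#' @param max_cond cap on the conditioning-set cardinality searched.
#' @return a [mixed_macro_graph()].
#' @export
icg_star <- function(oracle, processes = oracle$processes, max_cond = Inf) {
  processes <- sort(processes)
  thr <- oracle$threshold
  rows <- list()
  pairs <- if (length(processes) >= 2L) utils::combn(processes, 2L) else
    matrix(character(0), 2L)
  bidi <- character(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    found <- FALSE
    for (S in subsets_in_order(setdiff(processes, c(a, b)), max_cond)) {
      if (oracle$inst(a, b, S) <= thr) { found <- TRUE; break }
    }
    if (!found) {
      rows[[length(rows) + 1L]] <- edge_frame(a, b, type = "bidirectional")
      bidi <- c(bidi, pair_key(a, b))
    }
  }
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    if (pair_key(a, b) %in% bidi) next
    for (ordered in list(c(a, b), c(b, a))) {
      src <- ordered[[1L]]; dst <- ordered[[2L]]
      found <- FALSE
      for (S in subsets_in_order(setdiff(processes, c(src, dst)), max_cond)) {
        if (oracle$te(src, dst, S) <= thr) { found <- TRUE; break }
      }
      if (!found) rows[[length(rows) + 1L]] <-
          edge_frame(src, dst, type = "directed")
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    edge_frame(type = character(0))
  mixed_macro_graph(processes, edges)
}
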