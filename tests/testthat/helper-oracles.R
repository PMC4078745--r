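# Independent oracles and generators used across the suite.  Everything here
# is deliberately naive (explicit path enumeration, literal definitions,
# brute force) so it can serve as ground truth for the package's optimized
# implementations.

# ---- explicit-path d-separation oracle ------------------------------------
# Enumerates every simple path between a and b and applies the two blocking
# clauses literally: a path is blocked iff it contains a non-collider in S or
# a collider that is neither in S nor an ancestor of a node in S.
dsep_paths_oracle <- function(g, a, b, S = character(0)) {
  e <- dyncausal::edge_frame(g$edges$src, g$edges$dst)
  nodes <- g$nodes
  anS <- S
  repeat {
    more <- unique(e$src[e$dst %in% anS])
    new <- setdiff(more, anS)
    if (!length(new)) break
    anS <- c(anS, new)
  }
  # adjacency with direction flags
  nb <- lapply(nodes, function(v) {
    out <- e$dst[e$src == v]
    inn <- e$src[e$dst == v]
    rbind(
      if (length(out)) data.frame(to = out, arrives_head = FALSE) else NULL,
      if (length(inn)) data.frame(to = inn, arrives_head = TRUE) else NULL)
  })
  names(nb) <- nodes
  # arrives_head: going v -> w, TRUE if the edge points INTO v (w -> v), i.e.
  # the mark at v is a head.  We track, for each interior node, the marks of
  # the two incident path edges.
  found_open <- FALSE
  walk <- function(v, visited, mark_at_v) {
    if (found_open) return()
    steps <- nb[[v]]
    if (is.null(steps)) return()
    for (i in seq_len(nrow(steps))) {
      w <- steps$to[i]
      # mark at v for the departing edge: head iff edge is w -> v
      depart_head <- steps$arrives_head[i]
      if (!is.na(mark_at_v)) {   # v is interior: apply blocking clauses
        collider <- mark_at_v && depart_head
        open <- if (collider) v %in% anS else !(v %in% S)
        if (!open) next
      }
      if (w == b) {
        found_open <<- TRUE
        return()
      }
      if (w %in% visited) next
      mark_at_w <- !depart_head  # head at w iff edge is v -> w
      walk(w, c(visited, w), mark_at_w)
    }
  }
  walk(a, a, NA)
  !found_open
}

# ---- random structures -----------------------------------------------------
random_dag <- function(n, p = 0.35) {
  nodes <- paste0("n", seq_len(n))
  src <- character(0); dst <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) {
      src <- c(src, nodes[i]); dst <- c(dst, nodes[j])
    }
  }
  causal_structure(nodes, edge_frame(src, dst))
}

random_process_graph <- function(n_proc = 3, max_lag = 2, p = 0.4) {
  procs <- paste0("P", seq_len(n_proc))
  src <- character(0); dst <- character(0); lag <- integer(0)
  for (a in procs) {                      # autocausal links always present
    src <- c(src, a); dst <- c(dst, a); lag <- c(lag, 1L)
  }
  for (a in procs) for (b in procs) {
    if (a == b) next
    for (d in seq_len(max_lag)) {
      if (stats::runif(1) < p / max_lag) {
        src <- c(src, a); dst <- c(dst, b); lag <- c(lag, d)
      }
    }
  }
  process_graph(procs, edge_lags(src, dst, lag))
}

# Random stable VAR whose zero pattern matches a process graph (lag-1 part).
# rho_max bounds the spectral radius; tighten it when finite-lag information
# measures must decay below the numerical-zero threshold.
random_var_for_graph <- function(pg, lo = 0.2, hi = 0.6, rho_max = 0.95) {
  n <- length(pg$nodes)
  C <- matrix(0, n, n, dimnames = list(pg$nodes, pg$nodes))
  e1 <- pg$edges[pg$edges$lag == 1L, , drop = FALSE]
  for (i in seq_len(nrow(e1))) {
    C[e1$dst[i], e1$src[i]] <- stats::runif(1, lo, hi) *
      sample(c(-1, 1), 1)
  }
  diag(C)[diag(C) == 0] <- stats::runif(sum(diag(C) == 0), 0.1, 0.4)
  # damp until stable
  while (max(Mod(eigen(C, only.values = TRUE)$values)) >= rho_max) C <- C * 0.8
  var_model(C, names = pg$nodes)
}

# Covered-edge reversal: produces an observationally equivalent DAG.
reverse_covered_edge <- function(s) {
  e <- s$edges
  pa <- function(v) sort(e$src[e$dst == v])
  for (i in sample(seq_len(nrow(e)))) {
    x <- e$src[i]; y <- e$dst[i]
    if (identical(setdiff(pa(y), x), pa(x))) {
      e2 <- e
      e2$src[i] <- y; e2$dst[i] <- x
      return(causal_structure(s$nodes, edge_frame(e2$src, e2$dst)))
    }
  }
  NULL
}

# Complete a pattern by orienting its undirected edges as in the generating
# DAG, then read the v-structures of the completion.
v_structures_of_pattern <- function(p, s) {
  ek <- paste(s$edges$src, s$edges$dst)
  src <- p$edges$src; dst <- p$edges$dst
  for (i in which(p$edges$type == "undirected")) {
    if (!(paste(src[i], dst[i]) %in% ek)) {
      tmp <- src[i]; src[i] <- dst[i]; dst[i] <- tmp
    }
  }
  v_structures(causal_structure(s$nodes, edge_frame(src, dst)))
}

# ---- Monte-Carlo conditional mutual information ---------------------------
# I(A;B|C) = E[ log p(a|b,c) - log p(a|c) ] estimated by sampling from the
# Gaussian and evaluating exact conditional log-densities.
mc_gaussian_cmi <- function(joint, A, B, Cset, nsamp = 20000) {
  idx <- c(A, B, Cset)
  S <- joint[idx, idx, drop = FALSE]
  X <- matrix(stats::rnorm(nsamp * length(idx)), nsamp) %*% chol(S)
  ldnorm <- function(x, S) {
    k <- ncol(S)
    ch <- chol(S)
    z <- x %*% solve(ch)  # whitened via upper-tri inverse (x %*% ch^-1)
    -0.5 * rowSums(z^2) - sum(log(diag(ch))) - 0.5 * k * log(2 * pi)
  }
  ia <- seq_along(A)
  ib <- length(A) + seq_along(B)
  ic <- length(A) + length(B) + seq_along(Cset)
  lp <- function(cols) ldnorm(X[, cols, drop = FALSE],
                              S[cols, cols, drop = FALSE])
  vals <- lp(c(ia, ib, ic)) + lp(ic) - lp(c(ia, ic)) - lp(c(ib, ic))
  if (!length(Cset)) vals <- lp(c(ia, ib)) - lp(ia) - lp(ib)
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(nsamp))
}

# ---- plug-in transfer entropy from data -----------------------------------
# 1/2 log(RSS_restricted / RSS_full) from lagged linear regressions.
plugin_te <- function(series, src, dst, L = 10) {
  n <- nrow(series)
  rows <- (L + 1):n
  y <- series[rows, dst]
  lagblock <- function(sig) {
    sapply(seq_len(L), function(k) series[rows - k, sig])
  }
  Xr <- lagblock(dst)
  Xf <- cbind(Xr, lagblock(src))
  rss <- function(X) sum(stats::lm.fit(cbind(1, X), y)$residuals^2)
  0.5 * log(rss(Xr) / rss(Xf))
}

# All conditional-independence statements readable from a DAG by d-separation
# (exhaustive over pairs and conditioning subsets).
all_ci_statements <- function(s) {
  nodes <- sort(s$nodes)
  out <- list()
  prs <- utils::combn(nodes, 2)
  for (j in seq_len(ncol(prs))) {
    a <- prs[1, j]; b <- prs[2, j]
    for (S in dyncausal:::subsets_in_order(setdiff(nodes, c(a, b)))) {
      out[[length(out) + 1]] <- list(a = a, b = b, S = S,
                                     indep = d_separated(s, a, b, S))
    }
  }
  out
}
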