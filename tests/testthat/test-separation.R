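# d-separation: worked queries, the pruning procedure, hybrid graphs and the
# graphical sufficient conditions for Granger/instantaneous non-causality.

test_that("chain, fork and collider answer the textbook queries", {
  for (name in c("chain", "chain_rev", "fork")) {
    g <- fixture(name)
    expect_true(d_separated(g, "X", "Y", "Z"), label = name)
    expect_false(d_separated(g, "X", "Y"), label = name)
  }
  col <- fixture("collider")
  expect_true(d_separated(col, "X", "Y"))
  expect_false(d_separated(col, "X", "Y", "Z"))
  # conditioning on a collider's descendant also opens the path
  g <- causal_structure(c("X", "Z", "Y", "D"),
                        edge_frame(c("X", "Y", "Z"), c("Z", "Z", "D")))
  expect_false(d_separated(g, "X", "Y", "D"))
  # no path at all
  iso <- causal_structure(c("A", "B", "C"))
  expect_true(d_separated(iso, "A", "B"))
  expect_true(d_separated(iso, "A", "B", "C"))
  expect_error(d_separated(col, "X", "Y", c("X")), "conditioning")
})

test_that("reachability d-separation agrees with explicit path enumeration", {
  set.seed(101)
  for (rep in 1:12) {
    s <- random_dag(sample(4:7, 1), p = 0.4)
    nodes <- s$nodes
    prs <- utils::combn(nodes, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      rest <- setdiff(nodes, c(a, b))
      Ss <- dyncausal:::subsets_in_order(rest)
      if (length(Ss) > 12) Ss <- Ss[sample(length(Ss), 12)]
      for (S in Ss) {
        expect_identical(d_separated(s, a, b, S),
                         dsep_paths_oracle(s, a, b, S),
                         label = sprintf("rep %d: %s _|_ %s | {%s}",
                                         rep, a, b, paste(S, collapse = ",")))
      }
    }
  }
})

test_that("the ancestral pruning procedure matches path-based d-separation", {
  # exhaustive: all DAGs readable as subsets of the complete order on 4 nodes
  nodes <- c("a", "b", "c", "d")
  all_edges <- t(utils::combn(nodes, 2))
  for (mask in 0:(2^nrow(all_edges) - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nrow(all_edges)) - 1)) > 0)
    s <- causal_structure(nodes, edge_frame(all_edges[sel, 1],
                                            all_edges[sel, 2]))
    prs <- utils::combn(nodes, 2)
    for (j in seq_len(ncol(prs))) {
      a <- prs[1, j]; b <- prs[2, j]
      for (S in dyncausal:::subsets_in_order(setdiff(nodes, c(a, b)))) {
        expect_identical(d_separated_pruned(s, a, b, S),
                         d_separated(s, a, b, S))
      }
    }
  }
})

test_that("pruning procedure reads the Granger relations of the
           unidirectional system", {
  s <- unroll(fixture("unidirectional_pair"), 8)
  top <- 7
  past <- 0:(top - 1)
  # reverse direction: X's past is blocked given X's own past
  expect_true(d_separated_pruned(s, node_at("Y", top), node_at("X", past),
                                 node_at("Y", past)))
  # forward direction: Y's past reaches X_{i+1}
  expect_false(d_separated_pruned(s, node_at("X", top), node_at("Y", past),
                                  node_at("X", past)))
  # subordinate signals: the reverse direction becomes dependent
  s7 <- fixture("subordinate_signals")
  t7 <- attr(s7, "window") - 1
  p7 <- 0:(t7 - 1)
  expect_false(d_separated(s7, node_at("Ys", t7), node_at("Xs", p7),
                           node_at("Ys", p7)))
})

test_that("adding an edge never separates a previously connected pair", {
  set.seed(111)
  for (rep in 1:10) {
    s <- random_dag(6, p = 0.3)
    nodes <- s$nodes
    a <- sample(nodes, 1); b <- sample(setdiff(nodes, a), 1)
    S <- sample(setdiff(nodes, c(a, b)), sample(0:2, 1))
    before <- d_separated(s, a, b, S)
    # add one acyclicity-preserving edge (nodes are topologically named)
    free <- which(outer(nodes, nodes, "<"), arr.ind = TRUE)
    have <- paste(s$edges$src, s$edges$dst)
    cand <- free[!(paste(nodes[free[, 1]], nodes[free[, 2]]) %in% have), ,
                 drop = FALSE]
    if (!nrow(cand)) next
    pick <- cand[sample(nrow(cand), 1), ]
    s2 <- causal_structure(nodes, rbind(s$edges[, c("src", "dst")],
                                        edge_frame(nodes[pick[1]],
                                                   nodes[pick[2]])))
    if (!before) expect_false(d_separated(s2, a, b, S))
  }
})

test_that("hybrid-graph colliders use arrowheads of any edge style", {
  # A ..> C <.. B : dashed head-to-head collider
  ep <- embedded_pattern(c("A", "B", "C"),
                         edge_frame(c("A", "B"), c("C", "C"),
                                    type = "potential"))
  expect_true(d_separated(ep, "A", "B"))
  expect_false(d_separated(ep, "A", "B", "C"))
  # undirected edges never contribute an arrowhead: A - C - B is a
  # non-collider path through C
  un <- embedded_pattern(c("A", "B", "C"),
                         edge_frame(c("A", "B"), c("C", "C"),
                                    type = "undirected"))
  expect_false(d_separated(un, "A", "B"))
  expect_true(d_separated(un, "A", "B", "C"))
  # bidirectional into C from both sides: collider
  mm <- mixed_macro_graph(c("A", "B", "C"),
                          edge_frame(c("A", "B"), c("C", "C"),
                                     type = "bidirectional"))
  expect_true(d_separated(mm, "A", "B"))
  expect_false(d_separated(mm, "A", "B", "C"))
})

test_that("graphical Granger non-causality condition on macro graphs", {
  chain <- mixed_macro_graph(c("X", "Y", "Z"),
                             edge_frame(c("X", "Z"), c("Z", "Y"),
                                        type = "directed"))
  expect_true(granger_noncausal_graphical(chain, "X", "Y", "Z"))
  expect_false(granger_noncausal_graphical(chain, "X", "Y"))
  cd <- mixed_macro_graph(c("X", "Y"),
                          edge_frame("X", "Y", type = "bidirectional"))
  expect_false(granger_noncausal_graphical(cd, "X", "Y"))
  # path into Y exists but ends with a tail at Y: X <- Y has no head at Y
  rev <- mixed_macro_graph(c("X", "Y"),
                           edge_frame("Y", "X", type = "directed"))
  expect_true(granger_noncausal_graphical(rev, "X", "Y"))
  expect_false(granger_noncausal_graphical(rev, "Y", "X"))
})

test_that("graphical instantaneous non-causality condition", {
  one <- mixed_macro_graph(c("X", "Y"),
                           edge_frame("X", "Y", type = "directed"))
  expect_true(instantaneous_noncausal_graphical(one, "X", "Y"))
  cd <- mixed_macro_graph(c("X", "Y"),
                          edge_frame("X", "Y", type = "bidirectional"))
  expect_false(instantaneous_noncausal_graphical(cd, "X", "Y"))
  # two directed edges into a common sink never form a path with arrowheads
  # at both endpoints, whatever the conditioning: the innovations of X and Y
  # stay independent even when the collider process Z is conditioned on
  sink <- mixed_macro_graph(c("X", "Y", "Z"),
                            edge_frame(c("X", "Y"), c("Z", "Z"),
                                       type = "directed"))
  expect_true(instantaneous_noncausal_graphical(sink, "X", "Y"))
  expect_true(instantaneous_noncausal_graphical(sink, "X", "Y", "Z"))
  # a fork out of a latent-style double-headed pair is double-headed
  fork <- mixed_macro_graph(c("X", "Y", "Z"),
                            edge_frame(c("X", "Z"), c("Y", "Y"),
                                       type = c("bidirectional", "directed")))
  expect_false(instantaneous_noncausal_graphical(fork, "X", "Y"))
})

test_that("graphical non-causality verdicts are sound for compatible
           Gaussian models", {
  set.seed(121)
  reps <- 0
  while (reps < 30) {
    # random macro DAG over 3 processes + optional latent driver pair
    pg <- random_process_graph(3, max_lag = 1, p = 0.5)
    # moderate spectral radius: finite-lag conditioning only blocks paths
    # through deep history up to a geometrically decaying remainder
    m <- random_var_for_graph(pg, rho_max = 0.5)
    oracle <- granger_oracle_gaussian(m, L = 20)
    # macro graph mirrors the lag-1 edges
    e <- pg$edges[pg$edges$src != pg$edges$dst, ]
    mm <- mixed_macro_graph(pg$nodes,
                            unique(edge_frame(e$src, e$dst,
                                              type = "directed")))
    prs <- utils::combn(pg$nodes, 2)
    for (j in seq_len(ncol(prs))) {
      for (dir in list(prs[, j], rev(prs[, j]))) {
        a <- dir[1]; b <- dir[2]
        for (S in dyncausal:::subsets_in_order(setdiff(pg$nodes, c(a, b)))) {
          if (granger_noncausal_graphical(mm, a, b, S)) {
            expect_lt(oracle$te(a, b, S), 1e-9)
          }
          if (instantaneous_noncausal_graphical(mm, a, b, S)) {
            expect_lt(oracle$inst(a, b, S), 1e-9)
          }
        }
      }
    }
    reps <- reps + 1
  }
})
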