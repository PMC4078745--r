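# Conditional-independence and Granger oracles driving the inference
# algorithms.  Two families:
#   * ci_oracle_*      : query(a, b, S) -> TRUE iff a and b are independent
#                        given S, over variables (nodes).
#   * granger_oracle_* : te(src, dst, S) and inst(a, b, S) -> non-negative
#                        reals over processes, plus a zero threshold.
# Each family has a graphical implementation (answers from d-separation on
# a ground-truth structure) and, for processes, a Gaussian analytic one;
# algorithm outputs must not depend on which is plugged in.  Answers are
# cached keyed by (pair, frozen conditioning set).

oracle_cache <- function() new.env(parent = emptyenv())

cache_key <- function(a, b, S) {
  paste(min(a, b), max(a, b), paste(sort(S), collapse = ","), sep = "|")
}

cached <- function(cache, key, compute) {
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- compute()
  assign(key, val, envir = cache)
  val
}

#' Graphical conditional-independence oracle
#'
#' Answers independence queries over the observed variables of a ground-truth
#' causal structure by d-separation, i.e. assumes the generating model is
#' stable (faithful) so that separation and independence coincide.  Latent
#' nodes take part in paths but are not available for conditioning.
#'
#' @param structure a [causal_structure()].
#' @param observed character vector of queryable nodes; defaults to all
#'   nodes minus the `latent` attribute (if the structure was unrolled from
#'   a process graph with latent processes).
#' @return an object of class `ci_oracle` with elements `query(a, b, S)`,
#'   `variables` and `latent`.
#' @export
ci_oracle_graphical <- function(structure,
                                observed = setdiff(graph_nodes(structure),
                                                   attr(structure, "latent"))) {
  cache <- oracle_cache()
  latent <- setdiff(graph_nodes(structure), observed)
  query <- function(a, b, S = character(0)) {
    stopifnot_nodes(c(a, b, S), observed, "observed node")
    cached(cache, cache_key(a, b, S),
           function() d_separated(structure, a, b, S))
  }
  structure(list(query = query, variables = observed, latent = latent),
            class = "ci_oracle")
}

#' Conditional-independence oracle from an explicit independence list
#'
#' Declares exactly the listed conditional independencies (closed under
#' symmetry of the pair) to hold; every other query is dependent.  Useful to
#' encode worked examples such as "exactly X indep Y given Z".
#'
#' @param variables character vector of variable names.
#' @param independencies list of lists/character vectors `(a, b, S)`; `S`
#'   may be omitted for marginal independence.
#' @return a `ci_oracle`.
#' @export
ci_oracle_list <- function(variables, independencies = list()) {
  keys <- vapply(independencies, function(ind) {
    a <- ind[[1L]]; b <- ind[[2L]]
    S <- if (length(ind) >= 3L) as.character(ind[[3L]]) else character(0)
    cache_key(a, b, S)
  }, character(1))
  query <- function(a, b, S = character(0)) {
    stopifnot_nodes(c(a, b, S), variables, "variable")
    cache_key(a, b, S) %in% keys
  }
  structure(list(query = query, variables = variables, latent = character(0)),
            class = "ci_oracle")
}

#' Graphical Granger/instantaneous-causality oracle over processes
#'
#' Answers process-level queries by d-separation on the time-unrolled
#' ground-truth graph: `te(src, dst, S)` asks whether the next value of
#' `dst` is separated from the past `H` lags of `src` given the pasts of
#' `dst` and `S`; `inst(a, b, S)` asks about the two next values given all
#' three pasts.  Returns 0 for separated, 1 otherwise.  The history window
#' `H` is a finite truncation of "the whole past"; the default
#' `3 * n_processes * max_lag` exceeds the longest latent-mediated
#' dependence horizon of the systems studied here.
#'
#' @param g a [process_graph()] (latent processes allowed; they are never
#'   conditioned on).
#' @param H history window in time steps.
#' @return an object of class `granger_oracle` with elements `te`, `inst`,
#'   `threshold`, `processes`.
#' @export
granger_oracle_graphical <- function(g, H = NULL) {
  if (!inherits(g, "process_graph")) stop("invalid-argument: need a process_graph")
  max_lag <- if (nrow(g$edges)) max(g$edges$lag) else 1L
  H <- as.integer(H %||% (3L * length(g$nodes) * max_lag))
  window <- H + 1L
  s <- unroll(g, max(window, max_lag + 1L))
  top <- attr(s, "window") - 1L
  past <- (top - 1L):(top - H)
  past <- past[past >= 0L]
  observed <- setdiff(g$nodes, g$latent)
  cache_te <- oracle_cache(); cache_inst <- oracle_cache()
  te <- function(src, dst, S = character(0)) {
    stopifnot_nodes(c(src, dst, S), observed, "observed process")
    cached(cache_te, paste(src, dst, paste(sort(S), collapse = ","), sep = "|"),
           function() {
             sep <- d_separated(s,
                                a = node_at(dst, top),
                                b = node_at(src, past),
                                S = as.vector(outer(c(dst, S), past, node_at)))
             if (sep) 0 else 1
           })
  }
  inst <- function(a, b, S = character(0)) {
    stopifnot_nodes(c(a, b, S), observed, "observed process")
    cached(cache_inst, cache_key(a, b, S), function() {
      sep <- d_separated(s,
                         a = node_at(a, top),
                         b = node_at(b, top),
                         S = as.vector(outer(c(a, b, S), past, node_at)))
      if (sep) 0 else 1
    })
  }
  structure(list(te = te, inst = inst, threshold = 1e-9,
                 processes = observed, H = H),
            class = "granger_oracle")
}

#' Gaussian analytic Granger/instantaneous-causality oracle
#'
#' Answers process-level queries by exact covariance computation on a
#' Gaussian VAR model seen through an observation map: `te` is
#' [transfer_entropy()] and `inst` is [instantaneous_causality()] at lag
#' depth `L`.  Values at or below `threshold` nats count as zero.
#'
#' @param model a [var_model()].
#' @param obs an [observation_map()]; `NULL` observes the state directly.
#' @param L lag depth (default 20).
#' @param threshold numerical zero in nats (default `1e-9`).
#' @return a `granger_oracle`.
#' @export
granger_oracle_gaussian <- function(model, obs = NULL, L = 20L,
                                    threshold = 1e-9) {
  obs <- obs %||% identity_map(model)
  cache_te <- oracle_cache(); cache_inst <- oracle_cache()
  te <- function(src, dst, S = character(0)) {
    cached(cache_te, paste(src, dst, paste(sort(S), collapse = ","), sep = "|"),
           function() transfer_entropy(model, obs, src, dst, cond = S,
                                       L = L, check = FALSE)$value)
  }
  inst <- function(a, b, S = character(0)) {
    cached(cache_inst, cache_key(a, b, S),
           function() instantaneous_causality(model, obs, a, b, cond = S,
                                              L = L, check = FALSE)$value)
  }
  structure(list(te = te, inst = inst, threshold = threshold,
                 processes = obs$names, L = L),
            class = "granger_oracle")
}
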