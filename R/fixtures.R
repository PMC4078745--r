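# Named ground-truth systems reconstructing the worked examples: chains,
# forks and colliders over {X, Z, Y}, the bivariate coupled and
# common-driver process systems, the unidirectional system and its
# subordinate-signal variant, and the two aggregation studies.  The static
# graph shapes follow the verbal descriptions (chain / fork variants and a
# collider over three variables).

fixture_builders <- list(
  chain = function() {
    causal_structure(c("X", "Z", "Y"), edge_frame(c("Y", "Z"), c("Z", "X")))
  },
  chain_rev = function() {
    causal_structure(c("X", "Z", "Y"), edge_frame(c("X", "Z"), c("Z", "Y")))
  },
  fork = function() {
    causal_structure(c("X", "Z", "Y"), edge_frame(c("Z", "Z"), c("X", "Y")))
  },
  collider = function() {
    causal_structure(c("X", "Z", "Y"), edge_frame(c("X", "Y"), c("Z", "Z")))
  },
  genuine_cause = function() {
    causal_structure(c("A", "B", "X", "Y"),
                     edge_frame(c("A", "B", "X"), c("X", "X", "Y")))
  },
  mutual_coupling = function() {
    process_graph(c("X", "Y"),
                  edge_lags(src = c("X", "Y", "X", "Y"),
                            dst = c("Y", "X", "X", "Y"), lag = 1L))
  },
  common_driver_pair = function() {
    process_graph(c("X", "Y", "a"),
                  edge_lags(src = c("a", "a", "a", "X", "Y"),
                            dst = c("X", "Y", "a", "X", "Y"), lag = 1L),
                  latent = "a")
  },
  unidirectional_pair = function() {
    process_graph(c("X", "Y"),
                  edge_lags(src = c("Y", "X", "Y"),
                            dst = c("X", "X", "Y"), lag = 1L))
  },
  subordinate_signals = function() {
    s <- unroll(fixture_builders$unidirectional_pair(), 13L)
    attach_subordinates(s, list(Xs = "X", Ys = "Y"))
  },
  two_area_system = function() {
    sys <- build_two_area(0.8, 0.3, 0.3, 0.2)
    sys$graph <- two_area_process_graph()
    sys
  },
  integration_areas = function() {
    build_integration_areas(2L)
  }
)

#' Names of the bundled ground-truth fixtures
#'
#' @return character vector of fixture names usable with [fixture()].
#' @export
fixtures <- function() sort(names(fixture_builders))

#' Retrieve a bundled ground-truth fixture
#'
#' Worked-example systems: static three- and four-variable structures
#' (`chain`, `chain_rev`, `fork`, `collider`, `genuine_cause`), bivariate process systems with and without a latent
#' common driver (`mutual_coupling`, `common_driver_pair`), the
#' unidirectional system and its subordinate-signal variant
#' (`unidirectional_pair`, `subordinate_signals`) and the two spatial
#' aggregation setups (`two_area_system`, `integration_areas`).
#'
#' @param name one of [fixtures()].
#' @return a graph object, or a list with `model` / `obs` (and `graph`)
#'   for the VAR systems.
#' @export
fixture <- function(name) {
  b <- fixture_builders[[name]]
  if (is.null(b)) {
    stop(sprintf("invalid-argument: unknown fixture '%s'; see fixtures()", name))
  }
  b()
}

#' VAR models matching the bivariate and latent worked examples
#'
#' Gaussian parameterizations compatible with the process-graph fixtures:
#' `"mutual"` (mutual coupling), `"common_driver"` (latent common driver, observing
#' `X`, `Y`), `"mediator"` (latent chain `X -> a -> Y`, observing `X`, `Y`)
#' and `"unidirectional"` (unidirectional `Y` to `X`, fully observed).
#'
#' @param name one of `"mutual"`, `"common_driver"`, `"mediator"`, `"unidirectional"`.
#' @param coupling coupling strength for the non-self entries (default 0.5;
#'   self couplings 0.5).
#' @return list with `model` and `obs`.
#' @export
fixture_var <- function(name = c("mutual", "common_driver", "mediator", "unidirectional"),
                        coupling = 0.5) {
  name <- match.arg(name)
  k <- coupling
  switch(name,
    mutual = {
      m <- var_model(rbind(c(0.5, 0.3), c(0.3, 0.5)), names = c("X", "Y"))
      list(model = m, obs = identity_map(m))
    },
    common_driver = {
      m <- var_model(rbind(c(0.5, 0, k), c(0, 0.5, k), c(0, 0, 0.5)),
                     names = c("X", "Y", "a"))
      list(model = m,
           obs = observation_map(rbind(c(1, 0, 0), c(0, 1, 0)),
                                 names = c("X", "Y")))
    },
    mediator = {
      m <- var_model(rbind(c(0.5, 0, 0), c(0, 0.5, k), c(k, 0, 0.5)),
                     names = c("X", "Y", "a"))
      list(model = m,
           obs = observation_map(rbind(c(1, 0, 0), c(0, 1, 0)),
                                 names = c("X", "Y")))
    },
    unidirectional = {
      m <- var_model(rbind(c(0.8, k), c(0, 0.8)), names = c("X", "Y"))
      list(model = m, obs = identity_map(m))
    })
}
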