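# Numerical studies of spatial aggregation and of the other observation
# effects (measurement noise, time aggregation) that turn a unidirectional
# interaction into inconsistent positive Granger causality.

#' Two-area spatially aggregated system
#'
#' Four processes, two per area: `X1`, `X2` interact within area X with
#' coefficients `c11, c12, c21, c22`; each drives its paired target
#' (`X1 -> Y1`, `X2 -> Y2`) with coefficient 0.8; the Y processes are
#' autocausal with coefficient 0.8 and not directly connected.  All
#' innovations have unit variance.  The recorded signals are weighted
#' averages, `X = m_x X1 + (1 - m_x) X2` and `Y = m_y Y1 + (1 - m_y) Y2`.
#'
#' @param c11,c12,c21,c22 intra-area coupling coefficients of area X.
#' @param m_x,m_y observation weights in `[0, 1]`.
#' @return list with elements `model` (a [var_model()]) and `obs`
#'   (an [observation_map()] with observed signals `X`, `Y`).
#' @export
build_two_area <- function(c11, c12, c21, c22, m_x = 0.3, m_y = 0.7) {
  C <- rbind(c(c11, c12, 0,   0),
             c(c21, c22, 0,   0),
             c(0.8, 0,   0.8, 0),
             c(0,   0.8, 0,   0.8))
  model <- var_model(C, names = c("X1", "X2", "Y1", "Y2"))
  W <- rbind(X = c(m_x, 1 - m_x, 0, 0),
             Y = c(0, 0, m_y, 1 - m_y))
  list(model = model, obs = observation_map(W))
}

#' Two areas of N processes with intra-areal common drivers
#'
#' Area X holds processes `X1..XN`, all driven by a common driver `Z`
#' (coupling `c_xz`); area Y holds `Y1..YN`, all driven by `W` (coupling
#' `c_yw`).  The inter-areal coupling is pairwise unidirectional
#' `Xk -> Yk` (`c_yx`).  Observed signals are the per-area averages
#' `<X>` and `<Y>`.  Unit-variance innovations.
#'
#' @param N processes per area.
#' @param c_xx,c_xz,c_zz,c_yx,c_yy,c_yw,c_ww coefficients.
#' @return list with `model` and `obs` (observed signals `Xavg`, `Yavg`).
#' @export
build_integration_areas <- function(N, c_xx = 0.8, c_xz = 0.5, c_zz = 0.8, c_yx = 0.8,
                       c_yy = 0.8, c_yw = 0.8, c_ww = 0.8) {
  N <- as.integer(N)
  names <- c(paste0("X", seq_len(N)), "Z", paste0("Y", seq_len(N)), "W")
  n <- 2L * N + 2L
  C <- matrix(0, n, n, dimnames = list(names, names))
  xi <- seq_len(N); zi <- N + 1L; yi <- N + 1L + seq_len(N); wi <- n
  diag(C)[xi] <- c_xx
  C[xi, zi] <- c_xz
  C[zi, zi] <- c_zz
  diag(C)[yi] <- c_yy
  C[cbind(yi, xi)] <- c_yx
  C[yi, wi] <- c_yw
  C[wi, wi] <- c_ww
  model <- var_model(C, names = names)
  W <- matrix(0, 2L, n, dimnames = list(c("Xavg", "Yavg"), names))
  W[1L, xi] <- 1 / N
  W[2L, yi] <- 1 / N
  list(model = model, obs = observation_map(W))
}

#' Relative magnitude of the inconsistent reverse Granger causality
#'
#' `r = T_{Y->X} / T_{X->Y}` over the observed signals of a two-area
#' aggregated system: the true inter-areal interaction runs X to Y, so the
#' numerator is an inconsistent positive induced purely by aggregation.
#'
#' @param model a [var_model()].
#' @param obs an [observation_map()] with observed signals `X`, `Y`.
#' @param L lag depth (default 20).
#' @param zero_tol numerical zero for the denominator (default `1e-9`).
#' @return non-negative real.
#' @export
r_ratio <- function(model, obs, L = 20L, zero_tol = 1e-9) {
  fwd <- transfer_entropy(model, obs, "X", "Y", L = L, check = FALSE)$value
  if (fwd <= zero_tol) {
    stop("undefined-ratio: forward transfer entropy is numerically zero")
  }
  rev <- transfer_entropy(model, obs, "Y", "X", L = L, check = FALSE)$value
  rev / fwd
}

#' Map of r over the intra-areal coupling plane
#'
#' Sweeps `c12`, `c21` of the two-area system over a grid with the other
#' parameters fixed, screens every cell for stationarity (spectral radius
#' below 1 minus the margin), and records `r` for the stable cells.
#' Non-stationary cells are excluded, never assigned a sentinel value.
#'
#' @param c12,c21 grid axes (default `seq(-1, 1, by = 0.05)`).
#' @param c11,c22 fixed self couplings.
#' @param m_x,m_y observation weights.
#' @param L lag depth.
#' @return an object of class `r_grid`: matrix `r` (`c12` by `c21`, `NA`
#'   where excluded), logical matrix `excluded`, axes and parameters.
#' @export
r_map <- function(c12 = seq(-1, 1, by = 0.05), c21 = seq(-1, 1, by = 0.05),
                  c11 = 0.8, c22 = 0.2, m_x = 0.3, m_y = 0.7, L = 20L) {
  r <- matrix(NA_real_, length(c12), length(c21),
              dimnames = list(format(c12), format(c21)))
  excluded <- matrix(FALSE, length(c12), length(c21))
  for (i in seq_along(c12)) for (j in seq_along(c21)) {
    sys <- build_two_area(c11, c12[i], c21[j], c22, m_x, m_y)
    if (!is_stationary(sys$model)) {
      excluded[i, j] <- TRUE
      next
    }
    r[i, j] <- r_ratio(sys$model, sys$obs, L = L)
  }
  structure(list(r = r, excluded = excluded, c12 = c12, c21 = c21,
                 params = list(c11 = c11, c22 = c22, m_x = m_x, m_y = m_y,
                               L = L)),
            class = "r_grid")
}

#' @export
print.r_grid <- function(x, ...) {
  rec <- x$r[!is.na(x$r)]
  cat(sprintf(
    "r grid: %d x %d cells, %d excluded (non-stationary)\n",
    length(x$c12), length(x$c21), sum(x$excluded)))
  if (length(rec)) {
    cat(sprintf("  recorded r: min %.3g, median %.3g, max %.3g\n",
                min(rec), stats::median(rec), max(rec)))
  }
  invisible(x)
}

#' @export
plot.r_grid <- function(x, ...) {
  graphics::image(x$c12, x$c21, log10(x$r), xlab = "c12", ylab = "c21",
                  main = "log10 r = log10 T(Y->X)/T(X->Y)", ...)
  invisible(x)
}

#' Histogram of r over the four-coefficient space
#'
#' Counts stationary configurations of `(c11, c22, c12, c21)` per log-spaced
#' r bin, for each combination of observation weights.  Excluded
#' (non-stationary) cells are counted separately.
#'
#' @param axis grid used for all four coefficients
#'   (default `seq(-1, 1, by = 0.25)`).
#' @param weights list of `c(m_x, m_y)` combinations.
#' @param L lag depth.
#' @param breaks histogram breaks on `log10(r)`.
#' @return an object of class `r_histogram`: `counts` (bins by combos),
#'   `excluded` count, `breaks`, `weights`.
#' @export
r_histogram <- function(axis = seq(-1, 1, by = 0.25),
                        weights = list(c(0.5, 0.5), c(0.3, 0.7),
                                       c(0.7, 0.3), c(0.1, 0.9)),
                        L = 20L,
                        breaks = c(-Inf, seq(-6, 1, by = 0.5), Inf)) {
  combo_names <- vapply(weights, function(w)
    sprintf("mx=%.2f,my=%.2f", w[1L], w[2L]), character(1))
  counts <- matrix(0L, length(breaks) - 1L, length(weights),
                   dimnames = list(NULL, combo_names))
  excluded <- 0L
  grid <- expand.grid(c11 = axis, c22 = axis, c12 = axis, c21 = axis)
  for (row in seq_len(nrow(grid))) {
    p <- grid[row, ]
    base <- build_two_area(p$c11, p$c12, p$c21, p$c22)
    if (!is_stationary(base$model)) {
      excluded <- excluded + 1L
      next
    }
    cs <- stationary_cov(base$model, L)
    for (k in seq_along(weights)) {
      w <- weights[[k]]
      obs <- observation_map(rbind(X = c(w[1L], 1 - w[1L], 0, 0),
                                   Y = c(0, 0, w[2L], 1 - w[2L])))
      gobs <- observed_cov(cs, obs, L)
      joint <- stacked_cov(gobs, L)
      past <- 2:(L + 1L)
      xs <- function(sig, sl) slice_idx(obs, sig, sl)
      fwd <- gaussian_cmi(joint, xs("Y", 1L), xs("X", past),
                          xs("Y", past))
      if (fwd <= 1e-9) next
      rev <- gaussian_cmi(joint, xs("X", 1L), xs("Y", past),
                          xs("X", past))
      bin <- findInterval(log10(max(rev / fwd, 1e-300)), breaks,
                          all.inside = TRUE)
      counts[bin, k] <- counts[bin, k] + 1L
    }
  }
  structure(list(counts = counts, excluded = excluded, breaks = breaks,
                 weights = weights, axis = axis, L = L),
            class = "r_histogram")
}

#' @export
print.r_histogram <- function(x, ...) {
  cat(sprintf("r histogram: %d stationary cells per combo, %d excluded\n",
              sum(x$counts[, 1L]), x$excluded))
  invisible(x)
}

#' Aggregated transfer entropy versus intra-areal integration
#'
#' Computes `T_{<X>-><Y>}` on the per-area averages of the two-area
#' common-driver system as a function of the Y-area integration `c_yw` and
#' the number of processes per area `N`, at fixed X-area integration
#' `c_xz`.  Also reports the source-level pairwise transfer entropy
#' `T_{X1->Y1}` conditioned on all other processes of the fully observed
#' state, which is analytically invariant across the panel.
#'
#' @param N_values integer vector of area sizes.
#' @param c_yw sweep values.
#' @param c_xz fixed X-area integration (default 0.5).
#' @param coef value of the remaining non-zero coefficients (default 0.8).
#' @param L lag depth.
#' @return an object of class `te_profile`: matrices `T` and `pairwise`
#'   (`N` by `c_yw`).
#' @export
te_vs_integration <- function(N_values = 1:6, c_yw = seq(0, 1, by = 0.1),
                              c_xz = 0.5, coef = 0.8, L = 20L) {
  Tm <- matrix(NA_real_, length(N_values), length(c_yw),
               dimnames = list(paste0("N", N_values), format(c_yw)))
  Pm <- Tm
  for (i in seq_along(N_values)) for (j in seq_along(c_yw)) {
    sys <- build_integration_areas(N_values[i], c_xx = coef, c_xz = c_xz, c_zz = coef,
                      c_yx = coef, c_yy = coef, c_yw = c_yw[j], c_ww = coef)
    if (!is_stationary(sys$model)) next
    Tm[i, j] <- transfer_entropy(sys$model, sys$obs, "Xavg", "Yavg",
                                 L = L, check = FALSE)$value
    Pm[i, j] <- transfer_entropy(sys$model, NULL, "X1", "Y1",
                                 cond = setdiff(sys$model$names,
                                                c("X1", "Y1")),
                                 L = L, check = FALSE)$value
  }
  structure(list(T = Tm, pairwise = Pm, N = N_values, c_yw = c_yw,
                 c_xz = c_xz, L = L),
            class = "te_profile")
}

#' Relative change of aggregated Granger causality with coupling strength
#'
#' For each area size `N`, normalizes `T_{<X>-><Y>}(c_yx, N)` by its value
#' at the weakest coupling `c_yx = 0.1` (giving `T'`), then reports the
#' relative deviation of `T'` from the unaggregated `N = 1` profile:
#' `dT'(c_yx, N) = (T'(c_yx, N) - T'(c_yx, 1)) / T'(c_yx, 1)`.
#'
#' @param c_yx sweep values; must contain the reference 0.1.
#' @param N_values integer vector of area sizes; must contain 1.
#' @param c_xz,c_xx fixed coefficients (defaults 1.4 and 0.2).
#' @param coef remaining non-zero coefficients (default 0.8).
#' @param L lag depth.
#' @return an object of class `delta_t_profile`: matrices `T`, `Tprime`,
#'   `delta` (`N` by `c_yx`).
#' @export
delta_t_prime <- function(c_yx = seq(0.1, 1.4, by = 0.1), N_values = 1:6,
                          c_xz = 1.4, c_xx = 0.2, coef = 0.8, L = 20L) {
  if (!any(abs(c_yx - 0.1) < 1e-12)) {
    stop("invalid-argument: the sweep must contain the reference c_yx = 0.1")
  }
  if (!(1L %in% N_values)) {
    stop("invalid-argument: N_values must contain the unaggregated N = 1")
  }
  Tm <- matrix(NA_real_, length(N_values), length(c_yx),
               dimnames = list(paste0("N", N_values), format(c_yx)))
  for (i in seq_along(N_values)) for (j in seq_along(c_yx)) {
    sys <- build_integration_areas(N_values[i], c_xx = c_xx, c_xz = c_xz, c_zz = coef,
                      c_yx = c_yx[j], c_yy = coef, c_yw = coef, c_ww = coef)
    if (!is_stationary(sys$model)) next
    Tm[i, j] <- transfer_entropy(sys$model, sys$obs, "Xavg", "Yavg",
                                 L = L, check = FALSE)$value
  }
  ref_col <- which(abs(c_yx - 0.1) < 1e-12)[1L]
  if (any(Tm[, ref_col] <= 1e-9, na.rm = TRUE)) {
    stop("undefined-ratio: reference transfer entropy is numerically zero")
  }
  Tprime <- Tm / Tm[, ref_col]
  base_row <- which(N_values == 1L)[1L]
  delta <- sweep(Tprime, 2L, Tprime[base_row, ], `-`) /
    matrix(Tprime[base_row, ], nrow(Tprime), ncol(Tprime), byrow = TRUE)
  structure(list(T = Tm, Tprime = Tprime, delta = delta, N = N_values,
                 c_yx = c_yx, L = L),
            class = "delta_t_profile")
}

#' Observation-effect demonstrations: noise, time aggregation, spatial
#' aggregation
#'
#' Builds a unidirectional ground truth (`Y` drives `X`; `X` never drives
#' `Y`) under three observation scenarios and verifies, both analytically
#' (Gaussian transfer entropy) and graphically (d-separation on the unrolled
#' structure including the observation nodes), that the reverse-direction
#' measure becomes an inconsistent positive:
#' \describe{
#'   \item{measurement noise}{`X* = X + eps_x`, `Y* = Y + eps_y`; the true
#'     driver `Y` becomes a latent common driver of its own noisy copy and
#'     of `X`.}
#'   \item{time aggregation}{the driver carries a lag-2 self-coupling
#'     (represented as a VAR(1) by a delay-line component) and both signals
#'     are read every second step; the unsampled instants of `Y` act as
#'     common drivers.  For a purely first-order driver, subsampling is
#'     harmless: its subsampled past is still a Markov state, and the
#'     control rows show the reverse measure staying at zero.}
#'   \item{spatial aggregation}{the two-area system of [build_two_area()]; the
#'     reverse measure between the area averages is positive although every
#'     underlying pair interacts in one direction only.}
#' }
#'
#' @param L lag depth.
#' @return a data.frame of class `table1_report` with one row per scenario
#'   and control: analytic value, the d-separation verdict, and whether the
#'   positive is consistent with the generating structure.
#' @export
table1_demos <- function(L = 20L) {
  rows <- list()
  add <- function(scenario, measure, value, graph_dependent, consistent) {
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = scenario, measure = measure, value = value,
      graph_dependent = graph_dependent, consistent = consistent,
      stringsAsFactors = FALSE)
  }

  # -- measurement noise ----------------------------------------------------
  m <- var_model(rbind(c(0.8, 0.5), c(0, 0.8)), names = c("X", "Y"))
  noisy <- observation_map(diag(2), noise = c(1, 1), names = c("Xs", "Ys"))
  clean <- observation_map(diag(2), names = c("Xs", "Ys"))
  te_rev_noise <- transfer_entropy(m, noisy, "Xs", "Ys", L = L,
                                   check = FALSE)$value
  te_rev_clean <- transfer_entropy(m, clean, "Xs", "Ys", L = L,
                                   check = FALSE)$value
  s_sub <- fixture("subordinate_signals")
  top <- attr(s_sub, "window") - 1L
  past <- 0:(top - 1L)
  dep_noise <- !d_separated(s_sub, node_at("Ys", top), node_at("Xs", past),
                            node_at("Ys", past))
  s_plain <- unroll(fixture("unidirectional_pair"), attr(s_sub, "window"))
  dep_clean <- !d_separated(s_plain, node_at("Y", top), node_at("X", past),
                            node_at("Y", past))
  add("measurement noise", "T(X*->Y*)", te_rev_noise, dep_noise, FALSE)
  add("measurement noise control (no noise)", "T(X->Y)", te_rev_clean,
      dep_clean, TRUE)

  # -- time aggregation -----------------------------------------------------
  # driver with lag-2 memory: Y_{i+1} = 0.4 Y_i + 0.4 Y_{i-1}; delay line Yd
  m2 <- var_model(rbind(c(0.8, 0.5, 0),
                        c(0,   0.4, 0.4),
                        c(0,   1,   0)),
                  names = c("X", "Y", "Yd"))
  sel <- observation_map(rbind(c(1, 0, 0), c(0, 1, 0)), subsample = 2L,
                         names = c("X", "Y"))
  sel1 <- observation_map(rbind(c(1, 0, 0), c(0, 1, 0)), subsample = 1L,
                          names = c("X", "Y"))
  te_rev_sub <- transfer_entropy(m2, sel, "X", "Y", L = L, check = FALSE)$value
  te_rev_full <- transfer_entropy(m2, sel1, "X", "Y", L = L,
                                  check = FALSE)$value
  pg2 <- process_graph(c("X", "Y"),
                       edge_lags(src = c("Y", "X", "Y", "Y"),
                                 dst = c("X", "X", "Y", "Y"),
                                 lag = c(1L, 1L, 1L, 2L)))
  win <- 13L
  s2 <- unroll(pg2, win)
  tt <- win - 1L
  even_past <- seq(tt - 2L, 0L, by = -2L)
  dep_sub <- !d_separated(s2, node_at("Y", tt),
                          node_at("X", even_past),
                          node_at("Y", even_past))
  dep_full <- !d_separated(s2, node_at("Y", tt),
                           node_at("X", 0:(tt - 1L)),
                           node_at("Y", 0:(tt - 1L)))
  add("time aggregation (subsample 2)", "T(X->Y)", te_rev_sub, dep_sub, FALSE)
  add("time aggregation control (full sampling)", "T(X->Y)", te_rev_full,
      dep_full, TRUE)

  # -- spatial aggregation --------------------------------------------------
  sys <- build_two_area(0.8, 0.3, 0.3, 0.2)
  te_rev_agg <- transfer_entropy(sys$model, sys$obs, "Y", "X", L = L,
                                 check = FALSE)$value
  te_pair <- transfer_entropy(
    sys$model,
    observation_map(rbind(c(1, 0, 0, 0), c(0, 0, 1, 0)),
                    names = c("X1", "Y1")),
    "Y1", "X1", L = L, check = FALSE)$value
  s14 <- two_area_aggregated_structure(win)
  dep_agg <- !d_separated(s14, node_at("Xs", win - 1L),
                          node_at("Ys", 0:(win - 2L)),
                          node_at("Xs", 0:(win - 2L)))
  s14_pair <- unroll(two_area_process_graph(), win)
  dep_pair <- !d_separated(s14_pair, node_at("X1", win - 1L),
                           node_at("Y1", 0:(win - 2L)),
                           node_at("X1", 0:(win - 2L)))
  add("spatial aggregation", "T(Y->X)", te_rev_agg, dep_agg, FALSE)
  add("spatial aggregation control (single pair)", "T(Y1->X1)", te_pair,
      dep_pair, TRUE)

  out <- do.call(rbind, rows)
  class(out) <- c("table1_report", class(out))
  out
}

#' @export
print.table1_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$value <- signif(df$value, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

# Macroscopic ground truth of the two-area system (non-zero c12, c21 case).
two_area_process_graph <- function() {
  process_graph(c("X1", "X2", "Y1", "Y2"),
                edge_lags(src = c("X1", "X2", "X1", "X2", "X1", "X2",
                                  "Y1", "Y2"),
                          dst = c("X1", "X2", "X2", "X1", "Y1", "Y2",
                                  "Y1", "Y2"),
                          lag = 1L))
}

# Unrolled two-area ground truth plus same-time aggregated observation nodes
# Xs, Ys (children of both processes of their area).
two_area_aggregated_structure <- function(window) {
  attach_subordinates(unroll(two_area_process_graph(), window),
                      list(Xs = c("X1", "X2"), Ys = c("Y1", "Y2")))
}

#' Attach same-time subordinate observation nodes to an unrolled structure
#'
#' A subordinate signal (noisy copy, aggregate) depends on its sources at
#' the same time index, so it cannot be expressed as a lagged process-graph
#' edge; this helper adds, for every time slice, one node per subordinate
#' with a same-time edge from each of its source processes.
#'
#' @param s a [causal_structure()] produced by [unroll()].
#' @param mapping named list: subordinate name -> character vector of source
#'   process names.
#' @return a [causal_structure()] with the extra nodes and edges; `window`
#'   attribute preserved.
#' @export
attach_subordinates <- function(s, mapping) {
  window <- attr(s, "window")
  if (is.null(window)) stop("invalid-argument: structure lacks a window attribute")
  nodes <- graph_nodes(s)
  edges <- graph_edges(s)[, c("src", "dst")]
  for (sub in names(mapping)) {
    for (t in 0:(window - 1L)) {
      nodes <- c(nodes, node_at(sub, t))
      edges <- rbind(edges,
                     edge_frame(node_at(mapping[[sub]], t),
                                node_at(sub, t)))
    }
  }
  out <- causal_structure(nodes, edges, check = FALSE)
  attr(out, "window") <- window
  attr(out, "latent") <- attr(s, "latent")
  out
}
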