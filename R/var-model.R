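# Linear Gaussian VAR(1) models, observation maps and stationary covariances.
#
# Dynamics: V_{i+1} = C V_i + eps_i with eps ~ N(0, Sigma).  Only order-1
# dynamics are first class; higher-order processes are represented by state
# augmentation (delay-line components), which keeps every covariance formula
# below unchanged.

#' Linear Gaussian VAR(1) model
#'
#' @param C square coefficient matrix; entry `C[j, k]` is the coupling from
#'   signal `k` at time `i` onto signal `j` at time `i + 1`.
#' @param Sigma innovation covariance (symmetric positive definite); default
#'   identity, matching unit-variance innovations.
#' @param names character vector of signal names; defaults to rownames of
#'   `C` or `V1..Vn`.
#' @return an object of class `var_model`.
#' @export
#' @examples
#' m <- var_model(rbind(c(0.8, 0.5), c(0, 0.8)), names = c("X", "Y"))
#' is_stationary(m)
var_model <- function(C, Sigma = NULL, names = NULL) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (ncol(C) != n) stop("invalid-argument: C must be square")
  if (is.null(Sigma)) Sigma <- diag(n)
  Sigma <- as.matrix(Sigma)
  if (!all(dim(Sigma) == n)) stop("invalid-argument: Sigma dimension mismatch")
  if (max(abs(Sigma - t(Sigma))) > 1e-10) {
    stop("invalid-argument: Sigma must be symmetric")
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("invalid-argument: Sigma must be positive definite")
  names <- names %||% rownames(C) %||% paste0("V", seq_len(n))
  if (length(names) != n) stop("invalid-argument: wrong number of names")
  dimnames(C) <- list(names, names)
  dimnames(Sigma) <- list(names, names)
  structure(list(C = C, Sigma = Sigma, n = n, names = names),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("Gaussian VAR(1) model, %d signals (%s); spectral radius %.4f\n",
              x$n, paste(x$names, collapse = ", "), spectral_radius(x$C)))
  invisible(x)
}

spectral_radius <- function(C) max(Mod(eigen(C, only.values = TRUE)$values))

#' Stationarity check
#'
#' A VAR(1) model is stationary iff the spectral radius of its coefficient
#' matrix is below 1; a small margin guards covariance computations against
#' near-unit-root round-off.
#'
#' @param m a [var_model()].
#' @param margin exclusion margin on the spectral radius (default `1e-6`).
#' @return logical.
#' @export
is_stationary <- function(m, margin = 1e-6) {
  spectral_radius(m$C) < 1 - margin
}

#' Stationary lagged autocovariances of a VAR(1) model
#'
#' `Gamma_0` solves the discrete Lyapunov equation
#' `Gamma_0 = C Gamma_0 C' + Sigma` (via the Kronecker-vectorized linear
#' system) and `Gamma_k = C Gamma_{k-1}` for k >= 1, where
#' `Gamma_k = Cov(V_t, V_{t-k})`; `Gamma_{-k} = t(Gamma_k)` by convention.
#'
#' @param m a [var_model()].
#' @param L maximum lag.
#' @return an object of class `cov_sequence`: a list of matrices indexed
#'   `[[k + 1]]` for lags k = 0..L.
#' @export
stationary_cov <- function(m, L) {
  if (!is_stationary(m)) stop("stationarity-error: spectral radius >= 1")
  n <- m$n
  A <- diag(n * n) - kronecker(m$C, m$C)
  g0 <- matrix(solve(A, as.vector(m$Sigma)), n, n)
  g0 <- (g0 + t(g0)) / 2
  dimnames(g0) <- list(m$names, m$names)
  out <- vector("list", L + 1L)
  out[[1L]] <- g0
  if (L >= 1L) for (k in seq_len(L)) out[[k + 1L]] <- m$C %*% out[[k]]
  structure(out, class = "cov_sequence", names = paste0("lag", 0:L))
}

#' Observation map: mixing, additive noise and subsampling
#'
#' Observed signals are `O_t = W V_t + eta_t` read every `subsample`-th time
#' step, with `eta` independent Gaussian observation noise.  The identity map
#' with zero noise and `subsample = 1` observes the latent state directly.
#'
#' @param W mixing matrix, one row per observed signal, one column per
#'   latent signal.
#' @param noise vector of observation-noise variances (length = rows of `W`,
#'   recycled; default 0).
#' @param subsample positive integer sampling period T: observations are
#'   taken at latent times T, 2T, ... (default 1).
#' @param names names of the observed signals.
#' @return an object of class `observation_map`.
#' @export
observation_map <- function(W, noise = 0, subsample = 1L, names = NULL) {
  W <- as.matrix(W)
  m <- nrow(W)
  noise <- rep_len(as.numeric(noise), m)
  if (any(noise < 0)) stop("invalid-argument: noise variances must be >= 0")
  subsample <- as.integer(subsample)
  if (subsample < 1L) stop("invalid-argument: subsample factor must be >= 1")
  names <- names %||% rownames(W) %||% paste0("O", seq_len(m))
  if (length(names) != m) stop("invalid-argument: wrong number of names")
  rownames(W) <- names
  structure(list(W = W, noise = noise, subsample = subsample, m = m,
                 names = names),
            class = "observation_map")
}

#' Identity observation map of a model
#'
#' Observes every latent signal directly, with no noise or subsampling.
#'
#' @param m a [var_model()].
#' @return an [observation_map()].
#' @export
identity_map <- function(m) {
  observation_map(diag(m$n), names = m$names)
}

#' @export
print.observation_map <- function(x, ...) {
  cat(sprintf("Observation map: %d signals (%s), subsample %d%s\n", x$m,
              paste(x$names, collapse = ", "), x$subsample,
              if (any(x$noise > 0)) ", additive noise" else ""))
  invisible(x)
}

#' Lagged autocovariances of the observed signals
#'
#' `Gamma^obs_k = W Gamma_{k T} W' (+ diag(noise) at k = 0)` where T is the
#' subsampling period: the observed process inherits the latent covariances
#' at multiples of T, plus independent observation noise on the diagonal at
#' lag zero only.
#'
#' @param cs a `cov_sequence` from [stationary_cov()], with latent lags up
#'   to at least `L * subsample`.
#' @param om an [observation_map()].
#' @param L maximum observed lag.
#' @return a `cov_sequence` over the observed signals.
#' @export
observed_cov <- function(cs, om, L) {
  Tn <- om$subsample
  if (L * Tn + 1L > length(cs)) {
    stop("invalid-argument: insufficient latent lags for requested L")
  }
  out <- vector("list", L + 1L)
  for (k in 0:L) {
    g <- om$W %*% cs[[k * Tn + 1L]] %*% t(om$W)
    if (k == 0L) {
      g <- g + diag(om$noise, nrow = om$m)
      g <- (g + t(g)) / 2
    }
    dimnames(g) <- list(om$names, om$names)
    out[[k + 1L]] <- g
  }
  structure(out, class = "cov_sequence", names = paste0("lag", 0:L))
}

#' Simulate a VAR(1) model through an observation map
#'
#' Draws a trajectory of the latent state (after a discarded burn-in) and
#' applies the observation map (mixing, noise, subsampling).  Reproducible
#' given `seed`.
#'
#' @param object a [var_model()].
#' @param nsim number of latent time steps to return.
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   current RNG state).
#' @param obs an [observation_map()]; default observes the state directly.
#' @param burn number of initial steps discarded (default 1000).
#' @param ... unused.
#' @return list with matrices `latent` (`nsim` x n) and `observed`
#'   (`floor(nsim / subsample)` x m).
#' @export
simulate.var_model <- function(object, nsim = 1000L, seed = NULL,
                               obs = NULL, burn = 1000L, ...) {
  if (!is_stationary(object)) stop("stationarity-error: model is not stationary")
  if (!is.null(seed)) set.seed(seed)
  obs <- obs %||% identity_map(object)
  n <- object$n
  total <- nsim + burn
  E <- matrix(stats::rnorm(total * n), total, n) %*% chol(object$Sigma)
  V <- matrix(0, total, n)
  Ct <- t(object$C)
  v <- numeric(n)
  for (i in seq_len(total)) {
    v <- drop(v %*% Ct) + E[i, ]
    V[i, ] <- v
  }
  latent <- V[(burn + 1L):total, , drop = FALSE]
  colnames(latent) <- object$names
  idx <- seq(obs$subsample, nsim, by = obs$subsample)
  observed <- latent[idx, , drop = FALSE] %*% t(obs$W)
  if (any(obs$noise > 0)) {
    observed <- observed +
      matrix(stats::rnorm(length(idx) * obs$m), ncol = obs$m) %*%
        diag(sqrt(obs$noise), nrow = obs$m)
  }
  colnames(observed) <- obs$names
  list(latent = latent, observed = observed)
}
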