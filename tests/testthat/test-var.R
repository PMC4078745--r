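# Gaussian VAR machinery: stationarity, covariances, observation maps,
# information measures, simulation.

test_that("stationarity follows the spectral radius", {
  expect_true(is_stationary(var_model(matrix(0, 2, 2))))
  expect_false(is_stationary(var_model(matrix(1.0, 1, 1))))
  expect_true(is_stationary(var_model(matrix(0.99, 1, 1))))
  # simulation blow-up agrees with the analytic verdict
  set.seed(7)
  stable <- var_model(matrix(0.7, 1, 1))
  exploding <- matrix(1.05, 1, 1)
  tr <- simulate(stable, nsim = 2000, seed = 1)$latent
  expect_lt(max(abs(tr)), 50)
  v <- 1
  eps <- stats::rnorm(300)
  for (i in 1:300) v <- 1.05 * v + eps[i]
  expect_gt(abs(v), 1e4)
  expect_false(is_stationary(var_model(exploding)))
})

test_that("stationary covariances solve the Lyapunov recursion", {
  m0 <- var_model(matrix(0, 2, 2))
  cs0 <- stationary_cov(m0, 3)
  expect_equal(cs0[[1]], diag(2), ignore_attr = TRUE)
  expect_equal(cs0[[3]], matrix(0, 2, 2), ignore_attr = TRUE)
  # AR(1) closed form sigma^2 / (1 - c^2)
  ar <- var_model(matrix(0.8, 1, 1))
  cs <- stationary_cov(ar, 4)
  expect_equal(cs[[1]][1, 1], 1 / (1 - 0.64), tolerance = 1e-12)
  expect_equal(cs[[4]][1, 1], 0.8^3 / (1 - 0.64), tolerance = 1e-12)
  expect_error(stationary_cov(var_model(matrix(1.2, 1, 1)), 2),
               "stationarity-error")
  # Lyapunov identity on a random stable model
  set.seed(61)
  pg <- random_process_graph(3)
  m <- random_var_for_graph(pg)
  g <- stationary_cov(m, 2)
  expect_equal(g[[1]], m$C %*% g[[1]] %*% t(m$C) + m$Sigma,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(g[[2]], m$C %*% g[[1]], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("analytic covariances match a long simulation", {
  set.seed(71)
  m <- var_model(rbind(c(0.6, 0.25), c(0.1, 0.5)), names = c("A", "B"))
  g <- stationary_cov(m, 1)
  sim <- simulate(m, nsim = 1e6, seed = 72)$latent
  n <- nrow(sim)
  emp0 <- crossprod(sim) / n
  emp1 <- crossprod(sim[-1, ], sim[-n, ]) / (n - 1)
  # approximate standard error for dependent data; 3 sigma with a safety
  # factor for autocorrelation
  tol <- 10 / sqrt(n)
  expect_lt(max(abs(emp0 - g[[1]])), tol)
  expect_lt(max(abs(emp1 - g[[2]])), tol)
})

test_that("observation maps transform covariances as advertised", {
  ar <- var_model(matrix(0.8, 1, 1))
  cs <- stationary_cov(ar, 8)
  # identity map
  ident <- observation_map(matrix(1, 1, 1))
  expect_equal(observed_cov(cs, ident, 4)[[3]], cs[[3]], ignore_attr = TRUE)
  # sum of two independent AR(1) processes: variances add
  two <- var_model(diag(c(0.5, 0.7)))
  cs2 <- stationary_cov(two, 2)
  summed <- observation_map(matrix(c(1, 1), 1, 2))
  expect_equal(observed_cov(cs2, summed, 0)[[1]][1, 1],
               1 / (1 - 0.25) + 1 / (1 - 0.49), tolerance = 1e-12)
  # subsampling T = 2: observed lag-1 autocovariance is c^2 Gamma_0
  sub2 <- observation_map(matrix(1, 1, 1), subsample = 2)
  oc <- observed_cov(cs, sub2, 4)
  expect_equal(oc[[2]][1, 1], 0.64 / (1 - 0.64), tolerance = 1e-12)
  # additive noise only enters lag 0
  noisy <- observation_map(matrix(1, 1, 1), noise = 2)
  on <- observed_cov(cs, noisy, 2)
  expect_equal(on[[1]][1, 1], 1 / (1 - 0.64) + 2, tolerance = 1e-12)
  expect_equal(on[[2]][1, 1], 0.8 / (1 - 0.64), tolerance = 1e-12)
  expect_error(observed_cov(cs, sub2, 8), "insufficient")
})

test_that("gaussian_cmi reproduces closed forms and a Monte-Carlo estimate", {
  expect_equal(gaussian_cmi(diag(4), 1, 2, 3:4), 0)
  rho <- 0.5
  S <- matrix(c(1, rho, rho, 1), 2)
  expect_equal(gaussian_cmi(S, 1, 2), -0.5 * log(1 - rho^2),
               tolerance = 1e-12)
  set.seed(81)
  A <- matrix(stats::rnorm(25), 5)
  S5 <- crossprod(A) + diag(5)
  got <- gaussian_cmi(S5, 1, 2:3, 4:5)
  mc <- mc_gaussian_cmi(S5, 1, 2:3, 4:5, nsamp = 40000)
  expect_lt(abs(got - mc$mean), 4 * mc$se + 1e-3)
  expect_error(gaussian_cmi(S5, 1, 1, 2), "disjoint")
  sing <- matrix(1, 2, 2)
  expect_error(gaussian_cmi(sing, 1, 2), "ill-conditioned")
})

test_that("transfer entropy reads off coupling structure", {
  dec <- var_model(diag(c(0.6, 0.4)), names = c("X", "Y"))
  expect_equal(transfer_entropy(dec, src = "X", dst = "Y")$value, 0)
  expect_equal(transfer_entropy(dec, src = "Y", dst = "X")$value, 0)
  uni <- fixture_var("unidirectional")
  fwd <- transfer_entropy(uni$model, src = "Y", dst = "X")
  rev <- transfer_entropy(uni$model, src = "X", dst = "Y")
  expect_gt(fwd$value, 0.05)
  expect_lt(rev$value, 1e-12)
  expect_true(fwd$converged)
  expect_true(rev$converged)
  expect_error(transfer_entropy(uni$model, src = "X", dst = "Y",
                                cond = "X"), "cond")
})

test_that("analytic transfer entropy matches a regression plug-in estimate", {
  set.seed(91)
  m <- var_model(rbind(c(0.5, 0.3), c(0.25, 0.4)), names = c("X", "Y"))
  L <- 10
  analytic <- transfer_entropy(m, src = "X", dst = "Y", L = L)$value
  sim <- simulate(m, nsim = 2e5, seed = 92)$latent
  est <- plugin_te(sim, "X", "Y", L = L)
  # estimator sd ~ sqrt(2 * 2L) / (2n) scale; generous absolute band
  expect_lt(abs(analytic - est), 0.01)
  expect_gt(analytic, 0.01)
})

test_that("latent mediators and common drivers have distinct signatures", {
  set.seed(93)
  n_ok <- 0
  for (rep in 1:100) {
    k <- stats::runif(1, 0.25, 0.65)
    a <- stats::runif(1, 0.3, 0.6)
    med <- var_model(rbind(c(a, 0, 0), c(0, a, k), c(k, 0, a)),
                     names = c("X", "Y", "al"))
    cdv <- var_model(rbind(c(a, 0, k), c(0, a, k), c(0, 0, a)),
                     names = c("X", "Y", "al"))
    obsmap <- observation_map(rbind(c(1, 0, 0), c(0, 1, 0)),
                              names = c("X", "Y"))
    expect_lt(instantaneous_causality(med, obsmap, "X", "Y",
                                      check = FALSE)$value, 1e-9)
    expect_gt(transfer_entropy(med, obsmap, "X", "Y", check = FALSE)$value,
              1e-6)
    expect_gt(instantaneous_causality(cdv, obsmap, "X", "Y",
                                      check = FALSE)$value, 1e-6)
    expect_gt(transfer_entropy(cdv, obsmap, "X", "Y", check = FALSE)$value,
              1e-6)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("observation invariance and separation soundness", {
  set.seed(95)
  for (rep in 1:5) {
    pg <- random_process_graph(3, max_lag = 1)
    m <- random_var_for_graph(pg)
    # identity observation changes nothing
    lat <- transfer_entropy(m, NULL, pg$nodes[1], pg$nodes[2],
                            check = FALSE)$value
    thr <- transfer_entropy(m, identity_map(m), pg$nodes[1], pg$nodes[2],
                            check = FALSE)$value
    expect_equal(lat, thr, tolerance = 1e-12)
    # conditioning sets that d-separate in the unrolled truth give ~0
    s <- unroll(pg, 12)
    top <- 11; past <- 0:10
    for (tgt in pg$nodes) {
      others <- setdiff(pg$nodes, tgt)
      src <- others[1]; ctx <- others[-1]
      sep <- d_separated(s, node_at(tgt, top),
                         as.vector(outer(src, past, node_at)),
                         as.vector(outer(c(tgt, ctx), past, node_at)))
      if (sep) {
        expect_lt(transfer_entropy(m, NULL, src, tgt, cond = ctx,
                                   check = FALSE)$value, 1e-9)
      }
    }
  }
})

test_that("lag-depth convergence at L = 20 versus L = 40", {
  set.seed(97)
  for (rep in 1:5) {
    pg <- random_process_graph(3, max_lag = 1)
    m <- random_var_for_graph(pg, rho_max = 0.8)
    a <- pg$nodes[1]; b <- pg$nodes[2]
    t20 <- transfer_entropy(m, NULL, a, b, L = 20, check = FALSE)$value
    t40 <- transfer_entropy(m, NULL, a, b, L = 40, check = FALSE)$value
    expect_lt(abs(t20 - t40), 1e-8)
  }
})

test_that("simulation is reproducible and matches the AR(1) closed form", {
  m <- var_model(matrix(0.8, 1, 1), names = "X")
  s1 <- simulate(m, nsim = 500, seed = 42)
  s2 <- simulate(m, nsim = 500, seed = 42)
  expect_identical(s1, s2)
  big <- simulate(m, nsim = 2e5, seed = 43)$latent
  ac1 <- stats::cor(big[-1], big[-length(big)])
  expect_lt(abs(ac1 - 0.8), 3 * sqrt(1 / length(big)) * 3)
  # white noise: sample covariance near identity
  wn <- simulate(var_model(matrix(0, 2, 2)), nsim = 5e4, seed = 44)$latent
  expect_lt(max(abs(crossprod(wn) / nrow(wn) - diag(2))), 0.03)
  expect_error(simulate(var_model(matrix(1.1, 1, 1)), 10, seed = 1),
               "stationarity-error")
})
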