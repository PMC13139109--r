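test_that("drift_model enforces stability and PSD diffusion", {
  expect_error(drift_model(matrix(0.1, 1, 1), 0, matrix(1, 1, 1), 0),
               "unstable")
  expect_error(drift_model(matrix(-1, 1, 1), 0, matrix(-1, 1, 1), 0),
               "semi-definite")
  m <- drift_model(matrix(-1, 1, 1), 0, matrix(2, 1, 1), 0)
  expect_s3_class(m, "drift_model")
})

test_that("stationary covariance solves the Lyapunov equation", {
  for (seed in 1:5) {
    p <- sample(2:5, 1)
    A <- random_stable_drift(p, seed)
    set.seed(seed + 100)
    G <- matrix(rnorm(p * p), p)
    Q <- crossprod(G)
    S <- stationary_cov(A, Q)
    expect_lt(max(abs(A %*% S + S %*% t(A) + Q)), 1e-10)
    # independent route: vectorized Kronecker solve
    Skron <- matrix(solve(kronecker(diag(p), A) + kronecker(A, diag(p)),
                          -as.numeric(Q)), p, p)
    expect_equal(S, Skron, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("discretization matches the univariate closed form", {
  m <- drift_model(matrix(-1, 1, 1), 0, matrix(2, 1, 1), 0)
  expect_equal(stationary_cov(m)[1, 1], 1) # q / (-2a)
  d <- discretize(m, log(2))
  expect_equal(d$Phi[1, 1], 0.5)
  expect_equal(d$Qdt[1, 1], 0.75) # 1 - 0.25
})

test_that("discretized innovation covariance matches Monte-Carlo increments", {
  A <- random_stable_drift(3, 7)
  Q <- diag(c(1, 2, 0.5))
  m <- drift_model(A, rep(0, 3), Q, 0)
  dt <- 0.8
  d <- discretize(m, dt)
  y <- simulate_ctvar(m, cumsum(rep(dt, 20000)), seed = 3)
  incr <- y[-1, ] - y[-nrow(y), ] %*% t(d$Phi)
  expect_equal(cov(incr), d$Qdt, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("semigroup and identity properties of the propagator hold", {
  for (seed in 1:5) {
    A <- random_stable_drift(4, seed + 20)
    m <- drift_model(A, rep(0, 4), diag(4), 0)
    d0 <- discretize(m, 0)
    expect_equal(d0$Phi, diag(4), tolerance = 1e-12, ignore_attr = TRUE)
    expect_lt(max(abs(d0$Qdt)), 1e-12)
    p1 <- effect_matrix(m, 0.7)
    p2 <- effect_matrix(m, 1.6)
    p12 <- effect_matrix(m, 2.3)
    expect_lt(max(abs(p2 %*% p1 - p12)), 1e-10)
  }
})

test_that("state-space log-likelihood equals the closed-form AR(1) one", {
  set.seed(11)
  n <- 300
  phi <- 0.7
  y <- as.numeric(arima.sim(list(ar = phi), n))
  S <- 1 / (1 - phi^2) # stationary variance of the AR(1)
  a <- log(phi) # per unit gap
  m <- drift_model(matrix(a, 1, 1), 0, matrix(-2 * a * S, 1, 1), 0)
  ll <- ou_loglik(m, list(times = seq_len(n), Y = matrix(y)))
  ll_ar1 <- dnorm(y[1], 0, sqrt(S), log = TRUE) +
    sum(dnorm(y[-1], phi * y[-n], sqrt(S * (1 - phi^2)), log = TRUE))
  expect_equal(ll, ll_ar1, tolerance = 1e-6)
})

test_that("log-likelihood is invariant to node permutation and fully
           missing occasions, and marginalizes missing components", {
  A <- random_stable_drift(3, 31)
  m <- drift_model(A, c(1, 2, 3), diag(c(1, 2, 3)), c(0.5, 0.5, 0.5),
                   nodes = c("a", "b", "c"))
  y <- simulate_ctvar(m, cumsum(runif(60, 0.5, 2)), seed = 5)
  y[7, 2] <- NA
  ts <- attr(y, "times")
  ll <- ou_loglik(m, list(times = ts, Y = y))

  perm <- c(3, 1, 2)
  mp <- drift_model(A[perm, perm], m$mu[perm], m$Q[perm, perm], m$R[perm],
                    nodes = c("c", "a", "b"))
  expect_equal(ou_loglik(mp, list(times = ts, Y = y[, perm])), ll,
               tolerance = 1e-10)

  # inserting a fully missing occasion changes nothing
  y2 <- rbind(y[1:10, ], NA, y[11:nrow(y), ])
  ts2 <- c(ts[1:10], mean(ts[10:11]), ts[11:length(ts)])
  expect_equal(ou_loglik(m, list(times = ts2, Y = y2)), ll,
               tolerance = 1e-8)

  # C++ filter agrees with the plain-R reference filter
  expect_equal(ll, ctnetguide:::ou_loglik_ref(m, list(times = ts, Y = y)),
               tolerance = 1e-8)
})

test_that("log-likelihood is equivariant to affine rescaling", {
  A <- random_stable_drift(2, 77)
  m <- drift_model(A, c(10, 20), diag(c(2, 3)), c(0.3, 0.3))
  y <- simulate_ctvar(m, cumsum(rep(1, 50)), seed = 8)
  ts <- attr(y, "times")
  cc <- 2.5
  d <- c(7, -4)
  m2 <- drift_model(A, cc * m$mu + d, cc^2 * m$Q, cc^2 * m$R)
  ll1 <- ou_loglik(m, list(times = ts, Y = y))
  ll2 <- ou_loglik(m2, list(times = ts, Y = sweep(cc * y, 2, -d)))
  expect_equal(ll2, ll1 - 2 * 50 * log(cc), tolerance = 1e-8)
})

test_that("the generating model beats perturbed models on average", {
  A <- random_stable_drift(2, 5)
  m <- drift_model(A, c(0, 0), diag(2), 0)
  diffs <- vapply(1:20, function(s) {
    y <- simulate_ctvar(m, cumsum(rep(1, 150)), seed = s)
    mp <- m
    mp$A <- A - diag(0.3, 2)
    ou_loglik(m, list(times = attr(y, "times"), Y = y)) -
      ou_loglik(mp, list(times = attr(y, "times"), Y = y))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("simulation respects degenerate and stationary regimes", {
  m <- drift_model(random_stable_drift(2, 9), c(5, 10),
                   matrix(0, 2, 2), 0)
  y <- simulate_ctvar(m, 1:20, seed = 1)
  expect_equal(unname(y), matrix(rep(c(5, 10), each = 20), 20, 2),
               tolerance = 1e-10, ignore_attr = TRUE)

  A <- random_stable_drift(2, 13)
  m2 <- drift_model(A, c(0, 0), diag(c(1, 1.5)), 0)
  y2 <- simulate_ctvar(m2, cumsum(rep(0.5, 20000)), seed = 2)
  S <- stationary_cov(m2)
  expect_equal(cov(y2), S, tolerance = 0.06, ignore_attr = TRUE)
  # lagged covariance Cov(x_{t+dt}, x_t) = Phi(dt) S
  lc <- cov(y2[-1, ], y2[-nrow(y2), ])
  expect_equal(lc, effect_matrix(m2, 0.5) %*% S, tolerance = 0.06,
               ignore_attr = TRUE)
})

test_that("fitting recovers a 2-node model and is deterministic", {
  A <- matrix(c(-0.6, 0.25, 0.1, -0.8), 2, 2)
  m <- drift_model(A, c(50, 40), diag(c(20, 15)), 0)
  ts <- cumsum(rep(1, 400))
  y <- simulate_ctvar(m, ts, seed = 21)
  cfg <- ct_fit_control(r_mode = "zero", reltol = 1e-8)
  f1 <- fit_ctvar(list(times = ts, Y = y), cfg, seed = 3)
  f2 <- fit_ctvar(list(times = ts, Y = y), cfg, seed = 3)
  expect_identical(f1$model$A, f2$model$A) # bit-identical determinism
  expect_true(f1$converged)
  expect_lt(max(abs(f1$model$A - A)), 0.25)
  expect_lt(max(abs(f1$model$mu - m$mu)), 3)

  expect_error(fit_ctvar(list(times = ts,
                              Y = cbind(rep(1, 400), rnorm(400))), cfg),
               "constant")
  expect_error(fit_ctvar(list(times = 1:10, Y = matrix(rnorm(20), 10))),
               "at least 30 occasions")
})

test_that("bootstrap replicates satisfy the stability invariant", {
  A <- matrix(c(-0.7, 0.2, 0, -0.7), 2, 2)
  m <- drift_model(A, c(0, 0), diag(2), 0)
  ts <- cumsum(rep(1, 120))
  y <- simulate_ctvar(m, ts, seed = 4)
  f <- fit_ctvar(list(times = ts, Y = y),
                 ct_fit_control(B = 8, r_mode = "zero", reltol = 1e-6,
                                maxit = 150), seed = 5)
  expect_gt(length(f$boot_A), 0)
  for (Ab in f$boot_A) {
    expect_lt(max(Re(eigen(Ab, only.values = TRUE)$values)), 0)
  }
})
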