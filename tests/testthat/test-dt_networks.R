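make_resid <- function(Z, dt = 3) {
  n <- nrow(Z)
  structure(list(times = seq_len(n) * dt, day = rep(seq_len(ceiling(n / 5)),
                                                    each = 5)[seq_len(n)],
                 Z = Z), class = "dt_residuals")
}

test_that("detrending removes linear trends; normal scores are rank-based", {
  set.seed(1)
  n <- 60
  times <- cumsum(runif(n, 1, 4))
  y <- 5 + 0.8 * times + rnorm(n)
  s <- list(times = times, Y = cbind(a = y, b = exp(rnorm(n))))
  rt <- detrend_and_transform(s)
  # detrending removes the slope (the rank transform can reintroduce only
  # a negligible one)
  expect_lt(abs(coef(lm(rt$Z[, "a"] ~ times))[2]), 0.01)
  # invariance to adding any linear-in-time offset
  s2 <- s
  s2$Y[, "a"] <- s$Y[, "a"] + 100 - 7 * times
  expect_equal(detrend_and_transform(s2)$Z[, "a"], rt$Z[, "a"],
               tolerance = 1e-9)
  # rank-based: the output is exactly the normal scores of the residual
  # ranks, so any positive affine re-expression leaves it unchanged
  res <- stats::residuals(lm(s$Y[, "b"] ~ times))
  expect_equal(rt$Z[, "b"],
               qnorm((rank(res) - 0.5) / n), ignore_attr = TRUE)
  s3 <- s
  s3$Y[, "b"] <- s$Y[, "b"] * 3 + 1
  expect_equal(detrend_and_transform(s3)$Z[, "b"], rt$Z[, "b"],
               tolerance = 1e-9)
  # transformed margins closer to Gaussian than the log-normal input
  z <- rt$Z[, "b"]
  raw <- scale(s$Y[, "b"])
  expect_gt(shapiro.test(z)$statistic, shapiro.test(raw)$statistic)

  # degenerate inputs error
  expect_error(detrend_and_transform(list(times = times,
                                          Y = cbind(c = rep(1, n)))),
               "constant")
  expect_error(detrend_and_transform(list(times = times,
                                          Y = cbind(c = 2 * times))),
               "linear")
})

test_that("partial correlations come from the precision matrix", {
  expect_equal(ctnetguide:::prec_to_pcor(matrix(c(2, -1, -1, 2), 2))[1, 2],
               0.5)
  # population chain X -> Y -> Z: pcor(X, Z | Y) = 0
  set.seed(2)
  n <- 40000
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n)
  z <- 0.8 * y + rnorm(n)
  K <- solve(cov(cbind(x, y, z)))
  expect_lt(abs(ctnetguide:::prec_to_pcor(K)[1, 3]), 0.02)
})

test_that("unpenalized and penalized paths agree as the penalty vanishes", {
  set.seed(3)
  n <- 400
  Z <- matrix(rnorm(n * 3), n, 3)
  Z[, 2] <- Z[, 2] + 0.5 * Z[, 1]
  colnames(Z) <- c("a", "b", "c")
  S <- cov(Z)
  g <- glasso_fit(S, 1e-7)
  expect_lt(max(abs(g$K - solve(S))), 1e-4)
})

test_that("penalized estimation finds exact zeros on independent columns", {
  set.seed(4)
  hits <- 0
  for (r in 1:5) {
    Z <- matrix(rnorm(500 * 4), 500, 4, dimnames = list(NULL, letters[1:4]))
    fit <- fit_dtvar(make_resid(Z), penalized = TRUE)
    off <- fit$contemp$pcor[upper.tri(fit$contemp$pcor)]
    hits <- hits + all(off == 0)
  }
  expect_gte(hits, 4)
})

test_that("temporal estimation uses only same-day pairs and recovers the
           sign pattern of a planted discrete VAR", {
  set.seed(5)
  B <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2) # effect of col j at t-1 on row i
  n <- 1000
  Z <- matrix(0, n, 2)
  for (t in 2:n) Z[t, ] <- B %*% Z[t - 1, ] + rnorm(2, sd = 0.5)
  colnames(Z) <- c("x", "y")
  rt <- make_resid(scale(Z, scale = FALSE))
  fit <- fit_dtvar(rt, penalized = FALSE)
  expect_equal(fit$temporal["x", "x"] > 0.2, TRUE)
  expect_equal(fit$temporal["y", "x"] > 0.1, TRUE)
  expect_lt(abs(fit$temporal["x", "y"]), 0.15)

  # overnight lags excluded: pairs never straddle days
  pairs <- ctnetguide:::same_day_pairs(rt)
  expect_true(all(rt$day[pairs] == rt$day[pairs + 1L]))
  expect_true(length(pairs) < nrow(Z) - 1L)
})

test_that("singular residual covariance suggests the penalized path", {
  Z <- matrix(rnorm(40), 20, 2)
  Z <- cbind(Z, Z[, 1] + Z[, 2]) # exactly collinear
  colnames(Z) <- c("a", "b", "c")
  expect_error(fit_dtvar(make_resid(Z), penalized = FALSE), "penalized")
})

test_that("centrality indices match their definitions and a brute-force
           betweenness oracle", {
  W <- diag(3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[2, 3] <- W[3, 2] <- -0.2
  net <- ctnetguide:::new_contemp_network(
    structure(W, dimnames = list(c("a", "b", "c"), c("a", "b", "c"))),
    penalized = FALSE)
  cent <- dt_centrality(net)
  expect_equal(cent$strength[cent$node == "b"], 0.5)
  expect_equal(cent$expected_influence[cent$node == "b"], 0.1)
  # the middle of a path graph is the unique betweenness maximum
  expect_identical(cent$node[which.max(cent$betweenness)], "b")
  expect_equal(cent$betweenness[cent$node == "a"], 0)
  # closeness = 1 / sum of shortest-path distances
  expect_equal(cent$closeness[cent$node == "b"],
               1 / (1 / 0.3 + 1 / 0.2))

  set.seed(6)
  for (r in 1:8) {
    p <- 5
    W <- matrix(0, p, p)
    ut <- which(upper.tri(W))
    on <- sample(ut, 6)
    W[on] <- runif(6, -0.8, 0.8)
    W <- W + t(W)
    diag(W) <- 1
    dimnames(W) <- list(paste0("n", 1:p), paste0("n", 1:p))
    net <- ctnetguide:::new_contemp_network(W, penalized = TRUE)
    cent <- dt_centrality(net)
    expect_equal(cent$betweenness, oracle_betweenness(W), tolerance = 1e-9)
    expect_true(all(cent$strength >= abs(cent$expected_influence) - 1e-12))
    expect_true(all(cent$betweenness >= 0))
  }
})

test_that("isolated nodes get zero closeness and betweenness", {
  W <- diag(3)
  W[1, 2] <- W[2, 1] <- 0.4
  dimnames(W) <- list(c("a", "b", "c"), c("a", "b", "c"))
  net <- ctnetguide:::new_contemp_network(W, penalized = TRUE)
  cent <- dt_centrality(net)
  expect_equal(cent$closeness[cent$node == "c"], 0)
  expect_equal(cent$betweenness[cent$node == "c"], 0)
  # a/b cannot reach c, so their closeness is 0 under the all-nodes rule
  expect_equal(cent$closeness[cent$node == "a"], 0)
})

test_that("strongest edge to the outcome follows maximal magnitude with a
           deterministic tie-break and a 'none' sentinel", {
  W <- diag(4)
  dimnames(W) <- list(c("a", "b", "c", "out"), c("a", "b", "c", "out"))
  W["out", "a"] <- W["a", "out"] <- 0.1
  W["out", "b"] <- W["b", "out"] <- -0.4
  W["out", "c"] <- W["c", "out"] <- 0.2
  net <- ctnetguide:::new_contemp_network(W, penalized = FALSE)
  expect_identical(strongest_edge_to_outcome(net, "out"), "b")

  W0 <- diag(3)
  dimnames(W0) <- list(c("a", "b", "out"), c("a", "b", "out"))
  net0 <- ctnetguide:::new_contemp_network(W0, penalized = TRUE)
  expect_identical(strongest_edge_to_outcome(net0, "out"), "none")

  # on the synthetic truth, the small-delta lagged path to interference
  # points at the facet with the largest drift entry into the outcome
  truth <- synthetic_truth()
  Phi <- effect_matrix(truth$model, 0.01)
  sel <- strongest_edge_to_outcome(Phi, "interference")
  A <- truth$model$A
  cand <- setdiff(colnames(A), "interference")
  expect_identical(sel, cand[which.max(abs(A["interference", cand]))])
})
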