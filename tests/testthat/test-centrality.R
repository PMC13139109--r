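test_that("effect matrix matches closed forms and the identity at zero", {
  A <- matrix(c(-1, 0.5, 0, -1), 2, 2)
  m <- drift_model(A, c(0, 0), diag(2), 0)
  expect_equal(effect_matrix(m, 0), diag(2), ignore_attr = TRUE)
  # lower-triangular nilpotent structure: Phi[2,1] = 0.5 * delta * e^-delta
  expect_equal(effect_matrix(m, 1)[2, 1], 0.5 * exp(-1), tolerance = 1e-12)
})

test_that("effect matrix agrees with ODE integration of dPhi/dt = A Phi", {
  skip_if_not_installed("deSolve")
  for (seed in 1:4) {
    p <- 3
    A <- random_stable_drift(p, seed + 50)
    m <- drift_model(A, rep(0, p), diag(p), 0)
    delta <- 2.4
    sol <- deSolve::ode(
      y = as.numeric(diag(p)), times = c(0, delta),
      func = function(t, y, parms) list(as.numeric(A %*% matrix(y, p, p))),
      parms = NULL, method = "ode45", atol = 1e-12, rtol = 1e-12)
    Phi_ode <- matrix(sol[2, -1], p, p)
    expect_lt(max(abs(effect_matrix(m, delta) - Phi_ode)), 1e-8)
  }
})

test_that("TEC matches nilpotent closed forms and vanishes without coupling", {
  # diagonal drift: no cross-effects at any delta
  m0 <- drift_model(diag(c(-1, -2, -0.5)), rep(0, 3), diag(3), 0)
  expect_equal(tec(m0, 1.7)$point, rep(0, 3))

  A <- matrix(c(-1, 0.5, 0, -1), 2, 2)
  m <- drift_model(A, c(0, 0), diag(2), 0, nodes = c("x", "y"))
  tt <- tec(m, 1)
  expect_equal(tt$point[tt$node == "x"], 0.5 * exp(-1), tolerance = 1e-12)
  expect_equal(tt$point[tt$node == "y"], 0)

  # chain 1 -> 2 -> 3 with unit couplings and decay -1:
  # TEC(1) = e^-1 (1 + 1/2), via e^{-d}(b d + bc d^2/2) at d = 1
  A3 <- matrix(0, 3, 3)
  diag(A3) <- -1
  A3[2, 1] <- 1
  A3[3, 2] <- 1
  m3 <- drift_model(A3, rep(0, 3), diag(3), 0)
  expect_equal(tec(m3, 1)$point[1], exp(-1) * 1.5, tolerance = 1e-12)
})

test_that("IEC isolates mediated effects", {
  # any 2-node model has no mediators
  A <- matrix(c(-1, 0.8, -0.3, -1.2), 2, 2)
  m <- drift_model(A, c(0, 0), diag(2), 0)
  expect_equal(iec(m, 1.3)$point, c(0, 0), tolerance = 1e-12)

  A3 <- matrix(0, 3, 3)
  diag(A3) <- -1
  A3[2, 1] <- 1
  A3[3, 2] <- 1
  m3 <- drift_model(A3, rep(0, 3), diag(3), 0)
  v <- iec(m3, 1)$point
  # node 1's only indirect route is 1->2->3: e^-1 / 2; direct A[3,1] = 0
  expect_equal(v[1], exp(-1) / 2, tolerance = 1e-12)
  expect_equal(iec(m0 <- drift_model(diag(c(-1, -1, -1)), rep(0, 3),
                                     diag(3), 0), 1)$point, rep(0, 3))
})

test_that("TEC and IEC are permutation-invariant and TEC dominates IEC
           under nonnegative coupling", {
  A <- random_stable_drift(4, 61)
  A[row(A) != col(A)] <- abs(A[row(A) != col(A)]) # nonnegative couplings
  diag(A) <- diag(A) -
    max(0, max(Re(eigen(A, only.values = TRUE)$values))) - 0.1
  m <- drift_model(A, rep(0, 4), diag(4), 0,
                   nodes = c("n1", "n2", "n3", "n4"))
  t1 <- tec(m, 2)
  i1 <- iec(m, 2)
  expect_true(all(t1$point >= i1$point - 1e-12))

  perm <- c(2, 4, 1, 3)
  mp <- drift_model(A[perm, perm], rep(0, 4), diag(4), 0,
                    nodes = m$nodes[perm])
  t2 <- tec(mp, 2)
  expect_equal(t2$point[match(t1$node, t2$node)], t1$point,
               tolerance = 1e-12)
})

test_that("centrality profiles are continuous and hub-dominated", {
  truth <- synthetic_truth()
  deltas <- seq(0.25, 24, length.out = 32)
  prof <- centrality_profile(truth$model, deltas, "TEC",
                             outcome = "interference")
  # the planted hub has maximal TEC at every delta
  for (d in deltas) {
    sub <- prof[prof$delta == d, ]
    expect_identical(sub$node[which.max(sub$point)], truth$planted$hub_facet)
  }
  # TEC -> 0 as delta -> 0+
  tiny <- tec(truth$model, 1e-6, outcome = "interference")
  expect_lt(max(abs(tiny$point)), 1e-4)
  # numeric continuity: successive differences shrink with the grid
  steps <- apply(matrix(prof$point, ncol = length(deltas)), 1,
                 function(v) max(abs(diff(v))))
  fine_deltas <- seq(0.25, 24, length.out = 128)
  proff <- centrality_profile(truth$model, fine_deltas, "TEC",
                              outcome = "interference")
  steps_f <- apply(matrix(proff$point, ncol = length(fine_deltas)), 1,
                   function(v) max(abs(diff(v))))
  expect_true(all(steps_f <= steps + 1e-12))
})

test_that("bootstrap centrality intervals behave like percentiles", {
  A <- matrix(c(-0.8, 0.3, 0.1, -0.9), 2, 2)
  m <- drift_model(A, c(0, 0), diag(2), 0, nodes = c("a", "b"))
  fit <- structure(list(model = m, boot_A = list(A, A, A)),
                   class = "ctvar_fit")
  tab <- centrality_intervals(fit, 1, "TEC")
  expect_equal(tab$lo, tab$hi) # zero-variance replicates
  expect_equal(tab$lo, tab$point, tolerance = 1e-12)

  set.seed(4)
  noisy <- lapply(1:40, function(i) A + matrix(rnorm(4, sd = 0.05), 2))
  noisy <- Filter(function(M) {
    max(Re(eigen(M, only.values = TRUE)$values)) < 0
  }, noisy)
  fit$boot_A <- noisy
  tab2 <- centrality_intervals(fit, 1, "TEC")
  expect_true(all(tab2$lo <= tab2$hi))
  # the median replicate centrality lies inside the 50% interval
  reps <- vapply(noisy, function(M) {
    mm <- m
    dimnames(M) <- dimnames(m$A)
    mm$A <- M
    tec(mm, 1)$point[1]
  }, numeric(1))
  expect_gte(median(reps), tab2$lo[1])
  expect_lte(median(reps), tab2$hi[1])

  # wider replicate noise widens the interval
  noisier <- lapply(1:40, function(i) A + matrix(rnorm(4, sd = 0.15), 2))
  noisier <- Filter(function(M) {
    max(Re(eigen(M, only.values = TRUE)$values)) < 0
  }, noisier)
  fit$boot_A <- noisier
  tab3 <- centrality_intervals(fit, 1, "TEC")
  expect_gt(mean(tab3$hi - tab3$lo), mean(tab2$hi - tab2$lo))

  fit$boot_A <- list()
  expect_error(centrality_intervals(fit, 1), "bootstrap")
})
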