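#' Continuous-time VAR (multivariate Ornstein-Uhlenbeck) model
#'
#' The latent process follows \eqn{dx = A (x - \mu) dt + G\,dW} with
#' diffusion covariance \eqn{Q = GG'}, observed as \eqn{y_t = x_t + e_t},
#' \eqn{e_t \sim N(0, \mathrm{diag}(R))}. The drift entry `A[i, j]` is the
#' instantaneous effect of node j's deviation from its mean on node i's rate
#' of change (units 1/hour); stationarity requires every eigenvalue of `A`
#' to have a strictly negative real part.
#'
#' @param A p x p drift matrix (1/hour).
#' @param mu Stationary means (0-100 scale), length p.
#' @param Q p x p diffusion covariance (scale^2/hour), symmetric PSD.
#' @param R Measurement-noise variances, length p (or scalar), each >= 0.
#' @param nodes Node names; default taken from `A`'s dimnames or V1..Vp.
#' @return A `drift_model` object.
#' @export
drift_model <- function(A, mu, Q, R = 0, nodes = NULL) {
  A <- as.matrix(A)
  p <- nrow(A)
  if (ncol(A) != p) stop("A must be square")
  if (is.null(nodes)) nodes <- rownames(A)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  if (length(nodes) != p) stop("need ", p, " node names")
  if (length(mu) != p) stop("mu must have length ", p)
  Q <- as.matrix(Q)
  if (!isTRUE(all.equal(Q, t(Q), tolerance = 1e-8))) {
    stop("Q must be symmetric")
  }
  Q <- (Q + t(Q)) / 2
  if (min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("Q must be positive semi-definite")
  }
  if (length(R) == 1L) R <- rep(R, p)
  if (length(R) != p || any(R < 0)) stop("R must be ", p, " variances >= 0")
  ev <- max(Re(eigen(A, only.values = TRUE)$values))
  if (ev >= 0) {
    stop("drift matrix is unstable (max Re eigenvalue = ",
         signif(ev, 4), "); all eigenvalues need negative real part")
  }
  dimnames(A) <- list(nodes, nodes)
  dimnames(Q) <- list(nodes, nodes)
  structure(list(A = A, mu = setNames(as.numeric(mu), nodes),
                 Q = Q, R = setNames(as.numeric(R), nodes), nodes = nodes),
            class = "drift_model")
}

#' @rdname drift_model
#' @param x An object.
#' @export
is_drift_model <- function(x) inherits(x, "drift_model")

#' @export
print.drift_model <- function(x, ...) {
  cat("Continuous-time VAR (OU) model with", length(x$nodes), "nodes:",
      paste(x$nodes, collapse = ", "), "\n")
  cat("Drift matrix (1/hour):\n")
  print(round(x$A, 4))
  invisible(x)
}

#' Stationary covariance of an OU model
#'
#' Solves the Lyapunov equation \eqn{A S + S A' + Q = 0}.
#'
#' @param model A [drift_model()], or a drift matrix if `Q` is given.
#' @param Q Diffusion covariance when `model` is a plain matrix.
#' @return The stationary covariance matrix.
#' @export
stationary_cov <- function(model, Q = NULL) {
  if (is_drift_model(model)) {
    A <- model$A
    Q <- model$Q
  } else {
    A <- as.matrix(model)
  }
  S <- cpp_lyapunov(A, Q)
  dimnames(S) <- dimnames(A)
  S
}

#' Exact discretization of an OU model
#'
#' For a gap of `dt` hours the sampled process is a VAR(1):
#' \eqn{\Phi = e^{A\,dt}} and innovation covariance
#' \eqn{Q_{dt} = S_\infty - \Phi S_\infty \Phi'} with \eqn{S_\infty} the
#' stationary covariance.
#'
#' @param model A [drift_model()].
#' @param dt Gap length in hours, > 0 (0 returns identity / zero).
#' @return List with `Phi` and `Qdt`.
#' @export
discretize <- function(model, dt) {
  stopifnot(is_drift_model(model), dt >= 0)
  Phi <- cpp_expm(model$A * dt)
  S <- stationary_cov(model)
  Qdt <- S - Phi %*% S %*% t(Phi)
  Qdt <- (Qdt + t(Qdt)) / 2
  dimnames(Phi) <- dimnames(model$A)
  dimnames(Qdt) <- dimnames(model$A)
  list(Phi = Phi, Qdt = Qdt)
}

# Coerce an ema/composite series (single participant) or a list(times, Y)
# to the state-space data layout for the given nodes.
as_ou_data <- function(series, nodes) {
  if (is.list(series) && !is.data.frame(series) &&
      all(c("times", "Y") %in% names(series))) {
    Y <- as.matrix(series$Y)
    if (!is.null(colnames(Y))) Y <- Y[, nodes, drop = FALSE]
    return(list(times = as.numeric(series$times), Y = Y))
  }
  if (is_ema_series(series)) {
    w <- ema_wide(series, items = nodes)
    return(list(times = w$times, Y = w$Y))
  }
  stop("series must be an ema_series or a list(times, Y)")
}

#' Exact Gaussian state-space log-likelihood of an OU model
#'
#' Computed by a forward Kalman filter over the actual (possibly irregular)
#' inter-occasion intervals, starting from the stationary distribution.
#' Occasions with missing components are handled by marginalizing the
#' missing coordinates; fully missing occasions contribute nothing.
#'
#' @param model A [drift_model()].
#' @param series A single-participant [ema_series()] /
#'   [build_composites()] output containing the model's nodes as items, or a
#'   list with `times` and matrix `Y` (occasions x nodes, `NA` = missing).
#' @return The log-likelihood (scalar).
#' @export
ou_loglik <- function(model, series) {
  stopifnot(is_drift_model(model))
  d <- as_ou_data(series, model$nodes)
  if (length(d$times) < 2L) stop("need at least two occasions")
  ll <- cpp_ou_loglik(d$times, d$Y, model$A, model$mu, model$Q, model$R)
  if (!is.finite(ll)) {
    stop("log-likelihood is degenerate (non-finite); check that the model ",
         "is stable and Q/R are not singular for the observed pattern")
  }
  ll
}

# Pure-R reference Kalman filter (used as an independent cross-check in the
# test suite; O(n p^3) with no caching).
ou_loglik_ref <- function(model, series) {
  d <- as_ou_data(series, model$nodes)
  times <- d$times
  Y <- d$Y
  p <- length(model$nodes)
  S <- stationary_cov(model)
  z <- rep(0, p)
  P <- S
  ll <- 0
  for (t in seq_along(times)) {
    if (t > 1L) {
      dt <- times[t] - times[t - 1L]
      Phi <- cpp_expm(model$A * dt)
      z <- drop(Phi %*% z)
      P <- Phi %*% P %*% t(Phi) + (S - Phi %*% S %*% t(Phi))
      P <- (P + t(P)) / 2
    }
    obs <- which(!is.na(Y[t, ]))
    if (!length(obs)) next
    v <- Y[t, obs] - model$mu[obs] - z[obs]
    Sv <- P[obs, obs, drop = FALSE] + diag(model$R[obs],
                                           nrow = length(obs))
    ll <- ll + mvn_logdens(v, Sv)
    K <- P[, obs, drop = FALSE] %*% solve(Sv)
    z <- z + drop(K %*% v)
    P <- P - K %*% P[obs, , drop = FALSE]
    P <- (P + t(P)) / 2
  }
  ll
}

mvn_logdens <- function(v, S) {
  L <- chol(S)
  w <- backsolve(L, v, transpose = TRUE)
  -0.5 * (length(v) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(w^2))
}

# ----- parameter packing for ML estimation ---------------------------------

# theta = c(vec(A), mu, log-Cholesky of Q, log sd of R [if estimated])
pack_theta <- function(A, mu, Q, R, r_mode) {
  L <- t(chol(Q + diag(1e-10 * max(diag(Q), 1), nrow(Q))))
  low <- L[lower.tri(L)]
  c(as.numeric(A), mu, log(diag(L)), low,
    if (r_mode == "estimate") log(sqrt(pmax(R, 1e-8))))
}

unpack_theta <- function(theta, p, r_mode, nodes) {
  i <- 0
  A <- matrix(theta[seq_len(p * p)], p, p)
  i <- p * p
  mu <- theta[i + seq_len(p)]
  i <- i + p
  ld <- theta[i + seq_len(p)]
  i <- i + p
  nlow <- p * (p - 1) / 2
  L <- diag(exp(ld), p)
  L[lower.tri(L)] <- theta[i + seq_len(nlow)]
  i <- i + nlow
  Q <- L %*% t(L)
  R <- if (r_mode == "estimate") exp(2 * theta[i + seq_len(p)]) else rep(0, p)
  dimnames(A) <- list(nodes, nodes)
  dimnames(Q) <- list(nodes, nodes)
  list(A = A, mu = setNames(mu, nodes), Q = Q, R = setNames(R, nodes))
}

#' Fit-control settings for [fit_ctvar()]
#'
#' @param min_occasions Minimum occasions required (default 30).
#' @param B Parametric-bootstrap replicates (default 0 = none).
#' @param r_mode `"estimate"` for a freely estimated diagonal measurement
#'   noise, `"zero"` to fix R = 0 (latent = observed).
#' @param maxit,reltol Passed to [stats::optim()] (BFGS).
#' @param stability_margin Drift iterates whose maximum eigenvalue real part
#'   exceeds `-stability_margin` are rejected with a graded penalty.
#' @return A list of class `ct_fit_control`.
#' @export
ct_fit_control <- function(min_occasions = 30L, B = 0L,
                           r_mode = c("estimate", "zero"),
                           maxit = 500L, reltol = 1e-10,
                           stability_margin = 1e-4) {
  structure(list(min_occasions = as.integer(min_occasions), B = as.integer(B),
                 r_mode = match.arg(r_mode), maxit = as.integer(maxit),
                 reltol = reltol, stability_margin = stability_margin),
            class = "ct_fit_control")
}

# Warm start: lag regression on near-modal gaps mapped back through the
# matrix logarithm; falls back to a diagonal -1/hour drift.
ctvar_init <- function(times, Y, r_mode) {
  p <- ncol(Y)
  mu0 <- colMeans(Y, na.rm = TRUE)
  S0 <- var(Y, na.rm = TRUE, use = "pairwise.complete.obs")
  if (anyNA(S0) || min(eigen((S0 + t(S0)) / 2, symmetric = TRUE,
                             only.values = TRUE)$values) <= 1e-8) {
    S0 <- diag(pmax(apply(Y, 2, var, na.rm = TRUE), 1e-2), p)
  }
  S0 <- (S0 + t(S0)) / 2
  A0 <- -diag(p)
  dts <- diff(times)
  dt0 <- median(dts)
  use <- which(dts <= 1.5 * dt0)
  if (length(use) >= 5 * p) {
    X1 <- Y[use, , drop = FALSE]
    X2 <- Y[use + 1L, , drop = FALSE]
    ok <- stats::complete.cases(X1) & stats::complete.cases(X2)
    if (sum(ok) >= 5 * p) {
      X1c <- sweep(X1[ok, , drop = FALSE], 2, mu0)
      X2c <- sweep(X2[ok, , drop = FALSE], 2, mu0)
      Phi0 <- tryCatch(t(qr.solve(X1c, X2c)), error = function(e) NULL)
      if (!is.null(Phi0)) {
        eg <- eigen(Phi0)
        lam <- eg$values
        if (all(Mod(lam) < 0.99) && all(Mod(lam) > 1e-3)) {
          Acand <- Re(eg$vectors %*% diag(log(lam), p) %*% solve(eg$vectors)) /
            mean(dts[use][ok[seq_along(use)]], na.rm = TRUE)
          if (max(Re(eigen(Acand, only.values = TRUE)$values)) < -1e-3) {
            A0 <- Acand
          }
        }
      }
    }
  }
  Q0 <- -(A0 %*% S0 + S0 %*% t(A0))
  Q0 <- (Q0 + t(Q0)) / 2
  eg <- eigen(Q0, symmetric = TRUE)
  Q0 <- eg$vectors %*% diag(pmax(eg$values, 1e-3 * max(eg$values)), p) %*%
    t(eg$vectors)
  R0 <- 0.1 * diag(S0)
  pack_theta(A0, mu0, Q0, R0, r_mode)
}

#' Maximum-likelihood estimation of a continuous-time VAR network
#'
#' Maximizes the exact state-space likelihood over (A, mu, Q, R) by BFGS,
#' with stationarity enforced by a graded penalty on drift iterates whose
#' eigenvalues have non-negative real parts. Uncertainty is available via a
#' parametric bootstrap: `B` datasets are simulated from the fitted model at
#' the observed timestamps and refit, and the replicate drift matrices are
#' stored. Deterministic given `seed`.
#'
#' @param series Data accepted by [ou_loglik()].
#' @param config A [ct_fit_control()].
#' @param seed Integer seed controlling the bootstrap (and any RNG use).
#' @param nodes Nodes to model (default: all items/columns present).
#' @return A `ctvar_fit` with elements `model` ([drift_model()]), `loglik`,
#'   `converged`, `boot_A` (list of replicate drift matrices, possibly
#'   empty), `times`, and the control settings used.
#' @export
fit_ctvar <- function(series, config = ct_fit_control(), seed = 123L,
                      nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- if (is_ema_series(series)) unique(series$item)
             else colnames(series$Y)
  }
  d <- as_ou_data(series, nodes)
  times <- d$times
  Y <- d$Y
  p <- length(nodes)
  n <- nrow(Y)
  if (n < config$min_occasions) {
    stop("need at least ", config$min_occasions, " occasions (got ", n, ")")
  }
  sds <- apply(Y, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds < 1e-8)) {
    stop("degenerate input: item(s) ",
         paste(nodes[!is.finite(sds) | sds < 1e-8], collapse = ", "),
         " are constant")
  }

  set.seed(seed)
  margin <- config$stability_margin
  negll <- function(theta) {
    par <- unpack_theta(theta, p, config$r_mode, nodes)
    mre <- max(Re(eigen(par$A, only.values = TRUE)$values))
    if (mre > -margin) return(1e8 + 1e8 * (mre + margin))
    ll <- cpp_ou_loglik(times, Y, par$A, par$mu, par$Q, par$R)
    if (!is.finite(ll)) return(1e8)
    -ll
  }

  theta0 <- ctvar_init(times, Y, config$r_mode)
  opt <- optim(theta0, negll, method = "BFGS",
               control = list(maxit = config$maxit, reltol = config$reltol))
  par <- unpack_theta(opt$par, p, config$r_mode, nodes)
  model <- drift_model(par$A, par$mu, par$Q, par$R, nodes = nodes)
  fit <- structure(list(model = model, loglik = -opt$value,
                        converged = opt$convergence == 0L,
                        boot_A = list(), times = times,
                        config = config, seed = seed),
                   class = "ctvar_fit")

  if (config$B > 0L) {
    boot_cfg <- config
    boot_cfg$B <- 0L
    warm <- pack_theta(model$A, model$mu,
                       model$Q + diag(1e-8, p), model$R, config$r_mode)
    boot <- vector("list", config$B)
    for (b in seq_len(config$B)) {
      Yb <- simulate_ctvar(model, times, seed = seed + 1000L + b)
      Yb[is.na(Y)] <- NA # preserve the observed missingness pattern
      negll_b <- function(theta) {
        pr <- unpack_theta(theta, p, config$r_mode, nodes)
        mre <- max(Re(eigen(pr$A, only.values = TRUE)$values))
        if (mre > -margin) return(1e8 + 1e8 * (mre + margin))
        ll <- cpp_ou_loglik(times, Yb, pr$A, pr$mu, pr$Q, pr$R)
        if (!is.finite(ll)) return(1e8)
        -ll
      }
      ob <- tryCatch(
        optim(warm, negll_b, method = "BFGS",
              control = list(maxit = config$maxit, reltol = config$reltol)),
        error = function(e) NULL)
      if (is.null(ob)) next
      pb <- unpack_theta(ob$par, p, config$r_mode, nodes)
      if (max(Re(eigen(pb$A, only.values = TRUE)$values)) < 0) {
        boot[[b]] <- pb$A
      }
    }
    fit$boot_A <- Filter(Negate(is.null), boot)
  }
  fit
}

#' @export
print.ctvar_fit <- function(x, ...) {
  cat("CT-VAR fit:", length(x$model$nodes), "nodes,",
      length(x$times), "occasions, logLik =", round(x$loglik, 2),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (length(x$boot_A)) {
    cat("Bootstrap replicates:", length(x$boot_A), "\n")
  }
  print(x$model)
  invisible(x)
}

#' Simulate an OU path at given timestamps
#'
#' Exact sampling: the path starts from the stationary distribution and each
#' gap uses the exact discretized transition; measurement noise `R` is added
#' to the returned values.
#'
#' @param model A stable [drift_model()].
#' @param timestamps Strictly increasing times in hours.
#' @param seed Integer seed.
#' @return Numeric matrix (occasions x nodes) of observed values, with the
#'   latent path in attribute `"latent"` and `timestamps` in `"times"`.
#' @export
simulate_ctvar <- function(model, timestamps, seed = 1L) {
  stopifnot(is_drift_model(model))
  timestamps <- as.numeric(timestamps)
  if (any(diff(timestamps) <= 0)) stop("timestamps must be increasing")
  n <- length(timestamps)
  p <- length(model$nodes)
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  X <- cpp_ou_simulate(timestamps, model$A, model$mu, model$Q, Z)
  E <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(model$R), p)
  Yobs <- X + E
  colnames(Yobs) <- model$nodes
  colnames(X) <- model$nodes
  attr(Yobs, "latent") <- X
  attr(Yobs, "times") <- timestamps
  Yobs
}
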