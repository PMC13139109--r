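#' Detrend and normal-scores transform an EMA series
#'
#' Per item: an ordinary-least-squares linear trend in clock time is removed,
#' then the residuals are mapped through the rank-based normal-scores
#' transform \eqn{z = \Phi^{-1}((rank - 0.5)/n)}, giving columns with zero
#' empirical slope and near-Gaussian margins (the usual preparation before
#' graphical VAR estimation). Ties get average ranks.
#'
#' @param series A single-participant [ema_series()] (no missing values;
#'   interpolate first), or a list with `times` and matrix `Y`.
#' @param items Items to transform (default: all five-daily items present
#'   on a shared grid).
#' @return A list of class `dt_residuals` with `times`, `day`
#'   (`floor(times/24)`), `phase` (if available) and matrix `Z`.
#' @export
detrend_and_transform <- function(series, items = NULL) {
  if (is_ema_series(series)) {
    w <- ema_wide(series, items)
    times <- w$times
    Y <- w$Y
    phase <- w$phase
  } else {
    times <- series$times
    Y <- as.matrix(series$Y)
    phase <- series$phase
  }
  if (anyNA(Y)) stop("missing values present; interpolate or subset first")
  n <- nrow(Y)
  if (n < 10L) stop("need at least 10 occasions per item")
  Z <- Y
  for (j in seq_len(ncol(Y))) {
    if (sd(Y[, j]) < 1e-10) {
      stop("item '", colnames(Y)[j], "' is constant; cannot transform")
    }
    res <- stats::residuals(lm(Y[, j] ~ times))
    if (sd(res) < 1e-10) {
      stop("item '", colnames(Y)[j],
           "' is perfectly linear in time; residuals are degenerate")
    }
    r <- rank(res, ties.method = "average")
    Z[, j] <- qnorm((r - 0.5) / n)
  }
  structure(list(times = times, day = floor(times / 24), phase = phase,
                 Z = Z), class = "dt_residuals")
}

# Within-day consecutive occasion pairs (no overnight lags).
same_day_pairs <- function(rt) {
  n <- nrow(rt$Z)
  idx <- seq_len(n - 1L)
  idx[rt$day[idx] == rt$day[idx + 1L]]
}

# EBIC for a Gaussian regression with df k among p candidate predictors.
ebic_reg <- function(rss, n, k, p, gamma) {
  n * log(rss / n) + k * log(n) + 2 * gamma * k * log(p)
}

#' Graphical lasso (block coordinate descent)
#'
#' Estimates a sparse precision matrix by L1-penalized Gaussian
#' log-likelihood (off-diagonal penalty `rho`), using the classic block
#' coordinate-descent algorithm in which each column update is a lasso
#' problem solved by coordinate descent.
#'
#' @param S Sample covariance matrix.
#' @param rho Penalty (>= 0).
#' @param maxit,tol Outer-loop iteration cap and convergence tolerance on
#'   the estimated covariance.
#' @return List with precision `K` and covariance estimate `W`.
#' @export
glasso_fit <- function(S, rho, maxit = 200L, tol = 1e-6) {
  p <- ncol(S)
  if (p == 1L) return(list(K = 1 / S, W = S))
  W <- S + rho * diag(p)
  Beta <- matrix(0, p - 1L, p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      jm <- setdiff(seq_len(p), j)
      W11 <- W[jm, jm, drop = FALSE]
      s12 <- S[jm, j]
      beta <- Beta[, j]
      # lasso by coordinate descent on 0.5 b'W11 b - s12'b + rho|b|_1
      for (cd in seq_len(100L)) {
        bmax <- 0
        for (k in seq_len(p - 1L)) {
          bk <- beta[k]
          rk <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * bk
          bn <- soft(rk, rho) / W11[k, k]
          if (bn != bk) {
            beta[k] <- bn
            bmax <- max(bmax, abs(bn - bk))
          }
        }
        if (bmax < tol) break
      }
      Beta[, j] <- beta
      W[jm, j] <- W11 %*% beta
      W[j, jm] <- W[jm, j]
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(S - diag(diag(S)) + 1e-12)))
      break
  }
  K <- matrix(0, p, p)
  for (j in seq_len(p)) {
    jm <- setdiff(seq_len(p), j)
    k22 <- 1 / (W[j, j] - sum(W[jm, j] * Beta[, j]))
    K[j, j] <- k22
    K[jm, j] <- -Beta[, j] * k22
  }
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(S)
  list(K = K, W = W)
}

# EBIC over a log-spaced rho grid for the graphical lasso.
glasso_ebic <- function(S, n, gamma = 0.5, n_rho = 50L, ratio = 0.01) {
  p <- ncol(S)
  rho_max <- max(abs(S[upper.tri(S)]))
  if (rho_max <= 0) rho_max <- 1e-3
  rhos <- exp(seq(log(rho_max), log(rho_max * ratio), length.out = n_rho))
  best <- NULL
  for (rho in rhos) {
    fit <- glasso_fit(S, rho)
    K <- fit$K
    ld <- determinant(K, logarithm = TRUE)
    if (ld$sign <= 0) next
    ll <- (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
    E <- sum(abs(K[upper.tri(K)]) > 1e-8)
    score <- -2 * ll + E * log(n) + 4 * gamma * E * log(p)
    if (is.null(best) || score < best$score) {
      best <- list(K = K, rho = rho, score = score)
    }
  }
  if (is.null(best)) stop("graphical lasso failed on every penalty")
  best
}

prec_to_pcor <- function(K) {
  d <- sqrt(diag(K))
  R <- -K / tcrossprod(d)
  diag(R) <- 1
  R
}

new_contemp_network <- function(pcor, penalized, rho = NA_real_,
                                n_pairs = NA_integer_, n = NA_integer_) {
  structure(list(nodes = colnames(pcor), pcor = pcor, penalized = penalized,
                 rho = rho, n_pairs = n_pairs, n = n),
            class = "contemp_network")
}

#' @export
print.contemp_network <- function(x, ...) {
  cat(if (x$penalized) "Penalized" else "Unpenalized",
      "contemporaneous partial-correlation network (", length(x$nodes),
      " nodes", if (x$penalized) paste0(", rho = ", signif(x$rho, 3)),
      ")\n", sep = "")
  print(round(x$pcor, 3))
  invisible(x)
}

#' Discrete-time graphical VAR estimation
#'
#' Lag-1 temporal regression uses only *same-day* consecutive occasion pairs
#' (no overnight lags); the contemporaneous network is the partial
#' correlation matrix \eqn{\rho_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}} of the
#' temporal residuals (occasions without a same-day predecessor enter with
#' the marginal prediction, so all occasions inform the contemporaneous
#' part). The penalized path uses per-node lasso regressions for the
#' temporal matrix and the graphical lasso for the precision, both selected
#' by EBIC with weight `gamma` over a 50-point log-spaced penalty grid
#' (min/max ratio 0.01); the unpenalized path uses ordinary least squares
#' and the inverse sample covariance.
#'
#' @param rt A `dt_residuals` from [detrend_and_transform()].
#' @param penalized Logical.
#' @param gamma EBIC weight (default 0.5).
#' @return List with `temporal` (p x p, effect of column j at t-1 on row i
#'   at t) and `contemp` (a `contemp_network`).
#' @export
fit_dtvar <- function(rt, penalized = FALSE, gamma = 0.5) {
  stopifnot(inherits(rt, "dt_residuals"))
  Z <- rt$Z
  p <- ncol(Z)
  if (p < 2L) stop("need at least 2 nodes")
  pairs <- same_day_pairs(rt)
  if (!length(pairs)) stop("no within-day consecutive occasion pairs")
  Xlag <- Z[pairs, , drop = FALSE]
  Xnow <- Z[pairs + 1L, , drop = FALSE]
  n <- nrow(Z)
  nodes <- colnames(Z)

  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (penalized) {
    for (i in seq_len(p)) {
      y <- Xnow[, i]
      lmax <- max(abs(crossprod(Xlag, y - mean(y)))) / length(y)
      lams <- exp(seq(log(lmax), log(lmax * 0.01), length.out = 50L))
      gf <- glmnet::glmnet(Xlag, y, alpha = 1, lambda = lams,
                           standardize = FALSE)
      pred <- stats::predict(gf, Xlag)
      rss <- colSums((y - pred)^2)
      k <- gf$df
      score <- ebic_reg(pmax(rss, 1e-12), length(y), k, p, gamma)
      jbest <- which.min(score)
      B[i, ] <- as.numeric(coef(gf)[-1, jbest])
    }
  } else {
    for (i in seq_len(p)) {
      B[i, ] <- coef(lm(Xnow[, i] ~ Xlag))[-1]
    }
  }

  # residuals at every occasion: marginal (zero) prediction where no
  # same-day predecessor exists
  Res <- Z
  Res[pairs + 1L, ] <- Xnow - Xlag %*% t(B)
  S <- crossprod(Res) / nrow(Res)

  if (penalized) {
    gb <- glasso_ebic(S, n = nrow(Res), gamma = gamma)
    pc <- prec_to_pcor(gb$K)
    pc[abs(pc) < 1e-8] <- 0
    contemp <- new_contemp_network(pc, TRUE, rho = gb$rho,
                                   n_pairs = length(pairs), n = n)
  } else {
    if (!all(is.finite(S)) || rcond(S) < 1e-12) {
      stop("residual covariance is singular or degenerate; ",
           "use the penalized path")
    }
    contemp <- new_contemp_network(prec_to_pcor(solve(S)), FALSE,
                                   n_pairs = length(pairs), n = n)
  }
  list(temporal = B, contemp = contemp)
}

#' Centrality indices for a contemporaneous network
#'
#' Strength is the absolute edge-weight sum, expected influence the signed
#' sum. Betweenness and closeness are computed on the weighted graph whose
#' edge lengths are `1/|weight|` over nonzero edges; closeness is the
#' reciprocal of the summed shortest-path distances to all other nodes
#' (0 when any node is unreachable), and isolated nodes get betweenness 0.
#'
#' @param network A `contemp_network` from [fit_dtvar()].
#' @param outcome Optional outcome node excluded from the candidate rows
#'   (it still participates in paths).
#' @return A tibble with node, strength, expected_influence, betweenness,
#'   closeness.
#' @export
dt_centrality <- function(network, outcome = NULL) {
  stopifnot(inherits(network, "contemp_network"))
  W <- network$pcor
  diag(W) <- 0
  nodes <- network$nodes
  strength <- rowSums(abs(W))
  ei <- rowSums(W)

  g <- igraph::graph_from_adjacency_matrix(abs(W) > 0, mode = "undirected",
                                           diag = FALSE)
  elist <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(elist)) {
    wts <- abs(W)[elist]
    btw <- igraph::betweenness(g, weights = 1 / wts)
    D <- igraph::distances(g, weights = 1 / wts)
  } else {
    btw <- rep(0, length(nodes))
    D <- matrix(Inf, length(nodes), length(nodes))
    diag(D) <- 0
  }
  dsum <- rowSums(D)
  clo <- ifelse(is.finite(dsum) & dsum > 0, 1 / dsum, 0)
  out <- tibble::tibble(node = nodes, strength = unname(strength),
                        expected_influence = unname(ei),
                        betweenness = as.numeric(btw),
                        closeness = as.numeric(clo))
  if (!is.null(outcome)) out <- out[out$node != outcome, ]
  out
}

#' Strongest edge to the outcome variable
#'
#' For a contemporaneous network, the process node with the largest absolute
#' partial correlation with the outcome; for a lagged effect matrix, the
#' process node j with the largest `|Phi[outcome, j]|`. Ties are broken by
#' node name; if every candidate edge is zero the sentinel `"none"` is
#' returned.
#'
#' @param x A `contemp_network` or a named square effect matrix.
#' @param outcome Outcome node name.
#' @return A single node name or `"none"`.
#' @export
strongest_edge_to_outcome <- function(x, outcome) {
  W <- if (inherits(x, "contemp_network")) x$pcor else as.matrix(x)
  if (is.null(rownames(W))) stop("effect matrix needs node names")
  if (!outcome %in% rownames(W)) stop("outcome '", outcome, "' not a node")
  cand <- setdiff(colnames(W), outcome)
  w <- abs(W[outcome, cand])
  if (max(w) <= 0) return("none")
  cand[order(-w, cand)][1]
}

#' Serialize a network as an edge list with a metadata block
#'
#' Writes `<path>` as CSV (node_i, node_j, weight) and `<path>.meta.json`
#' with the penalty, gamma, and sample sizes.
#'
#' @param network A `contemp_network`.
#' @param path Output CSV path.
#' @param gamma EBIC weight recorded in the metadata.
#' @export
write_network_csv <- function(network, path, gamma = 0.5) {
  W <- network$pcor
  ut <- which(upper.tri(W), arr.ind = TRUE)
  el <- data.frame(node_i = network$nodes[ut[, 1]],
                   node_j = network$nodes[ut[, 2]],
                   weight = W[ut])
  write.csv(el[el$weight != 0 | !network$penalized, ], path,
            row.names = FALSE)
  meta <- list(penalized = network$penalized, rho = network$rho,
               gamma = if (network$penalized) gamma else NA,
               n_pairs = network$n_pairs, n_occasions = network$n)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
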