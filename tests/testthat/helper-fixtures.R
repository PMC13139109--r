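# Shared fixtures and independent brute-force oracles.

# Small long-format series builder: one participant, items on a shared grid.
make_series <- function(values, times = NULL, phase = NULL,
                        participant = "p1") {
  # values: named list item -> numeric vector (NA = missing)
  n <- length(values[[1]])
  if (is.null(times)) times <- seq_len(n)
  if (is.null(phase)) phase <- rep("baseline", n)
  rows <- lapply(names(values), function(it) {
    tibble::tibble(participant = participant, time = times, phase = phase,
                   item = it, value = values[[it]])
  })
  ema_series(do.call(rbind, rows))
}

# A registry-complete baseline series from the synthetic generator.
sim_baseline <- function(days = 20, seed = 1) {
  truth <- synthetic_truth()
  sched <- make_schedule(min(days, 20L), max(0L, days - 20L), 0L,
                         seed = seed)
  sched$phase <- "baseline"
  simulate_ema(truth, sched, seed = seed)
}

# Random stable drift matrix: random couplings, diagonal shifted to push
# eigenvalues left of -margin.
random_stable_drift <- function(p, seed, margin = 0.1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p, sd = 0.3), p, p)
  diag(A) <- -abs(rnorm(p, 1, 0.2))
  shift <- max(Re(eigen(A, only.values = TRUE)$values))
  if (shift > -margin) diag(A) <- diag(A) - (shift + margin)
  A
}

# --- Tau-U exhaustive pair-enumeration oracle ------------------------------

oracle_tau_u <- function(A, B, variant) {
  nA <- length(A)
  nB <- length(B)
  s_ab <- 0L
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      s_ab <- s_ab + sign(B[j] - A[i])
    }
  }
  trend <- function(x) {
    s <- 0L
    n <- length(x)
    if (n < 2) return(0L)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
    }
    s
  }
  useB <- variant %in% c("AvsB+TrendB", "AvsB+TrendB-TrendA")
  useA <- variant == "AvsB+TrendB-TrendA"
  s_tot <- s_ab + (if (useB) trend(B) else 0) - (if (useA) trend(A) else 0)
  den <- nA * nB + (if (useB) nB * (nB - 1) / 2 else 0) +
    (if (useA) nA * (nA - 1) / 2 else 0)
  v <- nA * nB * (nA + nB + 1) / 3 +
    (if (useB) nB * (nB - 1) * (2 * nB + 5) / 18 else 0) +
    (if (useA) nA * (nA - 1) * (2 * nA + 5) / 18 else 0)
  list(S_total = s_tot, denominator = den, tau = s_tot / den, SD_S = sqrt(v))
}

# --- brute-force weighted betweenness (fractional shortest-path counts) ----

oracle_betweenness <- function(W) {
  p <- ncol(W)
  L <- 1 / abs(W)
  diag(L) <- Inf
  L[abs(W) == 0] <- Inf
  # enumerate all simple paths between every pair
  paths <- function(from, to) {
    out <- list()
    walk <- function(path, cost) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- list(path = path, cost = cost)
        return()
      }
      for (nxt in seq_len(p)) {
        if (nxt %in% path || !is.finite(L[last, nxt])) next
        walk(c(path, nxt), cost + L[last, nxt])
      }
    }
    walk(from, 0)
    out
  }
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths(s, t)
      if (!length(ps)) next
      costs <- vapply(ps, `[[`, numeric(1), "cost")
      best <- min(costs)
      sp <- ps[abs(costs - best) < 1e-12]
      for (v in setdiff(seq_len(p), c(s, t))) {
        through <- sum(vapply(sp, function(q) v %in% q$path, logical(1)))
        btw[v] <- btw[v] + through / length(sp)
      }
    }
  }
  btw
}
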