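#' Delta-time lagged effect matrix
#'
#' \eqn{\Phi(\Delta) = e^{A\Delta}}; entry `[i, j]` is the lagged effect of a
#' unit deviation in node j on node i after `delta` hours.
#'
#' @param model A stable [drift_model()].
#' @param delta Lag in hours, >= 0.
#' @return p x p matrix with the model's node names.
#' @export
effect_matrix <- function(model, delta) {
  stopifnot(is_drift_model(model), delta >= 0)
  Phi <- cpp_expm(model$A * delta)
  dimnames(Phi) <- dimnames(model$A)
  Phi
}

new_centrality_table <- function(nodes, values, index, delta,
                                 lo = NA_real_, hi = NA_real_) {
  tab <- tibble::tibble(node = nodes, index = index, delta = delta,
                        point = as.numeric(values), lo = lo, hi = hi)
  class(tab) <- c("centrality_table", class(tab))
  tab
}

process_nodes <- function(model, outcome) {
  if (is.null(outcome)) return(model$nodes)
  if (!outcome %in% model$nodes) stop("outcome '", outcome, "' not a node")
  setdiff(model$nodes, outcome)
}

#' Total effect centrality (TEC)
#'
#' For candidate node j at lag `delta`, the sum of lagged effects of j on
#' every other network node (the outcome is included as a receiver but is
#' never a candidate): \eqn{TEC_j = \sum_{i \ne j} \Phi(\Delta)_{ij}}.
#' High-TEC nodes are those whose decrease would most quickly propagate
#' through the network.
#'
#' @param model A stable [drift_model()].
#' @param delta Lag in hours.
#' @param outcome Outcome node name excluded from candidacy (`NULL` to rank
#'   all nodes).
#' @return A `centrality_table` tibble (node, index, delta, point, lo, hi).
#' @export
tec <- function(model, delta, outcome = NULL) {
  Phi <- effect_matrix(model, delta)
  cand <- process_nodes(model, outcome)
  vals <- vapply(cand, function(j) {
    sum(Phi[setdiff(model$nodes, j), j])
  }, numeric(1))
  new_centrality_table(cand, vals, "TEC", delta)
}

#' Indirect effect centrality (IEC)
#'
#' The part of a node's total lagged effect transmitted through mediating
#' nodes. For the ordered pair (j -> i) the *direct* effect is the lagged
#' effect in the mediator-blocked model that keeps A's diagonal and the
#' i-j pair's mutual couplings but zeroes every pathway through other
#' nodes: \eqn{DE_{ij} = [e^{\tilde A \Delta}]_{ij}}. The indirect effect
#' is the total minus the direct effect, and
#' \eqn{IEC_j = \sum_{i \ne j} IE_{ij}}. With only two nodes there are no
#' mediators, so IEC is identically zero.
#'
#' @inheritParams tec
#' @return A `centrality_table` tibble.
#' @export
iec <- function(model, delta, outcome = NULL) {
  A <- model$A
  p <- length(model$nodes)
  Phi <- effect_matrix(model, delta)
  diagA <- diag(diag(A), p)
  cand <- process_nodes(model, outcome)
  vals <- vapply(cand, function(jn) {
    j <- match(jn, model$nodes)
    tot <- 0
    for (i in seq_len(p)) {
      if (i == j) next
      At <- diagA
      At[i, j] <- A[i, j]
      At[j, i] <- A[j, i]
      DE <- cpp_expm(At * delta)[i, j]
      tot <- tot + (Phi[i, j] - DE)
    }
    tot
  }, numeric(1))
  new_centrality_table(cand, vals, "IEC", delta)
}

#' Centrality profile over a range of delta-times
#'
#' @inheritParams tec
#' @param deltas Vector of lags in hours.
#' @param index `"TEC"` or `"IEC"`.
#' @return A `centrality_table` with one block per delta.
#' @export
centrality_profile <- function(model, deltas, index = c("TEC", "IEC"),
                               outcome = NULL) {
  index <- match.arg(index)
  fun <- if (index == "TEC") tec else iec
  out <- do.call(rbind, lapply(deltas, fun, model = model, outcome = outcome))
  class(out) <- c("centrality_table", class(tibble::tibble()))
  out
}

#' Centrality with bootstrap uncertainty intervals
#'
#' The point value is the centrality of the fitted point estimate; the
#' interval is the 25th-75th percentile (a 50% interval) of the centrality
#' across bootstrap replicate drift matrices.
#'
#' @param fit A [fit_ctvar()] result carrying bootstrap replicates.
#' @param delta Lag in hours.
#' @param index `"TEC"` or `"IEC"`.
#' @param outcome Outcome node excluded from candidacy.
#' @param probs Interval percentiles (default `c(0.25, 0.75)`).
#' @return A `centrality_table` with `lo`/`hi` filled in.
#' @export
centrality_intervals <- function(fit, delta, index = c("TEC", "IEC"),
                                 outcome = NULL, probs = c(0.25, 0.75)) {
  index <- match.arg(index)
  if (!inherits(fit, "ctvar_fit")) stop("fit must be a ctvar_fit")
  if (!length(fit$boot_A)) {
    stop("fit has no bootstrap replicates; rerun fit_ctvar() with ",
         "ct_fit_control(B = ...)")
  }
  fun <- if (index == "TEC") tec else iec
  tab <- fun(fit$model, delta, outcome = outcome)
  reps <- vapply(fit$boot_A, function(Ab) {
    m <- fit$model
    dimnames(Ab) <- dimnames(m$A)
    m$A <- Ab
    fun(m, delta, outcome = outcome)$point
  }, numeric(nrow(tab)))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  qs <- apply(reps, 1, quantile, probs = probs, names = FALSE)
  tab$lo <- qs[1, ]
  tab$hi <- qs[2, ]
  tab
}

#' Rank candidate nodes of a centrality table
#'
#' Ranking uses the point estimate. Exact ties are broken by the same index
#' evaluated at twice the delta, then by node name, so selection is
#' deterministic.
#'
#' @param tab A `centrality_table` (single delta).
#' @param model The [drift_model()] the table came from (used only for
#'   tie-breaking; optional).
#' @return The table's nodes ordered from most to least central.
#' @export
rank_central <- function(tab, model = NULL) {
  stopifnot(inherits(tab, "centrality_table"))
  if (length(unique(tab$delta)) != 1L) stop("rank_central needs one delta")
  key2 <- rep(0, nrow(tab))
  if (!is.null(model) && anyDuplicated(tab$point)) {
    fun <- if (tab$index[1] == "TEC") tec else iec
    wide <- fun(model, 2 * tab$delta[1])
    key2 <- wide$point[match(tab$node, wide$node)]
  }
  tab$node[order(-tab$point, -key2, tab$node)]
}

#' Serialize a centrality table to CSV
#'
#' @param tab A `centrality_table`.
#' @param path Output file.
#' @export
write_centrality_csv <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
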