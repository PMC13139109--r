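#' Tau-U single-case effect size with phase-trend corrections
#'
#' Nonparametric phase-contrast statistic combining cross-phase dominance
#' with within-phase Kendall trend corrections. `S_AB` is the sum over all
#' nA x nB cross-phase pairs of `sign(B_j - A_i)`; `S_trendA` / `S_trendB`
#' are the Kendall S statistics within each phase; ties contribute 0 to
#' every S. The variants are:
#' \itemize{
#'   \item `"AvsB"`: `S = S_AB`, denominator `nA*nB`.
#'   \item `"AvsB+TrendB"`: `S = S_AB + S_trendB`, denominator
#'     `nA*nB + nB(nB-1)/2`.
#'   \item `"AvsB+TrendB-TrendA"` (the conservative variant that adjusts for
#'     all phase trends): `S = S_AB + S_trendB - S_trendA`, denominator
#'     `nA*nB + nB(nB-1)/2 + nA(nA-1)/2`.
#' }
#' `SD_S` is the additive null standard deviation
#' \eqn{\sqrt{n_A n_B (n_A+n_B+1)/3 + n_B(n_B-1)(2n_B+5)/18 +
#' n_A(n_A-1)(2n_A+5)/18}} with the trend terms dropped to match simpler
#' variants; `z = S/SD_S` with a two-sided normal p-value.
#'
#' @param A,B Numeric vectors for the earlier and later phase (>= 3 points
#'   each).
#' @param variant One of `"AvsB"`, `"AvsB+TrendB"`, `"AvsB+TrendB-TrendA"`.
#' @return A `tau_u_result` tibble row: variant, nA, nB, S_AB, S_trendA,
#'   S_trendB, S_total, denominator, tau, SD_S, z, p.
#' @export
tau_u <- function(A, B, variant = c("AvsB+TrendB-TrendA", "AvsB",
                                    "AvsB+TrendB")) {
  variant <- match.arg(variant)
  A <- as.numeric(A[!is.na(A)])
  B <- as.numeric(B[!is.na(B)])
  nA <- length(A)
  nB <- length(B)
  if (nA < 3L || nB < 3L) stop("each phase needs at least 3 data points")

  S_AB <- sum(sign(outer(B, A, "-")))
  S_A <- kendall_s(A)
  S_B <- kendall_s(B)

  useB <- variant %in% c("AvsB+TrendB", "AvsB+TrendB-TrendA")
  useA <- variant == "AvsB+TrendB-TrendA"
  S_total <- S_AB + (if (useB) S_B else 0) - (if (useA) S_A else 0)
  denom <- nA * nB + (if (useB) nB * (nB - 1) / 2 else 0) +
    (if (useA) nA * (nA - 1) / 2 else 0)
  v <- nA * nB * (nA + nB + 1) / 3 +
    (if (useB) nB * (nB - 1) * (2 * nB + 5) / 18 else 0) +
    (if (useA) nA * (nA - 1) * (2 * nA + 5) / 18 else 0)
  SD_S <- sqrt(v)
  z <- S_total / SD_S
  out <- tibble::tibble(variant = variant, nA = nA, nB = nB, S_AB = S_AB,
                        S_trendA = S_A, S_trendB = S_B, S_total = S_total,
                        denominator = denom, tau = S_total / denom,
                        SD_S = SD_S, z = z, p = 2 * pnorm(-abs(z)))
  class(out) <- c("tau_u_result", class(out))
  out
}

# Kendall S: sum over i < j of sign(x_j - x_i).
kendall_s <- function(x) {
  n <- length(x)
  if (n < 2L) return(0L)
  sum(sign(outer(x, x, "-")[lower.tri(matrix(0, n, n))]))
}

#' Interpretation band for a Tau-U magnitude
#'
#' Magnitudes below 0.2 are labelled small, 0.2-0.6 moderately high,
#' 0.6-0.8 high, and above 0.8 very high.
#'
#' @param tau Tau-U value (sign ignored).
#' @return Character label.
#' @export
tau_u_band <- function(tau) {
  a <- abs(tau)
  ifelse(a < 0.2, "small",
         ifelse(a < 0.6, "moderately high",
                ifelse(a <= 0.8, "high", "very high")))
}

#' Phase-contrast Tau-U evaluation of a full study series
#'
#' Runs [tau_u()] for each outcome and each phase contrast
#' (baseline-phase1, baseline-phase2, phase1-phase2), under the chosen
#' missing-data handling: `"interpolate"` fills missing responses by
#' [interpolate_missing()] (interpolated points count as ordinary data),
#' `"exclude"` drops them. Each delivered component phase is one single-case
#' phase. Effects are labelled with [tau_u_band()].
#'
#' @param series A single-participant [ema_series()] with all three phases.
#' @param outcomes Item names to evaluate.
#' @param handling `"interpolate"` or `"exclude"`.
#' @param variant Tau-U variant (default the full trend-corrected one).
#' @return A tibble with one row per outcome x contrast, including
#'   significance stars at 0.05 / 0.01.
#' @export
evaluate_sced <- function(series,
                          outcomes = c("interference", "motivation",
                                       "pain_intensity"),
                          handling = c("interpolate", "exclude"),
                          variant = "AvsB+TrendB-TrendA") {
  stopifnot(is_ema_series(series))
  handling <- match.arg(handling)
  phases <- c("baseline", "phase1", "phase2")
  if (!all(phases %in% unique(series$phase))) {
    stop("series must contain all three phases (missing: ",
         paste(setdiff(phases, unique(series$phase)), collapse = ", "), ")")
  }
  if (handling == "interpolate") series <- interpolate_missing(series)
  contrasts <- list(c("baseline", "phase1"), c("baseline", "phase2"),
                    c("phase1", "phase2"))
  rows <- list()
  for (out in outcomes) {
    sub <- series[series$item == out, ]
    if (!nrow(sub)) stop("outcome item '", out, "' not in series")
    for (ct in contrasts) {
      a <- sub$value[sub$phase == ct[1]]
      b <- sub$value[sub$phase == ct[2]]
      if (handling == "exclude") {
        a <- a[!is.na(a)]
        b <- b[!is.na(b)]
      }
      r <- tau_u(a, b, variant = variant)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        outcome = out, contrast = paste(ct, collapse = "-"),
        tau = r$tau, SD_S = r$SD_S, z = r$z, p = r$p,
        band = tau_u_band(r$tau),
        stars = ifelse(r$p < 0.01, "**", ifelse(r$p < 0.05, "*", "")))
    }
  }
  do.call(rbind, rows)
}

#' Visual-analysis metrics for one outcome
#'
#' Per phase: mean, SD, and OLS slope in clock time. Per phase contrast:
#' overlap percent (share of later-phase points lying within the
#' earlier phase's observed [min, max] range), the high-overlap flag
#' (overlap > 30%), and immediacy (absolute difference between the mean of
#' the last five points of the earlier phase and the first five points of
#' the later phase; undefined when either phase has fewer than five points).
#'
#' @param series A single-participant [ema_series()].
#' @param outcome Outcome item name.
#' @return List with tibbles `phases` and `contrasts`.
#' @export
visual_metrics <- function(series, outcome) {
  stopifnot(is_ema_series(series))
  sub <- series[series$item == outcome & !is.na(series$value), ]
  if (!nrow(sub)) stop("no observed values for outcome '", outcome, "'")
  phases <- intersect(c("baseline", "phase1", "phase2"), unique(sub$phase))
  ph <- lapply(phases, function(p) {
    v <- sub$value[sub$phase == p]
    t <- sub$time[sub$phase == p]
    slope <- if (length(v) >= 2 && sd(t) > 0) unname(coef(lm(v ~ t))[2])
             else NA_real_
    tibble::tibble(phase = p, n = length(v), mean = mean(v), sd = sd(v),
                   slope = slope)
  })
  cts <- list()
  pairs <- utils::combn(phases, 2, simplify = FALSE)
  for (pr in pairs) {
    va <- sub$value[sub$phase == pr[1]]
    vb <- sub$value[sub$phase == pr[2]]
    overlap <- 100 * mean(vb >= min(va) & vb <= max(va))
    adjacent <- match(pr[2], phases) - match(pr[1], phases) == 1L
    imm <- if (adjacent && length(va) >= 5 && length(vb) >= 5) {
      abs(mean(tail(va, 5)) - mean(head(vb, 5)))
    } else NA_real_
    cts[[length(cts) + 1L]] <- tibble::tibble(
      contrast = paste(pr, collapse = "-"), overlap_pct = overlap,
      high_overlap = overlap > 30, immediacy = imm)
  }
  list(phases = do.call(rbind, ph), contrasts = do.call(rbind, cts))
}

#' Minimal-important-difference flags for BPI interference change
#'
#' A pre-to-post decrease of at least 0.87 points on the 0-10 Brief Pain
#' Inventory interference scale counts as meaningful improvement; a
#' symmetric increase counts as meaningful worsening.
#'
#' @param pre,post Scores in [0, 10].
#' @return Tibble with change (pre - post), `improved`, `worsened`.
#' @export
bpi_change <- function(pre, post) {
  if (any(!is.finite(c(pre, post))) || any(c(pre, post) < 0) ||
      any(c(pre, post) > 10)) {
    stop("BPI scores must lie in [0, 10]")
  }
  change <- pre - post
  tibble::tibble(pre = pre, post = post, change = change,
                 improved = change >= 0.87, worsened = -change >= 0.87)
}
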