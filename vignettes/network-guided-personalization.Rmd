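---
title: "Network-guided treatment personalization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-guided treatment personalization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctnetguide)
```

## The problem

Idiographic (within-person) network approaches to psychological treatment
assume that a person's symptoms and maintaining processes form a dynamic
system, and that intervening on the most *central* process — the one whose
change propagates most strongly through the rest of the system — should
yield the largest overall benefit. `ctnetguide` implements the full analysis
chain needed to test that hypothesis in a multiple-baseline single-case
experimental design (SCED) with ecological momentary assessment (EMA) data:

1. estimate a continuous-time VAR (Ornstein–Uhlenbeck) network from a
   participant's irregularly spaced baseline EMA series;
2. select treatment targets by total effect centrality, in two stages
   (overarching composites, then the facets within the selected
   composites);
3. evaluate phase effects with trend-corrected Tau-U and visual-analysis
   metrics;
4. probe the selection's robustness with a grid of alternative guidance
   procedures (discrete-time graphical VAR networks, other centrality
   indices, descriptive baseline statistics);
5. quantify, by simulation from a known synthetic truth, how reliably the
   whole chain recovers a planted network structure.

The intended data are daily self-reports on 0–100 visual-analogue scales:
six psychological-inflexibility facet items (experiential avoidance,
fusion, lack of present-moment awareness, self-as-content, lack of values
clarity, inaction), a pain-interference outcome, pain intensity, and a
once-daily motivation item, prompted five times a day at 8, 11, 14, 17 and
20 h with a 3-hour response window.

## The continuous-time VAR model

The latent process \(x(t) \in \mathbb{R}^p\) follows the linear stochastic
differential equation

\[ dx = A\,(x - \mu)\,dt + G\,dW, \qquad Q = GG', \]

observed at response times \(t_k\) as \(y_k = x(t_k) + e_k\),
\(e_k \sim N(0, \mathrm{diag}(R))\). `A[i, j]` (units 1/hour) is the
instantaneous effect of node *j*'s deviation from its equilibrium on node
*i*'s rate of change; stationarity requires all eigenvalues of \(A\) to
have negative real part. Between two occasions separated by \(\Delta\), the
process is exactly a VAR(1) with

\[ \Phi(\Delta) = e^{A\Delta}, \qquad
   Q_\Delta = S_\infty - \Phi S_\infty \Phi', \]

where \(S_\infty\) solves the Lyapunov equation
\(A S_\infty + S_\infty A' + Q = 0\). This is why a continuous-time model
suits EMA schedules: the irregular 3-hour daytime gaps and 12-hour
overnight gaps are handled exactly, with no equal-spacing assumption.

Estimation is maximum likelihood: an exact Kalman filter (compiled code)
accumulates the Gaussian state-space likelihood over the actual
inter-occasion gaps, marginalizing missing components occasion by
occasion, and BFGS maximizes it over \((A, \mu, Q, R)\) with \(Q\)
parameterized by its log-Cholesky factor and stationarity enforced by a
graded penalty on drift iterates with non-negative eigenvalue real parts.
The optimizer warm-starts from a lag-regression estimate mapped through
the matrix logarithm (falling back to a diagonal \(-1\)/hour drift) with
\(\mu\) and \(S_\infty\) taken from the data. Uncertainty comes from a
parametric bootstrap: `B` datasets are simulated from the fitted model at
the observed timestamps and refit; the "50% interval" reported with
centrality values is the 25th–75th percentile across replicate drift
matrices. This likelihood-plus-bootstrap backend is a deliberate,
documented stand-in for a Bayesian posterior: the intervals play the same
role, and the point ranking — which is what guidance uses — is unaffected.

### Centrality

Total effect centrality at lag \(\Delta\) sums the lagged effects a node
sends to every other node:

\[ \mathrm{TEC}_j(\Delta) = \sum_{i \ne j} \left[e^{A\Delta}\right]_{ij}. \]

Indirect effect centrality subtracts, for each ordered pair \(j \to i\),
the *direct* lagged effect computed in a mediator-blocked model
\(\tilde A\) that keeps the diagonal and the pair's mutual couplings
`A[i, j]`, `A[j, i]` but zeroes every pathway through other nodes:
\(\mathrm{IE}_{ij} = \Phi_{ij} - [e^{\tilde A\Delta}]_{ij}\), and
\(\mathrm{IEC}_j = \sum_{i\ne j} \mathrm{IE}_{ij}\). Keeping both mutual
couplings (rather than only the single directed entry) is the convention
chosen here because it makes IEC exactly zero in any two-node model —
there are no mediators — which the single-entry convention violates when
feedback is present.

The default \(\Delta\) is the median inter-occasion interval of the
analyzed series (about 3.2 h under the study schedule, computed after
interpolation). The outcome node is always a *receiver* of effects but
never a candidate for selection. Ranking uses the point estimate; exact
ties break by the same index at twice the delta, then lexicographically,
so selection is deterministic.

## Two-stage guidance

Stage 1 fits a 4-node network — the three overarching composites
(openness = mean of EA and fusion; awareness = mean of LPMA and SAC;
engagement = mean of LV and inaction; each the arithmetic mean of its two
facets, preserving the 0–100 scale) plus interference — and takes the
argmax/argmin of TEC as the most/least central node intervention (MCNI /
LCNI) composites. Stage 2 fits one 3-node network per selected composite
(its two facets plus interference); the MCNI phase delivers its more
central facet first and the LCNI phase its *less* central facet first.
Keeping the stage networks at 3–4 nodes protects the fits at single-case
sample sizes. Baseline length (uniform on 14–20 days) and phase order
(fair coin) are seeded draws, and `redact_plan()` exports the session
sequence with content identifiers only, so delivery can stay blind to the
selected nodes.

When one member facet of a composite is missing at an occasion the
composite uses the observed member and flags the occasion (`partial`),
rather than propagating the gap into the network fit. Missing responses
are interpolated linearly in clock time within each phase (never across a
phase boundary; edge gaps carry the nearest value), and original
missingness flags are kept so sensitivity analyses can exclude those
points instead.

## Discrete-time alternatives

The retrospective guidance grid re-runs selection under a graphical-VAR
style pipeline: each item is detrended by OLS on clock time and mapped
through the normal-scores transform \(z = \Phi^{-1}((r - 0.5)/n)\); the
lag-1 temporal matrix is estimated from *same-day* consecutive occasion
pairs only (overnight lags are dropped — an EMA convention, since a
12-hour gap is not one "lag" of a 3-hour process); and the
contemporaneous network is the partial-correlation matrix
\(\rho_{ij} = -K_{ij}/\sqrt{K_{ii}K_{jj}}\) of the temporal residuals
(occasions without a same-day predecessor contribute their marginal
values). The penalized path uses per-node lasso regressions and a
graphical lasso on the residual covariance — both selected by EBIC with
weight \(\gamma = 0.5\) over a 50-point log-spaced penalty grid with
min/max ratio 0.01; the unpenalized path keeps all edges (OLS plus the
inverse sample covariance). The graphical lasso is implemented in the
package (block coordinate descent with a coordinate-descent lasso inner
loop) and is checked in the tests against the inverse sample covariance as
the penalty vanishes. Node centralities on the contemporaneous network are
strength \(\sum_j |\rho_{ij}|\), expected influence \(\sum_j \rho_{ij}\),
and betweenness/closeness on the weighted graph with edge length
\(1/|\rho|\) (closeness is the reciprocal of summed shortest-path
distances and is 0 for any node that cannot reach every other node).
Temporal discrete-time networks are estimated but never drive guidance by
default — at single-case sample sizes they are underpowered — and the grid
records per-method failures as `NA` cells rather than aborting.

## Single-case evaluation

Tau-U compares phases nonparametrically. With phase vectors
\(A = (a_1..a_{n_A})\), \(B = (b_1..b_{n_B})\):
\(S_{AB} = \sum_{i,j} \mathrm{sign}(b_j - a_i)\), and the within-phase
Kendall statistics \(S_A, S_B\) correct for monotone trends; the
conservative variant reported by default is
\(S = S_{AB} + S_B - S_A\) with denominator
\(n_A n_B + \binom{n_B}{2} + \binom{n_A}{2}\). Ties contribute zero
everywhere. The null standard deviation is the additive combination

\[ SD_S = \sqrt{\tfrac{n_A n_B (n_A + n_B + 1)}{3}
   + \tfrac{n_B(n_B-1)(2n_B+5)}{18}
   + \tfrac{n_A(n_A-1)(2n_A+5)}{18}}, \]

with the trend terms dropped for the simpler variants, and
\(z = S/SD_S\) with a two-sided normal p-value. Under a continuous
exchangeable null the cross terms
\(\mathrm{Cov}(S_{AB}, S_B)\) vanish exactly (the per-triple
\(+\tfrac13\) and \(-\tfrac13\) contributions cancel pairwise), so the
additive formula is the exact null variance; the tests confirm the z-test
holds its nominal size and that \(SD_S\) matches a permutation null within
3%. Effect magnitudes are labelled small (< 0.2), moderately high
(0.2–0.6), high (0.6–0.8) and very high (> 0.8). Each delivered composite
phase is one SCED phase. Interpolated points count as ordinary data, with
an exclusion-based sensitivity path.

Visual-analysis metrics per contrast: overlap percent (share of
later-phase points inside the earlier phase's observed range, with a
high-overlap flag above 30%), immediacy (absolute difference between the
mean of the last five points of one phase and the first five of the next;
undefined below five points), and per-phase mean/SD/OLS slope. For
pre/post interference questionnaire scores on the 0–10 scale, a change of
at least 0.87 points flags meaningful improvement (or, symmetrically,
worsening) — a conservative minimal-important-difference threshold.

## The synthetic truth: what it emulates, and what it does not

Because per-participant EMA records from real studies of this design are
not redistributable, the package generates its own, with a known ground
truth so that every selection step can be scored exactly. The generating
model is a 7-node OU network (six facets + interference) in which node
*j* sends the same coupling `sends[j]` to every other node, so TEC order
is the sender-strength order at any positive delta — a *planted, strict*
centrality ordering that is recomputed from the stored matrices rather
than hard-coded. Defaults: decay 0.2/h (3-hour autocorrelation ≈ 0.55,
typical of affect EMA), diffusion 45 scale²/h (stationary SD ≈ 11 around
means of 40–50), measurement SD 5, and sender strengths making the
awareness pair (LPMA 0.08, SAC 0.06) a clear hub, engagement intermediate
(0.015, 0.010) and openness weakest (EA 0.006, Fusion 0.004), with
interference feeding back weakly (0.005). The ~5-fold separation between
adjacent composite ranks is a deliberate scenario choice: drift-entry
sampling noise at a 150-occasion baseline is roughly 0.1/h, so a
marginally separated hub is undetectable at single-case sample sizes and
a recovery experiment against it would only measure noise. The package's
recovery claims are therefore claims about a *clearly* hub-dominated
system observed at the study's sampling density — not about every network
a person might have.

The composite-level 4-node truth used to score stage 1 is the
block-average of the facet drift (exact when paired facets move in
unison; the member-asymmetry that orders facets within a composite makes
it an approximation, which the tests quantify only through recovery
rates). Intervention phases pull the *targeted facets'* equilibria down by
12 scale points with a 3-day linear ramp, implemented as intercept pulses
solved so the targeted facets land exactly 12 points lower; interference
receives no direct shift and declines only through the network coupling
(about 10 points at equilibrium under the defaults). Motivation
(once-daily) and pain intensity are declared affine functions of the
latent interference state plus noise — the design gives them no dynamic
role. Whole occasions go missing with probability 0.05, and values clip
to [0, 100] (the clip rate is recorded; under the defaults it stays below
1%).

Features of real EMA data the generator deliberately omits: response-time
heaping, weekday/weekend cycles, carry-over between intervention phases,
time-varying dynamics, floor effects from skewed items, and informative
missingness. Passing recovery tests therefore demonstrates that the
analysis chain is correct and adequately powered under its own
assumptions, not that those assumptions hold for any given participant.

## Numerical choices

* Matrix exponentials use scaling-and-squaring; inside the likelihood the
  propagator is built from one eigendecomposition of \(A\) per evaluation
  (with an automatic fall-back when the eigenvector basis is
  ill-conditioned), distinct gaps are cached, and runs of equal, fully
  observed gaps switch to the steady-state Kalman gain once the state
  covariance has converged (relative tolerance 1e-12).
* The Lyapunov equation is solved directly (Sylvester solver; the tests
  cross-check a Kronecker-product solve).
* Degenerate inputs fail loudly: constant items, unstable drift iterates,
  singular innovation covariances and perfectly linear series all raise
  informative errors rather than propagating NaNs; the likelihood returns
  \(-\infty\) to the optimizer for infeasible iterates instead of
  throwing.
* Desk-scale defaults: bootstrap `B = 200` for reported intervals (tests
  and the acceptance script use 20–40); recovery experiments run 100
  replicates of ~150 baseline occasions with measurement noise fixed at
  zero during fitting (measured to give identical selections ~3x faster;
  real-data analyses keep `R` freely estimated); optimizer `maxit = 500`,
  `reltol = 1e-10` (recovery: 200 / 1e-7).
* Determinism: every random draw (design randomization, simulation,
  bootstrap) flows from an explicit integer seed, and refitting the same
  data with the same seed is bit-identical.

## Known limitations

* The likelihood-plus-bootstrap backend is not a posterior; credible and
  bootstrap intervals can differ at these sample sizes, although the
  selection rule (point-estimate ranking) does not depend on the interval
  machinery.
* Composite-level networks inherit an aggregation approximation; the
  facet-level (7-node) grid methods exist partly to expose disagreements
  caused by it.
* CT-VAR drift estimates at 70–150 occasions are noisy; the package
  reports intervals and the recovery experiment quantifies how noisy,
  but single-participant selections should be read with those intervals
  in view.
* The penalized contemporaneous estimator is two-stage (nodewise lasso,
  then graphical lasso on residuals), not a joint-likelihood graphical
  VAR; with the EBIC defaults the two agree on the fixtures tested but
  can differ on small, dense networks.
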