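#' Randomize the multiple-baseline design
#'
#' Baseline length is a uniform integer in 14-20 days; the order of the
#' most-central-node intervention (MCNI) and least-central-node intervention
#' (LCNI) phases is a fair coin. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @return List with `baseline_days` and `order` (`"MCNI-first"` or
#'   `"LCNI-first"`).
#' @export
randomize_design <- function(seed) {
  set.seed(seed)
  list(baseline_days = sample(14:20, 1L),
       order = sample(c("MCNI-first", "LCNI-first"), 1L))
}

#' Map from network nodes to treatment content
#'
#' Each facet maps to two ordered session identifiers; each overarching
#' composite maps to its treatment-focus label. Content identifiers are
#' opaque.
#'
#' @return A tibble with columns `node`, `level`, `content` (list column of
#'   session ids).
#' @export
intervention_map <- function() {
  tibble::tibble(
    node = c("openness", "awareness", "engagement",
             "EA", "Fusion", "LPMA", "SAC", "LV", "Inaction"),
    level = c(rep("composite", 3), rep("facet", 6)),
    content = list("openness", "awareness", "engagement",
                   c("acceptance-1", "acceptance-2"),
                   c("defusion-1", "defusion-2"),
                   c("present-moment-awareness-1",
                     "present-moment-awareness-2"),
                   c("self-as-context-1", "self-as-context-2"),
                   c("values-clarity-1", "values-clarity-2"),
                   c("committed-action-1", "committed-action-2")))
}

facet_sessions <- function(facet) {
  m <- intervention_map()
  m$content[[match(facet, m$node)]]
}

#' Guidance-control settings
#'
#' @param delta Delta-time in hours for centrality; `NULL` uses the median
#'   inter-occasion interval of the analyzed series (computed after
#'   interpolation).
#' @param index Centrality index used for selection (`"TEC"` default).
#' @param fit_control A [ct_fit_control()] for the network fits.
#' @param use_truth Internal switch: when a [synthetic_truth()] is supplied
#'   to [guide_treatment()] instead of data, centrality is evaluated on the
#'   generating matrices directly (no fitting).
#' @return A list of class `guide_control`.
#' @export
guide_control <- function(delta = NULL, index = c("TEC", "IEC"),
                          fit_control = ct_fit_control(), use_truth = FALSE) {
  structure(list(delta = delta, index = match.arg(index),
                 fit_control = fit_control, use_truth = use_truth),
            class = "guide_control")
}

stage_fit <- function(series, nodes, config, seed, stage) {
  tryCatch(
    fit_ctvar(series, config = config$fit_control, seed = seed,
              nodes = nodes),
    error = function(e) {
      stop("guidance ", stage, " network fit failed: ",
           conditionMessage(e), call. = FALSE)
    })
}

#' Two-stage centrality-guided treatment-target selection
#'
#' Stage 1 fits a continuous-time VAR on the three overarching composites
#' plus the interference outcome and ranks the composites by centrality at
#' the chosen delta-time: the maximum becomes the MCNI composite, the
#' minimum the LCNI composite. Stage 2 fits one network per selected
#' composite on its two member facets plus interference: in the MCNI phase
#' the *most* central facet is delivered first, in the LCNI phase the
#' *least* central facet is delivered first. Baseline length and phase
#' order come from [randomize_design()] with the same seed, and the
#' facet-to-content mapping from [intervention_map()].
#'
#' @param baseline Either a single-participant [ema_series()] restricted to
#'   (or containing) the baseline phase, or a [synthetic_truth()] when
#'   `config$use_truth` is `TRUE`.
#' @param registry An [item_registry()].
#' @param config A [guide_control()].
#' @param seed Integer seed (design randomization and fits).
#' @return A `phase_plan`: baseline length, order, MCNI/LCNI composites with
#'   ordered facet and session delivery, the delta used, and the centrality
#'   tables behind each stage.
#' @export
guide_treatment <- function(baseline, registry = default_registry(),
                            config = guide_control(), seed = 1L) {
  outcome <- registry_outcome(registry)
  composites <- c("openness", "awareness", "engagement")

  if (config$use_truth) {
    stopifnot(inherits(baseline, "synthetic_truth"))
    delta <- if (is.null(config$delta)) baseline$delta_ref else config$delta
    m4 <- baseline$composite_model
    stage1 <- list(model = m4)
    stage2_model <- function(comp) {
      facet_submodel(baseline, composite_members(registry, comp))
    }
  } else {
    stopifnot(is_ema_series(baseline))
    base <- baseline[baseline$phase == "baseline", ]
    if (!nrow(base)) stop("no baseline occasions in series")
    base <- interpolate_missing(base)
    comp <- build_composites(base, registry)
    delta <- if (is.null(config$delta)) {
      median_interval(comp, items = c(composites, outcome))
    } else config$delta
    stage1 <- stage_fit(comp, c(composites, outcome), config, seed,
                        "stage-1 (composite)")
    stage1 <- list(model = stage1$model, fit = stage1)
    stage2_model <- function(cm) {
      members <- composite_members(registry, cm)
      f <- stage_fit(base, c(members, outcome), config, seed,
                     paste0("stage-2 (", cm, ")"))
      f$model
    }
  }

  cfun <- if (config$index == "TEC") tec else iec
  tab1 <- cfun(stage1$model, delta, outcome = outcome)
  ranked <- rank_central(tab1, stage1$model)
  mcni <- ranked[1]
  lcni <- ranked[length(ranked)]

  m_mod <- stage2_model(mcni)
  tab_m <- cfun(m_mod, delta, outcome = outcome)
  m_facets <- rank_central(tab_m, m_mod) # most central first

  l_mod <- stage2_model(lcni)
  tab_l <- cfun(l_mod, delta, outcome = outcome)
  l_facets <- rev(rank_central(tab_l, l_mod)) # least central first

  design <- randomize_design(seed)
  plan <- structure(list(
    baseline_days = design$baseline_days, order = design$order,
    mcni = list(composite = mcni, facets = m_facets,
                sessions = unlist(lapply(m_facets, facet_sessions))),
    lcni = list(composite = lcni, facets = l_facets,
                sessions = unlist(lapply(l_facets, facet_sessions))),
    delta = delta, index = config$index,
    centrality = list(stage1 = tab1, stage2_mcni = tab_m,
                      stage2_lcni = tab_l),
    seed = seed), class = "phase_plan")
  plan
}

#' @export
print.phase_plan <- function(x, ...) {
  cat("Phase plan (baseline", x$baseline_days, "days,", x$order, ")\n")
  cat("  MCNI:", x$mcni$composite, "- facets:",
      paste(x$mcni$facets, collapse = " then "), "\n")
  cat("  LCNI:", x$lcni$composite, "- facets:",
      paste(x$lcni$facets, collapse = " then "), "\n")
  cat("  delta =", round(x$delta, 3), "h, index =", x$index, "\n")
  invisible(x)
}

#' Redact a phase plan for blinded delivery
#'
#' Returns the plan with node names removed, keeping only the delivery
#' schedule of opaque session content identifiers.
#'
#' @param plan A `phase_plan`.
#' @return A list with `baseline_days`, `order`, and the two session
#'   sequences labelled `first_phase` / `second_phase`.
#' @export
redact_plan <- function(plan) {
  stopifnot(inherits(plan, "phase_plan"))
  seqs <- if (plan$order == "MCNI-first") {
    list(plan$mcni$sessions, plan$lcni$sessions)
  } else {
    list(plan$lcni$sessions, plan$mcni$sessions)
  }
  list(baseline_days = plan$baseline_days, order = "redacted",
       first_phase = unname(seqs[[1]]), second_phase = unname(seqs[[2]]))
}

#' Serialize a phase plan to JSON
#'
#' @param plan A `phase_plan` (or [redact_plan()] output).
#' @param path Output file.
#' @param redacted Write the redacted form.
#' @export
write_plan_json <- function(plan, path, redacted = FALSE) {
  obj <- if (redacted) redact_plan(plan) else {
    list(baseline_days = plan$baseline_days, order = plan$order,
         mcni = plan$mcni, lcni = plan$lcni, delta = plan$delta,
         index = plan$index, seed = plan$seed)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

grid_cell <- function(expr) {
  tryCatch(expr, error = function(e) NA_character_)
}

#' Alternative treatment-guiding methods grid
#'
#' Recomputes the treatment-target selection under the retrospective grid of
#' alternative procedures: CT-VAR TEC/IEC point estimates at the composite
#' (4-variable) and facet (7-variable) level, the same at a smaller
#' delta-time, the strongest CT lagged path to interference, penalized and
#' unpenalized discrete-time contemporaneous networks (strongest edge to
#' interference and strength / expected influence / betweenness / closeness
#' centralities), the facet with the highest baseline mean, and the facet
#' with the strongest absolute baseline Pearson correlation with each
#' outcome. Individual method failures are recorded as `NA` cells rather
#' than failing the grid.
#'
#' @param baseline A single-participant [ema_series()] baseline.
#' @param registry An [item_registry()].
#' @param config A [guide_control()].
#' @param seed Seed for the network fits.
#' @param small_delta_factor Smaller delta = this fraction of the median
#'   interval (default 0.25).
#' @return A tibble with columns `method`, `level` and `selected`.
#' @export
alternative_guidance_grid <- function(baseline, registry = default_registry(),
                                      config = guide_control(), seed = 1L,
                                      small_delta_factor = 0.25) {
  stopifnot(is_ema_series(baseline))
  outcome <- registry_outcome(registry)
  facets <- registry_facets(registry)
  composites <- c("openness", "awareness", "engagement")
  base <- baseline[baseline$phase == "baseline", ]
  base <- interpolate_missing(base)
  comp <- build_composites(base, registry)

  delta4 <- median_interval(comp, c(composites, outcome))
  delta7 <- median_interval(base, c(facets, outcome))

  fits <- list(
    c4 = tryCatch(fit_ctvar(comp, config$fit_control, seed,
                            nodes = c(composites, outcome)),
                  error = function(e) NULL),
    f7 = tryCatch(fit_ctvar(base, config$fit_control, seed,
                            nodes = c(facets, outcome)),
                  error = function(e) NULL))

  rows <- list()
  add <- function(method, level, selected) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      method = method, level = level, selected = selected)
  }

  for (lv in c("4", "7")) {
    fit <- if (lv == "4") fits$c4 else fits$f7
    delta <- if (lv == "4") delta4 else delta7
    level <- if (lv == "4") "composite" else "facet"
    sel <- function(tab, model) grid_cell(rank_central(tab, model)[1])
    if (is.null(fit)) {
      for (m in c("ct_tec_", "ct_iec_", "ct_tec_small_delta_",
                  "ct_iec_small_delta_", "ct_strongest_path_")) {
        add(paste0(m, lv), level, NA_character_)
      }
    } else {
      mod <- fit$model
      add(paste0("ct_tec_", lv), level,
          grid_cell(sel(tec(mod, delta, outcome), mod)))
      add(paste0("ct_iec_", lv), level,
          grid_cell(sel(iec(mod, delta, outcome), mod)))
      ds <- small_delta_factor * delta
      add(paste0("ct_tec_small_delta_", lv), level,
          grid_cell(sel(tec(mod, ds, outcome), mod)))
      add(paste0("ct_iec_small_delta_", lv), level,
          grid_cell(sel(iec(mod, ds, outcome), mod)))
      add(paste0("ct_strongest_path_", lv), level,
          grid_cell(strongest_edge_to_outcome(effect_matrix(mod, delta),
                                              outcome)))
    }
  }

  for (lv in c("4", "7")) {
    items <- if (lv == "4") c(composites, outcome) else c(facets, outcome)
    src <- if (lv == "4") comp else base
    level <- if (lv == "4") "composite" else "facet"
    rt <- tryCatch(detrend_and_transform(src, items),
                   error = function(e) NULL)
    for (pen in c(FALSE, TRUE)) {
      tag <- if (pen) "pen" else "unpen"
      net <- if (is.null(rt)) NULL else {
        tryCatch(fit_dtvar(rt, penalized = pen)$contemp,
                 error = function(e) NULL)
      }
      if (is.null(net)) {
        add(paste0("dt_", tag, "_strongest_path_", lv), level, NA_character_)
        for (idx in c("strength", "expected_influence", "betweenness",
                      "closeness")) {
          add(paste0("dt_", tag, "_", idx, "_", lv), level, NA_character_)
        }
      } else {
        add(paste0("dt_", tag, "_strongest_path_", lv), level,
            grid_cell(strongest_edge_to_outcome(net, outcome)))
        cent <- grid_cell(dt_centrality(net, outcome = outcome))
        for (idx in c("strength", "expected_influence", "betweenness",
                      "closeness")) {
          sel_idx <- if (is.character(cent)) NA_character_ else {
            v <- cent[[idx]]
            if (all(v == 0)) NA_character_
            else cent$node[order(-v, cent$node)][1]
          }
          add(paste0("dt_", tag, "_", idx, "_", lv), level, sel_idx)
        }
      }
    }
  }

  # descriptive candidates (facet level, baseline daily measures)
  wf <- ema_wide(base, facets)
  means <- colMeans(wf$Y, na.rm = TRUE)
  add("baseline_highest_mean", "facet",
      names(means)[order(-means, names(means))][1])
  for (out in c(outcome, "motivation", "pain_intensity")) {
    cell <- grid_cell({
      wo <- ema_wide(base, c(facets, out))
      co <- abs(cor(wo$Y[, facets], wo$Y[, out],
                    use = "pairwise.complete.obs"))
      if (all(!is.finite(co))) NA_character_
      else facets[order(-co, facets)][1]
    })
    add(paste0("baseline_strongest_cor_", out), "facet", cell)
  }

  do.call(rbind, rows)
}
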