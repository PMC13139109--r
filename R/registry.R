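#' Item registry for daily EMA assessments
#'
#' The registry declares every daily assessment item, its role in the
#' analysis, and its sampling cadence. The study design has one pain
#' interference outcome item, one motivation item, one pain intensity item,
#' and six psychological-inflexibility facet items that pair into three
#' overarching composites: experiential avoidance (EA) and fusion form
#' *openness*, lack of present-moment awareness (LPMA) and self-as-content
#' (SAC) form *awareness*, and lack of values clarity (LV) and inaction form
#' *engagement*.
#'
#' @param items A data frame with columns `item`, `role`, `facet`,
#'   `composite`, `cadence`. Use [default_registry()] for the study design.
#' @return An `item_registry` tibble.
#' @export
item_registry <- function(items) {
  req <- c("item", "role", "facet", "composite", "cadence")
  if (!all(req %in% names(items))) {
    stop("registry needs columns: ", paste(req, collapse = ", "))
  }
  reg <- tibble::as_tibble(items[req])
  roles <- c("outcome-interference", "motivation", "pain-intensity", "facet")
  bad <- setdiff(unique(reg$role), roles)
  if (length(bad)) stop("unknown item role(s): ", paste(bad, collapse = ", "))
  if (any(duplicated(reg$item))) stop("duplicate item names in registry")
  if (!all(reg$cadence %in% c("five-daily", "once-daily"))) {
    stop("cadence must be 'five-daily' or 'once-daily'")
  }

  fac <- reg[reg$role == "facet", ]
  if (nrow(fac) != 6L) stop("registry must define exactly six facet items")
  if (sum(reg$role == "outcome-interference") != 1L) {
    stop("registry must define exactly one outcome-interference item")
  }
  pairs <- list(openness  = c("EA", "Fusion"),
                awareness = c("LPMA", "SAC"),
                engagement = c("LV", "Inaction"))
  for (comp in names(pairs)) {
    got <- sort(fac$facet[fac$composite == comp])
    if (!identical(got, sort(pairs[[comp]]))) {
      stop("composite '", comp, "' must contain facets ",
           paste(pairs[[comp]], collapse = " + "))
    }
  }
  class(reg) <- c("item_registry", class(reg))
  reg
}

#' Default item registry for the chronic-pain EMA study design
#'
#' Eight items are assessed five times daily (pain interference, pain
#' intensity, and the six facet items); motivation is assessed once daily.
#'
#' @return An `item_registry` tibble with nine items.
#' @export
default_registry <- function() {
  item_registry(tibble::tibble(
    item = c("interference", "motivation", "pain_intensity",
             "EA", "Fusion", "LPMA", "SAC", "LV", "Inaction"),
    role = c("outcome-interference", "motivation", "pain-intensity",
             rep("facet", 6)),
    facet = c(NA, NA, NA, "EA", "Fusion", "LPMA", "SAC", "LV", "Inaction"),
    composite = c(NA, NA, NA, "openness", "openness", "awareness",
                  "awareness", "engagement", "engagement"),
    cadence = c("five-daily", "once-daily", "five-daily", rep("five-daily", 6))
  ))
}

#' @rdname item_registry
#' @param registry An object to check.
#' @export
is_item_registry <- function(registry) inherits(registry, "item_registry")

registry_outcome <- function(registry) {
  registry$item[registry$role == "outcome-interference"]
}

registry_facets <- function(registry) {
  registry$item[registry$role == "facet"]
}

#' Facet items belonging to a composite
#'
#' @param registry An [item_registry()].
#' @param composite One of `"openness"`, `"awareness"`, `"engagement"`.
#' @return Character vector of the two member facet items.
#' @export
composite_members <- function(registry, composite) {
  m <- registry$item[!is.na(registry$composite) &
                       registry$composite == composite]
  if (length(m) != 2L) stop("unknown composite: ", composite)
  m
}
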