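#' EMA series: long-format intensive-longitudinal record
#'
#' An `ema_series` is a long-format tibble with one row per participant x
#' occasion x scheduled item: columns `participant`, `time` (continuous hours
#' since study start; the response time, not the prompt time), `phase`
#' (`baseline`, `phase1`, `phase2`), `item`, `value` (0-100 visual-analogue
#' scale, `NA` for a missed response), and `observed` (`FALSE` where the
#' response was originally missing; interpolation fills `value` but never
#' flips this flag). Occasions are sorted by time; phases must be contiguous
#' and in study order.
#'
#' @param x A data frame with the columns above (`observed` optional;
#'   inferred as `!is.na(value)`).
#' @param registry Optional [item_registry()]; unknown items are rejected.
#' @return A validated `ema_series` tibble.
#' @export
ema_series <- function(x, registry = NULL) {
  req <- c("participant", "time", "phase", "item", "value")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  x <- tibble::as_tibble(x)
  if (!"observed" %in% names(x)) x$observed <- !is.na(x$value)
  x <- x[c(req, "observed")]
  x$participant <- as.character(x$participant)
  x$phase <- as.character(x$phase)
  x$item <- as.character(x$item)
  x$value <- as.numeric(x$value)

  phases <- c("baseline", "phase1", "phase2")
  bad <- which(!x$phase %in% phases)
  if (length(bad)) stop("row ", bad[1], ": unknown phase '", x$phase[bad[1]], "'")
  bad <- which(!is.na(x$value) & (x$value < 0 | x$value > 100))
  if (length(bad)) {
    stop("row ", bad[1], ": value ", x$value[bad[1]], " outside [0, 100]")
  }
  if (!is.null(registry)) {
    bad <- which(!x$item %in% registry$item)
    if (length(bad)) stop("row ", bad[1], ": unknown item '", x$item[bad[1]], "'")
  }
  bad <- which(!is.finite(x$time))
  if (length(bad)) stop("row ", bad[1], ": non-finite timestamp")

  x <- x[order(x$participant, x$time, x$item), ]
  dup <- duplicated(x[c("participant", "time", "item")])
  if (any(dup)) {
    stop("duplicate rows (participant, time, item) — timestamps must be ",
         "strictly increasing per item")
  }
  for (pid in unique(x$participant)) {
    sub <- x[x$participant == pid, ]
    occ <- unique(sub[c("time", "phase")])
    if (any(duplicated(occ$time))) {
      stop("participant ", pid, ": occasion with conflicting phase labels")
    }
    occ <- occ[order(occ$time), ]
    if (any(diff(occ$time) <= 0)) {
      stop("participant ", pid, ": timestamps not strictly increasing")
    }
    idx <- match(occ$phase, phases)
    if (any(diff(idx) < 0)) {
      stop("participant ", pid, ": phases out of order (must be baseline, ",
           "phase1, phase2)")
    }
  }
  class(x) <- unique(c("ema_series", class(x)))
  x
}

#' @rdname ema_series
#' @export
is_ema_series <- function(x) inherits(x, "ema_series")

#' Read / write long-format EMA tables
#'
#' The file dialect is UTF-8 comma-delimited text with a header and columns
#' `participant`, `timestamp`, `phase`, `item`, `value`. Timestamps are
#' numeric hours since study start or ISO-8601 date-times (converted to hours
#' since the participant's first record). An empty `value` is a missed
#' response.
#'
#' @param path File path.
#' @param registry Optional [item_registry()] used to reject unknown items.
#' @return [read_ema()] returns a validated [ema_series()];
#'   [write_ema()] returns `path` invisibly.
#' @export
read_ema <- function(path, registry = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("participant", "timestamp", "phase", "item", "value")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("malformed file: missing column(s) ",
                         paste(miss, collapse = ", "))
  n <- nrow(raw)
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  if (anyNA(ts)) {
    # fall back to ISO-8601; hours since each participant's first record
    dt <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d %H:%M", "%Y-%m-%d"))
    bad <- which(is.na(dt))
    if (length(bad)) stop("row ", bad[1], ": unparseable timestamp '",
                          raw$timestamp[bad[1]], "'")
    ts <- rep(NA_real_, n)
    for (pid in unique(raw$participant)) {
      i <- raw$participant == pid
      ts[i] <- as.numeric(difftime(dt[i], min(dt[i]), units = "hours"))
    }
  }
  val <- ifelse(raw$value == "" | is.na(raw$value), NA_character_, raw$value)
  num <- suppressWarnings(as.numeric(val))
  bad <- which(!is.na(val) & is.na(num))
  if (length(bad)) stop("row ", bad[1], ": non-numeric value '", val[bad[1]], "'")
  ema_series(data.frame(participant = raw$participant, time = ts,
                        phase = raw$phase, item = raw$item, value = num),
             registry = registry)
}

#' @rdname read_ema
#' @param series An [ema_series()].
#' @export
write_ema <- function(series, path) {
  stopifnot(is_ema_series(series))
  out <- data.frame(participant = series$participant,
                    timestamp = series$time, phase = series$phase,
                    item = series$item, value = series$value)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Build overarching-composite series from facet items
#'
#' Each composite value is the arithmetic mean of its two member facets at
#' that occasion (preserving the 0-100 scale). When exactly one member is
#' missing, the observed member is used and the occasion is flagged in the
#' `partial` column; when both are missing the composite is missing.
#' Non-facet items (outcome, motivation, pain intensity) pass through
#' unchanged with `partial = FALSE`.
#'
#' @param series An [ema_series()].
#' @param registry An [item_registry()] defining all six facets.
#' @return A `composite_series` (an [ema_series()] with items `openness`,
#'   `awareness`, `engagement` and the pass-through items, plus a `partial`
#'   flag column).
#' @export
build_composites <- function(series, registry) {
  stopifnot(is_ema_series(series), is_item_registry(registry))
  fac <- registry_facets(registry)
  keep <- series[!series$item %in% fac, ]
  keep$partial <- FALSE

  comps <- lapply(c("openness", "awareness", "engagement"), function(comp) {
    mem <- composite_members(registry, comp)
    sub <- series[series$item %in% mem, ]
    if (nrow(sub) == 0L) return(NULL)
    key <- paste(sub$participant, sub$time)
    vals <- tapply(sub$value, key, function(v) mean(v, na.rm = TRUE))
    nobs <- tapply(!is.na(sub$value), key, sum)
    first <- !duplicated(key)
    ord <- match(unique(key), key[first])
    base <- sub[first, ][ord, ]
    k <- match(paste(base$participant, base$time), names(vals))
    tibble::tibble(participant = base$participant, time = base$time,
                   phase = base$phase, item = comp,
                   value = unname(ifelse(nobs[k] > 0, vals[k], NA_real_)),
                   observed = unname(nobs[k] > 0),
                   partial = unname(nobs[k] == 1L))
  })
  all <- rbind(keep, do.call(rbind, comps))
  all <- all[order(all$participant, all$time, all$item), ]
  out <- ema_series(all[setdiff(names(all), "partial")])
  out$partial <- all$partial
  class(out) <- unique(c("composite_series", class(out)))
  out
}

#' Interpolate missing EMA responses
#'
#' Missing values are filled by linear interpolation in clock time between
#' the nearest non-missing neighbours of the same item *within the same
#' phase*; leading/trailing gaps within a phase are filled by carrying the
#' nearest observed value. Values are never interpolated across a phase
#' boundary, and the original `observed` flags are retained.
#'
#' @param series An [ema_series()].
#' @return The series with all missing values filled.
#' @export
interpolate_missing <- function(series) {
  stopifnot(is_ema_series(series))
  out <- series
  idx <- split(seq_len(nrow(series)),
               list(series$participant, series$item, series$phase),
               drop = TRUE)
  for (i in idx) {
    v <- series$value[i]
    if (!anyNA(v)) next
    if (all(is.na(v))) {
      stop("item '", series$item[i[1]], "' entirely missing in phase '",
           series$phase[i[1]], "' for participant ",
           series$participant[i[1]])
    }
    out$value[i] <- zoo::na.approx(v, x = series$time[i], na.rm = FALSE,
                                   rule = 2)
  }
  out
}

#' Pivot an EMA series to an occasions-by-items matrix
#'
#' Keeps occasions at which at least one of the requested items is scheduled;
#' unscheduled or missing responses become `NA`.
#'
#' @param series An [ema_series()] (single participant).
#' @param items Items to keep (default: all items present).
#' @return A list with `times`, `phase`, and numeric matrix `Y`
#'   (occasions x items).
#' @export
ema_wide <- function(series, items = NULL) {
  stopifnot(is_ema_series(series))
  if (length(unique(series$participant)) != 1L) {
    stop("ema_wide expects a single participant")
  }
  if (is.null(items)) items <- unique(series$item)
  sub <- series[series$item %in% items, ]
  if (nrow(sub) == 0L) stop("no rows for requested items")
  times <- sort(unique(sub$time))
  Y <- matrix(NA_real_, length(times), length(items),
              dimnames = list(NULL, items))
  Y[cbind(match(sub$time, times), match(sub$item, items))] <- sub$value
  phase <- sub$phase[match(times, sub$time)]
  list(times = times, phase = phase, Y = Y)
}

#' Median inter-occasion interval of a series
#'
#' The delta-time used for lagged-effect centrality defaults to this value,
#' computed on the occasion grid of the requested items.
#'
#' @param series An [ema_series()] (single participant).
#' @param items Items whose shared occasion grid defines the intervals.
#' @return Median gap in hours.
#' @export
median_interval <- function(series, items = NULL) {
  w <- ema_wide(series, items)
  median(diff(w$times))
}
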