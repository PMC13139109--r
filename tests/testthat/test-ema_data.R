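test_that("registry validates the facet/composite structure", {
  reg <- default_registry()
  expect_s3_class(reg, "item_registry")
  expect_length(registry_facets(reg), 6)
  expect_identical(registry_outcome(reg), "interference")
  expect_setequal(composite_members(reg, "openness"), c("EA", "Fusion"))
  expect_setequal(composite_members(reg, "awareness"), c("LPMA", "SAC"))
  expect_setequal(composite_members(reg, "engagement"), c("LV", "Inaction"))

  bad <- tibble::as_tibble(reg)
  bad$composite[bad$item == "LV"] <- "awareness"
  expect_error(item_registry(bad), "composite")
})

test_that("series validation rejects bad values, phases and timestamps", {
  expect_error(make_series(list(a = c(10, 101, 20))), "outside")
  df <- tibble::tibble(participant = "p", time = c(1, 2, 3),
                       phase = c("baseline", "phase1", "baseline"),
                       item = "a", value = 1)
  expect_error(ema_series(df), "phases out of order")
  df2 <- tibble::tibble(participant = "p", time = c(2, 2), phase = "baseline",
                        item = "a", value = 1:2)
  expect_error(ema_series(df2), "strictly increasing|conflicting")
})

test_that("read/write round-trips a table, rejecting malformed input", {
  s <- make_series(list(interference = c(10, NA, 30),
                        EA = c(5, 15, 25)),
                   times = c(0, 3.5, 6),
                   phase = rep("baseline", 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ema(s, f)
  s2 <- read_ema(f, registry = default_registry())
  expect_equal(s2$value, s$value)
  expect_equal(s2$time, s$time)
  expect_equal(s2$observed, s$observed)

  # out-of-range value named by row
  bad <- read.csv(f)
  bad$value[1] <- 101
  write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(read_ema(f), "outside \\[0, 100\\]")

  # ISO-8601 timestamps accepted
  iso <- data.frame(participant = "p1",
                    timestamp = c("2026-01-01T08:00:00",
                                  "2026-01-01T11:30:00"),
                    phase = "baseline", item = "EA", value = c(10, 20))
  write.csv(iso, f, row.names = FALSE)
  s3 <- read_ema(f)
  expect_equal(s3$time, c(0, 3.5))
})

test_that("composites average the member facets and flag partial occasions", {
  s <- make_series(list(EA = c(10, 10, NA), Fusion = c(30, NA, NA),
                        LPMA = c(20, 20, 20), SAC = c(40, 40, 40),
                        LV = c(10, 20, 30), Inaction = c(50, 40, 30),
                        interference = c(60, 60, 60)))
  cs <- build_composites(s, default_registry())
  op <- cs[cs$item == "openness", ]
  expect_equal(op$value, c(20, 10, NA_real_))
  expect_equal(op$partial, c(FALSE, TRUE, FALSE))
  expect_equal(op$observed, c(TRUE, TRUE, FALSE))
  expect_equal(cs$value[cs$item == "awareness"], c(30, 30, 30))
  expect_equal(cs$value[cs$item == "engagement"], c(30, 30, 30))
  # outcome passes through unchanged
  expect_equal(cs$value[cs$item == "interference"], c(60, 60, 60))
})

test_that("composite means match hand arithmetic on baseline facet means", {
  # facet-level baseline means in the style of the worked example:
  # EA 14.2 and Fusion 48.2 average to an openness mean of 31.2
  s <- make_series(list(EA = c(14.2, 14.2), Fusion = c(48.2, 48.2)))
  reg <- default_registry()
  sf <- make_series(list(EA = c(14.2, 14.2), Fusion = c(48.2, 48.2),
                         LPMA = c(1, 1), SAC = c(1, 1), LV = c(1, 1),
                         Inaction = c(1, 1), interference = c(1, 1)))
  cs <- build_composites(sf, reg)
  expect_equal(mean(cs$value[cs$item == "openness"]), 31.2)
})

test_that("interpolation is linear in clock time and phase-bounded", {
  s <- make_series(list(a = c(10, NA, 20)), times = c(0, 1, 2))
  expect_equal(interpolate_missing(s)$value, c(10, 15, 20))

  # two consecutive gaps between 0 and 30 at unit spacing -> 10 and 20
  s2 <- make_series(list(a = c(0, NA, NA, 30)), times = 0:3)
  expect_equal(interpolate_missing(s2)$value, c(0, 10, 20, 30))

  # linear in time, not occasion index
  s3 <- make_series(list(a = c(0, NA, 30)), times = c(0, 1, 3))
  expect_equal(interpolate_missing(s3)$value[2], 10)

  # missing at the phase edge filled by carry from its own phase only
  s4 <- make_series(list(a = c(10, 10, NA, 50, 60)),
                    phase = c("baseline", "baseline", "baseline",
                              "phase1", "phase1"))
  expect_equal(interpolate_missing(s4)$value[3], 10)

  # original missingness flags retained
  expect_false(interpolate_missing(s)$observed[2])

  # entirely missing item within a phase errors with item and phase
  s5 <- make_series(list(a = c(NA, NA, 10)),
                    phase = c("baseline", "baseline", "phase1"))
  expect_error(interpolate_missing(s5), "'a' entirely missing.*baseline")
})

test_that("interpolation is idempotent and identity on complete series", {
  s <- make_series(list(a = c(1, NA, 5, NA, NA, 9), b = c(2, 2, NA, 4, 4, 4)),
                   times = c(0, 1, 2, 4, 7, 8))
  once <- interpolate_missing(s)
  expect_identical(interpolate_missing(once), once)
  expect_identical(interpolate_missing(once)$value, once$value)
  full <- make_series(list(a = 1:5 * 1.0))
  expect_identical(interpolate_missing(full), full)
})

test_that("build_composites commutes with occasion subsetting", {
  s <- sim_baseline(days = 14, seed = 42)
  reg <- default_registry()
  keep_times <- sort(unique(s$time))[1:30]
  sub_first <- build_composites(
    ema_series(s[s$time %in% keep_times, ]), reg)
  full <- build_composites(s, reg)
  sub_after <- full[full$time %in% keep_times, ]
  expect_equal(sub_first$value, sub_after$value)
  expect_equal(sub_first$item, sub_after$item)
})
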