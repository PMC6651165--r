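sessions_of_durations <- function(durations,
                                  t0 = as.POSIXct("2017-04-05 08:00:00",
                                                  tz = TEST_ZONE)) {
  k <- length(durations)
  starts <- t0 + cumsum(c(0, head(durations, -1) + 60))
  tibble::tibble(
    participant_id = "P1",
    session_id = sprintf("P1#%04d", seq_len(k)),
    start = starts, end = starts + durations,
    duration_s = as.numeric(durations), split_of = NA_character_)
}

test_that("notification cut-point retains strictly longer sessions only", {
  s <- sessions_of_durations(c(4, 18, 300))
  expect_equal(apply_notification_cutpoint(s, 20)$duration_s, 300)
  # a session lasting exactly the cut-point is treated as a notification
  s20 <- sessions_of_durations(c(20, 21))
  expect_equal(apply_notification_cutpoint(s20, 20)$duration_s, 21)
  # cut-point 0 removes only zero-duration blips
  s0 <- sessions_of_durations(c(0, 1, 50))
  expect_equal(apply_notification_cutpoint(s0, 0)$duration_s, c(1, 50))
  expect_error(apply_notification_cutpoint(s, -1), "non-negative")
})

test_that("retained totals are monotone non-increasing in the cut-point", {
  withr::with_seed(8, s <- sessions_of_durations(stats::runif(500, 0, 60)))
  totals <- vapply(c(0, 5, 10, 15, 20), function(cp) {
    got <- apply_notification_cutpoint(s, cp)
    # enumeration oracle
    expect_equal(sort(got$duration_s), sort(s$duration_s[s$duration_s > cp]))
    sum(got$duration_s)
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("continuous-usage cap removes whole sessions above the cap", {
  s <- sessions_of_durations(c(30 * 60, 90 * 60, 5 * 3600))
  expect_equal(apply_continuous_usage_cap(s, 1)$duration_s, 30 * 60)
  expect_identical(apply_continuous_usage_cap(s, NA), s)
  expect_error(apply_continuous_usage_cap(s, 0), "positive")
})

test_that("tighter caps retain nested session sets", {
  withr::with_seed(9, s <- sessions_of_durations(stats::runif(300, 0, 7 * 3600)))
  kept <- lapply(c(6, 5, 4, 3, 2, 1), function(cap) {
    got <- apply_continuous_usage_cap(s, cap)
    expect_equal(sort(got$session_id),
                 sort(s$session_id[s$duration_s <= cap * 3600]))
    got$session_id
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("notification and continuous-usage filters commute", {
  withr::with_seed(10, s <- sessions_of_durations(stats::runif(200, 0, 3 * 3600)))
  a <- apply_continuous_usage_cap(apply_notification_cutpoint(s, 15), 2)
  b <- apply_notification_cutpoint(apply_continuous_usage_cap(s, 2), 15)
  expect_identical(a, b)
})

test_that("the 10 h/day rule keeps the 600-minute boundary day", {
  days <- tibble::tibble(
    participant_id = "P1",
    local_date = as.Date("2017-04-05") + 0:2,
    day_type = "weekday",
    total_minutes = c(590, 610, 600),
    n_sessions = 1L, longest_session_min = 1)
  kept <- apply_daily_rule(days, "exclude_gt_10h")
  expect_equal(kept$total_minutes, c(590, 600))
  expect_identical(apply_daily_rule(days, "include_all"), days)
})

test_that("filter_config validates the published level sets", {
  expect_error(filter_config(notification_cutpoint_s = 7), "one of")
  expect_error(filter_config(continuous_usage_cap_h = 8), "no-threshold")
  cfg <- filter_config(20, 2, "exclude_gt_10h")
  expect_s3_class(cfg, "filter_config")
})

test_that("the default grid covers 5 x 7 x 2 cells twice over day types", {
  cohort <- toy_cohort()
  g <- run_grid(cohort$sessions, cohort$subjective, zone = TEST_ZONE)
  expect_equal(nrow(g), 5 * 7 * 2 * 2)
  expect_equal(length(unique(g$cutpoint_s)), 5)
  expect_equal(length(unique(g$cap_h)), 7)
  expect_equal(sort(unique(g$daily_rule)),
               c("exclude_gt_10h", "include_all"))
  expect_equal(sort(unique(g$day_type)), c("weekday", "weekend"))
  expect_error(run_grid(cohort$sessions, cohort$subjective,
                        grid_spec(numeric(0), NA)), )
})

test_that("grid cells match a straight-line brute-force recomputation", {
  for (seed in c(42, 43, 44)) {
    cohort <- toy_cohort(n_participants = 3, seed = seed)
    g <- run_grid(cohort$sessions, cohort$subjective, zone = TEST_ZONE)
    for (r in sample(seq_len(nrow(g)), 30)) {
      row <- g[r, ]
      want <- oracle_grid_cell(cohort$sessions, cohort$subjective[
        cohort$subjective$period == row$day_type, ],
        row$cutpoint_s, row$cap_h, row$daily_rule, row$day_type, TEST_ZONE)
      expect_equal(row$n, want$n)
      if (want$n > 0) {
        expect_equal(row$obj_mean, want$obj_mean, tolerance = 1e-8)
        expect_equal(row$obj_sd, want$obj_sd, tolerance = 1e-8)
        expect_equal(row$subj_mean, want$subj_mean, tolerance = 1e-8)
      }
    }
  }
})

test_that("with no filters the cohort total equals the sessionizer total", {
  cohort <- toy_cohort()
  s <- cohort$sessions
  f <- split_at_day_boundaries(
    apply_continuous_usage_cap(apply_notification_cutpoint(s, 0), NA),
    TEST_ZONE)
  days <- apply_daily_rule(daily_totals(f, TEST_ZONE), "include_all")
  expect_equal(sum(days$total_minutes) * 60,
               sum(s$duration_s[s$duration_s > 0]), tolerance = 1e-9)
})

test_that("per-day totals never increase as the cut-point tightens", {
  cohort <- toy_cohort(seed = 7)
  day_tbl <- function(cp) {
    f <- split_at_day_boundaries(
      apply_notification_cutpoint(cohort$sessions, cp), TEST_ZONE)
    d <- daily_totals(f, TEST_ZONE)
    stats::setNames(d$total_minutes, paste(d$participant_id, d$local_date))
  }
  prev <- day_tbl(0)
  for (cp in c(5, 10, 15, 20)) {
    cur <- day_tbl(cp)
    common <- intersect(names(prev), names(cur))
    expect_true(all(cur[common] <= prev[common] + 1e-9))
    # days can only disappear, never appear, as the cut-point tightens
    expect_true(all(names(cur) %in% names(prev)))
    prev <- cur
  }
})

test_that("cell means decrease in cut-point and the no-threshold row dominates", {
  sim <- simulate_cohort(simulation_config(n_participants = 8, seed = 21))
  s <- sessionize(sim$events)
  g <- run_grid(s, sim$questionnaire, zone = sim$config$zone)
  by_cell <- split(g, list(g$day_type, g$daily_rule, g$cap_h), drop = TRUE)
  for (cell in by_cell) {
    cell <- cell[order(cell$cutpoint_s), ]
    expect_true(all(diff(cell$obj_mean) <= 1e-9))
  }
  # the uncapped row dominates every capped row, cut-point by cut-point
  for (dt in c("weekday", "weekend")) {
    for (rule in unique(g$daily_rule)) {
      sub <- g[g$day_type == dt & g$daily_rule == rule, ]
      free <- sub[is.na(sub$cap_h), ]
      for (cap in stats::na.omit(unique(sub$cap_h))) {
        capped <- sub[!is.na(sub$cap_h) & sub$cap_h == cap, ]
        m <- merge(as.data.frame(free[c("cutpoint_s", "obj_mean")]),
                   as.data.frame(capped[c("cutpoint_s", "obj_mean")]),
                   by = "cutpoint_s")
        expect_true(all(m$obj_mean.x >= m$obj_mean.y - 1e-9))
      }
    }
  }
})

test_that("formatted report prints four tables with the grid layout", {
  cohort <- toy_cohort()
  g <- run_grid(cohort$sessions, cohort$subjective, zone = TEST_ZONE)
  txt <- format_comparison_tables(g)
  expect_equal(lengths(regmatches(txt, gregexpr("Objective screen-state", txt))),
               4)
  expect_match(txt, "No threshold")
  expect_match(txt, "No filter")
})
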