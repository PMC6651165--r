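#' Run the full screen-state pipeline and write its artifacts
#'
#' Reads (or accepts in-memory) a screen-event stream and questionnaire,
#' sessionizes, evaluates the full cut-point sensitivity grid, and writes
#' to `out_dir`: `sessions.csv` (day-split sessions), `day_records.csv`,
#' `participants.csv` (inclusion summary at the unfiltered cell),
#' `grid.csv` (tidy grid results), `tables.txt` (the four formatted
#' comparison tables), `correlation_panel.csv`, and `manifest.json`
#' (inputs, configuration, drop and exclusion counts). Identical inputs
#' and configuration produce identical artifacts.
#'
#' @param events Path to an event CSV, or a [screen_events] tibble.
#' @param questionnaire Path to a questionnaire CSV, or a response tibble.
#' @param out_dir Output directory (created if missing).
#' @param zone Olson timezone for day attribution.
#' @param grid A [grid_spec()].
#' @param item_set Smartphone questionnaire items, see [smartphone_items()].
#' @param alpha Two-sided significance level.
#' @param gap_threshold_h App-off gap threshold, hours.
#' @param panel_cutpoint_s Notification cut-point for the correlation
#'   panel export.
#' @param strict Strict event parsing (see [read_events()]).
#' @return Invisibly, a list with the in-memory `sessions`, `day_records`,
#'   `summaries`, `grid`, `panel` and `manifest`.
#' @export
run_pipeline <- function(events, questionnaire, out_dir,
                         zone = "America/Regina",
                         grid = grid_spec(),
                         item_set = smartphone_items(),
                         alpha = 0.05,
                         gap_threshold_h = 24,
                         panel_cutpoint_s = 20,
                         strict = FALSE) {
  stream <- if (is.character(events)) {
    read_events(events, strict = strict, default_zone = zone)
  } else events
  responses <- if (is.character(questionnaire)) {
    read_questionnaire(questionnaire)
  } else questionnaire

  sessions <- sessionize(stream)
  coverage <- app_off_report(stream, gap_threshold_h = gap_threshold_h)
  frags <- split_at_day_boundaries(sessions, zone)
  day_records <- daily_totals(frags, zone)
  summaries <- apply_inclusion_criteria(day_records, coverage = coverage)
  grid_result <- run_grid(sessions, responses, grid = grid, zone = zone,
                          coverage = coverage, item_set = item_set,
                          alpha = alpha)
  panel <- correlation_panel(grid_result, cutpoint_s = panel_cutpoint_s)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sess_out <- frags
  sess_out$start <- format_utc(sess_out$start)
  sess_out$end <- format_utc(sess_out$end)
  readr::write_csv(sess_out, file.path(out_dir, "sessions.csv"),
                   progress = FALSE)
  readr::write_csv(day_records, file.path(out_dir, "day_records.csv"),
                   progress = FALSE)
  readr::write_csv(summaries, file.path(out_dir, "participants.csv"),
                   progress = FALSE)
  readr::write_csv(grid_result, file.path(out_dir, "grid.csv"),
                   progress = FALSE)
  writeLines(format_comparison_tables(grid_result),
             file.path(out_dir, "tables.txt"))
  readr::write_csv(panel, file.path(out_dir, "correlation_panel.csv"),
                   progress = FALSE)

  drops <- attr(sessions, "drops")
  manifest <- list(
    package_version = as.character(utils::packageVersion("screenstate")),
    zone = zone,
    alpha = alpha,
    gap_threshold_h = gap_threshold_h,
    item_set = item_set,
    grid = list(notification_levels = grid$notification_levels,
                cap_levels = grid$cap_levels,
                daily_rules = grid$daily_rules),
    n_events = nrow(stream),
    n_sessions = nrow(sessions),
    event_drops = attr(stream, "provenance")$n_dropped %||% 0,
    sessionizer_drops = list(
      duplicate_on = sum(drops$n_duplicate_on),
      orphan_off = sum(drops$n_orphan_off),
      trailing_on = sum(drops$n_trailing_on)
    ),
    n_participants_seen = dplyr::n_distinct(stream$participant_id),
    n_excluded_app_off = sum(coverage$app_off)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sessions = frags, day_records = day_records,
                 summaries = summaries, grid = grid_result, panel = panel,
                 manifest = manifest))
}

format_utc <- function(t) {
  format(lubridate::with_tz(t, "UTC"), "%Y-%m-%dT%H:%M:%OS6+00:00")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
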