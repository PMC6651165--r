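#' Daily screen-state totals
#'
#' Sums day-split session fragments into one record per participant per
#' local calendar day that has at least one retained fragment. Days with no
#' retained screen-state are absent, never zero-filled: a zero would drag
#' participant means down for days the app may simply not have observed.
#' Totals are exact in seconds and reported in minutes.
#'
#' @param sessions Day-split sessions from [split_at_day_boundaries()]
#'   (each fragment must lie within one local day; a session spanning a
#'   boundary is an error).
#' @param zone Olson timezone used for the weekday/weekend label.
#' @return A tibble `participant_id, local_date, day_type, total_minutes,
#'   n_sessions, longest_session_min` with `day_type` `"weekend"` iff the
#'   date falls on Saturday or Sunday in `zone`.
#' @export
daily_totals <- function(sessions, zone) {
  if (nrow(sessions) > 0) {
    end_date <- local_dates(sessions$end, zone)
    start_date <- local_dates(sessions$start, zone)
    spans <- end_date > start_date &
      !at_local_midnight(sessions$end, zone)
    if (any(spans)) {
      stop("unsplit session spans a day boundary: ",
           sessions$session_id[which(spans)[1]],
           " (run split_at_day_boundaries first)", call. = FALSE)
    }
  }
  local_date <- if ("local_date" %in% names(sessions)) {
    sessions$local_date
  } else {
    local_dates(sessions$start, zone)
  }
  sessions |>
    dplyr::mutate(local_date = local_date) |>
    dplyr::group_by(.data$participant_id, .data$local_date) |>
    dplyr::summarise(
      total_minutes = sum(.data$duration_s) / 60,
      n_sessions = dplyr::n(),
      longest_session_min = max(.data$duration_s) / 60,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      day_type = ifelse(lubridate::wday(.data$local_date, week_start = 1) >= 6,
                        "weekend", "weekday"),
      .after = "local_date"
    )
}

#' Detect app-off gaps in an event stream
#'
#' Operationalizes "did not turn off the app during the study window" as:
#' no gap between consecutive events of a participant longer than
#' `gap_threshold_h`. The threshold is configurable; the default of 24 h
#' tolerates an overnight idle phone while catching multi-day silences.
#'
#' @param stream A [screen_events] tibble.
#' @param gap_threshold_h Maximum tolerated gap, hours.
#' @return A tibble `participant_id, max_gap_h, app_off`.
#' @export
app_off_report <- function(stream, gap_threshold_h = 24) {
  stream |>
    dplyr::arrange(.data$participant_id, .data$timestamp) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      max_gap_h = if (dplyr::n() < 2) 0 else
        max(as.numeric(diff(.data$timestamp), units = "secs")) / 3600,
      .groups = "drop"
    ) |>
    dplyr::mutate(app_off = .data$max_gap_h > gap_threshold_h)
}

#' Per-participant means and inclusion decision
#'
#' Computes weekday/weekend day counts and mean daily minutes per
#' participant (over days *with* data only; a participant with no weekend
#' days has an absent weekend mean, not zero), then applies the inclusion
#' criteria: screen-state data on at least 2 weekdays and at least 1
#' weekend day, and not flagged by the app-off coverage report. Because "a
#' day with data" means at least one retained session after filtering,
#' inclusion is evaluated per grid cell and `n` can vary across cells.
#'
#' @param day_records Day records from [daily_totals()] (post-filter).
#' @param coverage Optional tibble from [app_off_report()]. Flagged
#'   participants are excluded regardless of day counts.
#' @param min_weekdays,min_weekend_days Inclusion thresholds.
#' @return A tibble `participant_id, n_weekday_days, n_weekend_days,
#'   mean_weekday_min, mean_weekend_min, included, exclusion_reason`.
#' @export
apply_inclusion_criteria <- function(day_records, coverage = NULL,
                                     min_weekdays = 2, min_weekend_days = 1) {
  summaries <- participant_means(day_records)
  summaries$included <- summaries$n_weekday_days >= min_weekdays &
    summaries$n_weekend_days >= min_weekend_days
  summaries$exclusion_reason <- ifelse(
    summaries$included, NA_character_, "insufficient_days")
  if (!is.null(coverage)) {
    off <- coverage$participant_id[coverage$app_off]
    hit <- summaries$participant_id %in% off
    summaries$included[hit] <- FALSE
    summaries$exclusion_reason[hit] <- "app_off_gap"
  }
  summaries
}

#' Per-participant weekday/weekend means
#'
#' Arithmetic mean of daily totals over observed days, separately for
#' weekdays and weekend days. Undefined means (no observed day of that
#' type) are `NA`, never zero.
#'
#' @param day_records Day records from [daily_totals()].
#' @return A tibble `participant_id, n_weekday_days, n_weekend_days,
#'   mean_weekday_min, mean_weekend_min`.
#' @export
participant_means <- function(day_records) {
  day_records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_weekday_days = sum(.data$day_type == "weekday"),
      n_weekend_days = sum(.data$day_type == "weekend"),
      mean_weekday_min = mean_or_na(
        .data$total_minutes[.data$day_type == "weekday"]),
      mean_weekend_min = mean_or_na(
        .data$total_minutes[.data$day_type == "weekend"]),
      .groups = "drop"
    )
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Cohort mean and SD of participant means
#'
#' Cross-participant mean and sample standard deviation (n - 1
#' denominator) of the per-participant daily means, for one day type,
#' over included participants.
#'
#' @param summaries Participant summaries from [apply_inclusion_criteria()].
#' @param day_type `"weekday"` or `"weekend"`.
#' @return A list `mean`, `sd`, `n`. `sd` is `NA` when `n < 2`.
#' @export
cohort_summary <- function(summaries, day_type = c("weekday", "weekend")) {
  day_type <- match.arg(day_type)
  col <- if (day_type == "weekday") "mean_weekday_min" else "mean_weekend_min"
  x <- summaries[[col]][summaries$included]
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("no included participants with ", day_type,
                           " data", call. = FALSE)
  list(mean = mean(x),
       sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
       n = length(x))
}
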