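NOTIFICATION_LEVELS <- c(0, 5, 10, 15, 20)   # seconds; 0 = no filter
CAP_LEVELS <- c(6, 5, 4, 3, 2, 1, NA)        # hours; NA = no-threshold
DAILY_RULES <- c("include_all", "exclude_gt_10h")

#' One cell of the cut-point sensitivity grid
#'
#' A notification cut-point (minimum valid session duration, screening out
#' auto-notification blips that light the screen without real use), a
#' continuous-usage cap (maximum plausible session duration, screening out
#' stuck-screen device errors) and a daily rule (whether participant-days
#' totalling more than 10 h of screen-state are kept or excluded).
#'
#' @param notification_cutpoint_s One of 0 (no filter), 5, 10, 15, 20
#'   seconds. Sessions are retained when `duration_s > cutpoint`.
#' @param continuous_usage_cap_h One of 6, 5, 4, 3, 2, 1 hours or `NA`
#'   (no-threshold). Sessions are retained when `duration_s <= cap`.
#' @param daily_rule `"include_all"` or `"exclude_gt_10h"` (drop
#'   participant-days with more than 600 min of screen-state).
#' @return A `filter_config` list.
#' @export
filter_config <- function(notification_cutpoint_s = 0,
                          continuous_usage_cap_h = NA,
                          daily_rule = c("include_all", "exclude_gt_10h")) {
  if (!notification_cutpoint_s %in% NOTIFICATION_LEVELS) {
    stop("notification_cutpoint_s must be one of ",
         paste(NOTIFICATION_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (!(is.na(continuous_usage_cap_h) ||
        continuous_usage_cap_h %in% CAP_LEVELS)) {
    stop("continuous_usage_cap_h must be NA (no-threshold) or one of 6..1 h",
         call. = FALSE)
  }
  daily_rule <- match.arg(daily_rule)
  structure(list(notification_cutpoint_s = notification_cutpoint_s,
                 continuous_usage_cap_h = continuous_usage_cap_h,
                 daily_rule = daily_rule),
            class = "filter_config")
}

#' The full sensitivity grid
#'
#' Defaults reproduce the 5 notification levels x 7 continuous-usage levels
#' x 2 daily rules of the published sensitivity analysis; each combination
#' is evaluated for weekdays and weekend days separately.
#'
#' @param notification_levels Seconds; 0 means no filter.
#' @param cap_levels Hours; `NA` means no-threshold. Kept in table order
#'   (6 h down to 1 h, then no-threshold).
#' @param daily_rules Subset of `c("include_all", "exclude_gt_10h")`.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(notification_levels = NOTIFICATION_LEVELS,
                      cap_levels = CAP_LEVELS,
                      daily_rules = DAILY_RULES) {
  stopifnot(length(notification_levels) > 0, length(cap_levels) > 0,
            all(daily_rules %in% DAILY_RULES), length(daily_rules) > 0)
  structure(list(notification_levels = notification_levels,
                 cap_levels = cap_levels,
                 daily_rules = daily_rules),
            class = "grid_spec")
}

#' Drop sessions at or below the notification cut-point
#'
#' A session lasting no longer than the cut-point is treated as an
#' auto-notification blip (the screen lit without the participant using
#' it) and removed; retention is strictly-greater (`duration_s > cutpoint`),
#' so cut-point 0 removes exactly the zero-duration sessions.
#'
#' @param sessions A session tibble.
#' @param cutpoint_s Cut-point in seconds, `>= 0`.
#' @return The retained sessions.
#' @export
apply_notification_cutpoint <- function(sessions, cutpoint_s) {
  if (!is.numeric(cutpoint_s) || length(cutpoint_s) != 1 || is.na(cutpoint_s) ||
      cutpoint_s < 0) {
    stop("cutpoint_s must be a single non-negative number", call. = FALSE)
  }
  sessions[sessions$duration_s > cutpoint_s, , drop = FALSE]
}

#' Drop sessions above the continuous-usage cap
#'
#' A session longer than the cap is treated as invalid data from a device
#' error (screen stuck ON) and removed entirely; retention is
#' `duration_s <= cap`. `cap_h = NA` is the no-threshold setting and
#' returns the input unchanged.
#'
#' @param sessions A session tibble.
#' @param cap_h Cap in hours (positive), or `NA` for no-threshold.
#' @return The retained sessions.
#' @export
apply_continuous_usage_cap <- function(sessions, cap_h) {
  if (length(cap_h) != 1) stop("cap_h must be scalar", call. = FALSE)
  if (is.na(cap_h)) return(sessions)
  if (!is.numeric(cap_h) || cap_h <= 0) {
    stop("cap_h must be positive or NA (no-threshold)", call. = FALSE)
  }
  sessions[sessions$duration_s <= cap_h * 3600, , drop = FALSE]
}

#' Apply the 10 hours/day rule to daily records
#'
#' `"include_all"` is the identity; `"exclude_gt_10h"` retains exactly the
#' participant-days with `total_minutes <= 600` (a day of exactly 10 h is
#' kept).
#'
#' @param day_records A day-record tibble from [daily_totals()].
#' @param rule `"include_all"` or `"exclude_gt_10h"`.
#' @return The retained day records.
#' @export
apply_daily_rule <- function(day_records, rule = c("include_all", "exclude_gt_10h")) {
  rule <- match.arg(rule)
  if (rule == "include_all") return(day_records)
  day_records[day_records$total_minutes <= 600, , drop = FALSE]
}

#' Run the full cut-point sensitivity grid
#'
#' For every grid cell the pipeline is, in fixed order: notification
#' cut-point, continuous-usage cap, split at local-day boundaries, daily
#' totals, daily 10 h rule, inclusion criteria (at least 2 weekdays and 1
#' weekend day with data, no app-off gap), per-participant weekday/weekend
#' means, then the paired subjective-vs-objective comparison statistics.
#' The surviving participant count `n` is recomputed per cell — tightening
#' a cut-point can empty a participant's days and void their inclusion —
#' so `n` may differ across cells.
#'
#' @param sessions Sessionized but *unsplit* sessions (see
#'   [split_at_day_boundaries()]: caps act on true continuous use).
#' @param questionnaire Questionnaire responses from
#'   [read_questionnaire()], or a pre-scored tibble with columns
#'   `participant_id, period, subjective_min`.
#' @param grid A [grid_spec()].
#' @param zone Olson timezone for day attribution.
#' @param coverage Optional app-off report from [app_off_report()];
#'   flagged participants are excluded everywhere.
#' @param item_set Questionnaire items summed into subjective smartphone
#'   minutes (see [smartphone_items()]); ignored when `questionnaire` is
#'   already scored.
#' @param alpha Two-sided significance level for the `flag` column.
#' @return A tibble with one row per
#'   `(day_type, daily_rule, cap_h, cutpoint_s)` cell carrying `n`,
#'   subjective and objective mean (SD), Wilcoxon signed rank, paired t,
#'   Spearman and Pearson results, the mean discrepancy
#'   (objective - subjective; positive means under-reporting) and a
#'   significance flag. Class `screenstate_grid`.
#' @export
run_grid <- function(sessions, questionnaire, grid = grid_spec(),
                     zone = "UTC", coverage = NULL,
                     item_set = smartphone_items(), alpha = 0.05) {
  if (length(grid$notification_levels) == 0 || length(grid$cap_levels) == 0) {
    stop("empty grid", call. = FALSE)
  }
  subjective <- score_subjective(questionnaire, item_set)

  cells <- expand.grid(
    cutpoint_s = grid$notification_levels,
    cap_h = grid$cap_levels,
    daily_rule = grid$daily_rules,
    stringsAsFactors = FALSE
  )
  rows <- purrr::pmap(cells, function(cutpoint_s, cap_h, daily_rule) {
    run_grid_cell(sessions, subjective, cutpoint_s, cap_h, daily_rule,
                  zone = zone, coverage = coverage, alpha = alpha)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(match(out$day_type, c("weekday", "weekend")),
                   match(out$daily_rule, DAILY_RULES),
                   match(out$cap_h, grid$cap_levels),
                   out$cutpoint_s), , drop = FALSE]
  class(out) <- c("screenstate_grid", class(out))
  attr(out, "grid") <- grid
  attr(out, "alpha") <- alpha
  out
}

# normalize the subjective side to participant_id/period/subjective_min
score_subjective <- function(questionnaire, item_set) {
  if (all(c("participant_id", "period", "subjective_min") %in% names(questionnaire))) {
    return(questionnaire[c("participant_id", "period", "subjective_min")])
  }
  questionnaire |>
    dplyr::mutate(subjective_min = smartphone_screen_time(questionnaire, item_set)) |>
    dplyr::select("participant_id", "period", "subjective_min")
}

run_grid_cell <- function(sessions, subjective, cutpoint_s, cap_h, daily_rule,
                          zone, coverage, alpha) {
  kept <- apply_notification_cutpoint(sessions, cutpoint_s)
  kept <- apply_continuous_usage_cap(kept, cap_h)
  frags <- split_at_day_boundaries(kept, zone)
  days <- daily_totals(frags, zone)
  days <- apply_daily_rule(days, daily_rule)
  summaries <- apply_inclusion_criteria(days, coverage = coverage)
  included <- summaries[summaries$included, , drop = FALSE]

  purrr::map_dfr(c("weekday", "weekend"), function(dt) {
    obj_col <- if (dt == "weekday") "mean_weekday_min" else "mean_weekend_min"
    obj <- tibble::tibble(participant_id = included$participant_id,
                          objective_min = included[[obj_col]])
    subj <- subjective[subjective$period == dt, , drop = FALSE]
    paired <- dplyr::inner_join(obj, subj, by = "participant_id")
    paired <- paired[!is.na(paired$objective_min) &
                       !is.na(paired$subjective_min), , drop = FALSE]
    cell <- compare_cell(paired$subjective_min, paired$objective_min,
                         alpha = alpha)
    dplyr::bind_cols(
      tibble::tibble(day_type = dt, daily_rule = daily_rule,
                     cap_h = cap_h, cutpoint_s = cutpoint_s),
      cell
    )
  })
}

#' Format the grid as four printed comparison tables
#'
#' Mirrors the published presentation: one table per
#' (day type x daily rule), rows = continuous-usage cut-points, columns =
#' notification cut-points, each cell `objective mean (SD)` min/day with
#' `*` for significant and `**` for borderline-significant paired
#' comparisons, preceded by the cell's `n` and the subjective mean (SD).
#'
#' @param grid A `screenstate_grid` from [run_grid()].
#' @return A single character string (print with `cat()`).
#' @export
format_comparison_tables <- function(grid) {
  fmt_cell <- function(m, s, flag) {
    if (is.na(m)) return("--")
    star <- switch(flag, significant = " *", borderline = " **", "")
    sprintf("%.2f (%.2f)%s", m, s, star)
  }
  cap_label <- function(cap) {
    ifelse(is.na(cap), "No threshold", sprintf("%d hours", as.integer(cap)))
  }
  cut_label <- function(cut) ifelse(cut == 0, "No filter", sprintf("%ds", cut))

  blocks <- character()
  for (dt in unique(grid$day_type)) {
    for (rule in unique(grid$daily_rule)) {
      g <- grid[grid$day_type == dt & grid$daily_rule == rule, , drop = FALSE]
      if (nrow(g) == 0) next
      title <- sprintf(
        "Objective screen-state vs. subjective screen time, %ss (%s, min/day)",
        dt, ifelse(rule == "include_all", "all records",
                   "excluding days > 10 h"))
      wide <- g |>
        dplyr::mutate(cell = mapply(fmt_cell, .data$obj_mean, .data$obj_sd,
                                    .data$flag),
                      subj = sprintf("%.2f (%.2f)", .data$subj_mean,
                                     .data$subj_sd)) |>
        dplyr::select("n", "subj", "cap_h", "cutpoint_s", "cell") |>
        tidyr::pivot_wider(names_from = "cutpoint_s", values_from = "cell")
      hdr <- c("n", "Subjective", "Continuous usage",
               cut_label(sort(unique(g$cutpoint_s))))
      body <- cbind(wide$n, wide$subj, cap_label(wide$cap_h),
                    as.matrix(wide[, -(1:3), drop = FALSE]))
      tab <- rbind(hdr, body)
      widths <- apply(nchar(tab), 2, max)
      lines <- apply(tab, 1, function(r) {
        paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
      })
      blocks <- c(blocks, title, strrep("-", max(nchar(lines))), lines, "")
    }
  }
  paste(blocks, collapse = "\n")
}
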