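#' Configuration for the synthetic cohort simulator
#'
#' Defaults describe an 8-consecutive-day observation window for a
#' 54-participant adult cohort in a single (DST-free) prairie timezone:
#' about 40 true usage sessions a day with right-skewed lognormal
#' durations averaging roughly 4 minutes (about 165 min/day of true
#' screen-state), around 30 auto-notification blips a day of 1-15 seconds
#' that light the screen without real use, an occasional stuck-screen day
#' (screen erroneously ON for hours), and self-reports that multiply true
#' usage by an under-reporting factor and add recall noise.
#'
#' @param n_participants Number of participants.
#' @param n_days Consecutive study days (default 8).
#' @param start_date First local day of the window.
#' @param sessions_per_day_mean Poisson mean of true usage sessions/day.
#' @param session_minutes_log_mu,session_minutes_log_sigma Lognormal
#'   meanlog/sdlog of true session duration, minutes.
#' @param blips_per_day_mean Poisson mean of auto-notification blips/day.
#' @param blip_seconds_range Uniform range of blip duration, seconds
#'   (upper end below the largest notification cut-point of 20 s).
#' @param p_stuck_day Probability a participant-day contains one
#'   stuck-screen artifact.
#' @param stuck_hours_range Uniform range of artifact duration, hours.
#' @param underreport_factor Multiplier applied to true mean daily usage
#'   when generating self-reports; values below 1 encode under-reporting.
#' @param report_noise_sd SD of additive recall noise, minutes.
#' @param zone Olson timezone of the cohort.
#' @param seed Integer seed; the simulation is fully deterministic given
#'   the seed and never touches the caller's RNG state.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_participants = 54,
                              n_days = 8,
                              start_date = as.Date("2017-04-05"),
                              sessions_per_day_mean = 40,
                              session_minutes_log_mu = log(2.5),
                              session_minutes_log_sigma = 1,
                              blips_per_day_mean = 30,
                              blip_seconds_range = c(1, 15),
                              p_stuck_day = 0.02,
                              stuck_hours_range = c(3, 12),
                              underreport_factor = 0.8,
                              report_noise_sd = 20,
                              zone = "America/Regina",
                              seed = 1L) {
  stopifnot(
    n_participants >= 1, n_days >= 1,
    sessions_per_day_mean >= 0, blips_per_day_mean >= 0,
    session_minutes_log_sigma >= 0,
    length(blip_seconds_range) == 2,
    blip_seconds_range[1] <= blip_seconds_range[2],
    blip_seconds_range[1] > 0,
    length(stuck_hours_range) == 2,
    stuck_hours_range[1] <= stuck_hours_range[2],
    p_stuck_day >= 0, p_stuck_day <= 1,
    underreport_factor > 0, underreport_factor <= 1,
    report_noise_sd >= 0,
    zone %in% OlsonNames()
  )
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a cohort of screen-event streams with ground truth
#'
#' Generates, per participant and day, true usage sessions, notification
#' blips and (rarely) stuck-screen artifacts, placed uniformly at random
#' without overlap (rejection-resampled); evening sessions may run past
#' local midnight, exercising day-boundary splitting. Every interval is
#' emitted as an ON/OFF event pair, and a ground-truth ledger labels each
#' generated session `usage`, `blip` or `artifact`. Self-reports are
#' `underreport_factor * (true mean daily usage)` plus Gaussian recall
#' noise, floored at zero, produced separately for weekdays and weekend
#' days and spread over the smartphone questionnaire items.
#'
#' @param config A [simulation_config()].
#' @return A list:
#'   * `events` — a [screen_events] stream;
#'   * `questionnaire` — responses in the [read_questionnaire()] layout;
#'   * `truth` — `sessions` (labelled ledger), `daily` (per
#'     participant-day `true_usage_min`, `n_true_sessions`, `n_blips`,
#'     `stuck_flag` over the full window), `participants` (true means and
#'     the reported values before flooring), and the window metadata;
#'   * `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  runner <- function() simulate_cohort_impl(config)
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, runner())
  } else {
    runner()
  }
}

simulate_cohort_impl <- function(config) {
  window_start <- lubridate::force_tz(
    lubridate::as_datetime(config$start_date), tzone = config$zone)
  day_len <- 86400
  horizon <- config$n_days * day_len
  pids <- sprintf("P%03d", seq_len(config$n_participants))

  ledgers <- lapply(pids, function(pid) {
    place_participant(pid, config, day_len, horizon)
  })
  ledger <- tibble::tibble(
    participant_id = rep(pids, vapply(ledgers, function(l) length(l$dur),
                                      integer(1))),
    day_index = unlist(lapply(ledgers, `[[`, "day")),
    class = unlist(lapply(ledgers, `[[`, "cls")),
    start_s = unlist(lapply(ledgers, `[[`, "starts")),
    duration_s = unlist(lapply(ledgers, `[[`, "dur"))
  )
  ledger$end_s <- ledger$start_s + ledger$duration_s
  ledger$start <- window_start + ledger$start_s
  ledger$end <- window_start + ledger$end_s
  ledger$start_local_date <- local_dates(ledger$start, config$zone)

  events <- tibble::tibble(
    participant_id = rep(ledger$participant_id, 2),
    timestamp = c(ledger$start, ledger$end),
    state = rep(c("ON", "OFF"), each = nrow(ledger))
  )
  stream <- new_screen_events(events, provenance = list(
    source = "simulate_cohort", n_rows = nrow(events), n_dropped = 0,
    drops = NULL))

  truth_daily <- truth_daily_table(ledger, config, window_start)
  participants <- subjective_reports(truth_daily, config)
  questionnaire <- build_questionnaire(participants)

  truth <- list(
    sessions = ledger[c("participant_id", "class", "start", "end",
                        "duration_s", "start_local_date")],
    daily = truth_daily,
    participants = participants,
    zone = config$zone,
    window_start = window_start,
    n_days = config$n_days
  )
  list(events = stream, questionnaire = questionnaire, truth = truth,
       config = config)
}

place_participant <- function(pid, config, day_len, horizon) {
  all_dur <- all_cls <- all_day <- list()
  for (d in seq_len(config$n_days)) {
    n_use <- stats::rpois(1, config$sessions_per_day_mean)
    n_blip <- stats::rpois(1, config$blips_per_day_mean)
    stuck <- stats::runif(1) < config$p_stuck_day
    dur <- c(
      60 * stats::rlnorm(n_use, config$session_minutes_log_mu,
                         config$session_minutes_log_sigma),
      stats::runif(n_blip, config$blip_seconds_range[1],
                   config$blip_seconds_range[2]),
      if (stuck) 3600 * stats::runif(1, config$stuck_hours_range[1],
                                     config$stuck_hours_range[2])
    )
    cls <- c(rep("usage", n_use), rep("blip", n_blip),
             if (stuck) "artifact")
    # place longest intervals first: a multi-hour artifact needs a gap
    # that will not exist once dozens of short sessions are scattered
    ord <- order(dur, decreasing = TRUE)
    all_dur[[d]] <- dur[ord]
    all_cls[[d]] <- cls[ord]
    all_day[[d]] <- rep(d, length(dur))
  }
  dur <- unlist(all_dur)
  cls <- unlist(all_cls)
  day <- unlist(all_day)
  n <- length(dur)
  busy_s <- busy_e <- numeric(n)
  starts <- numeric(n)
  # an interval can only collide with intervals starting within
  # `lookback` days before it (bounded by the longest duration drawn)
  lookback <- max(1, ceiling(max(dur, 1) / day_len))
  day_start <- findInterval(seq_len(config$n_days) - 0.5, day) + 1L
  for (i in seq_len(n)) {
    off <- (day[i] - 1) * day_len
    placed <- FALSE
    j0 <- day_start[max(1, day[i] - lookback)]
    prior_s <- busy_s[seq.int(j0, length.out = i - j0)]
    prior_e <- busy_e[seq.int(j0, length.out = i - j0)]
    for (try in seq_len(200)) {
      s <- off + stats::runif(1, 0, day_len)
      e <- s + dur[i]
      # sessions may cross midnight but the recording window is finite:
      # nothing extends past the last study day
      if (e <= horizon && !any(prior_s < e & prior_e > s)) {
        busy_s[i] <- s
        busy_e[i] <- e
        starts[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible session density: could not place a ", cls[i],
           " of ", round(dur[i]), " s for ", pid, " on day ", day[i],
           " after 200 attempts", call. = FALSE)
    }
  }
  list(day = day, cls = cls, starts = starts, dur = dur)
}

# True usage minutes attributed to local days exactly as the pipeline
# attributes them: usage sessions split at local midnight. Covers every
# participant-day of the window, zeros included (the truth knows a quiet
# day really was quiet).
truth_daily_table <- function(ledger, config, window_start) {
  all_days <- tidyr::expand_grid(
    participant_id = sprintf("P%03d", seq_len(config$n_participants)),
    local_date = config$start_date + seq_len(config$n_days) - 1
  )
  usage <- ledger[ledger$class == "usage", , drop = FALSE]
  if (nrow(usage) > 0) {
    us <- tibble::tibble(
      participant_id = usage$participant_id,
      session_id = sprintf("T#%06d", seq_len(nrow(usage))),
      start = usage$start, end = usage$end,
      duration_s = usage$duration_s, split_of = NA_character_
    )
    frags <- split_at_day_boundaries(us, config$zone)
    per_day <- frags |>
      dplyr::group_by(.data$participant_id, .data$local_date) |>
      dplyr::summarise(true_usage_min = sum(.data$duration_s) / 60,
                       .groups = "drop")
  } else {
    per_day <- tibble::tibble(participant_id = character(),
                              local_date = as.Date(character()),
                              true_usage_min = numeric())
  }
  counts <- ledger |>
    dplyr::group_by(.data$participant_id, .data$start_local_date) |>
    dplyr::summarise(
      n_true_sessions = sum(.data$class == "usage"),
      n_blips = sum(.data$class == "blip"),
      stuck_flag = any(.data$class == "artifact"),
      .groups = "drop"
    ) |>
    dplyr::rename(local_date = "start_local_date")
  all_days |>
    dplyr::left_join(per_day, by = c("participant_id", "local_date")) |>
    dplyr::left_join(counts, by = c("participant_id", "local_date")) |>
    tidyr::replace_na(list(true_usage_min = 0, n_true_sessions = 0L,
                           n_blips = 0L, stuck_flag = FALSE)) |>
    dplyr::mutate(day_type = ifelse(
      lubridate::wday(.data$local_date, week_start = 1) >= 6,
      "weekend", "weekday"), .after = "local_date")
}

subjective_reports <- function(truth_daily, config) {
  truth_daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      true_weekday_min = mean_or_na(
        .data$true_usage_min[.data$day_type == "weekday"]),
      true_weekend_min = mean_or_na(
        .data$true_usage_min[.data$day_type == "weekend"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reported_weekday_min = pmax(
        0, config$underreport_factor * .data$true_weekday_min +
          stats::rnorm(dplyr::n(), 0, config$report_noise_sd)),
      reported_weekend_min = pmax(
        0, config$underreport_factor * .data$true_weekend_min +
          stats::rnorm(dplyr::n(), 0, config$report_noise_sd)),
      underreport_factor = config$underreport_factor
    )
}

# Spread each report over the default smartphone items (random split) and
# add unrelated TV time in Q1 so item-subset scoring is exercised.
build_questionnaire <- function(participants) {
  items <- smartphone_items()
  n <- nrow(participants)
  out <- tibble::tibble(
    participant_id = rep(participants$participant_id, each = 2),
    period = rep(c("weekday", "weekend"), n),
    Q1 = stats::runif(2 * n, 0, 180)
  )
  total <- as.vector(rbind(participants$reported_weekday_min,
                           participants$reported_weekend_min))
  w <- matrix(stats::runif(2 * n * length(items)), nrow = 2 * n)
  w <- w / rowSums(w)
  for (i in seq_along(items)) out[[items[i]]] <- total * w[, i]
  out
}

#' Recovery of ground truth through the filtering pipeline
#'
#' Runs the notification and continuous-usage filters over sessionized
#' simulator output, recomputes daily totals, and scores them against the
#' ground-truth ledger: per-day bias and RMSE of estimated vs true usage
#' minutes, plus the fraction of blips and of stuck-screen artifacts the
#' filters removed. In the separable regime (all blips shorter than the
#' cut-point, all true sessions between cut-point and cap, all artifacts
#' above the cap) removal is total and the bias is exactly zero.
#'
#' @param sessions Sessionized (unsplit) sessions derived from the
#'   simulated event stream.
#' @param truth The `truth` component of [simulate_cohort()] output.
#' @param notification_cutpoint_s,continuous_usage_cap_h Filter settings
#'   under evaluation.
#' @return A list `bias_min`, `rmse_min`, `blip_removal_fraction`,
#'   `artifact_removal_fraction` (`NA` when the class was not generated),
#'   and `per_day` (estimated vs true minutes for every participant-day).
#' @export
recovery_report <- function(sessions, truth,
                            notification_cutpoint_s = 0,
                            continuous_usage_cap_h = NA) {
  key <- function(pid, t) paste(pid, round(as.numeric(t) * 1000))
  ledger_key <- key(truth$sessions$participant_id, truth$sessions$start)
  cls <- truth$sessions$class[match(key(sessions$participant_id,
                                        sessions$start), ledger_key)]
  if (anyNA(cls)) {
    stop("sessions do not match the ground-truth ledger ",
         "(mismatched participant sets or timestamps)", call. = FALSE)
  }
  kept <- apply_notification_cutpoint(sessions, notification_cutpoint_s)
  kept <- apply_continuous_usage_cap(kept, continuous_usage_cap_h)
  kept_key <- key(kept$participant_id, kept$start)
  removed <- !(ledger_key %in% kept_key)

  frac_removed <- function(class) {
    idx <- truth$sessions$class == class
    if (!any(idx)) return(NA_real_)
    mean(removed[idx])
  }

  frags <- split_at_day_boundaries(kept, truth$zone)
  est <- daily_totals(frags, truth$zone)
  per_day <- truth$daily |>
    dplyr::left_join(
      est[c("participant_id", "local_date", "total_minutes")],
      by = c("participant_id", "local_date")) |>
    tidyr::replace_na(list(total_minutes = 0)) |>
    dplyr::rename(est_min = "total_minutes") |>
    dplyr::mutate(error_min = .data$est_min - .data$true_usage_min)

  list(
    bias_min = mean(per_day$error_min),
    rmse_min = sqrt(mean(per_day$error_min^2)),
    blip_removal_fraction = frac_removed("blip"),
    artifact_removal_fraction = frac_removed("artifact"),
    per_day = per_day
  )
}
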