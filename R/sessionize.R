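#' Sessionization policy
#'
#' How ambiguous event patterns are resolved when pairing ON/OFF
#' transitions into sessions. Version 1 admits one lawful value per field;
#' the enum exists so that alternative policies (e.g. closing a trailing ON
#' at stream end) can be added without changing the sessionizer interface.
#'
#' @param duplicate_on A second ON while a session is open: `"keep_first"`
#'   (the duplicate is dropped and counted).
#' @param trailing_on An ON never closed before the stream ends: `"drop"`
#'   (closing it would fabricate duration; the drop is logged so coverage
#'   checks can flag it).
#' @param orphan_off An OFF with no open session: `"drop"`.
#' @return A `sessionize_policy` list.
#' @export
sessionize_policy <- function(duplicate_on = "keep_first",
                              trailing_on = "drop",
                              orphan_off = "drop") {
  duplicate_on <- match.arg(duplicate_on, "keep_first")
  trailing_on <- match.arg(trailing_on, "drop")
  orphan_off <- match.arg(orphan_off, "drop")
  structure(list(duplicate_on = duplicate_on,
                 trailing_on = trailing_on,
                 orphan_off = orphan_off),
            class = "sessionize_policy")
}

#' Pair ON/OFF events into usage sessions
#'
#' Scans each participant's events in time order (OFF before ON at equal
#' instants): an `ON` opens a session, the next `OFF` closes it. A second
#' `ON` while a session is open is ignored, an `OFF` with no open session
#' is dropped, and an `ON` never closed by stream end is dropped; every
#' dropped event is counted in the attached drop report. Sessions may have
#' duration zero (ON and OFF at the same instant); the notification
#' cut-point removes those downstream.
#'
#' @param stream A [screen_events] tibble (normalized: sorted,
#'   deduplicated). The function re-sorts defensively.
#' @param policy A [sessionize_policy()].
#' @return A tibble of sessions with columns `participant_id, session_id,
#'   start, end, duration_s, split_of` (`split_of` is `NA` until
#'   [split_at_day_boundaries()] runs). Attribute `drops` holds a
#'   per-participant tibble of `n_duplicate_on, n_orphan_off,
#'   n_trailing_on` counts.
#' @export
sessionize <- function(stream, policy = sessionize_policy()) {
  stopifnot(inherits(policy, "sessionize_policy"))
  ev <- stream[order(stream$participant_id, stream$timestamp,
                     stream$state, method = "radix"), , drop = FALSE]
  parts <- split(seq_len(nrow(ev)), ev$participant_id)
  pieces <- lapply(names(parts), function(pid) {
    idx <- parts[[pid]]
    pair_events(pid, ev$timestamp[idx], ev$state[idx])
  })
  sessions <- dplyr::bind_rows(lapply(pieces, `[[`, "sessions"))
  drops <- dplyr::bind_rows(lapply(pieces, `[[`, "drops"))
  if (nrow(sessions) == 0) {
    sessions <- empty_sessions()
  }
  attr(sessions, "drops") <- drops
  sessions
}

empty_sessions <- function() {
  tibble::tibble(
    participant_id = character(),
    session_id = character(),
    start = lubridate::as_datetime(character()),
    end = lubridate::as_datetime(character()),
    duration_s = numeric(),
    split_of = character()
  )
}

pair_events <- function(pid, ts, state) {
  n <- length(ts)
  # fast path: perfectly alternating ON/OFF starting with ON
  if (n %% 2 == 0 && n > 0 &&
      all(state == rep(c("ON", "OFF"), n / 2))) {
    on_i <- seq(1, n, by = 2)
    off_i <- seq(2, n, by = 2)
    starts <- ts[on_i]
    ends <- ts[off_i]
    dup <- orphan <- trailing <- 0L
  } else {
    starts <- ends <- ts[0]
    open_start <- NULL
    dup <- orphan <- trailing <- 0L
    for (i in seq_len(n)) {
      if (state[i] == "ON") {
        if (is.null(open_start)) open_start <- ts[i] else dup <- dup + 1L
      } else {
        if (is.null(open_start)) {
          orphan <- orphan + 1L
        } else {
          starts <- c(starts, open_start)
          ends <- c(ends, ts[i])
          open_start <- NULL
        }
      }
    }
    if (!is.null(open_start)) trailing <- trailing + 1L
  }
  k <- length(starts)
  sessions <- tibble::tibble(
    participant_id = rep(pid, k),
    session_id = if (k) sprintf("%s#%04d", pid, seq_len(k)) else character(),
    start = starts,
    end = ends,
    duration_s = as.numeric(difftime(ends, starts, units = "secs")),
    split_of = rep(NA_character_, k)
  )
  drops <- tibble::tibble(
    participant_id = pid,
    n_duplicate_on = dup,
    n_orphan_off = orphan,
    n_trailing_on = trailing
  )
  list(sessions = sessions, drops = drops)
}

#' Split sessions at local-day boundaries
#'
#' Cuts every session at each local midnight it spans so that each output
#' fragment lies within one calendar day of `zone`; fragment durations sum
#' exactly (to the second) to the parent duration, and fragments carry the
#' parent id in `split_of`. Sessions inside a single day pass through
#' unchanged. Continuous-usage filtering must happen *before* this step:
#' midnight does not interrupt actual continuous use.
#'
#' @param sessions A session tibble from [sessionize()].
#' @param zone Olson timezone name used to locate midnight.
#' @return A session tibble with an added `local_date` column (date of the
#'   fragment's start in `zone`).
#' @export
split_at_day_boundaries <- function(sessions, zone) {
  if (!zone %in% OlsonNames()) {
    stop("unknown timezone: ", zone, call. = FALSE)
  }
  if (nrow(sessions) == 0) {
    out <- sessions
    out$local_date <- as.Date(character())
    return(out)
  }
  start_date <- local_dates(sessions$start, zone)
  # a session ending exactly at midnight belongs wholly to the prior day
  end_date <- local_dates(sessions$end, zone)
  crosses <- (end_date > start_date & !at_local_midnight(sessions$end, zone)) |
    (end_date - start_date > 1)

  intact <- sessions[!crosses, , drop = FALSE]
  intact$local_date <- start_date[!crosses]

  if (any(crosses)) {
    idx <- which(crosses)
    bounds <- lapply(idx, function(i) {
      cuts <- local_midnight(seq(start_date[i] + 1, end_date[i], by = "day"),
                             zone)
      cuts <- cuts[cuts > sessions$start[i] & cuts < sessions$end[i]]
      as.numeric(c(sessions$start[i], cuts, sessions$end[i]))
    })
    k <- lengths(bounds) - 1L
    starts_n <- unlist(lapply(bounds, function(b) b[-length(b)]))
    ends_n <- unlist(lapply(bounds, function(b) b[-1]))
    tz0 <- lubridate::tz(sessions$start)
    starts <- lubridate::as_datetime(starts_n, tz = tz0)
    ends <- lubridate::as_datetime(ends_n, tz = tz0)
    parent <- rep(sessions$session_id[idx], k)
    frag <- tibble::tibble(
      participant_id = rep(sessions$participant_id[idx], k),
      session_id = sprintf("%s.%d", parent,
                           unlist(lapply(k, seq_len))),
      start = starts,
      end = ends,
      duration_s = ends_n - starts_n,
      split_of = parent,
      local_date = local_dates(starts, zone)
    )
    out <- dplyr::bind_rows(intact, frag)
  } else {
    out <- intact
  }
  out <- out[order(out$participant_id, out$start, method = "radix"), , drop = FALSE]
  attr(out, "drops") <- attr(sessions, "drops")
  out
}

local_midnight <- function(date, zone) {
  lubridate::force_tz(lubridate::as_datetime(date), tzone = zone)
}

# Vectorized local calendar date. UTC offsets are constant within any
# 15-minute bin (all real-world offsets and transition instants fall on
# 15-minute boundaries), so the offset is resolved once per unique bin
# instead of once per timestamp.
local_dates <- function(t, zone) {
  secs <- as.numeric(t)
  bin <- floor(secs / 900) * 900
  ub <- unique(bin)
  off <- as.POSIXlt(.POSIXct(ub, tz = "UTC"), tz = zone)$gmtoff
  if (is.null(off) || anyNA(off)) {
    return(as.Date(t, tz = zone))
  }
  .Date(floor((secs + off[match(bin, ub)]) / 86400))
}

at_local_midnight <- function(t, zone) {
  secs <- as.numeric(t)
  bin <- floor(secs / 900) * 900
  ub <- unique(bin)
  off <- as.POSIXlt(.POSIXct(ub, tz = "UTC"), tz = zone)$gmtoff
  if (is.null(off) || anyNA(off)) {
    off <- rep(0, length(ub))
    secs <- as.numeric(local_midnight(local_dates(t, zone), zone))
    return(abs(as.numeric(t) - secs) < 1e-6)
  }
  rem <- (secs + off[match(bin, ub)]) %% 86400
  rem < 1e-6 | rem > 86400 - 1e-6
}
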