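#' Screen-event streams
#'
#' A screen-event stream is a tibble with one row per screen-state
#' transition recorded by a smartphone sensing app:
#' `participant_id` (character), `timestamp` (POSIXct, stored in UTC) and
#' `state` (`"ON"` or `"OFF"`). Streams are kept sorted by
#' `(participant_id, timestamp)` with `OFF` ordered before `ON` at equal
#' instants, so that a closing transition always precedes a re-opening one,
#' and exact duplicate rows are collapsed. Provenance (source path, rows
#' read, rows dropped and why) travels along as attributes.
#'
#' @name screen_events
NULL

EVENT_COLUMNS <- c("participant_id", "timestamp", "state")

# ISO-8601 with an explicit UTC offset (Z or +hh:mm / +hhmm / +hh)
HAS_OFFSET_RE <- "(Z|[+-][0-9]{2}(:?[0-9]{2})?)$"

new_screen_events <- function(events, provenance = NULL) {
  events <- events[order(events$participant_id, events$timestamp,
                         events$state, method = "radix"), , drop = FALSE]
  events <- dplyr::distinct(events,
                            .data$participant_id, .data$timestamp, .data$state)
  out <- tibble::as_tibble(events)
  attr(out, "provenance") <- provenance
  class(out) <- c("screen_events", class(out))
  out
}

#' Read a screen-event CSV
#'
#' Reads a screen-state transition log with header
#' `participant_id,timestamp,state`. Timestamps must be ISO-8601; in lenient
#' mode (default) a timestamp without an explicit UTC offset is interpreted
#' in `default_zone`, state labels are trimmed and upper-cased, and every
#' malformed row is dropped with a counted reason. In strict mode any
#' malformed row, or any timestamp lacking an offset, is an error.
#'
#' The returned stream is sorted by `(participant_id, timestamp)` (with
#' `OFF` before `ON` at equal instants) and exact duplicate rows are
#' collapsed, so reading is idempotent: re-reading a written stream yields
#' the same events with zero drops.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE`, the first malformed row aborts the read.
#' @param default_zone Timezone assumed for offset-less timestamps in
#'   lenient mode (an Olson name, e.g. `"America/Regina"`).
#' @return A [screen_events] tibble. Attribute `provenance` records the
#'   source path, rows read, rows dropped and a per-reason drop table.
#' @export
read_events <- function(path, strict = FALSE, default_zone = "UTC") {
  if (!file.exists(path)) {
    stop("events file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(EVENT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("events file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[EVENT_COLUMNS]
  parsed <- parse_event_rows(raw, strict = strict, default_zone = default_zone)
  provenance <- list(
    source = path,
    n_rows = nrow(raw),
    n_dropped = sum(parsed$drops$n),
    drops = parsed$drops
  )
  new_screen_events(parsed$events, provenance = provenance)
}

parse_event_rows <- function(raw, strict, default_zone) {
  state <- toupper(trimws(raw$state))
  ts_raw <- trimws(raw$timestamp)

  bad_missing <- is.na(raw$participant_id) | raw$participant_id == "" |
    is.na(ts_raw) | ts_raw == "" | is.na(raw$state) | raw$state == ""
  bad_state <- !bad_missing & !(state %in% c("ON", "OFF"))

  has_offset <- grepl(HAS_OFFSET_RE, ts_raw)
  ts <- rep(lubridate::as_datetime(NA), nrow(raw))
  with_off <- !bad_missing & has_offset
  if (any(with_off)) {
    ts[with_off] <- lubridate::ymd_hms(ts_raw[with_off], tz = "UTC", quiet = TRUE)
  }
  without_off <- !bad_missing & !has_offset
  if (any(without_off)) {
    if (strict) {
      stop("timestamp without UTC offset in strict mode: ",
           ts_raw[which(without_off)[1]], call. = FALSE)
    }
    local <- lubridate::ymd_hms(ts_raw[without_off], tz = default_zone, quiet = TRUE)
    ts[without_off] <- lubridate::with_tz(local, "UTC")
  }
  bad_ts <- !bad_missing & is.na(ts)

  drop <- bad_missing | bad_state | bad_ts
  if (strict && any(drop)) {
    i <- which(drop)[1]
    reason <- if (bad_missing[i]) "missing field" else
      if (bad_state[i]) paste0("unknown state ", sQuote(raw$state[i])) else
        paste0("unparseable timestamp ", sQuote(ts_raw[i]))
    stop("malformed events row ", i, " in strict mode: ", reason, call. = FALSE)
  }
  drops <- tibble::tibble(
    reason = c("missing_field", "unknown_state", "unparseable_timestamp"),
    n = c(sum(bad_missing), sum(bad_state), sum(bad_ts))
  )
  events <- tibble::tibble(
    participant_id = raw$participant_id[!drop],
    timestamp = ts[!drop],
    state = state[!drop]
  )
  list(events = events, drops = drops)
}

#' Write a screen-event stream to CSV
#'
#' Writes the fixed dialect `participant_id,timestamp,state` with
#' timestamps formatted in UTC as `YYYY-MM-DDTHH:MM:SS.ssssss+00:00`
#' (microsecond precision, so sub-second sensor timestamps survive).
#' Writing then reading reproduces second-resolution events exactly, and
#' the file bytes are stable for a fixed stream.
#'
#' @param stream A [screen_events] tibble (or any tibble with the three
#'   event columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(stream, path) {
  out <- tibble::tibble(
    participant_id = stream$participant_id,
    timestamp = format(lubridate::with_tz(stream$timestamp, "UTC"),
                       "%Y-%m-%dT%H:%M:%OS6+00:00"),
    state = stream$state
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate a screen-event stream
#'
#' Per-participant diagnostics computed by a single pass over the sorted
#' stream: event count, first and last timestamp, number of consecutive
#' same-state events (an `ON` following an `ON`, or `OFF` following `OFF`),
#' and number of `OFF` events seen before any `ON`. The stream itself is
#' never modified; the report is the input to coverage checks and to
#' deciding whether the sessionizer's drop counts look plausible.
#'
#' @param stream A [screen_events] tibble.
#' @return A tibble with one row per participant:
#'   `participant_id, n_events, first_timestamp, last_timestamp,
#'   n_consecutive_same_state, n_off_before_on`.
#' @export
validate_stream <- function(stream) {
  stream |>
    dplyr::arrange(.data$participant_id, .data$timestamp, .data$state) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      first_timestamp = min(.data$timestamp),
      last_timestamp = max(.data$timestamp),
      n_consecutive_same_state =
        sum(.data$state[-1] == .data$state[-dplyr::n()]),
      n_off_before_on = {
        first_on <- match("ON", .data$state)
        if (is.na(first_on)) sum(.data$state == "OFF")
        else sum(.data$state[seq_len(first_on - 1)] == "OFF")
      },
      .groups = "drop"
    )
}

#' @export
print.screen_events <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<screen_events> ", nrow(x), " events, ",
      dplyr::n_distinct(x$participant_id), " participant(s)\n", sep = "")
  if (!is.null(prov)) {
    cat("  source: ", prov$source, " (", prov$n_rows, " rows, ",
        prov$n_dropped, " dropped)\n", sep = "")
  }
  NextMethod()
}
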