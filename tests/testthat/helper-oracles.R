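# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and base R only, so that agreement is evidence
# and not tautology.

TEST_ZONE <- "America/Regina"

utc <- function(x) as.POSIXct(x, tz = "UTC")

# build a screen_events-shaped tibble from vectors
make_stream <- function(participant_id, timestamp, state) {
  tibble::tibble(participant_id = participant_id,
                 timestamp = utc(timestamp),
                 state = state)
}

# event-by-event pairing, one participant at a time, written as the most
# literal state machine possible
oracle_sessionize <- function(stream) {
  out <- list()
  drops <- c(duplicate_on = 0, orphan_off = 0, trailing_on = 0)
  for (pid in sort(unique(stream$participant_id))) {
    ev <- stream[stream$participant_id == pid, ]
    ev <- ev[order(ev$timestamp, ev$state), ]  # OFF < ON at equal instants
    open <- NA
    for (i in seq_len(nrow(ev))) {
      if (ev$state[i] == "ON") {
        if (is.na(open)) open <- as.numeric(ev$timestamp[i])
        else drops["duplicate_on"] <- drops["duplicate_on"] + 1
      } else {
        if (is.na(open)) drops["orphan_off"] <- drops["orphan_off"] + 1
        else {
          out[[length(out) + 1]] <- data.frame(
            participant_id = pid, start = open,
            end = as.numeric(ev$timestamp[i]))
          open <- NA
        }
      }
    }
    if (!is.na(open)) drops["trailing_on"] <- drops["trailing_on"] + 1
  }
  sessions <- if (length(out)) do.call(rbind, out) else
    data.frame(participant_id = character(), start = numeric(),
               end = numeric())
  sessions$duration_s <- sessions$end - sessions$start
  list(sessions = sessions, drops = drops)
}

# random event stream with controllable dirtiness
random_stream <- function(n_events, n_participants = 3, p_on = 0.55,
                          t0 = utc("2017-04-05 00:00:00")) {
  tibble::tibble(
    participant_id = sample(sprintf("S%02d", seq_len(n_participants)),
                            n_events, replace = TRUE),
    timestamp = t0 + sort(sample.int(n_events * 50, n_events)),
    state = ifelse(stats::runif(n_events) < p_on, "ON", "OFF")
  )
}

# random non-overlapping sessions for one or more participants
random_sessions <- function(n, n_participants = 3, max_dur_s = 3 * 86400,
                            t0 = utc("2017-04-05 00:00:00")) {
  rows <- list()
  id <- 0
  for (pid in sprintf("S%02d", seq_len(n_participants))) {
    k <- ceiling(n / n_participants)
    gaps <- stats::rexp(k, 1 / 600)
    durs <- stats::runif(k, 0, max_dur_s)
    starts <- cumsum(gaps + c(0, durs[-k]))
    id <- id + k
    rows[[pid]] <- tibble::tibble(
      participant_id = pid,
      session_id = sprintf("%s#%04d", pid, seq_len(k)),
      start = t0 + starts,
      end = t0 + starts + durs,
      duration_s = durs,
      split_of = NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

empty_sessions_for_test <- function() {
  tibble::tibble(participant_id = character(), session_id = character(),
                 start = utc(character()), end = utc(character()),
                 duration_s = numeric(), split_of = character())
}

# every fragment stays within one local day (zero-length ones trivially so)
local_dates_check <- function(f, zone) {
  sd <- as.Date(as.POSIXlt(f$start, tz = zone))
  ed_open <- as.Date(as.POSIXlt(f$end - 1e-3, tz = zone))
  sd == ed_open | f$duration_s == 0
}

# group-and-sum daily totals from split fragments, via base aggregate
oracle_daily_totals <- function(frags, zone) {
  df <- data.frame(
    pid = frags$participant_id,
    date = as.Date(as.POSIXlt(frags$start, tz = zone)),
    dur = frags$duration_s
  )
  agg <- aggregate(dur ~ pid + date, df, sum)
  agg[order(agg$pid, agg$date), ]
}

# full 2^m sign-flip enumeration of the Wilcoxon signed rank null;
# two-sided symmetric-tail counting
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  vs <- apply(grid, 1, function(pos) sum(r[pos]))
  mu <- m * (m + 1) / 4
  list(v = v, p = mean(abs(vs - mu) >= abs(v - mu) - 1e-12))
}

# one grid cell recomputed as a straight-line loop over sessions
oracle_grid_cell <- function(sessions, subj, cutpoint_s, cap_h, rule,
                             day_type, zone, alpha = 0.05) {
  keep <- sessions$duration_s > cutpoint_s
  if (!is.na(cap_h)) keep <- keep & sessions$duration_s <= cap_h * 3600
  s <- sessions[keep, ]
  # split at local midnights by brute force, one second... no: by cutting
  # at successive midnights computed from POSIXlt
  frag <- list()
  for (i in seq_len(nrow(s))) {
    a <- s$start[i]; b <- s$end[i]
    repeat {
      la <- as.POSIXlt(a, tz = zone)
      next_mid <- as.POSIXct(
        format(as.Date(la) + 1), tz = zone)
      if (next_mid >= b) {
        frag[[length(frag) + 1]] <- data.frame(
          pid = s$participant_id[i], date = as.Date(la),
          dur = as.numeric(b) - as.numeric(a))
        break
      }
      frag[[length(frag) + 1]] <- data.frame(
        pid = s$participant_id[i], date = as.Date(la),
        dur = as.numeric(next_mid) - as.numeric(a))
      a <- next_mid
    }
  }
  if (length(frag) == 0) return(list(n = 0))
  fr <- do.call(rbind, frag)
  days <- aggregate(dur ~ pid + date, fr, sum)
  days$min <- days$dur / 60
  if (rule == "exclude_gt_10h") days <- days[days$min <= 600, ]
  days$wd <- as.POSIXlt(as.POSIXct(paste(days$date, "12:00:00"),
                                   tz = "UTC"))$wday
  days$type <- ifelse(days$wd %in% c(0, 6), "weekend", "weekday")
  means <- list()
  for (pid in unique(days$pid)) {
    dd <- days[days$pid == pid, ]
    if (sum(dd$type == "weekday") >= 2 && sum(dd$type == "weekend") >= 1) {
      x <- dd$min[dd$type == day_type]
      if (length(x) > 0) means[[pid]] <- mean(x)
    }
  }
  obj <- unlist(means)
  if (is.null(obj)) return(list(n = 0))
  sj <- subj$subjective_min[match(names(obj), subj$participant_id)]
  keep <- !is.na(sj)
  obj <- obj[keep]; sj <- sj[keep]
  n <- length(obj)
  if (n == 0) return(list(n = 0))
  list(n = n, obj_mean = mean(obj), obj_sd = sd(obj),
       subj_mean = mean(sj), subj_sd = sd(sj))
}

# tiny deterministic cohort for grid tests: a few participants, sessions
# of hand-chosen durations scattered across the 8-day window
toy_cohort <- function(n_participants = 3, seed = 42) {
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      pid <- sprintf("T%02d", p)
      k <- 60
      day <- sample(0:7, k, replace = TRUE)
      tod <- runif(k, 0, 86000)
      dur <- sample(c(runif(k / 2, 1, 30),          # blip-scale
                      runif(k / 4, 60, 3600),       # normal use
                      runif(k / 4, 3600, 8 * 3600)  # long / artifact-scale
                      ))[seq_len(k)]
      start <- sort(day * 86400 + tod)
      # enforce non-overlap by pushing starts after previous end
      end <- numeric(k)
      cur <- 0
      for (i in seq_len(k)) {
        s0 <- max(start[i], cur)
        end[i] <- s0 + dur[i]
        start[i] <- s0
        cur <- end[i]
      }
      t0 <- as.POSIXct("2017-04-05 00:00:00", tz = TEST_ZONE)
      dur_n <- end - start
      rows[[pid]] <- tibble::tibble(
        participant_id = pid,
        session_id = sprintf("%s#%04d", pid, seq_len(k)),
        start = t0 + start, end = t0 + end, duration_s = dur_n,
        split_of = NA_character_)
    }
    sessions <- dplyr::bind_rows(rows)
    subj <- tibble::tibble(
      participant_id = rep(sprintf("T%02d", seq_len(n_participants)), 2),
      period = rep(c("weekday", "weekend"), each = n_participants),
      subjective_min = runif(2 * n_participants, 60, 300))
    list(sessions = sessions, subjective = subj)
  })
}
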