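QUESTIONNAIRE_ITEMS <- paste0("Q", 1:14)

# Adapted sedentary behaviour questionnaire: behaviour covered by each item,
# in instrument order. Minutes/day, asked separately for a typical weekday
# and a typical weekend day.
SBQ_ITEM_LABELS <- c(
  Q1  = "Watching television",
  Q2  = "Internet surfing or general work on a desktop/laptop/tablet",
  Q3  = "Internet surfing or general work on a smartphone",
  Q4  = "Playing games on a desktop/laptop or television screen",
  Q5  = "Playing games on a smartphone or handheld video game console",
  Q6  = "Texting",
  Q7  = "Sitting and reading a paper-based book/magazine",
  Q8  = "Sitting and reading an electronic book/magazine on a desktop/laptop/tablet",
  Q9  = "Sitting and reading an electronic book/magazine on a smartphone",
  Q10 = "Sitting and listening to music",
  Q11 = "Sitting and talking on the phone",
  Q12 = "Sitting and playing a musical instrument",
  Q13 = "Sitting and doing artwork/craft",
  Q14 = "Driving/riding in a car/bus/train or other motorised transportation"
)

#' Items of the adapted sedentary behaviour questionnaire
#'
#' The 14 screen-and-sitting behaviours of the adapted sedentary behaviour
#' questionnaire, keyed `Q1`..`Q14` in instrument order. Each is answered
#' in minutes per day, once for a typical weekday and once for a typical
#' weekend day.
#'
#' @return A tibble `item, label`.
#' @export
sbq_items <- function() {
  tibble::tibble(item = QUESTIONNAIRE_ITEMS,
                 label = unname(SBQ_ITEM_LABELS))
}

#' Default smartphone screen-time item subset
#'
#' The items on which time is necessarily accumulated looking at a
#' smartphone screen: internet/general work on a smartphone (Q3),
#' smartphone or handheld gaming (Q5), texting (Q6) and smartphone
#' e-reading (Q9). Talking on the phone (Q11) is excluded because a call
#' does not require the screen to be on. Fully configurable.
#'
#' @param items Character vector of item keys in `Q1`..`Q14`.
#' @return The validated item vector.
#' @export
smartphone_items <- function(items = c("Q3", "Q5", "Q6", "Q9")) {
  if (length(items) == 0) stop("item set must be non-empty", call. = FALSE)
  bad <- setdiff(items, QUESTIONNAIRE_ITEMS)
  if (length(bad) > 0) {
    stop("unknown questionnaire item(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  items
}

#' Read questionnaire responses
#'
#' Reads a CSV with columns `participant_id, period, Q1..Q14` where
#' `period` is `"weekday"` or `"weekend"` and item values are minutes per
#' day. Missing cells stay missing (they are *not* zero: an unanswered
#' item is unknown time, not no time). Negative minutes are an error.
#'
#' @param path Path to the CSV.
#' @param strict If `TRUE`, columns beyond `participant_id`, `period` and
#'   `Q1`..`Q14` are an error instead of being ignored.
#' @return A tibble `participant_id, period, Q1..Q14` (items present in
#'   the file only).
#' @export
read_questionnaire <- function(path, strict = FALSE) {
  if (!file.exists(path)) {
    stop("questionnaire file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    period = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!all(c("participant_id", "period") %in% names(raw))) {
    stop("questionnaire needs participant_id and period columns",
         call. = FALSE)
  }
  extra <- setdiff(names(raw), c("participant_id", "period", QUESTIONNAIRE_ITEMS))
  if (length(extra) > 0) {
    if (strict) {
      stop("unknown questionnaire column(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    raw <- raw[setdiff(names(raw), extra)]
  }
  bad_period <- !raw$period %in% c("weekday", "weekend")
  if (any(bad_period)) {
    stop("period must be weekday or weekend (row ",
         which(bad_period)[1], ")", call. = FALSE)
  }
  items <- intersect(QUESTIONNAIRE_ITEMS, names(raw))
  for (it in items) {
    neg <- !is.na(raw[[it]]) & raw[[it]] < 0
    if (any(neg)) {
      stop("negative minutes in ", it, " (row ", which(neg)[1], ")",
           call. = FALSE)
    }
  }
  raw[c("participant_id", "period", items)]
}

#' Subjective smartphone screen time from questionnaire responses
#'
#' Sums the present values of the smartphone-relevant items for each
#' response row. When *every* item of the set is absent for a row the
#' result is `NA` — that participant/period contributes no subjective
#' measure and drops out of paired comparisons; a partial response sums
#' the items that are present. Enlarging the item set can never decrease
#' the result (items are non-negative).
#'
#' @param responses A response tibble from [read_questionnaire()] (or any
#'   tibble with item columns); one row per participant and period.
#' @param item_set Item subset from [smartphone_items()].
#' @return Numeric vector of minutes/day, one per row of `responses`.
#' @export
smartphone_screen_time <- function(responses, item_set = smartphone_items()) {
  item_set <- smartphone_items(item_set)
  present <- intersect(item_set, names(responses))
  if (length(present) == 0) {
    return(rep(NA_real_, nrow(responses)))
  }
  m <- as.matrix(responses[present])
  all_absent <- rowSums(!is.na(m)) == 0
  out <- rowSums(m, na.rm = TRUE)
  out[all_absent] <- NA_real_
  out
}
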