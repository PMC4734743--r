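#' Classify baseline smoking status
#'
#' A participant is a baseline smoker (at-least-monthly smoking) if *any* of
#' three baseline items gives a positive response: current smoking frequency
#' of at least once a month, having smoked one or more cigarettes in the
#' last 30 days, or a most recent cigarette within the last 30 days.
#' A missing item is treated as a non-positive response, so missingness can
#' never create a smoker. Note that a `freq` response of "less than once a
#' month" is *not* a positive response.
#'
#' Daily status additionally requires `freq` = "at least daily".
#'
#' @param items Data frame (or list) of baseline item codes with components
#'   `freq`, `smoked30`, `last_cig` (see [codebook()]). Vectors are recycled
#'   row-wise as in a data frame.
#' @return A list with logical vectors `smoker` and `daily` (never missing;
#'   `daily` implies `smoker`).
#' @export
#' @examples
#' classify_baseline_smoker(list(freq = 2, smoked30 = NA, last_cig = NA))
classify_baseline_smoker <- function(items) {
  items <- as.data.frame(items)
  freq <- items$freq
  smoked30 <- items$smoked30
  last_cig <- items$last_cig
  n <- max(length(freq), length(smoked30), length(last_cig))
  if (is.null(freq)) freq <- rep(NA_integer_, n)
  if (is.null(smoked30)) smoked30 <- rep(NA_integer_, n)
  if (is.null(last_cig)) last_cig <- rep(NA_integer_, n)
  validate_codes(freq, "freq")
  validate_codes(smoked30, "smoked30")
  validate_codes(last_cig, "last_cig")
  pos_freq <- !is.na(freq) & freq >= 2           # at least monthly
  pos_30   <- !is.na(smoked30) & smoked30 == 1
  pos_last <- !is.na(last_cig) & last_cig >= 7   # within the last 30 days
  smoker <- pos_freq | pos_30 | pos_last
  daily  <- !is.na(freq) & freq == 4
  list(smoker = smoker, daily = daily)
}

# last_cig codes consistent with each prolonged-abstinence duration
# (code 0 = never smoked counts as abstinent at every duration)
.duration_cut <- c("6y" = 1L, "3y" = 2L, "1y" = 3L, "6mo" = 4L)

#' Derive a prolonged-abstinence endpoint from one wave's items
#'
#' Prolonged abstinence of a given duration is affirmed conservatively: it
#' requires *consistent* reporting of abstinence on all three abstinence
#' items -- the last cigarette at least as long ago as the duration, current
#' smoking frequency "not at all", and "0 days" smoked of the last 30. Any
#' non-missing item that reports smoking more recent than the duration
#' forces `FALSE`; if no item contradicts abstinence but one or more of the
#' three is missing, consistency cannot be confirmed and the result is
#' missing (`NA`).
#'
#' @param items Data frame (or list) with components `last_cig`, `freq`,
#'   `days30` carrying one follow-up wave's codes.
#' @param duration One of `"6y"`, `"3y"`, `"1y"`, `"6mo"`.
#' @return Logical vector (with `NA` for undeterminable rows).
#' @export
#' @examples
#' derive_prolonged_abstinence(list(last_cig = 1, freq = 0, days30 = 0), "6y")
derive_prolonged_abstinence <- function(items, duration = c("6y", "3y", "1y", "6mo")) {
  duration <- match.arg(duration)
  items <- as.data.frame(items)
  last_cig <- items$last_cig
  freq <- items$freq
  days30 <- items$days30
  validate_codes(last_cig, "last_cig")
  validate_codes(freq, "freq")
  validate_codes(days30, "days30")
  cut <- .duration_cut[[duration]]
  res <- rep(NA, length(last_cig))
  contra <- (!is.na(last_cig) & last_cig > cut) |
            (!is.na(freq) & freq > 0L) |
            (!is.na(days30) & days30 > 0L)
  affirm <- !is.na(last_cig) & !is.na(freq) & !is.na(days30) &
            last_cig <= cut & freq == 0L & days30 == 0L
  res[contra] <- FALSE
  res[affirm] <- TRUE
  res
}

# the six sustained-progress measures: item name, flag name, direction of
# improvement (+1 = higher code is better, -1 = lower code is better)
.progress_measures <- data.frame(
  item = c("days30", "freq", "cigs_day", "quit_len", "ladder", "stage"),
  flag = c("prog_days30", "prog_freq", "prog_cigs", "prog_quitlen",
           "prog_ladder", "prog_stage"),
  dir  = c(-1L, -1L, -1L, 1L, 1L, 1L),
  stringsAsFactors = FALSE
)

#' Derive sustained-progress flags across three waves
#'
#' For each of six measures (days smoked of the last 30, smoking frequency,
#' cigarettes per day, longest quit-attempt length, contemplation ladder,
#' stage of change) the flag is `TRUE` when progress was *sustained*:
#' strict improvement from baseline to the first follow-up, no regression
#' from the first to the second follow-up, and a second follow-up strictly
#' better than baseline. "Better" is lower for the three smoking-level
#' measures and higher for quit length, ladder and stage. A flag is missing
#' wherever any of its three inputs is missing.
#'
#' @param baseline,plus1,plus7 Data frames of item codes for the three waves.
#' @param mode `"no-regress"` (default: strict first step, non-strict second
#'   step, strict overall) or `"strict-both"` (both steps strict), provided
#'   as a sensitivity switch since "consistently reduced" admits either
#'   reading.
#' @return Data frame of six logical columns `prog_days30`, `prog_freq`,
#'   `prog_cigs`, `prog_quitlen`, `prog_ladder`, `prog_stage`.
#' @export
derive_progress_flags <- function(baseline, plus1, plus7,
                                  mode = c("no-regress", "strict-both")) {
  mode <- match.arg(mode)
  baseline <- as.data.frame(baseline)
  plus1 <- as.data.frame(plus1)
  plus7 <- as.data.frame(plus7)
  n <- nrow(baseline)
  out <- data.frame(matrix(NA, n, nrow(.progress_measures)))
  names(out) <- .progress_measures$flag
  for (i in seq_len(nrow(.progress_measures))) {
    m <- .progress_measures$item[i]
    dir <- .progress_measures$dir[i]
    b  <- if (m %in% names(baseline)) baseline[[m]] else rep(NA_integer_, n)
    p1 <- if (m %in% names(plus1)) plus1[[m]] else rep(NA_integer_, n)
    p7 <- if (m %in% names(plus7)) plus7[[m]] else rep(NA_integer_, n)
    validate_codes(b, m); validate_codes(p1, m); validate_codes(p7, m)
    step1 <- dir * (p1 - b) > 0
    step2 <- if (mode == "no-regress") dir * (p7 - p1) >= 0 else dir * (p7 - p1) > 0
    overall <- dir * (p7 - b) > 0
    out[[.progress_measures$flag[i]]] <- step1 & step2 & overall
  }
  out
}

#' Derive all trial endpoints on a participant dataset
#'
#' Adds the derived binary endpoint columns to a participant data frame (or
#' the participant table of a [trial_dataset()]): baseline smoker/daily
#' flags, prolonged abstinence at the four durations from the Plus-7 items,
#' 6-month prolonged abstinence from the Plus-1 items, the consistent
#' (both-wave) abstinence endpoint, and the six sustained-progress flags.
#' Item columns are wave-prefixed: `b_`, `p1_`, `p7_`.
#'
#' @param x A participant data frame or `trial_dataset`.
#' @param progress_mode Passed to [derive_progress_flags()].
#' @return Object of the same type with endpoint columns appended/replaced.
#' @export
derive_endpoints <- function(x, progress_mode = "no-regress") {
  if (inherits(x, "trial_dataset")) {
    x$participants <- derive_endpoints(x$participants, progress_mode)
    return(x)
  }
  data <- x
  b  <- wave_items(data, "b")
  p1 <- wave_items(data, "p1")
  p7 <- wave_items(data, "p7")
  cls <- classify_baseline_smoker(b)
  data$baseline_smoker <- cls$smoker
  data$baseline_daily  <- cls$daily
  for (d in names(.duration_cut)) {
    data[[paste0("abst_", d)]] <- derive_prolonged_abstinence(p7, d)
  }
  data$abst_6mo_plus1 <- derive_prolonged_abstinence(p1, "6mo")
  data$consistent_abst <- data$abst_6mo_plus1 & data$abst_6mo
  prog <- derive_progress_flags(b, p1, p7, mode = progress_mode)
  for (nm in names(prog)) data[[nm]] <- prog[[nm]]
  data
}
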