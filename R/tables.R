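#' Render a results table
#'
#' Computes one of the trial's four report tables from a derived dataset:
#'
#' 1. Main endpoint (longest-duration prolonged abstinence) for all smokers
#'    and the daily / less-than-daily baseline strata.
#' 2. The shorter-duration (sleeper-effect) prolonged-abstinence endpoints
#'    for the same three baseline groups.
#' 3. The main endpoint by a priori baseline subgroups (quit attempt in the
#'    past year; stage of change).
#' 4. The relapse / delayed-abstinence transition decomposition.
#'
#' Tables 1-3 report, overall and by gender, the per-arm percentages, the
#' difference in percentage points with its test-inversion confidence
#' interval, and the two-sided permutation p-value. The pair-exclusion rule
#' is applied per cell and the excluded pairs are recorded in the
#' `excluded` attribute.
#'
#' @param data Participant data frame or `trial_dataset` with derived
#'   endpoint columns.
#' @param table Table number, 1-4.
#' @param level Confidence level.
#' @inheritParams permutation_test
#' @param tol CI bisection tolerance, percentage points.
#' @return For tables 1-3 a `results_table` data frame (one row per cell and
#'   gender group); for table 4 a long data frame of transition cells with
#'   the consistent-effect tests in attributes.
#' @export
run_table <- function(data, table = 1L, level = 0.95,
                      statistic = c("pooled", "school_mean"),
                      exact_threshold = 20L, n_resamples = 1e5L,
                      seed = NULL, tol = 0.05) {
  statistic <- match.arg(statistic)
  data <- participants(data)
  if (!table %in% 1:4) stop("table must be 1, 2, 3 or 4", call. = FALSE)
  genders <- list(female = c(gender = "F"), male = c(gender = "M"), all = NULL)
  need_wave <- function(cols, wave) {
    if (!any(cols %in% names(data)))
      stop("dataset lacks the ", wave, " wave columns needed for table ",
           table, call. = FALSE)
  }
  if (table %in% c(1L, 2L, 3L)) need_wave(c("abst_6y", "abst_6mo"), "Plus-7")
  if (table == 4L) need_wave("abst_6mo_plus1", "Plus-1")

  if (table == 4L) {
    rows <- list()
    tests <- list()
    for (g in names(genders)) {
      tr <- transition_analysis(data, subgroup = genders[[g]],
                                statistic = statistic,
                                exact_threshold = exact_threshold,
                                n_resamples = n_resamples, seed = seed)
      for (section in c("relapse", "delayed")) {
        df <- tr[[section]]
        df$section <- section
        df$gender <- g
        rows[[length(rows) + 1L]] <- df
      }
      tests[[g]] <- tr$consistent
    }
    out <- do.call(rbind, rows)
    out <- out[, c("section", "group", "gender", "arm", "n", "events", "pct")]
    attr(out, "consistent_tests") <- tests
    class(out) <- c("results_table", "data.frame")
    attr(out, "table") <- 4L
    return(out)
  }

  specs <- switch(as.character(table),
    "1" = list(
      list(label = "All smokers", endpoint = "abst_6y", subgroup = NULL),
      list(label = "Daily smokers", endpoint = "abst_6y",
           subgroup = c(baseline_daily = "TRUE")),
      list(label = "Less-than-daily smokers", endpoint = "abst_6y",
           subgroup = c(baseline_daily = "FALSE"))),
    "2" = {
      eps <- c("abst_3y", "abst_1y", "abst_6mo")
      labs <- c("3-yr abstinence", "1-yr abstinence", "6-mo abstinence")
      groups <- list(NULL, c(baseline_daily = "TRUE"), c(baseline_daily = "FALSE"))
      glabs <- c("All smokers", "Daily smokers", "Less-than-daily smokers")
      out <- list()
      for (gi in seq_along(groups)) for (ei in seq_along(eps))
        out[[length(out) + 1L]] <- list(
          label = paste0(glabs[gi], ": ", labs[ei]),
          endpoint = eps[ei], subgroup = groups[[gi]])
      out
    },
    "3" = list(
      list(label = "Quit attempt: none", endpoint = "abst_6y",
           subgroup = c(b_quit_attempt = "0")),
      list(label = "Quit attempt: one or more", endpoint = "abst_6y",
           subgroup = c(b_quit_attempt = "1")),
      list(label = "Stage: precontemplation", endpoint = "abst_6y",
           subgroup = c(b_stage = "1")),
      list(label = "Stage: contemplation", endpoint = "abst_6y",
           subgroup = c(b_stage = "2")),
      list(label = "Stage: preparation", endpoint = "abst_6y",
           subgroup = c(b_stage = "3"))))

  rows <- list()
  excluded <- list()
  for (sp in specs) {
    for (g in names(genders)) {
      sub <- c(sp$subgroup, genders[[g]])
      ps <- summarize_pairs(data, sp$endpoint, subgroup = sub)
      res <- perm_inference(ps, level = level, statistic = statistic,
                            exact_threshold = exact_threshold,
                            n_resamples = n_resamples, seed = seed, tol = tol)
      rows[[length(rows) + 1L]] <- data.frame(
        row = sp$label, gender = g, endpoint = sp$endpoint,
        n = sum(ps$n_ctl) + sum(ps$n_exp),
        pct_control = arm_pct(ps, "control"),
        pct_experimental = arm_pct(ps, "experimental"),
        delta = res$delta, ci_low = res$ci_low, ci_high = res$ci_high,
        p = res$p_two_sided, n_pairs = res$n_pairs_used,
        stringsAsFactors = FALSE)
      ex <- attr(ps, "excluded_pairs")
      if (length(ex)) excluded[[paste(sp$label, g, sep = " / ")]] <- ex
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("results_table", "data.frame")
  attr(out, "table") <- as.integer(table)
  attr(out, "excluded") <- excluded
  attr(out, "level") <- level
  out
}

#' @export
print.results_table <- function(x, ...) {
  tbl <- attr(x, "table")
  if (identical(tbl, 4L)) {
    df <- as.data.frame(x)
    df$pct <- ifelse(is.na(df$pct), "-", sprintf("%.1f", df$pct))
    print(df, row.names = FALSE)
    tests <- attr(x, "consistent_tests")
    cat("\nConsistent (both-wave) abstinence effect, p two-sided:",
        paste(names(tests),
              sprintf("%.2f", vapply(tests, function(t) t$p_two_sided, 1)),
              sep = " = ", collapse = ", "), "\n")
    return(invisible(x))
  }
  df <- as.data.frame(x)
  df$Control <- sprintf("%.1f", df$pct_control)
  df$Experimental <- sprintf("%.1f", df$pct_experimental)
  df$`Delta (CI)` <- sprintf("%.1f (%.1f, %.1f)", df$delta, df$ci_low, df$ci_high)
  df$P <- sprintf("%.2f", df$p)
  print(df[, c("row", "gender", "n", "Control", "Experimental", "Delta (CI)", "P")],
        row.names = FALSE)
  ex <- attr(x, "excluded")
  if (length(ex)) {
    cat("\nPair-exclusion rule applied:\n")
    for (nm in names(ex))
      cat("  ", nm, ": pairs ", paste(ex[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
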