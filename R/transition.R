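#' Relapse / delayed-abstinence transition analysis
#'
#' Decomposes the decay of a short-term intervention effect between the two
#' follow-up waves, restricted to participants observed at both waves
#' (non-missing Plus-1 and Plus-7 six-month abstinence):
#'
#' * **Relapse**: among participants six-months abstinent at Plus-1, the
#'   percent (and count) *not* six-months abstinent at Plus-7, by arm within
#'   all baseline smokers, baseline daily smokers, and less-than-daily
#'   smokers.
#' * **Delayed abstinence**: among participants *not* six-months abstinent
#'   at Plus-1, the percent (and count) achieving six-year prolonged
#'   abstinence at Plus-7, in the same cells.
#' * **Consistent effect**: a permutation test of the restricted endpoint
#'   "abstinent at Plus-1 followed by abstinent at Plus-7"
#'   (`consistent_abst`) on the both-waves subset.
#'
#' An empty cell is reported with count 0 and missing percent.
#'
#' @param data Participant data frame or `trial_dataset` with derived
#'   endpoint columns (see [derive_endpoints()]).
#' @param subgroup Optional subgroup conditions applied first (e.g.
#'   `c(gender = "M")`).
#' @param ... Passed to [permutation_test()] for the consistent-effect test.
#' @return A list of class `transition_analysis` with data frames `relapse`
#'   and `delayed` (columns `group`, `arm`, `n`, `events`, `pct`), the
#'   `permutation_result` `consistent`, and `n_both_waves`.
#' @export
transition_analysis <- function(data, subgroup = NULL, ...) {
  data <- participants(data)
  need <- c("abst_6mo_plus1", "abst_6mo", "abst_6y", "baseline_daily", "arm")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset lacks derived columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(subgroup)) {
    for (nm in names(subgroup)) {
      data <- data[!is.na(data[[nm]]) &
                     as.character(data[[nm]]) == subgroup[[nm]], , drop = FALSE]
    }
  }
  both <- data[!is.na(data$abst_6mo_plus1) & !is.na(data$abst_6mo), , drop = FALSE]

  cells <- function(rows, event) {
    groups <- list(all = rep(TRUE, nrow(rows)),
                   daily = rows$baseline_daily,
                   less_than_daily = !rows$baseline_daily)
    out <- list()
    for (g in names(groups)) {
      for (a in c("control", "experimental")) {
        sel <- groups[[g]] & rows$arm == a
        n <- sum(sel)
        ev <- sum(event[sel])
        out[[length(out) + 1L]] <- data.frame(
          group = g, arm = a, n = n, events = ev,
          pct = if (n > 0L) 100 * ev / n else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }

  p1_abst <- both[both$abst_6mo_plus1, , drop = FALSE]
  p1_not  <- both[!both$abst_6mo_plus1, , drop = FALSE]
  relapse <- cells(p1_abst, !p1_abst$abst_6mo)
  # delayed abstinence needs a non-missing 6-year flag; for rows observed at
  # Plus-7 the 6-year flag can still be NA (partially missing items)
  p1_not_cc <- p1_not[!is.na(p1_not$abst_6y), , drop = FALSE]
  delayed <- cells(p1_not_cc, p1_not_cc$abst_6y)
  consistent <- permutation_test(summarize_pairs(both, "consistent_abst",
                                                 subgroup = NULL), ...)
  structure(list(relapse = relapse, delayed = delayed,
                 consistent = consistent, n_both_waves = nrow(both)),
            class = "transition_analysis")
}

#' @export
print.transition_analysis <- function(x, ...) {
  cat("Transition analysis (n observed at both waves =", x$n_both_waves, ")\n")
  cat("\nA. Relapse at the final wave among those abstinent at the first follow-up:\n")
  print(format_cells(x$relapse), row.names = FALSE)
  cat("\nB. Delayed long-term abstinence among those not abstinent at the first follow-up:\n")
  print(format_cells(x$delayed), row.names = FALSE)
  cat("\nC. Consistent (both-wave) abstinence effect:\n")
  print(x$consistent)
  invisible(x)
}

format_cells <- function(df) {
  df$pct <- ifelse(is.na(df$pct), "-", sprintf("%.1f", df$pct))
  df
}
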