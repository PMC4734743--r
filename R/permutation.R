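#' Summarize endpoint counts by school within matched pairs
#'
#' Collapses a participant dataset to per-school event/eligible counts for
#' one binary endpoint, arranged by matched pair -- the unit of permutation.
#' The analysis is complete-case: rows with a missing endpoint are dropped
#' before counting, so `n_eligible` is the number of endpoint-evaluable
#' participants. The subgroup pair-exclusion rule is applied: whenever a
#' school has no eligible participants in the requested subgroup, that
#' school *and its matched pair* are removed from the summary.
#'
#' @param data Participant data frame or `trial_dataset` with columns
#'   `school_id`, `pair_id`, `arm`, and the endpoint.
#' @param endpoint Name of a logical (or 0/1) endpoint column.
#' @param subgroup Optional named character vector of subgroup conditions,
#'   e.g. `c(gender = "M")` or `c(gender = "F", baseline_daily = "TRUE")`;
#'   rows must match all conditions (values compared as character).
#' @return A `pair_summary` data frame with one row per retained pair and
#'   columns `pair_id`, `school_ctl`, `school_exp`, `n_ctl`, `e_ctl`,
#'   `n_exp`, `e_exp`. Attributes record the endpoint, the subgroup and the
#'   excluded pairs.
#' @export
summarize_pairs <- function(data, endpoint, subgroup = NULL) {
  data <- participants(data)
  if (!endpoint %in% names(data))
    stop("endpoint '", endpoint, "' not found in dataset", call. = FALSE)
  req <- c("school_id", "pair_id", "arm")
  if (!all(req %in% names(data)))
    stop("dataset must carry columns ", paste(req, collapse = ", "), call. = FALSE)
  # full school/pair roster before any filtering, so that schools emptied by
  # the subgroup or by missingness still trigger the pair-exclusion rule
  roster <- unique(data[, c("school_id", "pair_id", "arm")])
  if (!is.null(subgroup)) {
    for (nm in names(subgroup)) {
      if (!nm %in% names(data))
        stop("subgroup variable '", nm, "' not found in dataset", call. = FALSE)
      keep <- !is.na(data[[nm]]) & as.character(data[[nm]]) == subgroup[[nm]]
      data <- data[keep, , drop = FALSE]
    }
  }
  y <- data[[endpoint]]
  data <- data[!is.na(y), , drop = FALSE]          # complete-case
  y <- as.logical(data[[endpoint]])
  n_by <- table(factor(data$school_id, levels = roster$school_id))
  e_by <- tapply(y, factor(data$school_id, levels = roster$school_id), sum)
  e_by[is.na(e_by)] <- 0L
  roster$n <- as.integer(n_by[roster$school_id])
  roster$e <- as.integer(e_by[roster$school_id])
  empty_pairs <- unique(roster$pair_id[roster$n == 0L])
  kept <- roster[!roster$pair_id %in% empty_pairs, , drop = FALSE]
  ctl <- kept[kept$arm == "control", ]
  exp <- kept[kept$arm == "experimental", ]
  ctl <- ctl[order(ctl$pair_id), ]
  exp <- exp[order(exp$pair_id), ]
  if (!identical(ctl$pair_id, exp$pair_id))
    stop("each pair must have exactly one school per arm", call. = FALSE)
  out <- data.frame(pair_id = ctl$pair_id,
                    school_ctl = ctl$school_id, school_exp = exp$school_id,
                    n_ctl = ctl$n, e_ctl = ctl$e,
                    n_exp = exp$n, e_exp = exp$e,
                    stringsAsFactors = FALSE)
  structure(out, class = c("pair_summary", "data.frame"),
            endpoint = endpoint, subgroup = subgroup,
            excluded_pairs = sort(empty_pairs))
}

# pooled arm percentage (participant-level) over retained schools
arm_pct <- function(ps, arm = c("control", "experimental")) {
  arm <- match.arg(arm)
  if (arm == "control") 100 * sum(ps$e_ctl) / sum(ps$n_ctl)
  else 100 * sum(ps$e_exp) / sum(ps$n_exp)
}

# ---- swap engine ------------------------------------------------------------
#
# The randomization distribution is generated by within-pair arm swaps.  A
# swap vector s in {0,1}^K flips pair k's arms when s_k = 1.  The engine
# holds the swap matrix (all 2^K rows in exact mode, or seeded random rows
# plus the observed all-zero row in Monte Carlo mode) and recomputes the
# statistic for every row by matrix arithmetic.  Row 1 is always the
# observed arrangement.

perm_engine <- function(slist, weights, statistic, exact_threshold,
                        n_resamples, seed) {
  pair_ids <- sort(unique(unlist(lapply(slist, function(s) s$pair_id))))
  K <- length(pair_ids)
  if (K < 2L) stop("at least 2 pairs are required (got ", K, ")", call. = FALSE)
  if (K <= exact_threshold) {
    idx <- 0:(2^K - 1)
    S <- vapply(seq_len(K),
                function(k) as.numeric(bitwAnd(idx, 2L^(k - 1L)) > 0L),
                numeric(length(idx)))
    mode <- "exact"
  } else {
    if (n_resamples < 100L)
      stop("n_resamples must be at least 100 (got ", n_resamples, ")", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    S <- matrix(as.numeric(stats::rbinom(n_resamples * K, 1L, 0.5)),
                n_resamples, K)
    S <- rbind(matrix(0, 1L, K), S)
    mode <- "monte_carlo"
  }
  structure(list(S = S, slist = slist, weights = weights,
                 statistic = statistic, pair_ids = pair_ids, K = K,
                 mode = mode,
                 n_resamples = if (mode == "monte_carlo") as.integer(n_resamples) else NA_integer_,
                 seed = seed),
            class = "perm_engine")
}

# statistic for every swap row, under a hypothesized effect `delta`
# (percentage points).  The location-shift adjustment removes delta from the
# observed-experimental schools' outcomes (event counts shifted by
# delta/100 * n) before re-enacting the swaps, so row 1 equals T_obs - delta
# and the reference rows are exchangeable under the hypothesis.
swap_stats <- function(eng, delta = 0) {
  total <- 0
  for (i in seq_along(eng$slist)) {
    s <- eng$slist[[i]]
    cols <- match(s$pair_id, eng$pair_ids)
    Ssub <- eng$S[, cols, drop = FALSE]
    eE <- s$e_exp - delta / 100 * s$n_exp
    eC <- s$e_ctl
    if (eng$statistic == "pooled") {
      expe <- sum(eE) + Ssub %*% (eC - eE)
      expn <- sum(s$n_exp) + Ssub %*% (s$n_ctl - s$n_exp)
      ctle <- sum(eC) + Ssub %*% (eE - eC)
      ctln <- sum(s$n_ctl) + Ssub %*% (s$n_exp - s$n_ctl)
      Ti <- 100 * (expe / expn - ctle / ctln)
    } else {
      d <- 100 * (eE / s$n_exp - eC / s$n_ctl)
      Ti <- (sum(d) - 2 * (Ssub %*% d)) / length(d)
    }
    total <- total + eng$weights[i] * Ti
  }
  drop(total)
}

# two-sided p: proportion of reference values at least as extreme as the
# observed, ties counted as extreme, observed arrangement included
engine_p <- function(eng, delta = 0) {
  Tv <- swap_stats(eng, delta)
  mean(abs(Tv) >= abs(Tv[1L]) - 1e-9)
}

#' Matched-pair permutation test
#'
#' Tests the null hypothesis of no intervention effect by re-enacting the
#' within-pair randomization. The observed statistic is the difference in
#' arm percentages, experimental minus control, in percentage points. With
#' `statistic = "pooled"` each arm's percentage pools participants across
#' that arm's retained schools (the participant-level percentage reported in
#' trial tables); with `statistic = "school_mean"` it is the unweighted mean
#' of school-level percentages. The reference distribution recomputes the
#' statistic under all `2^K` within-pair arm swaps when the number of pairs
#' `K` is at most `exact_threshold` (exact mode), otherwise under
#' `n_resamples` seeded random swap vectors plus the observed arrangement
#' (Monte Carlo mode). The two-sided p-value is the proportion of reference
#' values whose absolute value reaches the observed one, ties counted as
#' extreme.
#'
#' @param summaries A `pair_summary` from [summarize_pairs()].
#' @param statistic `"pooled"` (default) or `"school_mean"`.
#' @param exact_threshold Largest `K` for exhaustive enumeration.
#' @param n_resamples Number of Monte Carlo swap vectors when `K` exceeds
#'   `exact_threshold`; must be at least 100.
#' @param seed Optional integer seed for Monte Carlo mode.
#' @return A `permutation_result` with elements `delta`, `p_two_sided`,
#'   `ci_low`/`ci_high` (`NA`; see [permutation_ci()]), `n_pairs_used`,
#'   `mode`, `n_resamples`, `seed`.
#' @export
permutation_test <- function(summaries, statistic = c("pooled", "school_mean"),
                             exact_threshold = 20L, n_resamples = 1e5L,
                             seed = NULL) {
  statistic <- match.arg(statistic)
  eng <- perm_engine(list(summaries), 1, statistic, exact_threshold,
                     n_resamples, seed)
  Tv <- swap_stats(eng)
  perm_result(delta = Tv[1L],
              p = mean(abs(Tv) >= abs(Tv[1L]) - 1e-9),
              eng = eng, statistic = statistic,
              endpoint = attr(summaries, "endpoint"),
              subgroup = attr(summaries, "subgroup"))
}

#' Permutation confidence interval by test inversion
#'
#' The confidence interval is the set of hypothesized effects `delta` (in
#' percentage points) not rejected by the two-sided permutation test of the
#' location-shifted statistic: shift the observed-experimental outcomes by
#' `-delta`, re-enact the swaps, and retain `delta` when the shifted p-value
#' is at least `1 - level`. Interval endpoints are located by bisection to a
#' tolerance of `tol` percentage points. With a small number of pairs the
#' smallest attainable two-sided p-value, `2/2^K`, can exceed `1 - level`;
#' the interval is then unbounded and `c(-Inf, Inf)` is returned with a
#' warning.
#'
#' @inheritParams permutation_test
#' @param level Confidence level (default 0.95).
#' @param tol Bisection tolerance in percentage points (default 0.05).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
permutation_ci <- function(summaries, level = 0.95,
                           statistic = c("pooled", "school_mean"),
                           exact_threshold = 20L, n_resamples = 1e5L,
                           seed = NULL, tol = 0.05) {
  statistic <- match.arg(statistic)
  eng <- perm_engine(list(summaries), 1, statistic, exact_threshold,
                     n_resamples, seed)
  engine_ci(eng, level = level, tol = tol)
}

engine_ci <- function(eng, level = 0.95, tol = 0.05) {
  alpha <- 1 - level
  N <- nrow(eng$S)
  if (2 / N > alpha) {
    warning("confidence level ", level, " is not attainable from ", N,
            " swap vectors; interval is unbounded", call. = FALSE)
    return(c(-Inf, Inf))
  }
  Tv <- swap_stats(eng, 0)
  dobs <- Tv[1L]
  span <- max(diff(range(Tv)), 1)
  bound <- function(side) {  # side = -1 lower, +1 upper
    lo <- dobs
    step <- span
    repeat {
      cand <- dobs + side * step
      if (engine_p(eng, cand) < alpha) break
      step <- 2 * step
      if (step > 1e6 * span) return(side * Inf)
    }
    inner <- dobs
    outer <- dobs + side * step
    while (abs(outer - inner) > tol) {
      mid <- (inner + outer) / 2
      if (engine_p(eng, mid) >= alpha) inner <- mid else outer <- mid
    }
    (inner + outer) / 2
  }
  c(bound(-1), bound(1))
}

#' Combined test and confidence interval
#'
#' Convenience wrapper running [permutation_test()] and the test-inversion
#' confidence interval on one swap engine (so Monte Carlo mode uses the same
#' resamples for both).
#'
#' @inheritParams permutation_ci
#' @return A complete `permutation_result` (with CI bounds).
#' @export
perm_inference <- function(summaries, level = 0.95,
                           statistic = c("pooled", "school_mean"),
                           exact_threshold = 20L, n_resamples = 1e5L,
                           seed = NULL, tol = 0.05) {
  statistic <- match.arg(statistic)
  eng <- perm_engine(list(summaries), 1, statistic, exact_threshold,
                     n_resamples, seed)
  Tv <- swap_stats(eng)
  ci <- engine_ci(eng, level = level, tol = tol)
  perm_result(delta = Tv[1L],
              p = mean(abs(Tv) >= abs(Tv[1L]) - 1e-9),
              eng = eng, statistic = statistic, ci = ci, level = level,
              endpoint = attr(summaries, "endpoint"),
              subgroup = attr(summaries, "subgroup"))
}

perm_result <- function(delta, p, eng, statistic, ci = c(NA_real_, NA_real_),
                        level = NA_real_, endpoint = NULL, subgroup = NULL,
                        extra = NULL) {
  structure(c(list(delta = as.numeric(delta), p_two_sided = p,
                   ci_low = ci[1L], ci_high = ci[2L], level = level,
                   n_pairs_used = eng$K, mode = eng$mode,
                   n_resamples = eng$n_resamples, seed = eng$seed,
                   statistic = statistic, endpoint = endpoint,
                   subgroup = subgroup), extra),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Matched-pair permutation test (", x$mode, ", ", x$statistic,
      " statistic)\n", sep = "")
  if (!is.null(x$endpoint)) cat("  endpoint:", x$endpoint, "\n")
  if (!is.null(x$subgroup) && length(x$subgroup))
    cat("  subgroup:", paste(names(x$subgroup), x$subgroup,
                             sep = " = ", collapse = ", "), "\n")
  cat(sprintf("  delta = %.1f pp", x$delta))
  if (!is.na(x$ci_low))
    cat(sprintf("  %d%% CI = (%.1f, %.1f)", round(100 * x$level),
                x$ci_low, x$ci_high))
  cat(sprintf("  p = %.2f  (K = %d pairs)\n", x$p_two_sided, x$n_pairs_used))
  invisible(x)
}

#' Stratified matched-pair permutation test
#'
#' Adjusts for a baseline stratification (by default daily vs
#' less-than-daily baseline smoking) by combining per-stratum arm
#' differences into a single statistic: a weighted sum with each stratum's
#' weight equal to its share of endpoint-evaluable participants. Weights are
#' computed from the observed data and held fixed across permutations; the
#' same swap vector is applied to every stratum (the school, not the
#' stratum, is the randomized unit). A stratum in which fewer than two pairs
#' survive the pair-exclusion rule, or in which one arm has no evaluable
#' participants, is dropped with a warning.
#'
#' @param data Participant data frame or `trial_dataset` with derived
#'   endpoint columns.
#' @param endpoint Endpoint column name.
#' @param strata Column defining the strata (default `"baseline_daily"`).
#' @param subgroup Optional subgroup conditions as in [summarize_pairs()].
#' @param level Confidence level for the inverted CI (`NULL` to skip).
#' @inheritParams permutation_test
#' @param tol Bisection tolerance for the CI, percentage points.
#' @return A `permutation_result`; the element `strata` records levels,
#'   weights and per-stratum deltas.
#' @export
stratified_test <- function(data, endpoint, strata = "baseline_daily",
                            subgroup = NULL,
                            statistic = c("pooled", "school_mean"),
                            exact_threshold = 20L, n_resamples = 1e5L,
                            seed = NULL, level = 0.95, tol = 0.05) {
  statistic <- match.arg(statistic)
  data <- participants(data)
  if (!strata %in% names(data))
    stop("stratum column '", strata, "' not found in dataset", call. = FALSE)
  levs <- sort(unique(as.character(data[[strata]][!is.na(data[[strata]])])))
  slist <- list()
  sizes <- numeric(0)
  for (lv in levs) {
    ps <- tryCatch(
      summarize_pairs(data, endpoint, subgroup = c(subgroup, stats::setNames(lv, strata))),
      error = function(e) NULL)
    if (is.null(ps) || nrow(ps) < 2L ||
        sum(ps$n_ctl) == 0L || sum(ps$n_exp) == 0L) {
      warning("stratum ", strata, " = ", lv,
              " dropped (insufficient evaluable participants)", call. = FALSE)
      next
    }
    slist[[lv]] <- ps
    sizes[lv] <- sum(ps$n_ctl) + sum(ps$n_exp)
  }
  if (!length(slist)) stop("no usable stratum", call. = FALSE)
  weights <- sizes / sum(sizes)
  eng <- perm_engine(slist, weights, statistic, exact_threshold,
                     n_resamples, seed)
  Tv <- swap_stats(eng)
  ci <- if (is.null(level)) c(NA_real_, NA_real_)
        else engine_ci(eng, level = level, tol = tol)
  per_stratum <- vapply(slist, function(ps)
    arm_pct(ps, "experimental") - arm_pct(ps, "control"), numeric(1))
  perm_result(delta = Tv[1L],
              p = mean(abs(Tv) >= abs(Tv[1L]) - 1e-9),
              eng = eng, statistic = statistic, ci = ci,
              level = if (is.null(level)) NA_real_ else level,
              endpoint = endpoint, subgroup = subgroup,
              extra = list(strata = list(variable = strata,
                                         levels = names(slist),
                                         weights = weights,
                                         delta_by_stratum = per_stratum)))
}
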