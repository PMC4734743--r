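#' Match clusters into pairs on baseline covariates
#'
#' Forms a perfect matching of schools minimizing the total pairwise
#' distance, where distance is Euclidean over z-scored matching covariates
#' (by default: number of smokers, smoking prevalence, fraction eligible for
#' free/reduced-price meals, and mean stage-of-readiness score). For up to
#' `brute_limit` schools the optimum is found by branch-and-bound
#' enumeration of all perfect matchings; above that, a greedy closest-pair
#' construction is refined by 2-opt exchanges until no re-pairing of two
#' pairs lowers the cost. Schools are processed in lexicographic
#' `school_id` order, which fixes tie-breaking and makes the result
#' deterministic.
#'
#' @param schools Data frame with column `school_id` and the matching
#'   covariates (no missing values).
#' @param covariates Character vector of covariate column names.
#' @param brute_limit Maximum number of schools for exhaustive search.
#' @return Data frame with columns `pair_id`, `school_a`, `school_b`;
#'   attributes `total_cost` (sum of matched distances) and `method`.
#' @export
match_pairs <- function(schools,
                        covariates = c("n_smokers", "smoking_prev",
                                       "frl_frac", "mean_readiness"),
                        brute_limit = 12L) {
  if (!is.data.frame(schools) || !"school_id" %in% names(schools))
    stop("'schools' must be a data frame with a school_id column", call. = FALSE)
  n <- nrow(schools)
  if (n < 2L || n %% 2L != 0L)
    stop("number of schools must be even and at least 2 (got ", n, ")", call. = FALSE)
  missing <- covariates[!covariates %in% names(schools)]
  if (length(missing))
    stop("missing matching covariates: ", paste(missing, collapse = ", "), call. = FALSE)
  for (cv in covariates) {
    bad <- is.na(schools[[cv]])
    if (any(bad))
      stop("missing covariate '", cv, "' for school ",
           paste(schools$school_id[bad], collapse = ", "), call. = FALSE)
  }
  schools <- schools[order(as.character(schools$school_id)), , drop = FALSE]
  z <- sapply(covariates, function(cv) {
    x <- as.numeric(schools[[cv]])
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  })
  D <- as.matrix(stats::dist(z))
  mt <- if (n <= brute_limit) matching_brute(D) else matching_greedy_2opt(D)
  pairs <- data.frame(
    pair_id = sprintf("P%02d", seq_len(n %/% 2L)),
    school_a = schools$school_id[mt[, 1L]],
    school_b = schools$school_id[mt[, 2L]],
    stringsAsFactors = FALSE
  )
  attr(pairs, "total_cost") <- sum(D[mt])
  attr(pairs, "method") <- if (n <= brute_limit) "exhaustive" else "greedy+2opt"
  pairs
}

# exhaustive minimum-cost perfect matching with branch-and-bound pruning;
# first-found (lexicographic) matching wins ties
matching_brute <- function(D) {
  n <- nrow(D)
  best <- list(cost = Inf, m = NULL)
  rec <- function(avail, acc, cost) {
    if (cost >= best$cost) return()
    if (!length(avail)) {
      best <<- list(cost = cost, m = acc)
      return()
    }
    i <- avail[1L]
    for (j in avail[-1L]) {
      rec(setdiff(avail, c(i, j)), rbind(acc, c(i, j)), cost + D[i, j])
    }
  }
  rec(seq_len(n), NULL, 0)
  best$m
}

# greedy closest-pair start, then 2-opt re-pairing passes
matching_greedy_2opt <- function(D) {
  n <- nrow(D)
  avail <- rep(TRUE, n)
  m <- matrix(0L, n %/% 2L, 2L)
  for (k in seq_len(n %/% 2L)) {
    Dv <- D
    Dv[!avail, ] <- Inf
    Dv[, !avail] <- Inf
    diag(Dv) <- Inf
    ij <- which(Dv == min(Dv), arr.ind = TRUE)
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE][1L, ]  # deterministic tie-break
    ij <- sort(ij)
    m[k, ] <- ij
    avail[ij] <- FALSE
  }
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    np <- nrow(m)
    for (p in seq_len(np - 1L)) {
      for (q in seq((p + 1L), np)) {
        a <- m[p, 1L]; b <- m[p, 2L]; c <- m[q, 1L]; d <- m[q, 2L]
        cur <- D[a, b] + D[c, d]
        alt1 <- D[a, c] + D[b, d]
        alt2 <- D[a, d] + D[b, c]
        if (alt1 < cur - 1e-12 && alt1 <= alt2) {
          m[p, ] <- sort(c(a, c)); m[q, ] <- sort(c(b, d)); improved <- TRUE
        } else if (alt2 < cur - 1e-12) {
          m[p, ] <- sort(c(a, d)); m[q, ] <- sort(c(b, c)); improved <- TRUE
        }
      }
    }
  }
  m[order(m[, 1L]), , drop = FALSE]
}

#' Randomize arms within matched pairs
#'
#' Assigns one school of each pair to the experimental condition by an
#' independent fair coin flip per pair, reproducible for a fixed seed.
#'
#' @param pairs Data frame from [match_pairs()] (columns `pair_id`,
#'   `school_a`, `school_b`).
#' @param seed Optional integer seed; if `NULL`, the current RNG stream is
#'   used.
#' @return Data frame with columns `pair_id`, `school_a`, `school_b`,
#'   `arm_of_a` (`"experimental"` or `"control"`).
#' @export
randomize_pairs <- function(pairs, seed = NULL) {
  req <- c("pair_id", "school_a", "school_b")
  if (!all(req %in% names(pairs)))
    stop("'pairs' must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(c(pairs$school_a, pairs$school_b)))
    stop("each school may appear in exactly one pair", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  coin <- stats::rbinom(nrow(pairs), 1L, 0.5)
  out <- pairs[, req]
  out$arm_of_a <- ifelse(coin == 1L, "experimental", "control")
  out
}

#' Baseline balance audit by arm
#'
#' Summarizes baseline covariates by arm and attaches a matched-pair
#' permutation p-value per covariate, re-using the trial's own permutation
#' machinery. Binary (logical or 0/1) covariates are summarized as
#' percentages of participants with a non-missing value.
#'
#' @param data Participant data frame or `trial_dataset` with `arm`,
#'   `school_id`, `pair_id` and the covariate columns.
#' @param covariates Character vector of binary covariate columns; defaults
#'   to the derived baseline flags present in the data.
#' @param ... Passed to [permutation_test()] (e.g. `exact_threshold`,
#'   `n_resamples`, `seed`).
#' @return Data frame with one row per covariate: per-arm percentages,
#'   difference (experimental minus control, percentage points), p-value and
#'   pairs used.
#' @export
balance_table <- function(data, covariates = NULL, ...) {
  data <- participants(data)
  if (is.null(covariates)) {
    candidates <- c("baseline_daily", "female", "b_quit_attempt")
    covariates <- candidates[candidates %in% names(data)]
  }
  if (!nrow(data) || !all(c("experimental", "control") %in% data$arm))
    stop("both arms must be non-empty", call. = FALSE)
  rows <- lapply(covariates, function(cv) {
    ps <- summarize_pairs(data, cv)
    pt <- permutation_test(ps, ...)
    data.frame(covariate = cv,
               pct_control = arm_pct(ps, "control"),
               pct_experimental = arm_pct(ps, "experimental"),
               delta = pt$delta,
               p = pt$p_two_sided,
               n_pairs = pt$n_pairs_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
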