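#' Configuration for a synthetic matched-pair cluster trial
#'
#' Bundles and validates the generator parameters. The defaults emulate the
#' study conditions of a 50-school adolescent smoking-cessation trial:
#' 25 matched pairs, ~43 baseline smokers per school (~2,150 in total), a
#' control-arm six-year prolonged-abstinence rate of 13.1% with a +1.1
#' percentage-point arm effect, between-school heterogeneity expressed as an
#' intraclass correlation of 0.02, a daily-smoker baseline stratum of 34.5%
#' (control) vs 39.9% (experimental) to reproduce the kind of chance
#' imbalance such trials exhibit, 81.5% final-wave follow-up and 88.8%
#' first-follow-up response, a first-follow-up abstinence rate of 17.8%
#' (control) with a +4.0-point arm effect, and first-to-final-wave
#' transitions of 63.9% relapse and 7.9% delayed abstinence.
#'
#' @param n_pairs Number of matched pairs of schools.
#' @param school_size_mean,school_size_dispersion Mean and negative-binomial
#'   dispersion (`size` parameter; `Inf` = Poisson) of baseline smokers per
#'   school; sizes are truncated below at 4.
#' @param p_control Control-arm probability of the main (longest-duration)
#'   endpoint, in (0,1).
#' @param delta Arm effect on the main endpoint, percentage points.
#' @param icc Intraclass correlation of the endpoint within schools, in
#'   \[0,1): school endpoint probabilities are drawn from a Beta with mean
#'   equal to the arm rate and shape sum `(1-icc)/icc`.
#' @param daily_frac_control,daily_frac_experimental Probability that a
#'   participant is a baseline daily smoker, by arm.
#' @param followup_rate Probability that a participant returns the final
#'   (Plus-7) survey.
#' @param plus1_followup_rate Probability of returning the first follow-up
#'   (Plus-1) survey.
#' @param plus1_rate Control-arm probability of 6-month abstinence at the
#'   first follow-up.
#' @param plus1_delta Arm effect on first-follow-up abstinence, percentage
#'   points.
#' @param relapse_rate Probability that a first-follow-up abstainer is *not*
#'   six-months abstinent at the final wave.
#' @param delayed_rate Target probability that a first-follow-up
#'   non-abstainer achieves the longest-duration endpoint at the final wave
#'   (matched as closely as the margins allow; see the methods vignette).
#' @param duration_mult Multipliers giving the 3-year, 1-year and 6-month
#'   prolonged-abstinence rates relative to the 6-year rate.
#' @param female_frac Probability that a participant is female.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_pairs = 25L,
                             school_size_mean = 43,
                             school_size_dispersion = 8,
                             p_control = 0.131,
                             delta = 1.1,
                             icc = 0.02,
                             daily_frac_control = 0.345,
                             daily_frac_experimental = 0.399,
                             followup_rate = 0.815,
                             plus1_followup_rate = 0.888,
                             plus1_rate = 0.178,
                             plus1_delta = 4.0,
                             relapse_rate = 0.639,
                             delayed_rate = 0.079,
                             duration_mult = c(23.2, 32.9, 39.1) / 13.1,
                             female_frac = 0.47,
                             seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              school_size_mean = school_size_mean,
              school_size_dispersion = school_size_dispersion,
              p_control = p_control, delta = delta, icc = icc,
              daily_frac_control = daily_frac_control,
              daily_frac_experimental = daily_frac_experimental,
              followup_rate = followup_rate,
              plus1_followup_rate = plus1_followup_rate,
              plus1_rate = plus1_rate, plus1_delta = plus1_delta,
              relapse_rate = relapse_rate, delayed_rate = delayed_rate,
              duration_mult = duration_mult, female_frac = female_frac,
              seed = as.integer(seed))
  chk <- function(cond, field, what) {
    if (!cond) stop("invalid config field '", field, "': ", what, call. = FALSE)
  }
  chk(cfg$n_pairs >= 1L, "n_pairs", "must be a positive integer")
  chk(cfg$school_size_mean > 0, "school_size_mean", "must be positive")
  chk(cfg$school_size_dispersion > 0, "school_size_dispersion", "must be positive")
  chk(cfg$p_control > 0 && cfg$p_control < 1, "p_control", "must lie in (0,1)")
  p_exp <- cfg$p_control + cfg$delta / 100
  chk(p_exp > 0 && p_exp < 1, "delta", "p_control + delta/100 must lie in (0,1)")
  chk(cfg$icc >= 0 && cfg$icc < 1, "icc", "must lie in [0,1)")
  for (f in c("daily_frac_control", "daily_frac_experimental", "followup_rate",
              "plus1_followup_rate", "plus1_rate", "relapse_rate",
              "delayed_rate", "female_frac"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must lie in [0,1]")
  chk(length(cfg$duration_mult) == 3L && all(cfg$duration_mult >= 1) &&
        !is.unsorted(cfg$duration_mult), "duration_mult",
      "must be three non-decreasing multipliers >= 1")
  structure(cfg, class = "synthetic_config")
}

# P(first-follow-up abstinent | final-wave duration category), solved from
# the arm margins so that the first-follow-up abstinence rate q and the
# relapse rate r hold exactly; the delayed rate d is matched when the
# margins permit, otherwise approximated by clamping into [0,1].
transition_probs <- function(q, r, d, p_long, p_short) {
  c_long <- 1 - d * (1 - q) / p_long
  c_long <- min(max(c_long, 0), 1)
  c_band <- if (p_short > p_long) (q * (1 - r) - c_long * p_long) / (p_short - p_long) else 0
  if (c_band < 0) {
    c_long <- min(1, q * (1 - r) / p_long)
    c_band <- 0
  }
  c_band <- min(c_band, 1)
  c_none <- min(max(q * r / (1 - p_short), 0), 1)
  c(long = c_long, band = c_band, none = c_none)
}

#' Generate a synthetic matched-pair cluster trial
#'
#' Simulates a full trial dataset with the statistical structure the
#' matched-pair permutation analysis assumes: schools of random size with
#' baseline covariates, optimal pair-matching on those covariates, a seeded
#' within-pair coin-flip randomization, school-level endpoint probabilities
#' drawn from a Beta distribution parameterized by the intraclass
#' correlation (extra-binomial heterogeneity), participant-level baseline
#' strata and survey items, nested prolonged-abstinence durations at the
#' final wave (drawn as a single "time since last cigarette" category so
#' duration nesting holds by construction), first-follow-up abstinence
#' consistent with the configured relapse and delayed-abstinence rates, and
#' survey non-response at the configured follow-up rates. Endpoint flags are
#' derived from the generated item codes via [derive_endpoints()], so the
#' generator exercises the same derivation path as real data.
#'
#' @param config A [synthetic_config()].
#' @return A [trial_dataset()] with participants (item codes and derived
#'   flags), the school table and the pair assignment table.
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  set.seed(config$seed)
  K <- config$n_pairs
  nsch <- 2L * K

  sizes <- if (is.finite(config$school_size_dispersion)) {
    stats::rnbinom(nsch, mu = config$school_size_mean,
                   size = config$school_size_dispersion)
  } else {
    stats::rpois(nsch, config$school_size_mean)
  }
  sizes <- pmax(4L, sizes)
  schools <- data.frame(
    school_id = sprintf("S%03d", seq_len(nsch)),
    n_smokers = sizes,
    smoking_prev = stats::runif(nsch, 0.15, 0.40),
    frl_frac = stats::runif(nsch, 0.10, 0.60),
    mean_readiness = stats::runif(nsch, 1.2, 2.2),
    stringsAsFactors = FALSE)
  schools$wave <- c("I", "II", "III")[1L + (seq_len(nsch) - 1L) %% 3L]

  pairs <- match_pairs(schools)
  assignment <- randomize_pairs(pairs)        # consumes the seeded stream
  arm_lookup <- stats::setNames(
    c(ifelse(assignment$arm_of_a == "experimental", "experimental", "control"),
      ifelse(assignment$arm_of_a == "experimental", "control", "experimental")),
    c(assignment$school_a, assignment$school_b))
  pair_lookup <- stats::setNames(rep(assignment$pair_id, 2L),
                                 c(assignment$school_a, assignment$school_b))
  schools$arm <- unname(arm_lookup[schools$school_id])
  schools$pair_id <- unname(pair_lookup[schools$school_id])

  p_arm_sch <- ifelse(schools$arm == "experimental",
                      config$p_control + config$delta / 100, config$p_control)
  p_sch <- if (config$icc > 0) {
    ab <- (1 - config$icc) / config$icc
    stats::rbeta(nsch, p_arm_sch * ab, (1 - p_arm_sch) * ab)
  } else p_arm_sch
  m <- config$duration_mult
  cap <- 0.97
  t_6y <- pmin(p_sch, cap)
  t_3y <- pmin(pmax(t_6y, p_sch * m[1L]), cap)
  t_1y <- pmin(pmax(t_3y, p_sch * m[2L]), cap)
  t_6mo <- pmin(pmax(t_1y, p_sch * m[3L]), cap)

  np <- sum(schools$n_smokers)
  idx <- rep(seq_len(nsch), schools$n_smokers)
  arm <- schools$arm[idx]
  is_exp <- arm == "experimental"

  daily <- stats::runif(np) < ifelse(is_exp, config$daily_frac_experimental,
                                     config$daily_frac_control)
  female <- stats::runif(np) < config$female_frac

  # final-wave duration category: 4 = longest (6y) ... 1 = 6mo, 0 = none
  u <- stats::runif(np)
  cat7 <- (u < t_6mo[idx]) + (u < t_1y[idx]) + (u < t_3y[idx]) + (u < t_6y[idx])

  # first-follow-up abstinence, conditional on the final-wave category
  tp_c <- transition_probs(config$plus1_rate, config$relapse_rate,
                           config$delayed_rate, config$p_control,
                           min(config$p_control * m[3L], cap))
  tp_e <- transition_probs(config$plus1_rate + config$plus1_delta / 100,
                           config$relapse_rate, config$delayed_rate,
                           config$p_control + config$delta / 100,
                           min((config$p_control + config$delta / 100) * m[3L], cap))
  pa1 <- ifelse(cat7 == 4L,
                ifelse(is_exp, tp_e["long"], tp_c["long"]),
                ifelse(cat7 >= 1L,
                       ifelse(is_exp, tp_e["band"], tp_c["band"]),
                       ifelse(is_exp, tp_e["none"], tp_c["none"])))
  a1 <- stats::runif(np) < pa1

  # baseline items (all participants are baseline smokers by construction)
  b_freq <- ifelse(daily, 4L, sample(2:3, np, replace = TRUE))
  b_days30 <- ifelse(daily, 6L,
                     sample(2:4, np, replace = TRUE, prob = c(0.40, 0.35, 0.25)))
  b_last_cig <- ifelse(daily, 9L, sample(7:8, np, replace = TRUE))
  b_smoked30 <- rep(1L, np)
  b_quit_attempt <- as.integer(stats::runif(np) < 0.481)
  b_quit_len <- ifelse(b_quit_attempt == 1L, sample(1:4, np, replace = TRUE), 0L)
  b_stage <- sample(1:3, np, replace = TRUE, prob = c(0.623, 0.180, 0.196))
  b_ladder <- sample(0:8, np, replace = TRUE)
  b_cigs_day <- ifelse(daily, sample(3:5, np, replace = TRUE),
                       sample(1:2, np, replace = TRUE))

  drift <- function(base, lo, hi) pmin(hi, pmax(lo, base + sample(-1:1, np, replace = TRUE)))

  # final-wave (Plus-7) items, consistent with the duration category
  abst7 <- cat7 >= 1L
  never <- stats::runif(np) < 0.02     # rare "never smoked" inconsistency
  smoker_last <- ifelse(stats::runif(np) < 0.85,
                        sample(7:9, np, replace = TRUE),   # current smoker
                        sample(5:6, np, replace = TRUE))   # quit < 6 months ago
  p7_last_cig <- ifelse(cat7 == 4L, ifelse(never, 0L, 1L),
                 ifelse(cat7 == 3L, 2L,
                 ifelse(cat7 == 2L, 3L,
                 ifelse(cat7 == 1L, 4L, smoker_last))))
  cur_smoker7 <- cat7 == 0L & smoker_last >= 7L
  p7_freq <- ifelse(cur_smoker7,
                    ifelse(daily, sample(3:4, np, replace = TRUE),
                           sample(1:3, np, replace = TRUE)), 0L)
  p7_days30 <- ifelse(cur_smoker7, pmax(1L, drift(b_days30, 0L, 6L)), 0L)
  p7_quit_len <- ifelse(abst7, 5L, drift(b_quit_len, 0L, 5L))
  p7_ladder <- ifelse(abst7, 10L, drift(b_ladder, 0L, 10L))
  p7_stage <- ifelse(abst7, 3L, drift(b_stage, 1L, 3L))
  p7_cigs_day <- ifelse(abst7 | !cur_smoker7, 0L, pmax(1L, drift(b_cigs_day, 0L, 5L)))

  # first-follow-up (Plus-1) items
  smoker_last1 <- ifelse(stats::runif(np) < 0.90,
                         sample(7:9, np, replace = TRUE),
                         sample(5:6, np, replace = TRUE))
  p1_last_cig <- ifelse(a1, 4L, smoker_last1)
  cur_smoker1 <- !a1 & smoker_last1 >= 7L
  p1_freq <- ifelse(cur_smoker1,
                    ifelse(daily, sample(3:4, np, replace = TRUE),
                           sample(1:3, np, replace = TRUE)), 0L)
  p1_days30 <- ifelse(cur_smoker1, pmax(1L, drift(b_days30, 0L, 6L)), 0L)
  p1_quit_len <- ifelse(a1, 5L, drift(b_quit_len, 0L, 5L))
  p1_ladder <- ifelse(a1, 10L, drift(b_ladder, 0L, 10L))
  p1_stage <- ifelse(a1, 3L, drift(b_stage, 1L, 3L))
  p1_cigs_day <- ifelse(a1 | !cur_smoker1, 0L, pmax(1L, drift(b_cigs_day, 0L, 5L)))

  participants <- data.frame(
    participant_id = sprintf("T%05d", seq_len(np)),
    school_id = schools$school_id[idx],
    pair_id = schools$pair_id[idx],
    arm = arm,
    wave = schools$wave[idx],
    gender = ifelse(female, "F", "M"),
    b_last_cig = b_last_cig, b_freq = b_freq, b_days30 = b_days30,
    b_smoked30 = b_smoked30, b_quit_attempt = b_quit_attempt,
    b_quit_len = b_quit_len, b_stage = b_stage, b_ladder = b_ladder,
    b_cigs_day = b_cigs_day,
    p1_last_cig = p1_last_cig, p1_freq = p1_freq, p1_days30 = p1_days30,
    p1_quit_len = p1_quit_len, p1_stage = p1_stage, p1_ladder = p1_ladder,
    p1_cigs_day = p1_cigs_day,
    p7_last_cig = p7_last_cig, p7_freq = p7_freq, p7_days30 = p7_days30,
    p7_quit_len = p7_quit_len, p7_stage = p7_stage, p7_ladder = p7_ladder,
    p7_cigs_day = p7_cigs_day,
    stringsAsFactors = FALSE)

  # survey non-response: a wave not returned is missing in every item
  ret1 <- stats::runif(np) < config$plus1_followup_rate
  ret7 <- stats::runif(np) < config$followup_rate
  p1_cols <- grep("^p1_", names(participants), value = TRUE)
  p7_cols <- grep("^p7_", names(participants), value = TRUE)
  for (cl in p1_cols) participants[[cl]][!ret1] <- NA_integer_
  for (cl in p7_cols) participants[[cl]][!ret7] <- NA_integer_

  ds <- trial_dataset(participants, schools = schools, assignment = assignment,
                      config = config)
  derive_endpoints(ds)
}

#' ANOVA estimate of the intraclass correlation
#'
#' One-way analysis-of-variance estimator of the intraclass correlation of a
#' binary endpoint, with schools as clusters:
#' `(MSB - MSW) / (MSB + (n0 - 1) MSW)`, where `n0` is the usual
#' cluster-size adjustment `(N - sum(n_j^2)/N) / (J - 1)`. The estimate is
#' clipped into \[0, 1). Complete-case: rows with a missing endpoint are
#' dropped first.
#'
#' @param data Participant data frame or `trial_dataset`.
#' @param endpoint Endpoint column name.
#' @return The estimated intraclass correlation (scalar).
#' @export
estimate_icc <- function(data, endpoint) {
  data <- participants(data)
  if (!endpoint %in% names(data))
    stop("endpoint '", endpoint, "' not found in dataset", call. = FALSE)
  y <- as.numeric(data[[endpoint]])
  keep <- !is.na(y)
  y <- y[keep]
  g <- factor(data$school_id[keep])
  nj <- tabulate(g)
  nj <- nj[nj > 0L]
  if (sum(nj >= 2L) < 2L)
    stop("insufficient clusters: need at least 2 schools with at least 2 ",
         "evaluable participants", call. = FALSE)
  J <- length(nj)
  N <- sum(nj)
  pj <- tapply(y, g, mean)
  pbar <- mean(y)
  msb <- sum(nj * (pj - pbar)^2) / (J - 1)
  msw <- sum(nj * pj * (1 - pj)) / (N - J)
  n0 <- (N - sum(nj^2) / N) / (J - 1)
  icc <- (msb - msw) / (msb + (n0 - 1) * msw)
  min(max(icc, 0), 1 - 1e-12)
}

#' Estimate design power by simulation
#'
#' Simulates trials under a configuration, analyzes each with the
#' matched-pair permutation test, and reports the fraction with a two-sided
#' p-value at or below `alpha`, together with its binomial standard error.
#' Simulation seeds are derived deterministically from `seed`, so two
#' configurations differing only in the effect size are compared under
#' common random numbers.
#'
#' @param config A [synthetic_config()].
#' @param n_sims Number of simulated trials (at least 100).
#' @param alpha Significance level in (0,1).
#' @param seed Base seed; defaults to the config seed.
#' @param endpoint Endpoint column to test.
#' @inheritParams permutation_test
#' @return List of class `power_estimate` with `power`, `se`, `n_sims`,
#'   `alpha`.
#' @export
estimate_power <- function(config, n_sims = 100L, alpha = 0.05, seed = NULL,
                           endpoint = "abst_6y",
                           statistic = c("pooled", "school_mean"),
                           exact_threshold = 20L, n_resamples = 999L) {
  statistic <- match.arg(statistic)
  if (n_sims < 100L) stop("n_sims must be at least 100", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("invalid alpha: must lie in (0,1)", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  sim_seeds <- seed + seq_len(n_sims)
  hits <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    cfg <- config
    cfg$seed <- sim_seeds[i]
    ds <- generate_trial(cfg)
    ps <- summarize_pairs(ds, endpoint)
    pt <- permutation_test(ps, statistic = statistic,
                           exact_threshold = exact_threshold,
                           n_resamples = n_resamples, seed = sim_seeds[i])
    hits[i] <- pt$p_two_sided <= alpha
  }
  pw <- mean(hits)
  structure(list(power = pw, se = sqrt(pw * (1 - pw) / n_sims),
                 n_sims = n_sims, alpha = alpha),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Estimated power = %.3f (SE %.3f) from %d simulations at alpha = %g\n",
              x$power, x$se, x$n_sims, x$alpha))
  invisible(x)
}
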