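test_that("baseline smoker classification follows the any-positive-item rule", {
  # at-least-monthly frequency alone is positive
  r <- classify_baseline_smoker(list(freq = 2, smoked30 = NA, last_cig = NA))
  expect_true(r$smoker); expect_false(r$daily)
  # all items at their most negative codes
  r <- classify_baseline_smoker(list(freq = 0, smoked30 = 0, last_cig = 0,
                                     days30 = 0))
  expect_false(r$smoker); expect_false(r$daily)
  # recent last cigarette is positive even when the other items are negative
  r <- classify_baseline_smoker(list(freq = 0, smoked30 = 0, last_cig = 8))
  expect_true(r$smoker); expect_false(r$daily)
  # "less than once a month" is NOT a positive response
  r <- classify_baseline_smoker(list(freq = 1, smoked30 = 0, last_cig = 5))
  expect_false(r$smoker)
  # daily requires the at-least-daily frequency code
  r <- classify_baseline_smoker(list(freq = 4, smoked30 = 1, last_cig = 9))
  expect_true(r$smoker); expect_true(r$daily)
  # invalid code errors name the item
  expect_error(classify_baseline_smoker(list(freq = 7, smoked30 = 0,
                                             last_cig = 0)), "freq")
})

test_that("smoker classification is monotone in each item's smoking level", {
  codes <- expand.grid(freq = c(NA, 0:4), smoked30 = c(NA, 0:1),
                       last_cig = c(NA, 0:9))
  base <- classify_baseline_smoker(codes)$smoker
  bump <- function(x, top) ifelse(is.na(x), x, pmin(x + 1L, top))
  for (item in c("freq", "smoked30", "last_cig")) {
    shifted <- codes
    top <- max(item_codes(item))
    shifted[[item]] <- bump(codes[[item]], top)
    expect_true(all(classify_baseline_smoker(shifted)$smoker >= base),
                info = item)
  }
})

test_that("prolonged abstinence requires consistent reports on all three items", {
  # consistent six-year abstinence
  expect_true(derive_prolonged_abstinence(
    list(last_cig = 1, freq = 0, days30 = 0), "6y"))
  # three-year report fails the six-year threshold but passes its own
  it <- list(last_cig = 2, freq = 0, days30 = 0)
  expect_false(derive_prolonged_abstinence(it, "6y"))
  expect_true(derive_prolonged_abstinence(it, "3y"))
  # current daily smoker is false at every duration
  it <- list(last_cig = 9, freq = 4, days30 = 6)
  for (d in c("6y", "3y", "1y", "6mo"))
    expect_false(derive_prolonged_abstinence(it, d))
  # a missing item with no contradicting item cannot confirm consistency
  expect_identical(derive_prolonged_abstinence(
    list(last_cig = 1, freq = NA, days30 = 0), "6y"), NA)
  # a contradicting item forces FALSE even when another is missing
  expect_false(derive_prolonged_abstinence(
    list(last_cig = 1, freq = 3, days30 = NA), "6y"))
  # "never smoked" at follow-up counts as abstinent at all durations
  expect_true(derive_prolonged_abstinence(
    list(last_cig = 0, freq = 0, days30 = 0), "6y"))
  expect_error(derive_prolonged_abstinence(
    list(last_cig = 12, freq = 0, days30 = 0), "6y"), "last_cig")
})

test_that("all 350 item combinations reproduce the stated rule and nest by duration", {
  combos <- expand.grid(lc = 0:9, fr = 0:4, dy = 0:6)
  durations <- c("6y", "3y", "1y", "6mo")
  got <- lapply(durations, function(d)
    derive_prolonged_abstinence(
      list(last_cig = combos$lc, freq = combos$fr, days30 = combos$dy), d))
  names(got) <- durations
  for (d in durations) {
    want <- mapply(function(a, b, c) oracle_abstinence(a, b, c, d),
                   combos$lc, combos$fr, combos$dy)
    expect_identical(got[[d]], as.logical(want), info = d)
  }
  # nesting: abstinence at a longer duration implies every shorter one
  expect_true(all(!(got$`6y` %in% TRUE) | got$`3y` %in% TRUE))
  expect_true(all(!(got$`3y` %in% TRUE) | got$`1y` %in% TRUE))
  expect_true(all(!(got$`1y` %in% TRUE) | got$`6mo` %in% TRUE))
})

test_that("duration nesting also holds with missing items", {
  set.seed(11)
  n <- 500
  pick <- function(v) {
    x <- sample(v, n, replace = TRUE)
    x[runif(n) < 0.3] <- NA
    x
  }
  it <- list(last_cig = pick(0:9), freq = pick(0:4), days30 = pick(0:6))
  a <- lapply(c("6y", "3y", "1y", "6mo"),
              function(d) derive_prolonged_abstinence(it, d))
  for (i in 1:3)
    expect_true(all(!(a[[i]] %in% TRUE) | a[[i + 1]] %in% TRUE))
})

test_that("sustained-progress flags match a hand evaluation of the rule", {
  # days smoked of the last 30: improvement = lower code
  b  <- c(6, 6, 6, 4, 0, 3, 5, 6, 2, 1)
  p1 <- c(4, 4, 4, 4, 0, 1, 2, NA, 1, 0)
  p7 <- c(0, 4, 5, 0, 6, 2, 2, 0, 0, 1)
  want <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, NA, TRUE, FALSE)
  got <- derive_progress_flags(data.frame(days30 = b),
                               data.frame(days30 = p1),
                               data.frame(days30 = p7))
  expect_identical(got$prog_days30, want)
  # strict-both mode additionally requires strict improvement at step two
  got2 <- derive_progress_flags(data.frame(days30 = b),
                                data.frame(days30 = p1),
                                data.frame(days30 = p7), mode = "strict-both")
  want2 <- want; want2[2] <- FALSE; want2[7] <- FALSE
  expect_identical(got2$prog_days30, want2)
  # an ascending measure: contemplation ladder, improvement = higher code
  lb <- c(0, 5, 3); lp1 <- c(4, 5, 6); lp7 <- c(10, 8, 5)
  lg <- derive_progress_flags(data.frame(ladder = lb),
                              data.frame(ladder = lp1),
                              data.frame(ladder = lp7))
  expect_identical(lg$prog_ladder, c(TRUE, FALSE, FALSE))
})

test_that("derive_endpoints populates flags and respects wave missingness", {
  cfg <- synthetic_config(n_pairs = 4, seed = 303, followup_rate = 0.7)
  ds <- generate_trial(cfg)
  p <- ds$participants
  # a wave with no returned survey yields missing endpoint flags
  no_p7 <- is.na(p$p7_last_cig) & is.na(p$p7_freq) & is.na(p$p7_days30)
  expect_true(all(is.na(p$abst_6y[no_p7])))
  expect_true(any(no_p7))
  # daily implies smoker, and everyone generated is a baseline smoker
  expect_true(all(p$baseline_smoker))
  expect_true(all(!p$baseline_daily | p$baseline_smoker))
  # derived flags are reproducible from the stored item codes alone
  rederived <- derive_endpoints(p[, !grepl("^(abst|prog|baseline|consistent)",
                                           names(p))])
  expect_identical(rederived$abst_6y, p$abst_6y)
  expect_identical(rederived$prog_freq, p$prog_freq)
})
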