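test_that("summarize_pairs recounts match a direct group-by and apply exclusions", {
  ps0 <- make_summary(e_ctl = c(3, 1, 4, 0), n_ctl = c(10, 8, 12, 9),
                      e_exp = c(5, 2, 2, 3), n_exp = c(11, 7, 13, 10))
  d <- summary_to_participants(ps0)
  ps <- summarize_pairs(d, "y")
  # independent tally over the raw rows
  for (k in seq_len(nrow(ps))) {
    for (side in c("ctl", "exp")) {
      sch <- ps[[paste0("school_", side)]][k]
      rows <- d[d$school_id == sch, ]
      expect_equal(ps[[paste0("n_", side)]][k], nrow(rows))
      expect_equal(ps[[paste0("e_", side)]][k], sum(rows$y))
    }
  }
  expect_equal(nrow(ps), 4)
  expect_error(summarize_pairs(d, "nonexistent"), "nonexistent")
})

test_that("a school with no eligible participants drops its whole pair", {
  ps0 <- make_summary(e_ctl = c(3, 1, 4, 2), n_ctl = c(10, 8, 12, 9),
                      e_exp = c(5, 2, 2, 3), n_exp = c(11, 7, 13, 10))
  d <- summary_to_participants(ps0)
  # subgroup membership that misses school C02 entirely
  d$grp <- ifelse(d$school_id == "C02", "other", "target")
  ps <- summarize_pairs(d, "y", subgroup = c(grp = "target"))
  expect_equal(nrow(ps), 3)
  expect_false("P02" %in% ps$pair_id)
  expect_identical(attr(ps, "excluded_pairs"), "P02")
  # missing endpoints behave like subgroup exclusion (complete-case)
  d2 <- summary_to_participants(ps0)
  d2$y[d2$school_id == "E03"] <- NA
  ps2 <- summarize_pairs(d2, "y")
  expect_false("P03" %in% ps2$pair_id)
  # dropping a pair from the summary equals deleting its rows from the data
  d3 <- summary_to_participants(ps0)
  d3 <- d3[d3$pair_id != "P04", ]
  ps3a <- summarize_pairs(d3, "y")
  ps3b <- summarize_pairs(summary_to_participants(ps0[ps0$pair_id != "P04", ]), "y")
  expect_equal(as.data.frame(ps3a), as.data.frame(ps3b))
})

test_that("identical event proportions give delta 0 and p 1", {
  ps <- make_summary(e_ctl = rep(2, 6), n_ctl = rep(10, 6),
                     e_exp = rep(2, 6), n_exp = rep(10, 6))
  for (st in c("pooled", "school_mean")) {
    r <- permutation_test(ps, statistic = st)
    expect_equal(r$delta, 0)
    expect_equal(r$p_two_sided, 1)
  }
})

test_that("3-pair exact p equals explicit enumeration of all 8 swap vectors", {
  ps <- make_summary(e_ctl = c(1, 2, 0), n_ctl = c(10, 12, 8),
                     e_exp = c(4, 3, 2), n_exp = c(9, 11, 10))
  for (st in c("pooled", "school_mean")) {
    r <- permutation_test(ps, statistic = st)
    expect_equal(r$mode, "exact")
    expect_equal(r$n_pairs_used, 3)
    expect_equal(r$p_two_sided, oracle_p(ps, st))
    # exact p has denominator 2^K
    expect_equal(r$p_two_sided * 8, round(r$p_two_sided * 8))
  }
})

test_that("exact p and inversion CI match brute force on random small fixtures", {
  for (K in c(4, 6, 8, 10)) {
    for (rep in 1:3) {
      ps <- random_summary(K, seed = 100 * K + rep)
      for (st in c("pooled", "school_mean")) {
        r <- permutation_test(ps, statistic = st)
        expect_equal(r$p_two_sided, oracle_p(ps, st),
                     info = sprintf("K=%d rep=%d %s", K, rep, st))
      }
    }
  }
  # CI vs grid-search oracle (level chosen attainable for K = 7: 2/128 < 0.1)
  ps <- random_summary(7, seed = 42)
  ci <- permutation_ci(ps, level = 0.9, tol = 0.01)
  dobs <- permutation_test(ps)$delta
  span <- 60
  oc <- oracle_ci_grid(ps, level = 0.9, lo = dobs - span, hi = dobs + span,
                       by = 0.02)
  expect_lt(abs(ci[1] - oc[1]), 0.05)
  expect_lt(abs(ci[2] - oc[2]), 0.05)
  expect_true(ci[1] <= dobs && dobs <= ci[2])
})

test_that("an unattainable confidence level yields an unbounded interval", {
  ps <- random_summary(3, seed = 9)
  expect_warning(ci <- permutation_ci(ps, level = 0.95), "unbounded")
  expect_equal(ci, c(-Inf, Inf))
})

test_that("the CI collapses to the observed delta when all schools are identical", {
  ps <- make_summary(e_ctl = rep(3, 8), n_ctl = rep(10, 8),
                     e_exp = rep(3, 8), n_exp = rep(10, 8))
  ci <- permutation_ci(ps, level = 0.95, tol = 0.01)
  expect_lt(abs(ci[1]), 0.05)
  expect_lt(abs(ci[2]), 0.05)
})

test_that("Monte Carlo p lies within binomial error of the exact p", {
  ps <- random_summary(9, seed = 77)
  exact <- permutation_test(ps)$p_two_sided
  mc <- permutation_test(ps, exact_threshold = 5, n_resamples = 4000,
                         seed = 123)
  expect_equal(mc$mode, "monte_carlo")
  expect_lt(abs(mc$p_two_sided - exact),
            3 * sqrt(exact * (1 - exact) / 4000) + 1 / 4000)
  # reproducible for a fixed seed
  mc2 <- permutation_test(ps, exact_threshold = 5, n_resamples = 4000,
                          seed = 123)
  expect_identical(mc$p_two_sided, mc2$p_two_sided)
})

test_that("globally exchanging arm labels negates delta and the CI, p unchanged", {
  ps <- random_summary(7, seed = 5)
  flip <- make_summary(e_ctl = ps$e_exp, n_ctl = ps$n_exp,
                       e_exp = ps$e_ctl, n_exp = ps$n_ctl)
  for (st in c("pooled", "school_mean")) {
    a <- permutation_test(ps, statistic = st)
    b <- permutation_test(flip, statistic = st)
    expect_equal(a$delta, -b$delta)
    expect_equal(a$p_two_sided, b$p_two_sided)
  }
  ca <- permutation_ci(ps, level = 0.9, tol = 0.01)
  cb <- permutation_ci(flip, level = 0.9, tol = 0.01)
  expect_lt(abs(ca[1] + cb[2]), 0.05)
  expect_lt(abs(ca[2] + cb[1]), 0.05)
})

test_that("errors: too few pairs and too few resamples", {
  ps <- make_summary(e_ctl = 1, n_ctl = 10, e_exp = 2, n_exp = 10)
  expect_error(permutation_test(ps), "2 pairs")
  ps2 <- random_summary(4, seed = 1)
  expect_error(permutation_test(ps2, exact_threshold = 2, n_resamples = 50),
               "100")
})

test_that("stratified test reduces to the unstratified test for one stratum", {
  ps0 <- random_summary(6, seed = 31)
  d <- summary_to_participants(ps0)
  d$stratum <- "only"
  a <- stratified_test(d, "y", strata = "stratum", level = NULL)
  b <- permutation_test(summarize_pairs(d, "y"))
  expect_equal(a$delta, b$delta)
  expect_equal(a$p_two_sided, b$p_two_sided)
})

test_that("stratified delta is the evaluable-share weighted sum of stratum deltas", {
  psA <- make_summary(e_ctl = c(2, 1, 3, 2), n_ctl = c(10, 10, 10, 10),
                      e_exp = c(4, 3, 3, 4), n_exp = c(10, 10, 10, 10))
  psB <- make_summary(e_ctl = c(5, 4, 6, 5), n_ctl = c(20, 20, 20, 20),
                      e_exp = c(5, 6, 7, 6), n_exp = c(20, 20, 20, 20))
  dA <- summary_to_participants(psA, extra = list(stratum = "daily"))
  dB <- summary_to_participants(psB, extra = list(stratum = "ltd"))
  dB$participant_id <- paste0("B", dB$participant_id)
  # keep school/pair ids aligned: stratum B lives in the same schools
  d <- rbind(dA, dB)
  res <- stratified_test(d, "y", strata = "stratum", level = NULL)
  dltA <- 100 * (sum(psA$e_exp) / sum(psA$n_exp) - sum(psA$e_ctl) / sum(psA$n_ctl))
  dltB <- 100 * (sum(psB$e_exp) / sum(psB$n_exp) - sum(psB$e_ctl) / sum(psB$n_ctl))
  wA <- 80 / 240; wB <- 160 / 240
  expect_equal(res$delta, wA * dltA + wB * dltB)
  # equal-weight strata with opposite deltas cancel
  psC <- make_summary(e_ctl = psA$e_exp, n_ctl = psA$n_ctl,
                      e_exp = psA$e_ctl, n_exp = psA$n_exp)
  dC <- summary_to_participants(psC, extra = list(stratum = "ltd"))
  dC$participant_id <- paste0("C", dC$participant_id)
  res2 <- stratified_test(rbind(dA, dC), "y", strata = "stratum", level = NULL)
  expect_equal(res2$delta, 0)
})

test_that("stratified exact p matches a brute-force enumeration of the combined statistic", {
  psA <- make_summary(e_ctl = c(2, 1, 3, 0, 2), n_ctl = c(10, 9, 11, 8, 10),
                      e_exp = c(4, 2, 3, 2, 5), n_exp = c(9, 10, 12, 9, 11))
  psB <- make_summary(e_ctl = c(6, 5, 7, 4, 6), n_ctl = c(18, 20, 19, 21, 20),
                      e_exp = c(6, 7, 8, 6, 9), n_exp = c(20, 19, 18, 20, 21))
  dA <- summary_to_participants(psA, extra = list(stratum = "daily"))
  dB <- summary_to_participants(psB, extra = list(stratum = "ltd"))
  dB$participant_id <- paste0("B", dB$participant_id)
  res <- stratified_test(rbind(dA, dB), "y", strata = "stratum", level = NULL)
  # brute force: combined statistic over all 2^5 shared swap vectors
  nA <- sum(psA$n_ctl) + sum(psA$n_exp)
  nB <- sum(psB$n_ctl) + sum(psB$n_exp)
  wA <- nA / (nA + nB); wB <- nB / (nA + nB)
  TA <- oracle_stats(psA); TB <- oracle_stats(psB)
  Tc <- wA * TA + wB * TB
  p_brute <- mean(abs(Tc) >= abs(Tc[1]) - 1e-9)
  expect_equal(res$p_two_sided, p_brute)
})
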