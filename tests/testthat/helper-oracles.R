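# Independent brute-force oracles, written separately from the package's
# code paths: plain loops, no matrix tricks, no shared internals.

# build a pair_summary by hand from per-school counts
make_summary <- function(e_ctl, n_ctl, e_exp, n_exp, endpoint = "y") {
  K <- length(e_ctl)
  structure(
    data.frame(pair_id = sprintf("P%02d", seq_len(K)),
               school_ctl = sprintf("C%02d", seq_len(K)),
               school_exp = sprintf("E%02d", seq_len(K)),
               n_ctl = n_ctl, e_ctl = e_ctl, n_exp = n_exp, e_exp = e_exp,
               stringsAsFactors = FALSE),
    class = c("pair_summary", "data.frame"), endpoint = endpoint)
}

random_summary <- function(K, seed) {
  set.seed(seed)
  n <- sample(8:40, 2 * K, replace = TRUE)
  e <- rbinom(2 * K, n, runif(2 * K, 0.05, 0.45))
  make_summary(e[1:K], n[1:K], e[(K + 1):(2 * K)], n[(K + 1):(2 * K)])
}

# statistic for every one of the 2^K swap vectors, recomputed naively;
# delta is removed from the observed-experimental schools first.  The grid
# of swap vectors is materialized once per fixture to keep the loop cheap.
oracle_stats <- function(ps, statistic = "pooled", delta = 0, grid = NULL) {
  K <- nrow(ps)
  if (is.null(grid)) grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  Tv <- numeric(nrow(grid))
  eE <- ps$e_exp - delta / 100 * ps$n_exp
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    ee <- ifelse(s, ps$e_ctl, eE);  ne <- ifelse(s, ps$n_ctl, ps$n_exp)
    ec <- ifelse(s, eE, ps$e_ctl);  nc <- ifelse(s, ps$n_exp, ps$n_ctl)
    Tv[r] <- if (statistic == "pooled") {
      100 * (sum(ee) / sum(ne) - sum(ec) / sum(nc))
    } else {
      mean(100 * ee / ne) - mean(100 * ec / nc)
    }
  }
  Tv
}

oracle_p <- function(ps, statistic = "pooled", delta = 0, grid = NULL) {
  Tv <- oracle_stats(ps, statistic, delta, grid)
  mean(abs(Tv) >= abs(Tv[1]) - 1e-9)
}

# confidence set by grid search on the shifted p-value: a coarse pass over a
# wide range brackets each endpoint, then a fine pass pins it down
oracle_ci_grid <- function(ps, level = 0.95, statistic = "pooled",
                           lo, hi, by = 0.01, coarse = 0.5) {
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nrow(ps))))
  in_set <- function(deltas) vapply(
    deltas, function(d) oracle_p(ps, statistic, d, grid = swaps) >= 1 - level,
    logical(1))
  rough <- seq(lo, hi, by = coarse)
  kept <- range(rough[in_set(rough)])
  fine_lo <- seq(kept[1] - coarse, kept[1] + coarse, by = by)
  fine_hi <- seq(kept[2] - coarse, kept[2] + coarse, by = by)
  c(min(fine_lo[in_set(fine_lo)]), max(fine_hi[in_set(fine_hi)]))
}

# expand a pair summary into participant rows (for summarize_pairs tests)
summary_to_participants <- function(ps, extra = NULL) {
  rows <- list()
  for (k in seq_len(nrow(ps))) {
    for (side in c("ctl", "exp")) {
      n <- ps[[paste0("n_", side)]][k]
      e <- ps[[paste0("e_", side)]][k]
      if (n == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        school_id = ps[[paste0("school_", side)]][k],
        pair_id = ps$pair_id[k],
        arm = if (side == "ctl") "control" else "experimental",
        y = rep(c(TRUE, FALSE), c(e, n - e)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$participant_id <- sprintf("X%04d", seq_len(nrow(out)))
  if (!is.null(extra)) for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# independent restatement of the prolonged-abstinence rule in terms of the
# response labels, not the integer codes
oracle_abstinence <- function(lc, fr, dy, duration) {
  lc_lab <- names(item_codes("last_cig"))[match(lc, item_codes("last_cig"))]
  fr_lab <- names(item_codes("freq"))[match(fr, item_codes("freq"))]
  dy_lab <- names(item_codes("days30"))[match(dy, item_codes("days30"))]
  ok_last <- c("I have never smoked, or even tried, a cigarette",
               "over 6 years ago")
  if (duration %in% c("3y", "1y", "6mo")) ok_last <- c(ok_last, "over 3 years ago")
  if (duration %in% c("1y", "6mo")) ok_last <- c(ok_last, "over 12 months ago")
  if (duration == "6mo") ok_last <- c(ok_last, "between 6 months and 12 months ago")
  conds <- c(lc_lab %in% ok_last, fr_lab == "not at all", dy_lab == "0 days")
  avail <- c(!is.na(lc), !is.na(fr), !is.na(dy))
  if (any(avail & !conds)) return(FALSE)
  if (all(avail)) return(TRUE)
  NA
}
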