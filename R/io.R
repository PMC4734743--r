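#' Trial dataset container
#'
#' A light container for one trial: a participant table (one row per
#' participant, wave-prefixed item columns `b_*`, `p1_*`, `p7_*` and any
#' derived endpoint columns), plus optional school, pair-assignment and
#' generator-configuration tables. Referential integrity (each participant's
#' school in exactly one pair, one school per arm within a pair) is checked
#' on construction.
#'
#' @param participants Data frame with at least `participant_id`,
#'   `school_id`, `pair_id`, `arm`.
#' @param schools Optional school-level data frame.
#' @param assignment Optional pair-assignment data frame.
#' @param config Optional [synthetic_config()] that generated the data.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(participants, schools = NULL, assignment = NULL,
                          config = NULL) {
  req <- c("participant_id", "school_id", "pair_id", "arm")
  miss <- setdiff(req, names(participants))
  if (length(miss))
    stop("unmapped required column: ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- participants$participant_id[duplicated(participants$participant_id)]
  if (length(dup))
    stop("duplicate participant id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad_arm <- setdiff(unique(participants$arm), c("control", "experimental"))
  if (length(bad_arm))
    stop("invalid arm label: ", paste(bad_arm, collapse = ", "),
         " (expected 'control'/'experimental')", call. = FALSE)
  roster <- unique(participants[, c("school_id", "pair_id", "arm")])
  if (anyDuplicated(roster$school_id))
    stop("school assigned to more than one pair/arm: ",
         paste(roster$school_id[duplicated(roster$school_id)], collapse = ", "),
         call. = FALSE)
  per_pair <- table(roster$pair_id)
  bad <- names(per_pair)[per_pair != 2L]
  if (length(bad))
    stop("pair with != 2 schools: ", paste(bad, collapse = ", "), call. = FALSE)
  one_each <- tapply(roster$arm, roster$pair_id,
                     function(a) all(sort(a) == c("control", "experimental")))
  if (!all(one_each))
    stop("pair without one school per arm: ",
         paste(names(one_each)[!one_each], collapse = ", "), call. = FALSE)
  structure(list(participants = participants, schools = schools,
                 assignment = assignment, config = config),
            class = "trial_dataset")
}

# uniform access to the participant table
participants <- function(x) {
  if (inherits(x, "trial_dataset")) x$participants else x
}

#' @export
print.trial_dataset <- function(x, ...) {
  p <- x$participants
  cat("trial_dataset:", nrow(p), "participants,",
      length(unique(p$school_id)), "schools,",
      length(unique(p$pair_id)), "pairs\n")
  flags <- intersect(c("baseline_daily", "abst_6y", "abst_6mo_plus1"), names(p))
  for (f in flags)
    cat(sprintf("  %-15s %5.1f%% (of %d evaluable)\n", f,
                100 * mean(p[[f]], na.rm = TRUE), sum(!is.na(p[[f]]))))
  invisible(x)
}

#' Read a column-map configuration
#'
#' A column map adapts an external participant file to the canonical
#' schema: a `columns` mapping from canonical column names to the source
#' file's names, and an optional `recodes` block translating each item's
#' source codes to code-book codes. Stored as YAML.
#'
#' @param path Path to a YAML file with top-level keys `columns` and
#'   (optionally) `recodes`.
#' @return List with elements `columns` (named character) and `recodes`
#'   (named list of named vectors), class `colmap`.
#' @export
read_colmap <- function(path) {
  raw <- yaml::read_yaml(path)
  cm <- list(columns = unlist(raw$columns),
             recodes = lapply(raw$recodes, unlist))
  structure(cm, class = "colmap")
}

#' Read a participant file into a trial dataset
#'
#' Reads a delimited participant file (header row, one row per participant),
#' optionally applying a column map, validates it, and attaches a
#' data-quality report: row counts, per-item missingness, out-of-range codes
#' (which are set to missing and reported row by row), and the count of
#' participants reporting "never smoked" at a follow-up wave despite being
#' baseline smokers (retained, and counted as abstinent, per the
#' conservative consistency rules).
#'
#' @param path Path to a CSV file.
#' @param colmap Optional [read_colmap()] result (or a list shaped like
#'   one).
#' @return A [trial_dataset()]; the quality report is in
#'   `attr(x, "quality")`.
#' @export
read_participants <- function(path, colmap = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(colmap)) {
    for (canonical in names(colmap$columns)) {
      src <- colmap$columns[[canonical]]
      if (!src %in% names(raw))
        stop("unmapped required column: '", canonical,
             "' (source column '", src, "' not in file)", call. = FALSE)
      names(raw)[names(raw) == src] <- canonical
    }
    for (item in names(colmap$recodes)) {
      if (!item %in% names(raw)) next
      map <- colmap$recodes[[item]]
      raw[[item]] <- unname(map[as.character(raw[[item]])])
    }
  }
  item_cols <- grep("^(b|p1|p7)_", names(raw), value = TRUE)
  invalid <- data.frame(row = integer(0), item = character(0),
                        value = character(0), stringsAsFactors = FALSE)
  for (cl in item_cols) {
    item <- sub("^(b|p1|p7)_", "", cl)
    codes <- tryCatch(item_codes(item), error = function(e) NULL)
    if (is.null(codes)) next
    x <- suppressWarnings(as.integer(raw[[cl]]))
    bad <- which(!is.na(raw[[cl]]) & (is.na(x) | !(x %in% codes)))
    if (length(bad)) {
      invalid <- rbind(invalid,
                       data.frame(row = bad, item = cl,
                                  value = as.character(raw[[cl]][bad]),
                                  stringsAsFactors = FALSE))
      x[bad] <- NA_integer_
    }
    raw[[cl]] <- x
  }
  ds <- trial_dataset(raw)
  if (length(item_cols)) ds <- derive_endpoints(ds)
  p <- ds$participants
  never_incons <- sum(
    (p$baseline_smoker %in% TRUE) &
      ((!is.na(p$p7_last_cig) & p$p7_last_cig == 0L) |
         (!is.na(p$p1_last_cig) & p$p1_last_cig == 0L)))
  quality <- list(
    n_rows = nrow(p),
    n_schools = length(unique(p$school_id)),
    n_pairs = length(unique(p$pair_id)),
    missing_per_item = vapply(p[intersect(item_cols, names(p))],
                              function(x) sum(is.na(x)), integer(1)),
    invalid = invalid,
    never_smoked_inconsistent = never_incons)
  attr(ds, "quality") <- quality
  ds
}

#' Write a trial dataset to a participant CSV
#'
#' Writes the participant table (item codes, ids, and any derived columns)
#' as a plain CSV readable by [read_participants()].
#'
#' @param dataset A `trial_dataset` or participant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(dataset, path) {
  utils::write.csv(participants(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write and read generator configurations
#'
#' Plain-text (YAML) serialization of a [synthetic_config()].
#'
#' @param config A `synthetic_config`.
#' @param path File path.
#' @return `read_config` returns a `synthetic_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(synthetic_config, yaml::read_yaml(path))
}

#' Write a machine-readable run log
#'
#' Serializes the inputs and enumeration metadata of a `permutation_result`
#' (endpoint, subgroup, pairs used, mode, resamples, seed, and the results)
#' as JSON, so a run can be audited and reproduced.
#'
#' @param result A `permutation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(result, path) {
  log <- list(endpoint = result$endpoint,
              subgroup = as.list(result$subgroup),
              statistic = result$statistic,
              mode = result$mode,
              n_pairs_used = result$n_pairs_used,
              n_resamples = result$n_resamples,
              seed = result$seed,
              delta = result$delta,
              p_two_sided = result$p_two_sided,
              ci = c(result$ci_low, result$ci_high),
              level = result$level)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
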