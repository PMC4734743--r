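#' Survey item code book
#'
#' Returns the code book mapping each survey item to its integer codes and
#' response labels. Items are ordinal: larger codes always mean "more
#' smoking" for `last_cig`, `freq`, `days30`, `smoked30` and `cigs_day`, and
#' "more progress" for `quit_len`, `ladder` and `stage`. The code book is
#' shipped as a delimited text file so that questionnaire dialects with
#' different wording can be mapped onto the same codes via a column map
#' (see [read_colmap()]).
#'
#' @return A data frame with columns `item`, `code`, `label`.
#' @export
#' @examples
#' head(codebook())
codebook <- function() {
  if (is.null(.pairperm_env$codebook)) {
    path <- system.file("extdata", "codebook.csv", package = "pairperm", mustWork = TRUE)
    .pairperm_env$codebook <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .pairperm_env$codebook
}

#' Valid codes for one survey item
#'
#' @param item Item name, e.g. `"freq"`.
#' @return Integer vector of valid codes, named by response label.
#' @export
item_codes <- function(item) {
  cb <- codebook()
  rows <- cb[cb$item == item, ]
  if (nrow(rows) == 0L) stop("unknown survey item: '", item, "'", call. = FALSE)
  stats::setNames(rows$code, rows$label)
}

# names of the items carried at each wave
.baseline_items <- c("last_cig", "freq", "days30", "smoked30", "quit_attempt",
                     "quit_len", "stage", "ladder", "cigs_day")
.plus_items     <- c("last_cig", "freq", "days30", "quit_len", "stage",
                     "ladder", "cigs_day")

# check that codes lie in the documented range; NA allowed (missing sentinel)
validate_codes <- function(x, item) {
  ok <- item_codes(item)
  bad <- !is.na(x) & !(x %in% ok)
  if (any(bad)) {
    stop("invalid code for item '", item, "': ",
         paste(unique(x[bad]), collapse = ", "),
         " (valid: ", min(ok), "-", max(ok), ")", call. = FALSE)
  }
  invisible(TRUE)
}

# extract one wave's items from a prefixed participant data frame
wave_items <- function(data, prefix) {
  items <- if (prefix == "b") .baseline_items else .plus_items
  cols <- paste0(prefix, "_", items)
  present <- cols %in% names(data)
  out <- data.frame(matrix(NA_integer_, nrow(data), length(items)))
  names(out) <- items
  for (i in which(present)) out[[items[i]]] <- data[[cols[i]]]
  out
}
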