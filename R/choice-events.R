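# Choice-event tables: one row per accept/reject decision with its
# correctness category derived from stimulus rank, never stored upstream.

.categories <- c("CA", "IA", "CR", "IR")

#' Derive correctness categories for choice events
#'
#' Each decision is one of four outcomes: correct acceptance (CA, accepting
#' the higher-rewarded colour), incorrect acceptance (IA, accepting the
#' lower-rewarded colour), correct rejection (CR, rejecting the
#' lower-rewarded colour) and incorrect rejection (IR, rejecting the
#' higher-rewarded colour).
#'
#' @param events Data frame with at least columns `stimulus_id` and
#'   `response` (`"accept"`/`"reject"`).
#' @param high_stimulus Character: the higher-rewarded stimulus id, or a
#'   named vector keyed by `test_id` when tests differ.
#' @return `events` with a `category` column added (factor-free character).
#' @export
categorise_events <- function(events, high_stimulus) {
  stopifnot(is.data.frame(events),
            all(c("stimulus_id", "response") %in% names(events)))
  bad <- !events$response %in% c("accept", "reject")
  if (any(bad)) {
    stop("response must be 'accept' or 'reject'; offending row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(names(high_stimulus)) && length(high_stimulus) > 1L) {
    if (!"test_id" %in% names(events)) {
      stop("per-test high_stimulus given but events lack a test_id column",
           call. = FALSE)
    }
    hi <- unname(high_stimulus[events$test_id])
    if (anyNA(hi)) stop("high_stimulus has no entry for some test_id", call. = FALSE)
  } else {
    hi <- rep(unname(high_stimulus)[1], nrow(events))
  }
  is_high <- events$stimulus_id == hi
  events$category <- ifelse(events$response == "accept",
                            ifelse(is_high, "CA", "IA"),
                            ifelse(is_high, "IR", "CR"))
  events
}

#' Read / write choice-event tables
#'
#' Choice events are exchanged as delimited text with columns `bee_id`,
#' `test_id`, `stimulus_id`, `response` (`accept`/`reject`) and
#' `response_time` (seconds).  The correctness category is derived on read
#' from `high_stimulus`, not stored in the file.
#'
#' @param file Path to a delimited text file.
#' @param high_stimulus Higher-rewarded stimulus id (scalar or named by
#'   `test_id`); when `NULL` the category column is not derived.
#' @param sep Field separator.
#' @return `read_choice_events()` returns a data frame of events;
#'   `write_choice_events()` invisibly returns `file`.
#' @export
read_choice_events <- function(file, high_stimulus = NULL, sep = ",") {
  ev <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("bee_id", "test_id", "stimulus_id", "response", "response_time")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols) > 0) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(ev$response_time <= 0)) {
    stop("response_time must be positive", call. = FALSE)
  }
  if (!is.null(high_stimulus)) ev <- categorise_events(ev, high_stimulus)
  ev
}

#' @rdname read_choice_events
#' @param events Data frame of choice events to write; a derived `category`
#'   column, if present, is dropped.
#' @export
write_choice_events <- function(events, file, sep = ",") {
  keep <- setdiff(names(events), "category")
  utils::write.table(events[keep], file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Four-outcome response counts
#'
#' @param nCA,nIA,nCR,nIR Non-negative integer counts of correct acceptances,
#'   incorrect acceptances, correct rejections and incorrect rejections.
#' @return An object of class `response_counts` (named integer vector).
#' @export
response_counts <- function(nCA = 0, nIA = 0, nCR = 0, nIR = 0) {
  x <- c(nCA = nCA, nIA = nIA, nCR = nCR, nIR = nIR)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.integer(x), names = names(x), class = "response_counts")
}

#' @export
print.response_counts <- function(x, ...) {
  cat("Response counts: CA =", x[["nCA"]], " IA =", x[["nIA"]],
      " CR =", x[["nCR"]], " IR =", x[["nIR"]],
      " (total", sum(x), ")\n")
  invisible(x)
}

#' Tally choice events into four-outcome counts
#'
#' @param events Data frame of categorised choice events (see
#'   [categorise_events()]).
#' @param bee,test Optional selectors: keep only rows whose `bee_id` /
#'   `test_id` are in these sets.
#' @return A [response_counts()] object.
#' @export
count_responses <- function(events, bee = NULL, test = NULL) {
  stopifnot(is.data.frame(events))
  if (!"category" %in% names(events)) {
    stop("events carry no category column; derive it with categorise_events()",
         call. = FALSE)
  }
  bad <- !events$category %in% .categories
  if (any(bad)) {
    stop("invalid category in row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  if ("response" %in% names(events)) {
    want <- ifelse(events$category %in% c("CA", "IA"), "accept", "reject")
    inconsistent <- events$response != want
    if (any(inconsistent)) {
      stop("category inconsistent with response in row(s): ",
           paste(utils::head(which(inconsistent), 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(bee)) events <- events[events$bee_id %in% bee, , drop = FALSE]
  if (!is.null(test)) events <- events[events$test_id %in% test, , drop = FALSE]
  tab <- table(factor(events$category, levels = .categories))
  response_counts(tab[["CA"]], tab[["IA"]], tab[["CR"]], tab[["IR"]])
}
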