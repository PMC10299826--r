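# Choice statistics: Matthews correlation coefficient over the four-outcome
# table, signal-detection discriminability and criterion, conditional
# accuracy functions and first-choice latencies.

.as_counts <- function(counts) {
  if (inherits(counts, "response_counts")) return(counts)
  if (is.numeric(counts) && length(counts) == 4L) {
    nm <- names(counts)
    if (is.null(nm)) nm <- c("nCA", "nIA", "nCR", "nIR")
    return(response_counts(counts[[which(nm == "nCA")]], counts[[which(nm == "nIA")]],
                           counts[[which(nm == "nCR")]], counts[[which(nm == "nIR")]]))
  }
  stop("counts must be a response_counts object or a length-4 numeric vector",
       call. = FALSE)
}

#' Matthews correlation coefficient of a four-outcome table
#'
#' Summarises a bee's (or model bee's) performance in one test on a scale
#' from -1 (every choice inverted) through 0 (chance) to +1 (every
#' acceptance of the higher-rewarded colour, every rejection of the lower):
#' \deqn{MCC = \frac{n_{CA} n_{CR} - n_{IA} n_{IR}}
#'   {\sqrt{(n_{CA}+n_{IA})(n_{CA}+n_{IR})(n_{CR}+n_{IA})(n_{CR}+n_{IR})}}}
#' When any of the four marginal sums is zero the coefficient is undefined;
#' the conventional value 0 is returned.
#'
#' @param counts A [response_counts()] object (or length-4 numeric
#'   `c(nCA, nIA, nCR, nIR)`).
#' @return Numeric in `[-1, 1]`.
#' @examples
#' mcc(response_counts(5, 0, 5, 0))  # +1: error-free
#' mcc(response_counts(6, 6, 4, 4))  # 0: proportional rows
#' @export
mcc <- function(counts) {
  x <- .as_counts(counts)
  nCA <- as.numeric(x[["nCA"]]); nIA <- as.numeric(x[["nIA"]])
  nCR <- as.numeric(x[["nCR"]]); nIR <- as.numeric(x[["nIR"]])
  marg <- c(nCA + nIA, nCA + nIR, nCR + nIA, nCR + nIR)
  if (any(marg == 0)) return(0)
  (nCA * nCR - nIA * nIR) / sqrt(prod(marg))
}

#' Hit and false-positive rates of a four-outcome table
#'
#' Rates follow the acceptance/rejection decomposition used throughout the
#' package: the hit rate is the fraction of acceptances that were correct,
#' `nCA / (nCA + nIA)`, and the false-positive rate is the fraction of
#' rejections that were incorrect, `nIR / (nIR + nCR)`.  A textbook
#' signal-detection false-alarm rate (incorrect acceptances over all
#' lower-colour presentations, `nIA / (nIA + nCR)`) is available via
#' `fp_definition = "noise_trials"`.
#'
#' A rate of exactly 0 or 1 makes the inverse-normal transform infinite, so
#' an edge policy is applied: `"clamp"` (default) moves such a rate to
#' `1/(2N)` or `1 - 1/(2N)` with `N` the relevant denominator;
#' `"loglinear"` adds 0.5 to every cell before forming the ratios;
#' `"none"` leaves rates untouched.
#'
#' @param counts A [response_counts()] object.
#' @param edge_policy `"clamp"`, `"loglinear"` or `"none"`.
#' @param fp_definition `"rejections"` (default: incorrect rejections over
#'   all rejections) or `"noise_trials"` (textbook false alarms).
#' @return List with `hit_rate`, `false_positive_rate`, `edge_corrected`
#'   (logical) and `fp_definition`.
#' @export
response_rates <- function(counts,
                           edge_policy = c("clamp", "loglinear", "none"),
                           fp_definition = c("rejections", "noise_trials")) {
  x <- .as_counts(counts)
  edge_policy <- match.arg(edge_policy)
  fp_definition <- match.arg(fp_definition)
  nCA <- x[["nCA"]]; nIA <- x[["nIA"]]; nCR <- x[["nCR"]]; nIR <- x[["nIR"]]

  n_acc <- nCA + nIA
  if (n_acc == 0) stop("no acceptances: hit rate undefined", call. = FALSE)
  if (fp_definition == "rejections") {
    n_fp <- nIR + nCR
    fp_num <- nIR
    if (n_fp == 0) stop("no rejections: false positive rate undefined", call. = FALSE)
  } else {
    n_fp <- nIA + nCR
    fp_num <- nIA
    if (n_fp == 0) stop("no lower-colour presentations: false alarm rate undefined",
                        call. = FALSE)
  }

  if (edge_policy == "loglinear") {
    hit <- (nCA + 0.5) / (n_acc + 1)
    fp <- (fp_num + 0.5) / (n_fp + 1)
    corrected <- TRUE
  } else {
    hit <- nCA / n_acc
    fp <- fp_num / n_fp
    corrected <- FALSE
    if (edge_policy == "clamp") {
      clamp1 <- function(r, n) {
        if (r <= 0) return(1 / (2 * n))
        if (r >= 1) return(1 - 1 / (2 * n))
        r
      }
      h2 <- clamp1(hit, n_acc); f2 <- clamp1(fp, n_fp)
      corrected <- (h2 != hit) || (f2 != fp)
      hit <- h2; fp <- f2
    }
  }
  list(hit_rate = hit, false_positive_rate = fp,
       edge_corrected = corrected, fp_definition = fp_definition)
}

#' Signal-detection summary: discriminability d' and decision criterion
#'
#' Computes \eqn{d' = Z(\mathrm{hit}) - Z(\mathrm{fp})} and the decision
#' criterion \eqn{c = -(Z(\mathrm{hit}) + Z(\mathrm{fp}))/2}, where `Z` is
#' the inverse standard normal cumulative distribution function and the two
#' rates come from [response_rates()] after edge correction.  A negative
#' criterion indicates acceptance is the more conservative (more accurate)
#' response.
#'
#' @inheritParams response_rates
#' @return An object of class `sdt_summary`: list with `hit_rate`,
#'   `false_positive_rate`, `d_prime`, `decision_criterion`,
#'   `edge_corrected`, `fp_definition`.
#' @examples
#' sdt_summary(response_counts(84, 16, 84, 16))  # d' about 1.99
#' @export
sdt_summary <- function(counts,
                        edge_policy = c("clamp", "loglinear", "none"),
                        fp_definition = c("rejections", "noise_trials")) {
  r <- response_rates(counts, edge_policy, fp_definition)
  zh <- stats::qnorm(r$hit_rate)
  zf <- stats::qnorm(r$false_positive_rate)
  structure(list(
    hit_rate = r$hit_rate,
    false_positive_rate = r$false_positive_rate,
    d_prime = zh - zf,
    decision_criterion = -(zh + zf) / 2,
    edge_corrected = r$edge_corrected,
    fp_definition = r$fp_definition
  ), class = "sdt_summary")
}

#' @export
print.sdt_summary <- function(x, ...) {
  cat(sprintf("SDT summary: hit = %.3f, fp = %.3f (%s%s)\n  d' = %.3f, criterion = %.3f\n",
              x$hit_rate, x$false_positive_rate, x$fp_definition,
              if (x$edge_corrected) ", edge-corrected" else "",
              x$d_prime, x$decision_criterion))
  invisible(x)
}

#' Conditional accuracy function over binned response times
#'
#' Response times of one response type (acceptances or rejections) are
#' divided into half-open bins `[k*w, (k+1)*w)` starting at 0, and the
#' proportion of correct responses is computed per bin.  Bins holding fewer
#' than `min_count` responses carry an `NA` proportion and are excluded from
#' trend statistics.
#'
#' @param events Categorised choice-event data frame with a `response_time`
#'   column.
#' @param response_type `"accept"` or `"reject"`.
#' @param bin_width Bin width in seconds (default 0.5).
#' @param min_count Minimum responses per bin for a defined proportion
#'   (default 3).
#' @return An object of class `caf_curve`: data frame with columns
#'   `bin_start`, `bin_mid`, `n_correct`, `n_total`, `prop_correct`, plus
#'   attributes `bin_width`, `response_type`, `min_count`.
#' @export
caf <- function(events, response_type = c("accept", "reject"),
                bin_width = 0.5, min_count = 3) {
  response_type <- match.arg(response_type)
  stopifnot(is.data.frame(events), bin_width > 0)
  if (!"category" %in% names(events)) {
    stop("events carry no category column; derive it with categorise_events()",
         call. = FALSE)
  }
  cats <- if (response_type == "accept") c("CA", "IA") else c("CR", "IR")
  ev <- events[events$category %in% cats, , drop = FALSE]
  if (nrow(ev) == 0) {
    stop("no events of type '", response_type, "'", call. = FALSE)
  }
  correct_cat <- if (response_type == "accept") "CA" else "CR"
  idx <- floor(ev$response_time / bin_width)
  bins <- seq(0, max(idx))
  n_total <- vapply(bins, function(b) sum(idx == b), integer(1))
  n_correct <- vapply(bins, function(b) {
    sum(idx == b & ev$category == correct_cat)
  }, integer(1))
  prop <- ifelse(n_total >= min_count, n_correct / pmax(n_total, 1L), NA_real_)
  out <- data.frame(
    bin_start = bins * bin_width,
    bin_mid = (bins + 0.5) * bin_width,
    n_correct = n_correct,
    n_total = n_total,
    prop_correct = prop
  )
  structure(out, bin_width = bin_width, response_type = response_type,
            min_count = min_count, class = c("caf_curve", "data.frame"))
}

#' Rank-correlation trend of a conditional accuracy function
#'
#' Spearman rank correlation between bin mid-times and the proportion
#' correct, over bins with a defined proportion.  A negative trend means
#' faster responses of this type were more often correct.  Constant
#' proportions (zero variance) return a trend of 0 under the average-rank
#' ties policy.
#'
#' @param curve A [caf()] curve.
#' @return List with `rho` (rank correlation) and `n_bins` used.
#' @export
caf_trend <- function(curve) {
  stopifnot(inherits(curve, "caf_curve"))
  keep <- !is.na(curve$prop_correct)
  n <- sum(keep)
  if (n < 3) {
    stop("need at least 3 defined bins for a trend; have ", n, call. = FALSE)
  }
  p <- curve$prop_correct[keep]
  if (stats::sd(p) == 0) {
    rho <- 0
  } else {
    rho <- stats::cor(curve$bin_mid[keep], p, method = "spearman")
  }
  list(rho = rho, n_bins = n)
}

#' First-choice latency per bee and test
#'
#' @param events Choice-event data frame with `bee_id`, `test_id`,
#'   `response_time`.
#' @param by Grouping: `"bee_test"` (default), `"bee"` or `"test"`.
#' @return Data frame of group keys and `first_latency` (seconds, the
#'   minimum response time in the group).
#' @export
first_choice_latency <- function(events, by = c("bee_test", "bee", "test")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) stop("no events selected", call. = FALSE)
  keys <- switch(by,
    bee_test = list(bee_id = events$bee_id, test_id = events$test_id),
    bee = list(bee_id = events$bee_id),
    test = list(test_id = events$test_id))
  agg <- stats::aggregate(events$response_time, by = keys, FUN = min)
  names(agg)[ncol(agg)] <- "first_latency"
  agg
}
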