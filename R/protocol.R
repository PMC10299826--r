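# Training-protocol representation: ordered two-colour trials with the
# rewarded member marked, and per-colour reward likelihoods.

# The five trained colours, keyed by likelihood rank.  Reward likelihoods are
# kept as integer numerator/denominator pairs derived from the trial tables,
# never as pre-rounded percentages.
.colour_levels <- c("S100", "S66", "S50", "S33", "S0")

# Nominal reward likelihood of each trained colour as an exact fraction.
.nominal_likelihood <- c(S100 = 1, S66 = 2 / 3, S50 = 1 / 2, S33 = 1 / 3, S0 = 0)

# Trial sequences: each row one trial, higher-likelihood member first.
.protocol_pairs <- list(
  P1 = list(
    c("S100", "S66"), c("S50", "S0"), c("S100", "S33"), c("S66", "S0"),
    c("S50", "S33"), c("S100", "S50"), c("S33", "S0"), c("S66", "S50"),
    c("S100", "S0"),
    c("S100", "S66"), c("S50", "S0"), c("S100", "S33"), c("S66", "S0"),
    c("S50", "S33"), c("S100", "S50"), c("S33", "S0"), c("S66", "S50"),
    c("S100", "S0")
  ),
  P2 = list(
    c("S50", "S0"), c("S100", "S66"), c("S100", "S33"), c("S66", "S0"),
    c("S100", "S50"), c("S50", "S33"), c("S100", "S0"), c("S33", "S0"),
    c("S66", "S50"),
    c("S100", "S0"), c("S50", "S33"), c("S66", "S50"), c("S33", "S0"),
    c("S100", "S50"), c("S66", "S0"), c("S100", "S33"), c("S100", "S66"),
    c("S50", "S0")
  )
)

# Optional display metadata: hue orderings used for the two bee groups.
# All computation keys on likelihood rank, never on hue.
.colour_groups <- list(
  A = c(S100 = "blue", S66 = "yellow", S50 = "pink", S33 = "orange", S0 = "green"),
  B = c(S100 = "green", S66 = "orange", S50 = "white", S33 = "yellow", S0 = "blue")
)

#' Rank a colour label by its nominal reward likelihood
#'
#' @param colour Character vector of colour ids (`"S100"`, `"S66"`, `"S50"`,
#'   `"S33"`, `"S0"`).
#' @return Numeric vector of nominal reward likelihoods in `[0, 1]`.
#' @keywords internal
.likelihood_of <- function(colour) {
  unknown <- setdiff(colour, .colour_levels)
  if (length(unknown) > 0) {
    stop("unknown colour id(s): ", paste(unknown, collapse = ", "),
         "; expected one of ", paste(.colour_levels, collapse = ", "),
         call. = FALSE)
  }
  unname(.nominal_likelihood[colour])
}

#' Build a shipped training protocol
#'
#' Constructs one of the two 18-trial colour-discrimination training
#' schedules, `"P1"` or `"P2"`.  Each trial presents a pair of the five
#' trained colours; the member with the higher nominal reward likelihood is
#' the rewarded one and the other is punished.  Over the 18 trials every
#' unordered colour pair occurs exactly twice, except the (66%, 33%) pair
#' which never occurs (it is withheld for the reduced-likelihood test).
#'
#' @param name `"P1"` or `"P2"`.
#' @param colour_group Optional display metadata: `"A"` or `"B"` attaches the
#'   corresponding hue names to the trials; `NULL` (default) omits hues.
#' @return An object of class `training_protocol`: a list with elements
#'   `name` and `trials`, the latter a data frame with columns `index`,
#'   `colour_a`, `colour_b`, `rewarded`.
#' @examples
#' p1 <- build_protocol("P1")
#' p1$trials[1, ]         # trial 1: S100 vs S66, S100 rewarded
#' reward_likelihoods(p1) # the five likelihoods 1, 2/3, 1/2, 1/3, 0
#' @seealso [reward_likelihood()], [validate_protocol()]
#' @export
build_protocol <- function(name = c("P1", "P2"), colour_group = NULL) {
  name <- match.arg(name)
  pairs <- .protocol_pairs[[name]]
  trials <- data.frame(
    index = seq_along(pairs),
    colour_a = vapply(pairs, `[`, character(1), 1L),
    colour_b = vapply(pairs, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  # generating rule: the higher nominal likelihood member is rewarded
  higher <- ifelse(.likelihood_of(trials$colour_a) >= .likelihood_of(trials$colour_b),
                   trials$colour_a, trials$colour_b)
  trials$rewarded <- higher
  out <- list(name = name, trials = trials)
  if (!is.null(colour_group)) {
    colour_group <- match.arg(colour_group, names(.colour_groups))
    out$colour_group <- colour_group
    out$hues <- .colour_groups[[colour_group]]
  }
  class(out) <- "training_protocol"
  out
}

#' Construct a training protocol from a trial table
#'
#' @param trials Data frame with columns `index`, `colour_a`, `colour_b`,
#'   `rewarded`.
#' @param name Label for the protocol.
#' @return A `training_protocol` object.
#' @export
as_training_protocol <- function(trials, name = "user") {
  need <- c("index", "colour_a", "colour_b", "rewarded")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols) > 0) {
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- trials$rewarded != trials$colour_a & trials$rewarded != trials$colour_b
  if (any(bad)) {
    stop("rewarded colour is not a member of its pair in trial(s) ",
         paste(trials$index[bad], collapse = ", "), call. = FALSE)
  }
  if (any(trials$colour_a == trials$colour_b)) {
    stop("a trial pairs a colour with itself", call. = FALSE)
  }
  structure(list(name = name, trials = as.data.frame(trials)[need]),
            class = "training_protocol")
}

#' @export
print.training_protocol <- function(x, ...) {
  cat("Training protocol", x$name, "-", nrow(x$trials), "trials\n")
  print(x$trials, row.names = FALSE)
  invisible(x)
}

#' Reward likelihood of one colour under a protocol
#'
#' The empirical likelihood of reward for a colour is the fraction of trials
#' presenting that colour in which it is the rewarded member.  For the
#' shipped protocols this evaluates to exactly 1, 4/6, 4/8, 2/6 and 0 for the
#' five colours.
#'
#' @param protocol A `training_protocol`.
#' @param colour A single colour id appearing in the protocol.
#' @return Fraction in `[0, 1]`.
#' @examples
#' reward_likelihood(build_protocol("P1"), "S66")  # 4/6
#' @export
reward_likelihood <- function(protocol, colour) {
  stopifnot(inherits(protocol, "training_protocol"), length(colour) == 1L)
  tr <- protocol$trials
  present <- tr$colour_a == colour | tr$colour_b == colour
  if (!any(present)) {
    stop("colour ", colour, " does not appear in protocol ", protocol$name,
         call. = FALSE)
  }
  sum(tr$rewarded[present] == colour) / sum(present)
}

#' Reward likelihoods of every colour in a protocol
#'
#' @param protocol A `training_protocol`.
#' @return Named numeric vector of per-colour reward likelihoods, ordered by
#'   decreasing likelihood.
#' @export
reward_likelihoods <- function(protocol) {
  stopifnot(inherits(protocol, "training_protocol"))
  cols <- unique(c(protocol$trials$colour_a, protocol$trials$colour_b))
  lik <- vapply(cols, function(cc) reward_likelihood(protocol, cc), numeric(1))
  sort(lik, decreasing = TRUE)
}

#' Validate a training protocol against the shipped design rules
#'
#' Checks trial count (18), pair coverage (every unordered pair of the five
#' trained colours exactly twice except the withheld (66%, 33%) pair), the
#' rewarded-member rule (higher nominal likelihood rewarded), and the
#' resulting per-colour likelihoods.  Violations are reported, not raised.
#'
#' @param protocol A `training_protocol`.
#' @return An object of class `protocol_validation`: list with `n_trials`,
#'   `pair_counts`, `excluded_pair_absent`, `likelihoods`, `flags` (character
#'   vector of violations, empty when the protocol conforms) and `ok`.
#' @export
validate_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "training_protocol"))
  tr <- protocol$trials
  flags <- character(0)
  n <- nrow(tr)
  if (n != 18L) flags <- c(flags, sprintf("expected 18 trials, found %d", n))

  if (n > 0) {
    key <- apply(cbind(tr$colour_a, tr$colour_b), 1L, function(p) {
      paste(sort(p), collapse = ":")
    })
    pair_counts <- table(key)
    expected <- utils::combn(.colour_levels, 2L, function(p) {
      paste(sort(p), collapse = ":")
    })
    excluded <- paste(sort(c("S66", "S33")), collapse = ":")
    for (pp in setdiff(expected, excluded)) {
      cnt <- if (pp %in% names(pair_counts)) pair_counts[[pp]] else 0L
      if (cnt != 2L) flags <- c(flags, sprintf("pair %s occurs %d times (expected 2)", pp, cnt))
    }
    excluded_absent <- !(excluded %in% names(pair_counts))
    if (!excluded_absent) flags <- c(flags, sprintf("withheld pair %s occurs", excluded))
    wrong <- tr$rewarded != ifelse(
      .likelihood_of(tr$colour_a) >= .likelihood_of(tr$colour_b),
      tr$colour_a, tr$colour_b)
    if (any(wrong)) {
      flags <- c(flags, sprintf("lower-likelihood member rewarded in trial(s) %s",
                                paste(tr$index[wrong], collapse = ", ")))
    }
    likelihoods <- reward_likelihoods(protocol)
  } else {
    pair_counts <- table(character(0))
    excluded_absent <- FALSE
    likelihoods <- numeric(0)
    flags <- c(flags, "no trials", "pair coverage unverifiable",
               "likelihoods unverifiable")
  }

  structure(list(
    name = protocol$name,
    n_trials = n,
    pair_counts = pair_counts,
    excluded_pair_absent = excluded_absent,
    likelihoods = likelihoods,
    flags = flags,
    ok = length(flags) == 0L
  ), class = "protocol_validation")
}

#' @export
print.protocol_validation <- function(x, ...) {
  cat("Protocol", x$name, "-", x$n_trials, "trials;",
      length(x$pair_counts), "distinct pairs\n")
  if (length(x$likelihoods)) {
    cat("Reward likelihoods:\n")
    print(round(x$likelihoods, 4))
  }
  if (x$ok) cat("All checks passed.\n")
  else cat("Violations:\n", paste(" -", x$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write a protocol trial table
#'
#' Protocols round-trip through a delimited text table with columns `index`,
#' `colour_a`, `colour_b`, `rewarded`.
#'
#' @param file Path to a delimited text file.
#' @param name Protocol label to attach on read.
#' @param sep Field separator (default comma).
#' @return `read_protocol()` returns a `training_protocol`;
#'   `write_protocol()` invisibly returns `file`.
#' @export
read_protocol <- function(file, name = "user", sep = ",") {
  tr <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_training_protocol(tr, name = name)
}

#' @rdname read_protocol
#' @param protocol A `training_protocol` to write.
#' @export
write_protocol <- function(protocol, file, sep = ",") {
  stopifnot(inherits(protocol, "training_protocol"))
  utils::write.table(protocol$trials, file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
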