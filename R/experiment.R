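# Population-level simulated experiments: delta-rule training of reward
# estimates over a protocol, the three post-training tests on cohorts of
# model bees, ablations, and behavioural summaries.

#' Train per-colour reward estimates over a protocol
#'
#' An abstract learning stage stands in for the mushroom-body plasticity
#' that tracks each colour's reinforcement history: every colour presented
#' in a trial updates its reward estimate by a delta rule,
#' `q_hat <- q_hat + eta * (r - q_hat)` with `r = 1` when that colour is the
#' rewarded member and 0 otherwise, starting from `q_hat = 0.5`.  The
#' default `eta = 0.1` keeps the trained estimates rank-ordered with the
#' nominal reward likelihoods under both shipped protocols (larger rates
#' over-weight the most recent trials and can invert neighbouring colours).
#' The rule is deterministic; `seed` is accepted for interface symmetry with
#' the stochastic stages and ignored.
#'
#' @param protocol A [build_protocol()] object.
#' @param eta Learning rate in `(0, 1]`.
#' @param q0 Initial estimate for every colour (default 0.5).
#' @param seed Ignored (the update is deterministic).
#' @return An object of class `learned_state`: list with `q_hat` (named
#'   vector), `eta`, `n_trials` and `history` (per-trial estimates).
#' @export
train_weights <- function(protocol, eta = 0.1, q0 = 0.5, seed = NULL) {
  stopifnot(inherits(protocol, "training_protocol"))
  if (eta <= 0 || eta > 1) {
    stop("learning rate eta must lie in (0, 1]", call. = FALSE)
  }
  tr <- protocol$trials
  colours <- unique(c(tr$colour_a, tr$colour_b))
  q <- stats::setNames(rep(q0, length(colours)), colours)
  history <- matrix(NA_real_, nrow = nrow(tr) + 1L, ncol = length(colours),
                    dimnames = list(NULL, colours))
  history[1L, ] <- q
  for (i in seq_len(nrow(tr))) {
    for (cc in c(tr$colour_a[i], tr$colour_b[i])) {
      r <- as.numeric(tr$rewarded[i] == cc)
      q[cc] <- q[cc] + eta * (r - q[cc])
    }
    history[i + 1L, ] <- q
  }
  structure(list(q_hat = q, eta = eta, n_trials = nrow(tr),
                 history = history),
            class = "learned_state")
}

#' @export
print.learned_state <- function(x, ...) {
  cat("Learned reward estimates after", x$n_trials, "trials (eta =", x$eta, "):\n")
  print(round(sort(x$q_hat, decreasing = TRUE), 4))
  invisible(x)
}

#' Generalise a learned estimate to a blend stimulus
#'
#' A novel colour blended between two trained anchors inherits a reward
#' estimate by linear interpolation on its blend similarity `b` to the
#' high anchor: `q_hat(blend) = b * q_hat(high) + (1 - b) * q_hat(low)`.
#'
#' @param blend_similarity Similarity to the high anchor in `[0, 1]`.
#' @param learned A [train_weights()] state.
#' @param high,low Anchor colour ids (defaults `"S100"`, `"S0"`).
#' @return The interpolated estimate.
#' @export
generalise <- function(blend_similarity, learned, high = "S100", low = "S0") {
  stopifnot(inherits(learned, "learned_state"))
  if (any(blend_similarity < 0 | blend_similarity > 1)) {
    stop("blend_similarity must lie in [0, 1]", call. = FALSE)
  }
  missing_anchor <- setdiff(c(high, low), names(learned$q_hat))
  if (length(missing_anchor) > 0) {
    stop("anchor colour(s) untrained: ", paste(missing_anchor, collapse = ", "),
         call. = FALSE)
  }
  blend_similarity * learned$q_hat[[high]] +
    (1 - blend_similarity) * learned$q_hat[[low]]
}

#' Specify a post-training test for model bees
#'
#' Three standard tests probe a trained model: `easy` presents the
#' always-rewarded versus never-rewarded colours (idealised estimates 1 and
#' 0); `reduced_evidence` presents two blend stimuli whose estimates are
#' generalised from the trained anchors at blend similarities `blend_high`
#' and `blend_low`; `reduced_likelihood` presents the trained 66%- and
#' 33%-rewarded colours at their trained estimates.
#'
#' @param test_id `"easy"`, `"reduced_evidence"` or `"reduced_likelihood"`.
#' @param n_trials Stimulus presentations per model bee (default 25).
#' @param n_bees Model bees in the cohort (default 20).
#' @param blend_high,blend_low Blend similarities of the two
#'   reduced-evidence stimuli (defaults 0.7 and 0.3).
#' @return An object of class `test_spec`.
#' @export
test_spec <- function(test_id = c("easy", "reduced_evidence", "reduced_likelihood"),
                      n_trials = 25, n_bees = 20,
                      blend_high = 0.7, blend_low = 0.3) {
  test_id <- match.arg(test_id)
  stopifnot(n_trials >= 1, n_bees >= 1)
  structure(list(test_id = test_id, n_trials = n_trials, n_bees = n_bees,
                 blend_high = blend_high, blend_low = blend_low),
            class = "test_spec")
}

# Resolve the (high, low) stimulus ids and their q_hat for a test.
.test_stimuli <- function(spec, learned) {
  switch(spec$test_id,
    easy = list(ids = c("S100", "S0"), q_hat = c(1, 0)),
    reduced_evidence = list(
      ids = c("blend_high", "blend_low"),
      q_hat = c(generalise(spec$blend_high, learned),
                generalise(spec$blend_low, learned))),
    reduced_likelihood = {
      missing_col <- setdiff(c("S66", "S33"), names(learned$q_hat))
      if (length(missing_col) > 0) {
        stop("learned state lacks estimates for: ",
             paste(missing_col, collapse = ", "), call. = FALSE)
      }
      list(ids = c("S66", "S33"),
           q_hat = c(learned$q_hat[["S66"]], learned$q_hat[["S33"]]))
    })
}

#' Run a test on a cohort of model bees
#'
#' Each of `n_bees` model bees receives `n_trials` presentations drawn
#' uniformly at random from the test's stimulus pair, each simulated as one
#' accumulator trial.  Bee `i` uses the noise stream seeded with
#' `seed + i`, so cohorts are reproducible and bees differ only in their
#' noise.  Decision times are also reported normalised to the maximum over
#' the whole cohort.
#'
#' @param spec A [test_spec()].
#' @param params A [model_params()] object.
#' @param variant Model variant (see [simulate_trial()]).
#' @param learned A [train_weights()] state (needed for the
#'   reduced-evidence and reduced-likelihood tests; may be `NULL` for
#'   `easy`).
#' @param seed Master seed (integer).
#' @return A data frame of class `simulation_table`: columns `bee_id`,
#'   `trial`, `test_id`, `stimulus_id`, `q_hat`, `response`, `category`,
#'   `decision_time`, `forced`, `time_norm`, `response_time` (alias of
#'   `decision_time` so choice-event analyses apply unchanged).
#' @export
run_test <- function(spec, params, variant = .model_variants,
                     learned = NULL, seed = 1L) {
  stopifnot(inherits(spec, "test_spec"), inherits(params, "model_params"))
  variant <- match.arg(variant)
  if (is.null(learned) && spec$test_id != "easy") {
    stop("tests other than 'easy' need a trained learned state", call. = FALSE)
  }
  stim <- .test_stimuli(spec, learned)

  old <- .save_rng(); on.exit(.restore_rng(old))
  rows <- vector("list", spec$n_bees)
  for (b in seq_len(spec$n_bees)) {
    set.seed(seed + b)
    which_stim <- sample(c(1L, 2L), spec$n_trials, replace = TRUE)
    sim <- .simulate_batch(spec$n_trials, params, variant,
                           q_hat = stim$q_hat[which_stim])
    rows[[b]] <- data.frame(
      bee_id = b,
      trial = seq_len(spec$n_trials),
      test_id = spec$test_id,
      stimulus_id = stim$ids[which_stim],
      q_hat = stim$q_hat[which_stim],
      response = sim$response,
      decision_time = sim$decision_time,
      forced = sim$forced,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- categorise_events(out, high_stimulus = stim$ids[1])
  out$time_norm <- out$decision_time / max(out$decision_time)
  out$response_time <- out$decision_time
  attr(out, "variant") <- variant
  attr(out, "seed") <- seed
  attr(out, "bee_seeds") <- seed + seq_len(spec$n_bees)
  class(out) <- c("simulation_table", "data.frame")
  out
}

#' Ablate model components
#'
#' Returns a parameter set with the learning cells silenced
#' (`no_learning`: `alpha = 0`), the command-cell feedback removed
#' (`no_feedback`: `va = vr = 0`), or both (`neither`), leaving all other
#' parameters unchanged.
#'
#' @param params A [model_params()] object.
#' @param mode `"no_learning"`, `"no_feedback"` or `"neither"`.
#' @return A modified `model_params` object.
#' @export
ablate <- function(params, mode = c("no_learning", "no_feedback", "neither")) {
  stopifnot(inherits(params, "model_params"))
  mode <- match.arg(mode)
  p <- unclass(params)
  if (mode %in% c("no_learning", "neither")) p$alpha <- 0
  if (mode %in% c("no_feedback", "neither")) { p$va <- 0; p$vr <- 0 }
  do.call(model_params, p)
}

#' Summarise a simulated test
#'
#' Produces the same statistics used for live-bee analyses: pooled and
#' per-bee four-outcome counts and MCC, a pooled signal-detection summary,
#' mean decision times by category, and the percentage of correct choices
#' per block of trials (mean and standard error across bees).
#'
#' @param table A [run_test()] table (or any categorised event table with
#'   `bee_id`, `category`, `decision_time`).
#' @param block_size Trials per block for the percent-correct course
#'   (default 25, one test = one block).
#' @param edge_policy Passed to [sdt_summary()].
#' @return An object of class `simulation_summary`.
#' @export
summarise_simulation <- function(table, block_size = 25,
                                 edge_policy = "clamp") {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) stop("empty simulation table", call. = FALSE)
  pooled <- count_responses(table)

  bees <- sort(unique(table$bee_id))
  per_bee <- do.call(rbind, lapply(bees, function(b) {
    ct <- count_responses(table, bee = b)
    data.frame(bee_id = b, nCA = ct[["nCA"]], nIA = ct[["nIA"]],
               nCR = ct[["nCR"]], nIR = ct[["nIR"]], mcc = mcc(ct))
  }))

  pooled_mcc <- mcc(pooled)
  mcc_note <- NULL
  marg <- c(pooled[["nCA"]] + pooled[["nIA"]], pooled[["nCA"]] + pooled[["nIR"]],
            pooled[["nCR"]] + pooled[["nIA"]], pooled[["nCR"]] + pooled[["nIR"]])
  if (any(marg == 0)) {
    mcc_note <- "a marginal of the pooled table is zero; MCC reported as 0 by convention"
  }

  sdt <- tryCatch(sdt_summary(pooled, edge_policy = edge_policy),
                  error = function(e) NULL)

  mean_times <- stats::aggregate(table$decision_time,
                                 by = list(category = table$category),
                                 FUN = mean)
  names(mean_times)[2] <- "mean_time"

  correct <- table$category %in% c("CA", "CR")
  block <- (stats::ave(seq_len(nrow(table)), table$bee_id,
                       FUN = seq_along) - 1L) %/% block_size + 1L
  block_df <- stats::aggregate(correct, by = list(bee_id = table$bee_id,
                                                  block = block), FUN = mean)
  names(block_df)[3] <- "prop_correct"
  course <- stats::aggregate(block_df$prop_correct,
                             by = list(block = block_df$block),
                             FUN = function(v) {
                               c(mean = mean(v),
                                 se = stats::sd(v) / sqrt(length(v)))
                             })
  course <- data.frame(block = course$block,
                       pct_correct = 100 * course$x[, "mean"],
                       se = 100 * course$x[, "se"])

  structure(list(
    counts = pooled,
    mcc = pooled_mcc,
    mcc_note = mcc_note,
    per_bee = per_bee,
    sdt = sdt,
    mean_times = mean_times,
    block_correct = block_df,
    pct_correct = course,
    n_forced = if ("forced" %in% names(table)) sum(table$forced) else NA_integer_
  ), class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  print(x$counts)
  cat(sprintf("Pooled MCC = %.3f%s\n", x$mcc,
              if (!is.null(x$mcc_note)) paste0(" (", x$mcc_note, ")") else ""))
  if (!is.null(x$sdt)) {
    cat(sprintf("Pooled d' = %.3f, criterion = %.3f\n",
                x$sdt$d_prime, x$sdt$decision_criterion))
  }
  cat("Mean decision time by category (s):\n")
  print(x$mean_times, row.names = FALSE)
  cat("Percent correct per block (mean +/- SE over bees):\n")
  print(x$pct_correct, row.names = FALSE)
  invisible(x)
}

#' Write a simulation table as delimited text
#'
#' The schema matches the choice-event format consumed by the behavioural
#' metrics (plus `forced` and `time_norm`), so the same analyses run on
#' model and bee data.
#'
#' @param table A [run_test()] table.
#' @param file Output path.
#' @param sep Field separator.
#' @export
write_simulation <- function(table, file, sep = ",") {
  utils::write.table(as.data.frame(table), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
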