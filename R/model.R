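# Leaky stochastic accumulator models of accept/reject choice.
#
# Evidence for accepting (Pa) and rejecting (Pr) a stimulus accumulates in
# two leaky integrators driven by a common sensory input I, integrated by
# Euler-Maruyama.  Command cells read the accumulators through a floor at a
# baseline activity; a decision fires when a command output reaches the
# threshold theta, or is forced at t_max by the larger command output.
# Four variants switch terms on and off:
#   race      dP = (-k P + I) dt + sigma dW                  (independent)
#   cross     race + cross-inhibition -v * (opposing command) as drift
#   learning  race + learning-cell inhibition -w * rL as drift
#   full      both learning and cross-inhibition

.model_variants <- c("race", "cross", "learning", "full")

#' Accumulator model parameters
#'
#' All symbols of the accumulator equations in one validated container.
#' Defaults are calibrated (see [calibrate_model()]) to reproduce the
#' qualitative behavioural signatures of trained bees (they are modelling
#' choices, not measured quantities): `k = 1`, `I = 1`, `sigma = 0.6`,
#' `theta = 1.5`, `t_max = 10`, `dt = 0.01`, cross-inhibition
#' `va = 0.2 < vr = 0.6` (rejection inhibits
#' acceptance more strongly), learning-cell rate `alpha = 0.8` and weights
#' `w1a = 0.8 > w2a = 0.1`, `w2r = 0.8 > w1r = 0.1` (the low-colour cell L1
#' mainly inhibits the accept accumulator, the high-colour cell L2 mainly
#' the reject accumulator).
#'
#' @param k Leak (decay) rate of both accumulators, 1/s.
#' @param I Sensory input magnitude, evidence/s.
#' @param sigma Diffusion scale of the Brownian noise, evidence/sqrt(s).
#' @param theta Command threshold triggering a decision, evidence units.
#' @param t_max Maximal assessment time, s; reaching it forces a decision.
#' @param dt Euler-Maruyama step, s.
#' @param va,vr Fractions of the accept/reject command outputs that inhibit
#'   the opposing accumulator (cross-inhibition); asymmetric variants use
#'   `vr > va`.
#' @param alpha Learning-cell activation rate in `[0, 1]`.
#' @param w1a,w1r,w2a,w2r Learning-cell inhibition weights onto the accept
#'   (`*a`) and reject (`*r`) accumulators from the low-colour cell L1
#'   (`w1*`) and high-colour cell L2 (`w2*`); require `w1a > w2a` and
#'   `w2r > w1r` when learning is enabled.
#' @param baseline Command-cell floor activity (0.1).
#' @return An object of class `model_params` (named list).
#' @export
model_params <- function(k = 1, I = 1, sigma = 0.6, theta = 1.5, t_max = 10,
                         dt = 0.01, va = 0.2, vr = 0.6, alpha = 0.8,
                         w1a = 0.8, w1r = 0.1, w2a = 0.1, w2r = 0.8,
                         baseline = 0.1) {
  p <- list(k = k, I = I, sigma = sigma, theta = theta, t_max = t_max,
            dt = dt, va = va, vr = vr, alpha = alpha,
            w1a = w1a, w1r = w1r, w2a = w2a, w2r = w2r, baseline = baseline)
  stopifnot(k >= 0, sigma >= 0, dt > 0, t_max >= dt,
            alpha >= 0, alpha <= 1, va >= 0, vr >= 0)
  if (theta <= baseline) {
    stop("threshold theta must exceed the command baseline (", baseline, ")",
         call. = FALSE)
  }
  if (alpha > 0 && !(w1a > w2a && w2r > w1r)) {
    stop("learning weights must satisfy w1a > w2a and w2r > w1r", call. = FALSE)
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Accumulator model parameters:\n")
  cat(sprintf("  k = %g, I = %g, sigma = %g, theta = %g, t_max = %g, dt = %g\n",
              x$k, x$I, x$sigma, x$theta, x$t_max, x$dt))
  cat(sprintf("  cross-inhibition: va = %g, vr = %g\n", x$va, x$vr))
  cat(sprintf("  learning: alpha = %g, w1a = %g, w2a = %g, w1r = %g, w2r = %g\n",
              x$alpha, x$w1a, x$w2a, x$w1r, x$w2r))
  cat(sprintf("  command baseline = %g\n", x$baseline))
  invisible(x)
}

#' Load / save model parameters as YAML or JSON
#'
#' Every symbol is named as in [model_params()]; unknown keys raise an error.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return `read_model_params()` returns a `model_params` object;
#'   `write_model_params()` invisibly returns `file`.
#' @export
read_model_params <- function(file) {
  vals <- if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  known <- names(formals(model_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_params, vals)
}

#' @rdname read_model_params
#' @param params A `model_params` object.
#' @export
write_model_params <- function(params, file) {
  stopifnot(inherits(params, "model_params"))
  vals <- unclass(params)
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    yaml::write_yaml(vals, file)
  } else {
    jsonlite::write_json(vals, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Command-cell transfer function
#'
#' A command cell relays its accumulator's evidence, floored at the baseline
#' activity: `max(baseline, P)`.
#'
#' @param P Accumulated evidence (vectorised).
#' @param baseline Floor activity (default 0.1).
#' @return Command activity, same length as `P`.
#' @examples
#' command_output(-0.5)  # 0.1
#' command_output(2.3)   # 2.3
#' @export
command_output <- function(P, baseline = 0.1) {
  pmax(baseline, P)
}

#' Learning-cell drives for a stimulus
#'
#' The low-colour cell L1 and high-colour cell L2 fire in proportion to the
#' stimulus' learned reward estimate `q_hat`: `rL1 = alpha * I * (1 - q_hat)`
#' and `rL2 = alpha * I * q_hat`.  This graded scheme reduces to the binary
#' one (only L1 for a never-rewarded colour, only L2 for an always-rewarded
#' one) at the endpoints.
#'
#' @param q_hat Learned reward estimate in `[0, 1]`.
#' @param params A [model_params()] object.
#' @return List with `rL1` and `rL2`.
#' @export
learning_drive <- function(q_hat, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(q_hat < 0 | q_hat > 1)) {
    stop("q_hat must lie in [0, 1]", call. = FALSE)
  }
  list(rL1 = params$alpha * params$I * (1 - q_hat),
       rL2 = params$alpha * params$I * q_hat)
}

#' One Euler-Maruyama step of the accumulator pair
#'
#' Advances the state `(t, Pa, Pr)` by `dt`.  Cross-inhibition and
#' learning-cell terms enter as drifts evaluated from the pre-step state so
#' that dynamics are step-size consistent.
#'
#' @param state List with `t`, `Pa`, `Pr` (each possibly vectors of equal
#'   length for batched trials).
#' @param params A [model_params()] object.
#' @param variant One of `"race"`, `"cross"`, `"learning"`, `"full"`.
#' @param rL1,rL2 Learning-cell activities (scalars or vectors matching the
#'   state), ignored unless the variant includes learning.
#' @param xi1,xi2 Standard-normal noise draws; when `NULL`, drawn from the
#'   current RNG stream.
#' @return The advanced state list.
#' @export
step_accumulators <- function(state, params, variant = .model_variants,
                              rL1 = 0, rL2 = 0, xi1 = NULL, xi2 = NULL) {
  variant <- match.arg(variant)
  n <- length(state$Pa)
  if (is.null(xi1)) xi1 <- stats::rnorm(n)
  if (is.null(xi2)) xi2 <- stats::rnorm(n)
  p <- params
  learn_on <- variant %in% c("learning", "full")
  feed_on <- variant %in% c("cross", "full")

  A <- command_output(state$Pa, p$baseline)
  R <- command_output(state$Pr, p$baseline)
  drift_a <- -p$k * state$Pa + p$I
  drift_r <- -p$k * state$Pr + p$I
  if (learn_on) {
    drift_a <- drift_a - (p$w1a * rL1 + p$w2a * rL2)
    drift_r <- drift_r - (p$w1r * rL1 + p$w2r * rL2)
  }
  if (feed_on) {
    drift_a <- drift_a - p$vr * R
    drift_r <- drift_r - p$va * A
  }
  noise <- p$sigma * sqrt(p$dt)
  list(t = state$t + p$dt,
       Pa = state$Pa + drift_a * p$dt + noise * xi1,
       Pr = state$Pr + drift_r * p$dt + noise * xi2)
}

# Batched simulation of n independent trials sharing params/variant, each
# with its own q_hat.  Uses the current RNG stream (seed it upstream).
# The update matches step_accumulators() exactly but is inlined for speed
# (the equivalence is unit-tested).
# Returns data.frame(response, decision_time, forced).
.simulate_batch <- function(n, params, variant, q_hat) {
  p <- params
  if (length(q_hat) == 1L) q_hat <- rep(q_hat, n)
  stopifnot(length(q_hat) == n)
  drive <- learning_drive(q_hat, p)
  learn_on <- variant %in% c("learning", "full")
  feed_on <- variant %in% c("cross", "full")
  inh_a <- if (learn_on) p$w1a * drive$rL1 + p$w2a * drive$rL2 else numeric(n)
  inh_r <- if (learn_on) p$w1r * drive$rL1 + p$w2r * drive$rL2 else numeric(n)
  k <- p$k; I <- p$I; dt <- p$dt; va <- p$va; vr <- p$vr
  noise <- p$sigma * sqrt(dt); base <- p$baseline; theta <- p$theta

  Pa <- numeric(n); Pr <- numeric(n)   # evidence starts at zero
  response <- character(n)
  decision_time <- rep(NA_real_, n)
  forced <- logical(n)
  active <- seq_len(n)
  n_steps <- ceiling(p$t_max / dt)

  for (s in seq_len(n_steps)) {
    m <- length(active)
    if (m == 0L) break
    pa <- Pa[active]; pr <- Pr[active]
    A <- pmax(base, pa); R <- pmax(base, pr)
    da <- (-k * pa + I) * dt
    dr <- (-k * pr + I) * dt
    if (learn_on) {
      da <- da - inh_a[active] * dt
      dr <- dr - inh_r[active] * dt
    }
    if (feed_on) {
      da <- da - vr * R * dt
      dr <- dr - va * A * dt
    }
    pa <- pa + da + noise * stats::rnorm(m)
    pr <- pr + dr + noise * stats::rnorm(m)
    if (anyNA(pa) || anyNA(pr) || any(is.infinite(pa)) || any(is.infinite(pr))) {
      stop("non-finite accumulator state at step ", s,
           " (t = ", format(s * dt), "): check parameter magnitudes",
           call. = FALSE)
    }
    Pa[active] <- pa; Pr[active] <- pr
    A <- pmax(base, pa); R <- pmax(base, pr)
    hit <- A >= theta | R >= theta
    if (any(hit)) {
      hi <- active[hit]
      # larger command wins; exact tie resolves to reject (the default action)
      response[hi] <- ifelse(A[hit] > R[hit], "accept", "reject")
      decision_time[hi] <- s * dt
      active <- active[!hit]
    }
  }
  if (length(active) > 0L) {
    A <- pmax(base, Pa[active]); R <- pmax(base, Pr[active])
    response[active] <- ifelse(A > R, "accept", "reject")
    decision_time[active] <- n_steps * dt
    forced[active] <- TRUE
  }
  data.frame(response = response, decision_time = decision_time,
             forced = forced, stringsAsFactors = FALSE)
}

#' Simulate one decision trial
#'
#' Runs the accumulator pair from `Pa = Pr = 0` until a command output
#' reaches the threshold `theta` (the larger command wins if both cross in
#' the same step; an exact tie resolves to reject) or until `t_max`, at
#' which point the decision is forced to the larger command output (tie:
#' reject) and flagged `forced`.
#'
#' @param params A [model_params()] object.
#' @param variant One of `"race"`, `"cross"`, `"learning"`, `"full"`.
#' @param q_hat Learned reward estimate of the presented stimulus in
#'   `[0, 1]`; drives the learning cells in the learning/full variants.
#' @param seed Optional integer fixing the noise stream; identical
#'   `(params, variant, q_hat, seed)` give identical outcomes.
#' @param trace When `TRUE`, record the full time series of
#'   `(t, Pa, Pr, A, R)`.
#' @return An object of class `decision_outcome`: list with `response`
#'   (`"accept"`/`"reject"`), `decision_time` (s), `forced` (logical) and,
#'   when requested, `trace` (data frame).
#' @export
simulate_trial <- function(params, variant = .model_variants, q_hat = 0.5,
                           seed = NULL, trace = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(params, "model_params"), length(q_hat) == 1L)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  p <- params
  drive <- learning_drive(q_hat, p)
  n_steps <- ceiling(p$t_max / p$dt)
  st <- list(t = 0, Pa = 0, Pr = 0)
  tr <- if (trace) {
    data.frame(t = numeric(n_steps + 1), Pa = NA_real_, Pr = NA_real_,
               A = NA_real_, R = NA_real_)
  } else NULL
  record <- function(i, st) {
    tr[i, ] <<- c(st$t, st$Pa, st$Pr,
                  command_output(st$Pa, p$baseline),
                  command_output(st$Pr, p$baseline))
  }
  if (trace) record(1L, st)

  for (s in seq_len(n_steps)) {
    st <- step_accumulators(st, p, variant, drive$rL1, drive$rL2)
    if (!is.finite(st$Pa) || !is.finite(st$Pr)) {
      stop("non-finite accumulator state at step ", s, call. = FALSE)
    }
    if (trace) record(s + 1L, st)
    A <- command_output(st$Pa, p$baseline)
    R <- command_output(st$Pr, p$baseline)
    if (A >= p$theta || R >= p$theta) {
      out <- list(response = if (A > R) "accept" else "reject",
                  decision_time = s * p$dt, forced = FALSE)
      if (trace) out$trace <- tr[seq_len(s + 1L), ]
      class(out) <- "decision_outcome"
      return(out)
    }
  }
  A <- command_output(st$Pa, p$baseline)
  R <- command_output(st$Pr, p$baseline)
  out <- list(response = if (A > R) "accept" else "reject",
              decision_time = n_steps * p$dt, forced = TRUE)
  if (trace) out$trace <- tr
  class(out) <- "decision_outcome"
  out
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat(sprintf("Decision: %s at t = %.3f s%s\n", x$response, x$decision_time,
              if (x$forced) " (forced at t_max)" else ""))
  invisible(x)
}

#' Export a decision trace as delimited text
#'
#' @param outcome A [simulate_trial()] outcome produced with `trace = TRUE`.
#' @param file Path for the output table (columns `t, Pa, Pr, A, R`).
#' @param sep Field separator.
#' @export
write_trace <- function(outcome, file, sep = ",") {
  stopifnot(inherits(outcome, "decision_outcome"))
  if (is.null(outcome$trace)) stop("outcome carries no trace", call. = FALSE)
  utils::write.table(outcome$trace, file, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
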