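# Synthetic choice-event tables and flight trajectories with known ground
# truth, so every analysis in the package is testable without external data.

#' Specify a synthetic choice-behaviour generator
#'
#' Emulates per-bee sequences of accept/reject events against a two-colour
#' test within a fixed observation window.  Response times are log-normal
#' (positive and right-skewed, as free-flight inspection times are); the
#' default per-category location parameters make correct acceptances faster
#' than incorrect ones while rejection times are insensitive to
#' correctness, mimicking the qualitative pattern of trained bees.  These
#' defaults are illustrative, not measured values.
#'
#' @param p_accept_high,p_accept_low Acceptance probability on encountering
#'   the higher-/lower-rewarded colour.
#' @param rt_meanlog Named numeric: log-scale location of the response-time
#'   distribution per category (`CA`, `IA`, `CR`, `IR`).
#' @param rt_sdlog Log-scale spread (shared across categories).
#' @param encounters_mean Mean encounters per bee (Poisson, minimum 1).
#' @param n_bees Number of bees.
#' @param window Observation window in seconds (default 120); events whose
#'   cumulative time exceeds it are truncated.
#' @param high_stimulus,low_stimulus Stimulus ids.
#' @param test_id Test label attached to every event.
#' @return An object of class `behaviour_spec`.
#' @export
behaviour_spec <- function(p_accept_high = 0.8, p_accept_low = 0.3,
                           rt_meanlog = c(CA = log(0.8), IA = log(1.6),
                                          CR = log(1.0), IR = log(1.0)),
                           rt_sdlog = 0.4,
                           encounters_mean = 20, n_bees = 10, window = 120,
                           high_stimulus = "S100", low_stimulus = "S0",
                           test_id = "easy") {
  stopifnot(p_accept_high >= 0, p_accept_high <= 1,
            p_accept_low >= 0, p_accept_low <= 1,
            window > 0, encounters_mean > 0, n_bees >= 1,
            rt_sdlog > 0,
            all(c("CA", "IA", "CR", "IR") %in% names(rt_meanlog)))
  structure(list(p_accept_high = p_accept_high, p_accept_low = p_accept_low,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 encounters_mean = encounters_mean, n_bees = n_bees,
                 window = window, high_stimulus = high_stimulus,
                 low_stimulus = low_stimulus, test_id = test_id),
            class = "behaviour_spec")
}

#' Generate a synthetic choice-event table
#'
#' Per bee, draws an encounter count, a uniformly random stimulus per
#' encounter, an accept/reject response by the stimulus' acceptance
#' probability, and a log-normal response time by category.  Events whose
#' cumulative inspection time passes the observation window are dropped.
#' A pure function of its seed.
#'
#' @param spec A [behaviour_spec()].
#' @param seed Integer seed.
#' @return List with `events` (categorised choice-event data frame) and
#'   `truth` (the generating parameters, including the exact acceptance
#'   probabilities).
#' @export
generate_choice_events <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "behaviour_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  rows <- vector("list", spec$n_bees)
  for (b in seq_len(spec$n_bees)) {
    n <- max(1L, stats::rpois(1L, spec$encounters_mean))
    is_high <- stats::runif(n) < 0.5
    p <- ifelse(is_high, spec$p_accept_high, spec$p_accept_low)
    accept <- stats::runif(n) < p
    category <- ifelse(accept, ifelse(is_high, "CA", "IA"),
                       ifelse(is_high, "IR", "CR"))
    rt <- stats::rlnorm(n, meanlog = spec$rt_meanlog[category],
                        sdlog = spec$rt_sdlog)
    keep <- cumsum(rt) <= spec$window
    rows[[b]] <- data.frame(
      bee_id = b,
      test_id = spec$test_id,
      stimulus_id = ifelse(is_high, spec$high_stimulus, spec$low_stimulus),
      response = ifelse(accept, "accept", "reject"),
      response_time = rt,
      stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
  }
  events <- do.call(rbind, rows)
  rownames(events) <- NULL
  events <- categorise_events(events, spec$high_stimulus)
  list(events = events,
       truth = list(p_accept_high = spec$p_accept_high,
                    p_accept_low = spec$p_accept_low,
                    seed = seed))
}

#' Specify a synthetic flight-trajectory generator
#'
#' Emulates a planar arena flight at a fixed frame rate: the bee cruises
#' between stimuli, and at each planned visit either decelerates inside the
#' focal radius and dwells (an acceptance) or traverses the focal area at
#' cruise speed (a rejection/fly-over).  Gaussian positional jitter is
#' added per frame.
#'
#' @param layout A [stimulus_layout()].
#' @param visit_plan Data frame with columns `stimulus_id`, `intent`
#'   (`"accept"`/`"reject"`) and optionally `dwell` (seconds, default 1).
#' @param arena Arena extent in metres (default `c(1.0, 0.8)`).
#' @param fps Frame rate (default 240).
#' @param cruise_speed Flight speed between and over stimuli, m/s (default
#'   0.35, within the observed 0-0.5 m/s range).
#' @param dwell_speed Hover speed during an acceptance, m/s (default 0.02).
#' @param noise_sd Positional jitter per frame, metres (default 5e-5).
#' @param start Starting position (default near the arena corner).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(layout, visit_plan, arena = c(1.0, 0.8),
                            fps = 240, cruise_speed = 0.35,
                            dwell_speed = 0.02, noise_sd = 5e-5,
                            start = c(0.05, 0.05)) {
  stopifnot(inherits(layout, "stimulus_layout"),
            is.data.frame(visit_plan),
            all(c("stimulus_id", "intent") %in% names(visit_plan)),
            cruise_speed > 0, dwell_speed >= 0, noise_sd >= 0, fps > 0)
  unknown <- setdiff(visit_plan$stimulus_id, layout$stimulus_id)
  if (length(unknown) > 0) {
    stop("visit plan references unknown stimulus: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(visit_plan$intent %in% c("accept", "reject"))) {
    stop("visit intents must be 'accept' or 'reject'", call. = FALSE)
  }
  if (is.null(visit_plan$dwell)) visit_plan$dwell <- rep(1, nrow(visit_plan))
  structure(list(layout = layout, visit_plan = visit_plan, arena = arena,
                 fps = fps, cruise_speed = cruise_speed,
                 dwell_speed = dwell_speed, noise_sd = noise_sd,
                 start = start),
            class = "trajectory_spec")
}

# straight-line waypoint run at constant speed; returns matrix of positions
# (excluding the starting point)
.fly_to <- function(from, to, speed, fps) {
  d <- sqrt(sum((to - from)^2))
  n <- max(1L, ceiling(d / (speed / fps)))
  cbind(from[1] + (to[1] - from[1]) * seq_len(n) / n,
        from[2] + (to[2] - from[2]) * seq_len(n) / n)
}

# cruise from `from` to `to`, detouring around every focal disc except the
# allowed target's so cruise legs never create unplanned fly-overs
.cruise_route <- function(from, to, speed, fps, lay, allow_id = NULL,
                          clearance = 0.02) {
  seg <- to - from
  len <- sqrt(sum(seg^2))
  if (len == 0) return(matrix(numeric(0), ncol = 2))
  u <- seg / len
  detours <- list()
  for (j in seq_len(nrow(lay))) {
    if (!is.null(allow_id) && lay$stimulus_id[j] == allow_id) next
    centre <- c(lay$x[j], lay$y[j])
    proj <- sum((centre - from) * u)
    if (proj <= 0 || proj >= len) next
    foot <- from + proj * u
    off <- centre - foot
    miss <- sqrt(sum(off^2))
    avoid_r <- lay$focal_radius[j] + clearance
    if (miss >= avoid_r) next
    # push the waypoint perpendicular, away from the disc centre
    perp <- if (miss > 1e-9) -off / miss else c(-u[2], u[1])
    detours[[length(detours) + 1L]] <-
      list(proj = proj, point = foot + perp * (avoid_r + 0.01))
  }
  if (length(detours) == 0) return(.fly_to(from, to, speed, fps))
  detours <- detours[order(vapply(detours, `[[`, numeric(1), "proj"))]
  legs <- list()
  pos <- from
  for (d in detours) {
    legs[[length(legs) + 1L]] <- .fly_to(pos, d$point, speed, fps)
    pos <- d$point
  }
  legs[[length(legs) + 1L]] <- .fly_to(pos, to, speed, fps)
  do.call(rbind, legs)
}

#' Generate a synthetic flight trajectory with planted choices
#'
#' Builds the piecewise path described by the spec's visit plan and returns
#' it with the planted accept/reject labels, enabling end-to-end validation
#' of the visit classifier.  A pure function of its seed.
#'
#' @param spec A [trajectory_spec()].
#' @param seed Integer seed.
#' @return List with `trajectory` (a [trajectory()] object) and `labels`
#'   (the visit plan with planted intents, in visit order).
#' @export
generate_trajectory <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  lay <- spec$layout
  pos <- spec$start
  path <- list(matrix(pos, ncol = 2))
  for (i in seq_len(nrow(spec$visit_plan))) {
    row <- spec$visit_plan[i, ]
    j <- match(row$stimulus_id, lay$stimulus_id)
    centre <- c(lay$x[j], lay$y[j])
    focal <- lay$focal_radius[j]
    dir <- centre - pos
    dir <- dir / sqrt(sum(dir^2))
    entry <- centre - dir * focal

    if (row$intent == "accept") {
      # cruise to the focal boundary, creep to the centre, hover, then leave
      leg1 <- .cruise_route(pos, entry, spec$cruise_speed, spec$fps,
                            lay, allow_id = row$stimulus_id)
      leg2 <- .fly_to(entry, centre, spec$dwell_speed, spec$fps)
      n_dwell <- max(1L, round(row$dwell * spec$fps))
      ang <- 2 * pi * seq_len(n_dwell) / n_dwell
      hover_r <- spec$dwell_speed / spec$fps * n_dwell / (2 * pi)
      hover_r <- min(hover_r, focal / 4)
      leg3 <- cbind(centre[1] + hover_r * cos(ang),
                    centre[2] + hover_r * sin(ang))
      exit <- centre + dir * (focal + 0.05)
      leg4 <- .cruise_route(leg3[nrow(leg3), ], exit, spec$cruise_speed,
                            spec$fps, lay, allow_id = row$stimulus_id)
      path <- c(path, list(leg1, leg2, leg3, leg4))
      pos <- exit
    } else {
      # fly straight through the focal area at cruise speed
      exit <- centre + dir * (focal + 0.05)
      leg <- .cruise_route(pos, entry, spec$cruise_speed, spec$fps,
                           lay, allow_id = row$stimulus_id)
      leg2 <- .fly_to(entry, exit, spec$cruise_speed, spec$fps)
      path <- c(path, list(leg, leg2))
      pos <- exit
    }
  }
  # cruise away to a neutral point so the last visit terminates cleanly
  away <- pmin(pmax(pos + c(0.1, 0.1), c(0.02, 0.02)),
               spec$arena - 0.02)
  path <- c(path, list(.cruise_route(pos, away, spec$cruise_speed, spec$fps,
                                     lay)))

  xy <- do.call(rbind, path)
  if (spec$noise_sd > 0) {
    xy <- xy + matrix(stats::rnorm(length(xy), sd = spec$noise_sd), ncol = 2)
  }
  xy[, 1] <- pmin(pmax(xy[, 1], 0), spec$arena[1])
  xy[, 2] <- pmin(pmax(xy[, 2], 0), spec$arena[2])
  tt <- (seq_len(nrow(xy)) - 1) / spec$fps
  list(trajectory = trajectory(tt, xy[, 1], xy[, 2], fps = spec$fps),
       labels = spec$visit_plan)
}
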