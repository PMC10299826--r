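# Flight-trajectory analysis: per-frame speeds, stimulus-visit segmentation
# within a fixed focal radius, an exact one-dimensional two-means flight
# speed threshold, and accept/reject classification of visits.

#' Construct a flight trajectory
#'
#' @param t Frame timestamps in seconds, strictly increasing and uniform.
#' @param x,y Planar positions in metres (arena coordinates).
#' @param orientation Optional body orientation in radians.
#' @param fps Frame rate; inferred from `t` when `NULL`.
#' @return An object of class `trajectory` (data frame with columns `frame`,
#'   `t`, `x`, `y` and optionally `orientation`; attribute `fps`).
#' @export
trajectory <- function(t, x, y, orientation = NULL, fps = NULL) {
  stopifnot(length(t) == length(x), length(x) == length(y))
  if (length(t) >= 2) {
    dtv <- diff(t)
    if (any(dtv <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
    if (diff(range(dtv)) > 1e-6) {
      stop("timestamps must be uniformly spaced", call. = FALSE)
    }
    if (is.null(fps)) fps <- 1 / stats::median(dtv)
  }
  out <- data.frame(frame = seq_along(t), t = t, x = x, y = y)
  if (!is.null(orientation)) out$orientation <- orientation
  structure(out, fps = fps, class = c("trajectory", "data.frame"))
}

#' Read a trajectory from delimited text
#'
#' Expects columns `t`, `x`, `y` (and optionally `orientation`); a `frame`
#' column is ignored and regenerated.
#'
#' @param file Path to a delimited text file.
#' @param fps Frame rate override; inferred from timestamps when `NULL`.
#' @param sep Field separator.
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(file, fps = NULL, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep)
  need <- c("t", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trajectory table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trajectory(df$t, df$x, df$y,
             orientation = if ("orientation" %in% names(df)) df$orientation,
             fps = fps)
}

#' Stimulus layout for visit segmentation
#'
#' @param stimulus_id Stimulus labels.
#' @param x,y Disc centres in metres.
#' @param radius Disc radii in metres (display only).
#' @param focal_radius Radius around each centre within which hovering and
#'   inspection are scored (default 0.05 m).
#' @return Data frame of class `stimulus_layout`.
#' @export
stimulus_layout <- function(stimulus_id, x, y, radius = 0.0125,
                            focal_radius = 0.05) {
  stopifnot(length(stimulus_id) == length(x), length(x) == length(y))
  structure(data.frame(stimulus_id = stimulus_id, x = x, y = y,
                       radius = radius, focal_radius = focal_radius,
                       stringsAsFactors = FALSE),
            class = c("stimulus_layout", "data.frame"))
}

#' Per-frame flight speeds
#'
#' Finite-difference speed between consecutive frames:
#' `speed[i] = dist(p[i+1], p[i]) * fps`, giving `n - 1` values for `n`
#' frames.
#'
#' @param traj A [trajectory()] object.
#' @return Numeric vector of speeds in m/s.
#' @export
traj_speeds <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) < 2) stop("need at least 2 frames to compute speeds", call. = FALSE)
  fps <- attr(traj, "fps")
  sqrt(diff(traj$x)^2 + diff(traj$y)^2) * fps
}

#' Segment a trajectory into stimulus visits
#'
#' Maximal runs of consecutive frames inside a stimulus's focal radius
#' become visit segments.  Segments shorter than `min_duration` whose first
#' and last frames both lie within `edge_margin` of the focal boundary are
#' marked `excluded` (brief grazes across the rim, e.g. high-speed
#' fly-overs clipping the focal area).
#'
#' @param traj A [trajectory()] object.
#' @param layout A [stimulus_layout()].
#' @param min_duration Seconds below which an edge-hugging segment is
#'   excluded (default 0.2).
#' @param edge_margin Distance from the focal boundary, in metres, within
#'   which a segment endpoint counts as "close to the edge" (default 0.01).
#' @return Data frame of class `visit_segments`: columns `stimulus_id`,
#'   `start_frame`, `end_frame`, `duration`, `hover_time`, `mean_speed`,
#'   `median_speed`, `excluded`.
#' @export
segment_visits <- function(traj, layout, min_duration = 0.2,
                           edge_margin = 0.01) {
  stopifnot(inherits(traj, "trajectory"), nrow(layout) > 0)
  fps <- attr(traj, "fps")
  speeds <- if (nrow(traj) >= 2) traj_speeds(traj) else numeric(0)

  segs <- list()
  for (j in seq_len(nrow(layout))) {
    dx <- traj$x - layout$x[j]
    dy <- traj$y - layout$y[j]
    dist <- sqrt(dx^2 + dy^2)
    inside <- dist <= layout$focal_radius[j]
    if (!any(inside)) next
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      s <- starts[r]; e <- ends[r]
      dur <- (e - s + 1L) / fps
      near_edge <- dist[s] >= layout$focal_radius[j] - edge_margin &&
        dist[e] >= layout$focal_radius[j] - edge_margin
      sp <- if (e > s) speeds[s:(e - 1L)] else numeric(0)
      segs[[length(segs) + 1L]] <- data.frame(
        stimulus_id = layout$stimulus_id[j],
        start_frame = s, end_frame = e,
        duration = dur, hover_time = dur,
        mean_speed = if (length(sp)) mean(sp) else NA_real_,
        median_speed = if (length(sp)) stats::median(sp) else NA_real_,
        excluded = (dur < min_duration && near_edge) || length(sp) == 0L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(segs) == 0) {
    out <- data.frame(stimulus_id = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration = numeric(0),
                      hover_time = numeric(0), mean_speed = numeric(0),
                      median_speed = numeric(0), excluded = logical(0))
  } else {
    out <- do.call(rbind, segs)
    out <- out[order(out$start_frame), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, fps = fps, class = c("visit_segments", "data.frame"))
}

#' Exact one-dimensional two-means threshold
#'
#' Splits speed samples into a low-speed (landing/inspection) and a
#' high-speed (fly-over) cluster by exact 1-D 2-means: every contiguous
#' split of the sorted samples is scored by within-cluster sum of squares
#' and the optimum taken, so the result is deterministic with no
#' initialisation sensitivity.  The classification threshold is the
#' midpoint of the two cluster means.
#'
#' @param speeds Numeric speed samples (at least two distinct values).
#' @return List with `threshold`, cluster means `low_mean`/`high_mean` and
#'   `wcss` (the minimised within-cluster sum of squares).
#' @examples
#' two_means_threshold(c(0.01, 0.02, 0.40, 0.45))$threshold  # 0.22
#' @export
two_means_threshold <- function(speeds) {
  x <- sort(as.numeric(speeds))
  n <- length(x)
  if (n < 2 || diff(range(x)) == 0) {
    stop("need at least two distinct speed values to cluster", call. = FALSE)
  }
  # prefix sums give each contiguous split's WCSS in O(1)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  i <- seq_len(n - 1L)
  lo_n <- i; hi_n <- n - i
  lo_sum <- cs[i]; hi_sum <- cs[n] - cs[i]
  lo_sq <- cs2[i]; hi_sq <- cs2[n] - cs2[i]
  wcss <- (lo_sq - lo_sum^2 / lo_n) + (hi_sq - hi_sum^2 / hi_n)
  best <- which.min(wcss)
  low_mean <- lo_sum[best] / lo_n[best]
  high_mean <- hi_sum[best] / hi_n[best]
  list(threshold = (low_mean + high_mean) / 2,
       low_mean = low_mean, high_mean = high_mean,
       wcss = wcss[best])
}

#' Classify visit segments as acceptances or rejections
#'
#' A non-excluded segment is an acceptance when its within-focal-area speed
#' statistic falls below the threshold (the low-speed landing cluster) and
#' a rejection otherwise.  Excluded segments keep their `excluded` label.
#'
#' @param segments A [segment_visits()] table.
#' @param threshold Speed threshold in m/s, typically from
#'   [two_means_threshold()] on the segments' speed statistics.
#' @param stat Segment statistic compared to the threshold: `"mean"`
#'   (default) or `"median"` within-border speed.
#' @return `segments` with a `classification` column
#'   (`"accept"`/`"reject"`/`"excluded"`).
#' @export
classify_visits <- function(segments, threshold, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(is.data.frame(segments))
  sp <- if (stat == "mean") segments$mean_speed else segments$median_speed
  segments$classification <- ifelse(segments$excluded, "excluded",
                                    ifelse(sp < threshold, "accept", "reject"))
  segments
}

#' Convert classified visits to choice events
#'
#' Bridges trajectory classification to the behavioural metrics: each
#' non-excluded visit becomes one choice event whose response time is the
#' hover (within-focal-area) time, categorised against the higher-rewarded
#' stimulus.
#'
#' @param segments A [classify_visits()] table.
#' @param high_stimulus Id of the higher-rewarded stimulus.
#' @param bee_id,test_id Labels attached to every event.
#' @return Data frame of categorised choice events; the number of excluded
#'   segments is attached as attribute `n_excluded`.
#' @export
visits_to_events <- function(segments, high_stimulus, bee_id = 1L,
                             test_id = "easy") {
  stopifnot(is.data.frame(segments), "classification" %in% names(segments))
  known <- unique(segments$stimulus_id)
  if (!high_stimulus %in% known && nrow(segments) > 0) {
    stop("high_stimulus '", high_stimulus, "' not among visited stimuli: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  keep <- segments$classification != "excluded"
  ev <- data.frame(
    bee_id = bee_id,
    test_id = test_id,
    stimulus_id = segments$stimulus_id[keep],
    response = segments$classification[keep],
    response_time = segments$hover_time[keep],
    stringsAsFactors = FALSE
  )
  ev <- categorise_events(ev, high_stimulus)
  attr(ev, "n_excluded") <- sum(!keep)
  ev
}
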