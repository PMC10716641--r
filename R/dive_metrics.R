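#' Segment dives from a depth series
#'
#' A dive is a maximal run of samples strictly deeper than the threshold
#' (default 3 m; samples at exactly the threshold are surface) containing at
#' least two samples. Adjacent dives are separated by at least one surface
#' sample by construction.
#'
#' @param series a `tag_series` (or data frame with `time_s`, `depth_m`).
#' @param threshold_m dive threshold in metres.
#' @return data frame of dive intervals: `start_s`, `end_s`, `max_depth_m`,
#'   `start_idx`, `end_idx` (sample indices), `dive_time_s`.
#' @export
segment_dives <- function(series, threshold_m = 3) {
  if (threshold_m <= 0) stop_invalid("threshold_m must be positive")
  tt <- series$time_s
  if (length(tt) > 2) {
    steps <- diff(tt)
    if (max(steps) - min(steps) > 1e-6 * max(steps)) {
      stop_invalid("depth series is not uniformly sampled; resample first")
    }
  }
  below <- series$depth_m > threshold_m
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  if (!any(keep)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      max_depth_m = numeric(0), start_idx = integer(0),
                      end_idx = integer(0), dive_time_s = numeric(0)))
  }
  s <- starts[keep]; e <- ends[keep]
  dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
  data.frame(start_s = tt[s], end_s = tt[e],
             max_depth_m = vapply(seq_along(s), function(i)
               max(series$depth_m[s[i]:e[i]]), numeric(1)),
             start_idx = s, end_idx = e,
             dive_time_s = (e - s + 1L) * dt)
}

#' Behavioural metrics for one segmented dive
#'
#' Dive phases follow the standard biologging convention: the bottom phase is
#' the set of samples deeper than `bottom_frac` (default 85%) of the dive's
#' maximum depth; descent runs from the dive start to the first bottom-phase
#' sample, ascent from the last bottom-phase sample to the dive end, and
#' bottom time is the span between them (zero when the bottom phase is a
#' single sample). Angular summaries are circular means over the descent and
#' ascent samples; turning rate is the wrapped heading difference per unit
#' time. Lunges and breaths are counted from the series' annotated event
#' streams. Category 3 (horizontal) metrics need a source track.
#'
#' @param series a `tag_series`.
#' @param dive one row of [segment_dives()] output.
#' @param category `"dive"`, `"angular"` or `"horizontal"`.
#' @param source_track data frame with `time_s`, `x_m`, `y_m` of the sound
#'   source (category 3 only); the whale's horizontal track is dead-reckoned
#'   from heading and speed.
#' @param bottom_frac bottom-phase depth fraction.
#' @return named list of the category's metrics.
#' @export
compute_metrics <- function(series, dive,
                            category = c("dive", "angular", "horizontal"),
                            source_track = NULL, bottom_frac = 0.85) {
  category <- match.arg(category)
  hz <- attr(series, "sampling_hz") %||%
    (1 / (series$time_s[2] - series$time_s[1]))
  idx <- dive$start_idx:dive$end_idx
  dsub <- series$depth_m[idx]
  md <- max(dsub)
  bphase <- which(dsub > bottom_frac * md)
  fb <- min(bphase); lb <- max(bphase)
  desc_idx <- idx[seq_len(fb)]
  asc_idx <- idx[lb:length(idx)]
  dt <- 1 / hz
  if (category == "dive") {
    ev <- attr(series, "events") %||% list(lunge_times = numeric(0),
                                           breath_times = numeric(0))
    t0 <- series$time_s[dive$start_idx]; t1 <- series$time_s[dive$end_idx]
    post <- post_surface_time(series, dive)
    return(list(dive_time_s = dive$dive_time_s, max_depth_m = md,
                post_surface_s = post,
                descent_s = (fb - 1) * dt, ascent_s = (length(idx) - lb) * dt,
                bottom_s = (lb - fb) * dt,
                lunges = sum(ev$lunge_times >= t0 & ev$lunge_times <= t1),
                breaths = sum(ev$breath_times > t1 &
                                ev$breath_times < t1 + post + dt)))
  }
  if (category == "angular") {
    if (is.null(series$pitch_rad) || is.null(series$heading_rad)) {
      stop_invalid("angular metrics need pitch/roll/heading channels")
    }
    ang <- function(ix, ch) circular_mean(series[[ch]][ix])
    chg <- function(ix, ch) wrap_angle(series[[ch]][ix[length(ix)]] - series[[ch]][ix[1]])
    return(list(
      descent_pitch = ang(desc_idx, "pitch_rad"),
      descent_roll = ang(desc_idx, "roll_rad"),
      descent_heading = ang(desc_idx, "heading_rad"),
      d_descent_pitch = chg(desc_idx, "pitch_rad"),
      d_descent_roll = chg(desc_idx, "roll_rad"),
      d_descent_heading = chg(desc_idx, "heading_rad"),
      ascent_pitch = ang(asc_idx, "pitch_rad"),
      ascent_roll = ang(asc_idx, "roll_rad"),
      ascent_heading = ang(asc_idx, "heading_rad"),
      d_ascent_pitch = chg(asc_idx, "pitch_rad"),
      d_ascent_roll = chg(asc_idx, "roll_rad"),
      d_ascent_heading = chg(asc_idx, "heading_rad")))
  }
  # horizontal: dead-reckoned track from heading/speed (clockwise from north)
  hx <- cumsum(c(0, sin(series$heading_rad) * series$speed_ms * dt)[seq_len(nrow(series))])
  hy <- cumsum(c(0, cos(series$heading_rad) * series$speed_ms * dt)[seq_len(nrow(series))])
  hspeed <- mean(series$speed_ms[idx])
  surf <- which(series$depth_m <= 3)
  sspeed <- if (length(surf)) mean(series$speed_ms[surf]) else NA_real_
  dh <- wrap_angle(diff(series$heading_rad[idx]))
  turn_rate <- if (length(dh)) mean(dh) / dt else 0
  out <- list(horizontal_speed_ms = hspeed, surface_speed_ms = sspeed,
              turning_rate_rad_s = turn_rate)
  if (!is.null(source_track)) {
    src_at <- function(t) {
      i <- which.min(abs(source_track$time_s - t))
      c(source_track$x_m[i], source_track$y_m[i])
    }
    p0 <- c(hx[dive$start_idx], hy[dive$start_idx])
    p1 <- c(hx[dive$end_idx], hy[dive$end_idx])
    d0 <- sqrt(sum((p0 - src_at(series$time_s[dive$start_idx]))^2))
    d1 <- sqrt(sum((p1 - src_at(series$time_s[dive$end_idx]))^2))
    out <- c(out, list(dist_start_m = d0, dist_end_m = d1,
                       d_dist_m = d1 - d0))
  }
  out
}

post_surface_time <- function(series, dive) {
  after <- series$depth_m[-seq_len(dive$end_idx)]
  nxt <- which(after > 3)[1]
  dt <- series$time_s[2] - series$time_s[1]
  if (is.na(nxt)) (length(after)) * dt else (nxt - 1) * dt
}

#' Metric table for all dives of a tag series
#'
#' Runs [segment_dives()] and [compute_metrics()] for every dive and category
#' and returns one row per dive with `c1_` / `c2_` / `c3_` column prefixes.
#'
#' @inheritParams compute_metrics
#' @param threshold_m dive threshold.
#' @return data frame, one row per dive.
#' @export
dive_metric_table <- function(series, threshold_m = 3, source_track = NULL,
                              bottom_frac = 0.85) {
  dv <- segment_dives(series, threshold_m)
  if (nrow(dv) == 0) return(data.frame())
  rows <- lapply(seq_len(nrow(dv)), function(i) {
    d <- dv[i, ]
    c1 <- compute_metrics(series, d, "dive", bottom_frac = bottom_frac)
    c2 <- compute_metrics(series, d, "angular", bottom_frac = bottom_frac)
    c3 <- compute_metrics(series, d, "horizontal", source_track = source_track,
                          bottom_frac = bottom_frac)
    as.data.frame(c(setNames(c1, paste0("c1_", names(c1))),
                    setNames(c2, paste0("c2_", names(c2))),
                    setNames(c3, paste0("c3_", names(c3)))))
  })
  cbind(dv[, c("start_s", "end_s")], do.call(rbind, rows))
}

#' Attach per-dive exposure covariates
#'
#' For each dive, `max_rl` is the maximum and `avg_rl` the arithmetic mean of
#' the received levels (dB) of the pings whose transmission time falls within
#' the dive; both are exactly 0 when no ping overlaps the dive ("0 when there
#' is no exposure"). `csel` is the cumulative sound exposure level at the
#' last ping at or before the dive's end (0 before any ping). The CEE phase
#' is assigned from the schedule's phase bounds using the dive's start time;
#' a dive spanning a phase boundary therefore belongs to the phase containing
#' its start.
#'
#' @param dives data frame of dives with `start_s`, `end_s` (times on the
#'   schedule's clock, exposure start = 0), plus any behavioural columns.
#' @param exposure a [received_levels()] object (may be `NULL` for controls).
#' @param schedule the [make_cee_schedule()] object.
#' @return `dives` with added columns `max_rl`, `avg_rl`, `min_rl`, `csel`,
#'   `exposure` (0/1 flag) and `phase` (before/during/after).
#' @export
attach_exposure <- function(dives, exposure, schedule) {
  pb <- schedule$phase_bounds
  n <- nrow(dives)
  out <- dives
  out$max_rl <- out$avg_rl <- out$min_rl <- out$csel <- numeric(n)
  out$exposure <- integer(n)
  out$phase <- cut(dives$start_s, c(-Inf, pb["exposure"], pb["post"], Inf),
                   labels = c("before", "during", "after"), right = FALSE)
  pt <- schedule$ping_times
  if (length(pt) && !is.null(exposure)) {
    for (i in seq_len(n)) {
      sel <- pt >= dives$start_s[i] & pt <= dives$end_s[i]
      if (any(sel)) {
        out$max_rl[i] <- max(exposure$per_ping_rl[sel])
        out$avg_rl[i] <- mean(exposure$per_ping_rl[sel])
        out$min_rl[i] <- min(exposure$per_ping_rl[sel])
        out$exposure[i] <- 1L
      }
      past <- which(pt <= dives$end_s[i])
      if (length(past)) out$csel[i] <- exposure$cumulative_sel[max(past)]
    }
  }
  out$phase <- as.character(out$phase)
  out
}
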