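test_that("dive segmentation follows the strict 3 m convention", {
  mk <- function(depths) data.frame(time_s = seq_along(depths) - 1,
                                    depth_m = depths)
  # hand-counted example: two runs of >3 m, 3 samples each
  dv <- segment_dives(mk(c(0, 0, 10, 40, 10, 0, 0, 5, 20, 5, 0)))
  expect_equal(nrow(dv), 2)
  expect_equal(dv$dive_time_s, c(3, 3))
  expect_equal(dv$max_depth_m, c(40, 20))
  # never below threshold
  expect_equal(nrow(segment_dives(mk(rep(0, 50)))), 0)
  # an excursion exactly to 3.0 m is surface (strict inequality)
  expect_equal(nrow(segment_dives(mk(c(0, 3, 3, 3, 0)))), 0)
  # single-sample spikes are not dives
  expect_equal(nrow(segment_dives(mk(c(0, 10, 0, 10, 0)))), 0)
  # non-uniform sampling is refused
  bad <- data.frame(time_s = c(0, 1, 3, 4), depth_m = c(0, 10, 10, 0))
  expect_error(segment_dives(bad), "uniform")
})

test_that("dive-phase metrics split descent, bottom and ascent correctly", {
  # symmetric V-dive, 300 s, apex the only sample above 85% of max depth
  up <- seq(4, 84, length.out = 150)
  depths <- c(0, up, 100, rev(up), 0)
  ts <- structure(data.frame(time_s = seq_along(depths) - 1, depth_m = depths,
                             pitch_rad = 0, roll_rad = 0, heading_rad = 0.7,
                             speed_ms = 2),
                  sampling_hz = 1, class = c("tag_series", "data.frame"))
  dv <- segment_dives(ts)
  expect_equal(nrow(dv), 1)
  m <- compute_metrics(ts, dv[1, ], "dive")
  expect_equal(m$descent_s, 150)
  expect_equal(m$ascent_s, 150)
  expect_equal(m$bottom_s, 0)
  expect_equal(m$max_depth_m, 100)
  # constant heading: zero turning rate and zero change in heading
  a <- compute_metrics(ts, dv[1, ], "angular")
  h <- compute_metrics(ts, dv[1, ], "horizontal")
  expect_equal(h$turning_rate_rad_s, 0)
  expect_equal(a$d_descent_heading, 0)
  expect_equal(a$descent_heading, 0.7)
})

test_that("angular summaries are circular means", {
  pitch <- c(-0.5, -0.6, -0.4, -0.55, 3.0, -0.1, 0.5, 0.45, 0.6, 0.5)
  depths <- c(4, 30, 60, 85, 100, 100, 85, 60, 30, 4)
  ts <- structure(data.frame(time_s = 0:9, depth_m = depths,
                             pitch_rad = pitch, roll_rad = 0,
                             heading_rad = seq(0, 0.9, by = 0.1), speed_ms = 1),
                  sampling_hz = 1, class = c("tag_series", "data.frame"))
  dv <- segment_dives(ts)
  m <- compute_metrics(ts, dv[1, ], "angular")
  # bottom phase: samples deeper than 85 m (indices 5, 6); descent = 1..5
  oracle <- atan2(sum(sin(pitch[1:5])), sum(cos(pitch[1:5])))
  expect_equal(m$descent_pitch, oracle, tolerance = 1e-12)
  oracle_asc <- atan2(sum(sin(pitch[6:10])), sum(cos(pitch[6:10])))
  expect_equal(m$ascent_pitch, oracle_asc, tolerance = 1e-12)
  ts$pitch_rad <- NULL
  expect_error(compute_metrics(ts, dv[1, ], "angular"), "channel")
})

test_that("metrics are invariant to surface padding", {
  d <- data.frame(dive_time = c(200, 300), max_depth = c(50, 120),
                  lunges = c(2, 4), speed = c(1.5, 1.2), angle = c(0.3, -0.2))
  ts <- render_depth_series(d, sampling_hz = 1)
  pad <- data.frame(time_s = 0, depth_m = 0, pitch_rad = 0, roll_rad = 0,
                    heading_rad = 0, speed_ms = 1)
  padded <- rbind(pad[rep(1, 40), ], as.data.frame(ts), pad[rep(1, 40), ])
  padded$time_s <- seq_len(nrow(padded)) - 1
  padded <- structure(padded, sampling_hz = 1, events = attr(ts, "events"),
                      class = c("tag_series", "data.frame"))
  # re-point events at the padded clock
  ev <- attr(ts, "events"); ev$lunge_times <- ev$lunge_times + 40
  attr(padded, "events") <- ev
  dv0 <- segment_dives(ts); dv1 <- segment_dives(padded)
  expect_equal(nrow(dv0), nrow(dv1))
  m0 <- compute_metrics(ts, dv0[1, ], "dive")
  m1 <- compute_metrics(padded, dv1[1, ], "dive")
  for (f in c("dive_time_s", "max_depth_m", "descent_s", "ascent_s",
              "bottom_s", "lunges")) {
    expect_equal(m0[[f]], m1[[f]], info = f)
  }
})

test_that("render -> segment round trip recovers the dive sequence", {
  spec <- hmm_spec(3, 1)
  p <- default_hmm_params(spec)
  sim <- simulate_dives(p, spec, 1, 20, seed = 21)
  d <- sim$data
  d <- d[d$max_depth > 4 & d$dive_time > 10, ]
  ts <- render_depth_series(d, sampling_hz = 1)
  dv <- segment_dives(ts)
  expect_equal(nrow(dv), nrow(d))
  expect_true(all(abs(dv$dive_time_s - round(d$dive_time)) <= 1.5))
  expect_true(all(abs(dv$max_depth_m - d$max_depth) <= 1))
  # lunge counts survive the rendering
  tab <- dive_metric_table(ts)
  expect_equal(sum(tab$c1_lunges), sum(d$lunges))
  # empty input renders an all-surface series
  empty <- render_depth_series(d[0, ])
  expect_equal(nrow(segment_dives(empty)), 0)
  # resolution guard
  expect_error(render_depth_series(data.frame(dive_time = 1, max_depth = 50),
                                   sampling_hz = 1), "2 samples")
})

test_that("exposure covariates attach with the stated zero convention", {
  sched <- make_cee_schedule("MFAS")
  expo <- received_levels(sched, range_m = 1000)
  dives <- data.frame(start_s = c(-900, 10, 500, 2000),
                      end_s = c(-700, 60, 560, 2200))
  out <- attach_exposure(dives, expo, sched)
  expect_equal(out$phase, c("before", "during", "during", "after"))
  # pre-exposure dive: all-zero covariates
  expect_equal(out$max_rl[1], 0)
  expect_equal(out$avg_rl[1], 0)
  expect_equal(out$exposure[1], 0L)
  # dive covering pings at t = 25, 50 (SL 163, 166; RL = SL - 60)
  expect_equal(out$max_rl[2], 106)
  expect_equal(out$avg_rl[2], 104.5)
  expect_equal(out$exposure[2], 1L)
  # hand mean of two dB values
  two <- attach_exposure(data.frame(start_s = 24, end_s = 51),
                         structure(list(per_ping_rl = c(120, 126),
                                        per_ping_sel = c(120, 126),
                                        cumulative_sel = c(120, 127),
                                        ping_times = c(25, 50)),
                                   class = "received_exposure"),
                         structure(list(ping_times = c(25, 50),
                                        phase_bounds = sched$phase_bounds),
                                   class = "cee_schedule"))
  expect_equal(two$max_rl, 126)
  expect_equal(two$avg_rl, 123)
  # control CEE: no pings anywhere
  ctrl <- make_cee_schedule("CONTROL")
  out2 <- attach_exposure(dives, NULL, ctrl)
  expect_true(all(out2$exposure == 0))
  expect_true(all(out2$max_rl == 0))
})
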