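# Savitzky-Golay kinematics and the saccade/fixation detector.

make_trace <- function(x, y = NULL, fs = 2000, onset = 0) {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  gaze_trace((seq_len(n) - 1) / fs, x, y, sampling_rate = fs,
             stimulus_onset = onset)
}

test_that("kinematics are exact on constant, linear and quadratic signals", {
  fs <- 2000
  t <- (0:(2 * fs)) / fs

  k0 <- estimate_kinematics(make_trace(rep(3, length(t)), fs = fs))
  expect_equal(max(abs(k0$speed[k0$valid])), 0, tolerance = 1e-9)
  expect_equal(max(abs(k0$acc[k0$valid])), 0, tolerance = 1e-7)

  k1 <- estimate_kinematics(make_trace(10 * t, fs = fs))
  expect_equal(range(k1$speed[k1$valid]), c(10, 10), tolerance = 1e-6)

  a <- 7
  k2 <- estimate_kinematics(make_trace(a * t^2, fs = fs))
  expect_equal(range(k2$acc[k2$valid]), c(2 * a, 2 * a), tolerance = 1e-4)
  # agreement with central finite differences on the interior
  fd <- diff(diff(a * t^2)) * fs^2
  expect_equal(median(k2$acc[k2$valid]), median(fd), tolerance = 1e-4)
})

test_that("the filter window is scaled to an odd sample count", {
  expect_equal(gazemodes:::sg_window_samples(0.010, 20000), 199L)
  expect_equal(gazemodes:::sg_window_samples(0.010, 2000), 19L)
  expect_equal(gazemodes:::sg_window_samples(0.010, 1000), 9L)
})

test_that("short traces and mismatched grids are rejected", {
  tr <- make_trace(rep(0, 10), fs = 2000)
  expect_error(estimate_kinematics(tr), "shorter than")
  tr2 <- make_trace(rep(0, 100), fs = 2000)
  kin <- estimate_kinematics(tr2)
  expect_error(detect_saccades(kin[-1, ], tr2), "sample grid")
})

test_that("a rendered saccade is detected once with accurate amplitude", {
  trace <- render_gaze_trace(step_truth(3),
                             render_config(sampling_rate = 2000,
                                           position_noise_sd = 0))
  ev <- detect_events(trace)
  expect_equal(nrow(ev$saccades), 1L)
  expect_lt(abs(ev$saccades$amplitude - 3), 0.05)
})

test_that("artifact rules reject transients, jitter and ballistic spikes", {
  fs <- 2000
  n <- fs  # 1 s
  t <- (seq_len(n) - 1) / fs

  # 3 ms supra-threshold transient: duration below the 5 ms minimum.
  # Synthetic kinematics pin the run length exactly.
  trace <- make_trace(rep(0, n), fs = fs)
  kin <- data.frame(t = t, speed = 0, acc = 0, valid = TRUE)
  run <- t >= 0.500 & t < 0.503
  kin$speed[run] <- 200
  kin$acc[run] <- 20000
  trace$x[run] <- seq(0, 0.5, length.out = sum(run))
  expect_equal(nrow(detect_saccades(kin, trace)), 0L)
  # the same run stretched to 10 ms is kept
  run2 <- t >= 0.500 & t < 0.510
  kin2 <- data.frame(t = t, speed = 0, acc = 0, valid = TRUE)
  kin2$speed[run2] <- 200
  kin2$acc[run2] <- 20000
  trace2 <- make_trace(rep(0, n), fs = fs)
  trace2$x[run2] <- seq(0, 0.5, length.out = sum(run2))
  trace2$x[t >= 0.510] <- 0.5
  expect_equal(nrow(detect_saccades(kin2, trace2)), 1L)

  # fast oscillatory jitter with < 0.1 deg displacement
  x2 <- 0.03 * sin(2 * pi * 250 * t) * (t > 0.4 & t < 0.44)
  ev2 <- detect_events(make_trace(x2, fs = fs))
  expect_equal(nrow(ev2$saccades), 0L)

  # implausible peak velocity (> 1500 deg/s): 12-deg jump in 6 ms
  x3 <- rep(0, n)
  i0 <- 1000
  len3 <- round(0.006 * fs)
  u <- seq(0, 1, length.out = len3 + 1)
  x3[i0:(i0 + len3)] <- 12 * (u - sin(2 * pi * u) / (2 * pi))
  x3[(i0 + len3 + 1):n] <- 12
  kin3 <- estimate_kinematics(make_trace(x3, fs = fs))
  expect_gt(max(kin3$speed), 1500)
  ev3 <- detect_events(make_trace(x3, fs = fs))
  expect_equal(nrow(ev3$saccades), 0L)
})

test_that("detection recall and precision are perfect over the amplitude
           sweep on noise-free renders", {
  amps <- c(0.5, 0.7, 1, 2, 3, 5, 8, 12, 15)
  trace <- render_gaze_trace(step_truth(amps),
                             render_config(sampling_rate = 2000,
                                           position_noise_sd = 0))
  ev <- detect_events(trace)
  expect_equal(nrow(ev$saccades), length(amps))
  expect_true(all(abs(ev$saccades$amplitude - amps) < 0.05))
  # alternating, non-overlapping event stream
  events <- rbind(data.frame(on = ev$saccades$onset,
                             off = ev$saccades$offset, type = "s"),
                  data.frame(on = ev$fixations$onset,
                             off = ev$fixations$offset, type = "f"))
  events <- events[order(events$on), ]
  expect_true(all(diff(events$on) > 0))
  expect_true(all(events$off[-nrow(events)] <= events$on[-1] + 1e-9))
  expect_true(all(events$type[-1] != events$type[-nrow(events)]))
})

test_that("gaussian position noise of sd 0.02 does not change the count", {
  amps <- c(1, 3, 6, 10)
  truth <- step_truth(amps)
  clean <- render_gaze_trace(truth, render_config(sampling_rate = 2000,
                                                  position_noise_sd = 0))
  noisy <- render_gaze_trace(truth, render_config(sampling_rate = 2000,
                                                  position_noise_sd = 0.02),
                             seed = 5)
  expect_equal(nrow(detect_events(noisy)$saccades),
               nrow(detect_events(clean)$saccades))
})

test_that("fixation extraction applies the drift rule and the exclusion
           window", {
  # two saccades separated by a 300 ms stationary epoch
  truth <- step_truth(c(3, 3), dur = 0.3)
  trace <- render_gaze_trace(truth, render_config(sampling_rate = 2000,
                                                  position_noise_sd = 0))
  ev <- detect_events(trace)
  interior <- ev$fixations[ev$fixations$onset > 0.65 &
                             ev$fixations$offset < 1.2, ]
  expect_equal(nrow(interior), 1L)
  expect_equal(interior$duration, 0.3, tolerance = 0.02)

  # slow 1.5-deg drift between saccades: no fixation for that interval
  fs <- 2000
  t <- (0:(3 * fs - 1)) / fs
  x <- numeric(length(t))
  seg <- function(t0, t1) t >= t0 & t < t1
  sacc <- function(t0, d, a0, a1) {
    tau <- (t[seg(t0, t0 + d)] - t0) / d
    a0 + (a1 - a0) * (tau - sin(2 * pi * tau) / (2 * pi))
  }
  x[seg(0, 1)] <- 0
  x[seg(1, 1.02)] <- sacc(1, 0.02, 0, 4)
  drift_sel <- seg(1.02, 1.52)
  x[drift_sel] <- 4 + seq(0, 1.5, length.out = sum(drift_sel))  # 3 deg/s
  x[seg(1.52, 1.54)] <- sacc(1.52, 0.02, 5.5, 9.5)
  x[t >= 1.54] <- 9.5
  ev2 <- detect_events(make_trace(x, fs = fs))
  expect_equal(nrow(ev2$saccades), 2L)
  drift_fix <- ev2$fixations[ev2$fixations$onset > 0.9 &
                               ev2$fixations$offset < 1.6, ]
  expect_equal(nrow(drift_fix), 0L)

  # saccade onset 100 ms after stimulus onset is discarded
  truth3 <- step_truth(3, dur = 0.25)
  trace3 <- render_gaze_trace(truth3,
                              render_config(sampling_rate = 2000,
                                            position_noise_sd = 0,
                                            pre_stimulus_fixation = 0.5))
  # place stimulus onset 150 ms before the saccade (at 0.75 s - 0.10 s)
  attr(trace3, "stimulus_onset") <- 0.65
  ev3 <- detect_events(trace3)
  expect_equal(nrow(ev3$saccades), 0L)
  # with the true onset the same saccade survives
  attr(trace3, "stimulus_onset") <- 0.5
  expect_equal(nrow(detect_events(trace3)$saccades), 1L)
})

test_that("overlapping saccade tables are a structural error", {
  trace <- render_gaze_trace(step_truth(3),
                             render_config(sampling_rate = 1000))
  bad <- data.frame(onset = c(0.1, 0.15), offset = c(0.2, 0.25))
  expect_error(extract_fixations(bad, trace), "overlapping")
})
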