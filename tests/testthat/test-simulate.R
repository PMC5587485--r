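test_that("flight-type counts follow the mix at the field-study scale", {
  cfg <- simConfig(pass_rate = 784, night_duration = 3600, seed = 101)
  set.seed(cfg@seed)
  passes <- simulateFlightPaths(cfg,
                                start_times = sort(runif(784, 0, 3600)))
  counts <- table(factor(vapply(passes, trajectoryType, ""),
                         levels = c("straight", "curved", "erratic")))
  expected <- c(416, 290, 78)
  sds <- sqrt(784 * c(0.53, 0.37, 0.10) * (1 - c(0.53, 0.37, 0.10)))
  expect_true(all(abs(as.numeric(counts) - expected) <= 3 * sds))
})

test_that("a degenerate flight mix yields a single type", {
  cfg <- simConfig(flight_mix = c(1, 0, 0), seed = 1)
  set.seed(1)
  passes <- simulateFlightPaths(cfg, start_times = seq(0, 90, by = 10))
  expect_true(all(vapply(passes, trajectoryType, "") == "straight"))
})

test_that("the same seed reproduces byte-identical waypoints", {
  cfg <- simConfig(seed = 77, pass_rate = 30, night_duration = 3600)
  s1 <- simulateNight(cfg)
  s2 <- simulateNight(cfg)
  expect_identical(lapply(s1$passes, waypoints),
                   lapply(s2$passes, waypoints))
  expect_identical(s1$recorded, s2$recorded)
})

test_that("waypoint times increase and speeds respect the limit", {
  cfg <- simConfig(seed = 5)
  set.seed(5)
  passes <- simulateFlightPaths(cfg, start_times = seq(0, 190, by = 10))
  for (p in passes) {
    w <- waypoints(p)
    expect_true(all(diff(w$t) > 0))
    step <- sqrt(diff(w$x)^2 + diff(w$y)^2 + diff(w$z)^2)
    expect_lte(max(step / diff(w$t)), 12 + 1e-6)
  }
})

test_that("erratic trajectories contain >= 2 large heading reversals", {
  cfg <- simConfig(flight_mix = c(0, 0, 1), seed = 9)
  set.seed(9)
  passes <- simulateFlightPaths(cfg, start_times = seq(0, 90, by = 10))
  for (p in passes) {
    w <- waypoints(p)
    head <- atan2(diff(w$y), diff(w$x))
    turns <- echoSync:::wrapAngle(diff(head)) * 180 / pi
    expect_gte(echoSync:::countReversals(turns, 45), 2)
  }
})

test_that("silent passes emit nothing and p_silent = 1 silences the night",
{
  cfg <- simConfig(p_silent = 1, seed = 3)
  sim <- simulateNight(cfg, start_times = seq(0, 900, by = 100))
  expect_equal(nrow(truthPulses(sim$truth)), 0)
  expect_true(all(truthPasses(sim$truth)$silent))
  expect_equal(nrow(sim$recorded), 0)
})

test_that("emitted call parameters reproduce the call-structure model", {
  set.seed(42)
  cfg <- simConfig(p_silent = 0, seed = 42)
  passes <- withr::with_seed(42,
    simulateFlightPaths(cfg, start_times = seq(0, 7990, by = 10)))
  truth <- withr::with_seed(43,
    simulateCallEmissions(passes, callModel(buzz_probability = 0,
                                            social_probability = 0), 0))
  q <- truthPulses(truth)
  expect_gte(nrow(q), 584)
  # within-bout interpulse intervals, per pass
  ipis <- unlist(lapply(split(q$onset, q$pass_id), function(on) {
    d <- diff(sort(on)) * 1000
    d[d < 1000]          # successive pulses of one bout
  }))
  expect_lt(abs(mean(ipis) - 217) / 217, 0.05)
  expect_lt(abs(mean(q$fpeak_khz) - 29.3) / 29.3, 0.02)
  expect_true(all(q$fmin_khz <= q$fpeak_khz & q$fpeak_khz <= q$fmax_khz))
})

test_that("the acoustic channel applies the transmission-loss formula", {
  w <- data.frame(t = c(0, 1), x = c(0, 0), y = c(1, 1 + 1e-6),
                  z = c(0, 0))
  # pulse emitted at 1 m, heading straight at the microphone
  p <- new("BatPass", pass_id = 1L, trajectory_type = "straight",
           waypoints = data.frame(t = c(0, 1), x = 0:1 * 0, y = c(1, 0.9),
                                  z = c(0, 0)), speed = 1)
  truth <- new("GroundTruthLog",
               passes = data.frame(pass_id = 1L, trajectory_type = "straight",
                                   silent = FALSE, t_start = 0, t_end = 1,
                                   min_distance_m = 1),
               pulses = data.frame(onset = 0, duration_ms = 7,
                                   fmin_khz = 26, fmax_khz = 36,
                                   fpeak_khz = 29, kind = "search",
                                   pass_id = 1L))
  out <- applyAcousticChannel(truth, list(p), micModel(noise_floor = 30),
                              atmosphereModel(alpha = 0),
                              source_level = 110)
  q <- truthPulses(out)
  # d = 1 m, on-axis, alpha = 0: zero transmission loss
  expect_equal(q$received_level_db, 110, tolerance = 1e-6)

  # d = 10 m, alpha = 0.3: spherical spreading 20 dB + absorption 3 dB
  p10 <- new("BatPass", pass_id = 1L, trajectory_type = "straight",
             waypoints = data.frame(t = c(0, 1), x = c(0, 0),
                                    y = c(10, 9.9), z = c(0, 0)),
             speed = 1)
  out10 <- applyAcousticChannel(truth, list(p10),
                                micModel(noise_floor = 30),
                                atmosphereModel(alpha = 0.3), 110)
  expect_equal(truthPulses(out10)$received_level_db, 110 - 23,
               tolerance = 1e-6)
})

test_that("a pulse 0.1 dB under the trigger threshold is not recorded", {
  # received level 47.9 dB over a 30 dB noise floor -> SNR 17.9 < 18
  p <- new("BatPass", pass_id = 1L, trajectory_type = "straight",
           waypoints = data.frame(t = c(0, 1), x = c(0, 0),
                                  y = c(10, 9.9), z = c(0, 0)), speed = 1)
  truth <- new("GroundTruthLog",
               passes = data.frame(pass_id = 1L, trajectory_type = "straight",
                                   silent = FALSE, t_start = 0, t_end = 1,
                                   min_distance_m = 10),
               pulses = data.frame(onset = 0, duration_ms = 7,
                                   fmin_khz = 26, fmax_khz = 36,
                                   fpeak_khz = 29, kind = "search",
                                   pass_id = 1L))
  out <- applyAcousticChannel(truth, list(p), micModel(noise_floor = 30),
                              atmosphereModel(alpha = 0),
                              source_level = 30 + 17.9 + 20)
  q <- truthPulses(out)
  expect_equal(q$received_snr_db, 17.9, tolerance = 1e-6)
  expect_false(q$recorded)
  # raising the source by 0.2 dB crosses the trigger
  out2 <- applyAcousticChannel(truth, list(p), micModel(noise_floor = 30),
                               atmosphereModel(alpha = 0),
                               source_level = 30 + 18.1 + 20)
  expect_true(truthPulses(out2)$recorded)
})

test_that("received SNR is monotone non-increasing in distance", {
  mkpass <- function(d) new("BatPass", pass_id = 1L,
    trajectory_type = "straight",
    waypoints = data.frame(t = c(0, 1), x = c(0, 0), y = c(d, d - 0.1),
                           z = c(0, 0)), speed = 1)
  truth <- new("GroundTruthLog",
               passes = data.frame(pass_id = 1L, trajectory_type = "straight",
                                   silent = FALSE, t_start = 0, t_end = 1,
                                   min_distance_m = 1),
               pulses = data.frame(onset = 0, duration_ms = 7,
                                   fmin_khz = 26, fmax_khz = 36,
                                   fpeak_khz = 29, kind = "search",
                                   pass_id = 1L))
  snr <- vapply(c(1, 2, 5, 10, 20, 40, 80), function(d) {
    truthPulses(applyAcousticChannel(truth, list(mkpass(d)),
                                     micModel(), atmosphereModel(0.3),
                                     110))$received_snr_db
  }, 0)
  expect_true(all(diff(snr) < 0))
})

test_that("every recorded pulse traces to exactly one logged pass", {
  cfg <- simConfig(p_silent = 0.3, seed = 8, pass_rate = 40,
                   night_duration = 3600)
  sim <- simulateNight(cfg)
  q <- truthPulses(sim$truth)
  expect_true(all(q$pass_id %in% truthPasses(sim$truth)$pass_id))
  expect_equal(nrow(sim$recorded), sum(q$recorded))
  # and recorded pulses never come from silent passes
  sil <- truthPasses(sim$truth)$pass_id[truthPasses(sim$truth)$silent]
  expect_false(any(q$pass_id[q$recorded] %in% sil))
})
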