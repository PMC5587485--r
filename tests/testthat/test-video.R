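test_that("frame subsampling keeps every step-th frame with its timestamp",
{
  cam <- cameraModel(width_px = 8, height_px = 6)
  frames <- replicate(300, matrix(0, 6, 8), simplify = FALSE)
  fs <- FrameSequence(frames, (0:299) / 30, cam)
  sub <- subsampleFrames(fs, 10)
  expect_equal(nFrames(sub), 30)
  expect_equal(frameTimes(sub), (seq(0, 290, by = 10)) / 30)

  nine <- subsampleFrames(FrameSequence(frames[1:9], (0:8) / 30, cam), 10)
  expect_equal(nFrames(nine), 1)
  expect_equal(frameTimes(nine), 0)

  empty <- subsampleFrames(FrameSequence(list(), numeric(0), cam), 10)
  expect_equal(nFrames(empty), 0)
})

test_that("the size filter is absolute: sub-5-px components are dropped", {
  bg <- flatBackground()
  fr <- bg$median
  fr[10:11, 10:11] <- 1          # 4-pixel cluster
  expect_equal(nrow(detectBlobs(fr, bg)), 0)
  # a uniform frame equal to background has no blobs at all
  expect_equal(nrow(detectBlobs(bg$median, bg)), 0)
  # 5 contiguous pixels pass
  fr[10, 12] <- 1
  b <- detectBlobs(fr, bg)
  expect_equal(nrow(b), 1)
  expect_equal(b$area_px, 5)
})

test_that("disjoint bright squares are separate blobs with true centroids",
{
  bg <- flatBackground()
  fr <- bg$median
  fr[10:12, 10:12] <- 1
  fr[30:32, 40:42] <- 1
  b <- detectBlobs(fr, bg)
  expect_equal(nrow(b), 2)
  got <- b[order(b$row), ]
  expect_equal(got$row, c(10, 30))   # 0-based centres of 10:12 / 30:32
  expect_equal(got$col, c(10, 40))
})

test_that("diagonal contact joins pixels (8-connectivity)", {
  bg <- flatBackground()
  fr <- bg$median
  fr[cbind(10:14, 10:14)] <- 1      # a pure diagonal of 5 pixels
  b <- detectBlobs(fr, bg)
  expect_equal(nrow(b), 1)
  expect_equal(b$area_px, 5)
})

test_that("frame/background shape mismatch is an error", {
  bg <- flatBackground(h = 48, w = 64)
  expect_error(detectBlobs(matrix(0, 10, 10), bg), "dimensions")
})

test_that("track linking follows drifting blobs and drops singletons", {
  drift <- data.frame(frame_idx = 1:6, t = (0:5) / 3, blob_id = 1L,
                      area_px = 20L, row = 100 + 5 * (0:5),
                      col = 200 + 5 * (0:5), size_px = 8, sharpness = 0.8)
  tr <- linkTracks(drift, gate_px = 60)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 6)

  single <- drift[3, ]
  expect_length(linkTracks(single, gate_px = 60), 0)

  # two well-separated simultaneous streams stay distinct
  two <- rbind(drift, transform(drift, row = row + 300))
  tr2 <- linkTracks(two, gate_px = 60)
  expect_length(tr2, 2)
  expect_true(all(vapply(tr2, nrow, 0L) == 6))
})

test_that("a skipped analyzed frame does not break a track", {
  drift <- data.frame(frame_idx = c(1, 2, 4, 5), t = c(0, 1, 3, 4) / 3,
                      blob_id = 1L, area_px = 20L,
                      row = c(100, 110, 130, 140),
                      col = rep(200, 4), size_px = 8, sharpness = 0.8)
  tr <- linkTracks(drift, gate_px = 60)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 4)
})

test_that("bat/insect discrimination needs both blur and speed", {
  sharp_slow <- makeTrack(100 + 5 * (0:5), 200 + 5 * (0:5))
  expect_equal(discriminateBatInsect(sharp_slow), "bat")
  blurred_fast <- makeTrack(100 + 150 * (0:3), rep(200, 4),
                            sharpness = 0.2)
  expect_equal(discriminateBatInsect(blurred_fast), "insect")
  blurred_slow <- makeTrack(100 + 5 * (0:5), rep(200, 6), sharpness = 0.2)
  expect_equal(discriminateBatInsect(blurred_slow), "bat")
  # sharpness exactly at threshold favours the bat call
  at_thresh <- makeTrack(100 + 150 * (0:3), rep(200, 4), sharpness = 0.4)
  expect_equal(discriminateBatInsect(at_thresh), "bat")
})

test_that("proximity classes follow the calibrated pinhole inversion", {
  cam <- cameraModel()
  f <- focalPx(cam)
  # apparent size 8.3 px (after calibration) -> 24.8 m -> near
  tr <- makeTrack(1:3, 1:3, size_px = 8.316 + cam@psf_px)
  pr <- classifyProximity(tr, cam)
  expect_equal(pr$distance_m, 24.8, tolerance = 1e-3)
  expect_equal(pr$class, "near")
  # exactly 25.0 m is still near (inclusive boundary)
  tr25 <- makeTrack(1:3, 1:3, size_px = f * 0.35 / 25 + cam@psf_px)
  expect_equal(classifyProximity(tr25, cam)$class, "near")
  tr35 <- makeTrack(1:3, 1:3, size_px = f * 0.35 / 35 + cam@psf_px)
  expect_equal(classifyProximity(tr35, cam)$class, "mid")
  tr70 <- makeTrack(1:3, 1:3, size_px = f * 0.35 / 70 + cam@psf_px)
  expect_equal(classifyProximity(tr70, cam)$class, "far")
  # vanishing size diverges out of range
  tr0 <- makeTrack(1:3, 1:3, size_px = cam@psf_px + 1e-9)
  expect_equal(classifyProximity(tr0, cam)$class, "out_of_range")
  # nearest approach governs the event distance
  trmix <- makeTrack(1:4, 1:4, size_px = f * 0.35 / c(60, 30, 20, 40) +
                       cam@psf_px)
  expect_equal(classifyProximity(trmix, cam)$distance_m, 20,
               tolerance = 1e-6)
})

test_that("flight classification separates the three path archetypes", {
  expect_equal(classifyFlight(makeTrack(rep(100, 8), 100 + 20 * (0:7))),
               "straight")
  # 90-degree single-sign arc
  ang <- seq(0, pi / 2, length.out = 10)
  expect_equal(classifyFlight(makeTrack(100 + 50 * sin(ang),
                                        100 + 50 * (1 - cos(ang)))),
               "curved")
  # alternating +-60 degree turns
  turns <- cumsum(c(0, rep(c(60, -60), 3)) * pi / 180)
  steps <- 20 * cbind(cos(turns), sin(turns))
  path <- apply(rbind(c(100, 100), steps), 2, cumsum)
  expect_equal(classifyFlight(makeTrack(path[, 1], path[, 2])), "erratic")
  # two points default to straight, flagged low confidence
  short <- classifyFlight(makeTrack(c(1, 2), c(1, 2)))
  expect_equal(as.character(short), "straight")
  expect_true(attr(short, "low_confidence"))
})

test_that("interaction requires close approach and non-straight flight", {
  cam <- cameraModel()
  f <- focalPx(cam)
  sz <- f * 0.35 / 20 + cam@psf_px    # both at ~20 m
  # two straight tracks crossing in the image: noninteracting
  a <- makeTrack(rep(240, 6), 100 + 40 * (0:5), size_px = sz)
  b <- makeTrack(140 + 40 * (0:5), rep(320, 6), size_px = sz)
  expect_equal(classifyInteraction(list(a, b), cam), "noninteracting")
  expect_equal(classifyInteraction(list(a), cam), "none")
  # two erratic tracks within ~1 m of each other: agonistic
  turns <- cumsum(c(0, rep(c(60, -60), 3)) * pi / 180)
  steps <- 15 * cbind(cos(turns), sin(turns))
  path <- apply(rbind(c(200, 200), steps), 2, cumsum)
  c1 <- makeTrack(path[, 1], path[, 2], size_px = sz)
  c2 <- makeTrack(path[, 1] + 5, path[, 2] + 5, size_px = sz)
  expect_equal(classifyInteraction(list(c1, c2), cam), "agonistic")
})

test_that("events respect the minimum duration and area invariants", {
  cam <- cameraModel()
  set.seed(21)
  p <- passAtDepth(18, seed = 21)
  w <- waypoints(p)
  fs <- renderThermalFrames(list(p), cam,
                            times = seq(w$t[1], w$t[nrow(w)], by = 1 / 3))
  blobs <- detectAllBlobs(fs)
  expect_true(all(blobs$area_px >= 5))
  ev <- detectVideoEvents(fs, step = 1)
  expect_gte(nrow(ev), 1)
  expect_true(all(ev$t_end - ev$t_start >= 0.3))
  expect_true(all(ev$n_bats >= 1))
})

test_that("concurrent well-separated bats become one multi-bat event", {
  cam <- cameraModel()
  set.seed(31)
  p1 <- echoSync:::makePass(1L, "straight", 0, cam, 7, c(15, 15.001))
  p2 <- echoSync:::makePass(2L, "straight", 0.2, cam, 7, c(30, 30.001))
  t1 <- range(waypoints(p1)$t); t2 <- range(waypoints(p2)$t)
  times <- seq(min(t1[1], t2[1]), max(t1[2], t2[2]), by = 1 / 3)
  fs <- renderThermalFrames(list(p1, p2), cam, times = times)
  ev <- detectVideoEvents(fs, step = 1)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$n_bats[1], 2)
})
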