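test_that("synthesized FM sweeps are measured to STFT precision", {
  set.seed(7)
  pul <- data.frame(onset = 0.05, duration_ms = 7, fmin_khz = 30,
                    fmax_khz = 40, fpeak_khz = 35)
  det <- detectPulses(synthesizeWaveform(pul, total_s = 0.3))
  expect_equal(nrow(det), 1)
  hop_ms <- 64 / 192000 * 1000
  expect_lt(abs(det$onset - 0.05) * 1000, hop_ms)
  expect_lt(abs(det$duration_ms - 7), 1.4)
  # peak within one 750 Hz bin of the sweep energy maximum
  expect_lt(abs(det$fpeak_khz - 35), 0.76)
  expect_lt(abs(det$fmax_khz - 40), 1)
  expect_lt(abs(det$fmin_khz - 30), 1)
})

test_that("silence produces no pulses", {
  set.seed(8)
  expect_equal(nrow(detectPulses(rnorm(192000 / 2, sd = 1e-3))), 0)
  expect_equal(nrow(detectPulses(numeric(0))), 0)
})

test_that("two sweeps 200 ms apart are resolved with the right spacing", {
  set.seed(9)
  pul <- data.frame(onset = c(0.05, 0.25), duration_ms = 7, fmin_khz = 30,
                    fmax_khz = 40, fpeak_khz = 35)
  det <- detectPulses(synthesizeWaveform(pul, total_s = 0.5))
  expect_equal(nrow(det), 2)
  expect_lt(abs(diff(det$onset) * 1000 - 200), 2)
})

test_that("trigger-file grouping follows the window and length rules", {
  cfg <- detectorConfig()
  # activity up to 1 s then a pulse at 3.5 s: the 2.5 s gap closes the file
  g <- groupPulseFiles(makePulseTable(c(0, 0.4, 1.0, 3.5)), cfg)
  expect_equal(unname(g$file_id), c(1, 1, 1, 2))
  # no pulses, no files
  expect_equal(nrow(groupPulseFiles(makePulseTable(numeric(0)), cfg)), 0)
  # continuous pulses every 0.2 s for 20 s: split at the 15 s length cap
  g2 <- groupPulseFiles(makePulseTable(seq(0, 19.8, by = 0.2)), cfg)
  expect_equal(length(unique(g2$file_id)), 2)
  first <- g2$onset[g2$file_id == 1]
  expect_equal(max(first), 15)
  expect_equal(min(g2$onset[g2$file_id == 2]), 15.2)
  # a gap of exactly the trigger window also closes the file
  g3 <- groupPulseFiles(makePulseTable(c(0, 2.0)), cfg)
  expect_equal(unname(g3$file_id), c(1, 2))
})

test_that("bandwidth and modulation follow their definitions", {
  m <- computePulseMetrics(makePulseTable(0, fmin = 26.3, fmax = 35.6))
  expect_equal(m$bandwidth_khz, 9.3, tolerance = 1e-9)
  expect_equal(m$modulation_pct, 100 * 9.3 / 35.6, tolerance = 1e-9)
  expect_equal(round(m$modulation_pct), 26)
  m2 <- computePulseMetrics(makePulseTable(0, fmin = 30, fmax = 30))
  expect_equal(m2$bandwidth_khz, 0)
  expect_equal(m2$modulation_pct, 0)
  m3 <- computePulseMetrics(makePulseTable(0, fmin = 30, fmax = 40))
  expect_equal(m3$bandwidth_khz, 10)
  expect_equal(m3$modulation_pct, 25)
  expect_error(computePulseMetrics(makePulseTable(0, fmax = 0)), "fmax")
})

test_that("search-phase extraction enforces its three constraints", {
  # 4 qualifying pulses spaced 200 ms: one sequence of 4
  s1 <- extractSearchPhase(makePulseTable(c(0, 0.2, 0.4, 0.6)))
  expect_length(s1, 1)
  expect_equal(nrow(s1[[1]]), 4)
  # 2 qualifying pulses: nothing
  expect_length(extractSearchPhase(makePulseTable(c(0, 0.2))), 0)
  # a 90 ms first gap breaks the run; pulses 2-5 form the sequence
  s2 <- extractSearchPhase(makePulseTable(c(0, 0.09, 0.29, 0.49, 0.69)))
  expect_length(s2, 1)
  expect_equal(s2[[1]]$onset, c(0.09, 0.29, 0.49, 0.69))
  # weak pulses are excluded before run-building
  tab <- makePulseTable(c(0, 0.2, 0.4, 0.6))
  tab$amp_db <- c(40, 10, 40, 40)
  s3 <- extractSearchPhase(tab)
  expect_length(s3, 1)
  expect_equal(s3[[1]]$onset, c(0, 0.4, 0.6))   # weak pulse dropped
  # every returned sequence satisfies the constraints exactly
  set.seed(12)
  for (i in 1:20) {
    on <- cumsum(runif(12, 0.03, 0.4))
    tab <- makePulseTable(on, amp_db = sample(c(10, 40), 12, TRUE))
    for (s in extractSearchPhase(tab)) {
      expect_gte(nrow(s), 3)
      expect_true(all(diff(s$onset) >= 0.1))
      expect_true(all(s$amp_db >= 15))
    }
  }
})

test_that("sequence metrics follow the rate and IPI definitions", {
  tab <- makePulseTable(c(0, 0.2, 0.42), duration_ms = c(7, 7, 10))
  m <- computeSequenceMetrics(tab)
  expect_equal(m$ipis_ms, c(200, 220))
  expect_equal(m$span_ms, 430)
  expect_equal(m$pulse_rate_hz, 3 / 0.43, tolerance = 1e-9)
  # degenerate last duration
  m2 <- computeSequenceMetrics(makePulseTable(c(0, 0.1, 0.2),
                                              duration_ms = 0))
  expect_equal(m2$pulse_rate_hz, 15)
  expect_error(computeSequenceMetrics(makePulseTable(c(0, 0.2, 0.1))),
               "increasing")
})

test_that("rate equals n / ((n-1) * mean IPI + last duration)", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    on <- cumsum(c(0, runif(n - 1, 0.1, 0.5)))
    dur <- runif(n, 1, 15)
    m <- computeSequenceMetrics(makePulseTable(on, duration_ms = dur))
    expect_equal(m$pulse_rate_hz,
                 n / ((n - 1) * mean(m$ipis_ms) / 1000 + dur[n] / 1000),
                 tolerance = 1e-9)
  }
})

test_that("call-type flags capture buzz, social and search structure", {
  # 8 pulses at 30 ms IPI: terminal
  expect_true("terminal" %in%
                classifyCallType(makePulseTable(seq(0, 0.21, by = 0.03))))
  # low-frequency long pulses: social
  soc <- makePulseTable(c(0, 0.2), duration_ms = 15, fpeak = 15)
  expect_true("social" %in% classifyCallType(soc))
  # 5 pulses at 200 ms, 29 kHz: search only
  plain <- classifyCallType(makePulseTable(seq(0, 0.8, by = 0.2)))
  expect_equal(plain, "search")
  # 4 pulses at 50 ms IPI are not yet a buzz (needs >= 5)
  expect_false("terminal" %in%
                 classifyCallType(makePulseTable(seq(0, 0.15, by = 0.05))))
})

test_that("summary quartiles agree with a sort-based oracle", {
  set.seed(14)
  seqs <- lapply(1:5, function(i)
    makePulseTable(cumsum(c(0, runif(3, 0.15, 0.4))),
                   duration_ms = runif(4, 2, 12),
                   fmin = runif(4, 22, 26), fmax = runif(4, 30, 45),
                   fpeak = runif(4, 26, 30)))
  sm <- summarizeCallMetrics(seqs)
  ipis <- unlist(lapply(seqs, function(s) diff(s$onset) * 1000))
  expect_equal(sm$ipi_ms[sm$statistic == "median"], median(ipis))
  expect_equal(sm$ipi_ms[sm$statistic == "q1"],
               unname(quantile(ipis, 0.25)))
  expect_equal(sm$ipi_ms[sm$statistic == "max"], max(ipis))
  durs <- unlist(lapply(seqs, `[[`, "duration_ms"))
  expect_equal(sm$duration_ms[sm$statistic == "mean"], mean(durs))
  expect_equal(sm$duration_ms[sm$statistic == "sd"], sd(durs))
  # identical pulses give zero spread
  one <- summarizeCallMetrics(list(makePulseTable(c(0, 0.2, 0.4))))
  expect_equal(one$ipi_ms[one$statistic == "sd"], 0)
  expect_equal(one$duration_ms[one$statistic == "sd"], 0)
})

test_that("modulation and bandwidth stay within their ranges on all output",
{
  set.seed(15)
  q <- makePulseTable(cumsum(runif(50, 0.1, 0.3)),
                      fmin = runif(50, 20, 28), fmax = runif(50, 29, 60),
                      fpeak = runif(50, 26, 30))
  m <- computePulseMetrics(q)
  expect_true(all(m$bandwidth_khz >= 0))
  expect_true(all(m$modulation_pct >= 0 & m$modulation_pct <= 100))
})

test_that("waveform detection feeds the metric chain end to end", {
  set.seed(16)
  truth <- makePulseTable(c(0.1, 0.32, 0.53, 0.74), duration_ms = 7,
                          fmin = 26, fmax = 36, fpeak = 30)
  det <- detectPulses(synthesizeWaveform(truth, total_s = 1))
  expect_equal(nrow(det), 4)
  seqs <- extractSearchPhase(det)
  expect_length(seqs, 1)
  m <- computeSequenceMetrics(seqs[[1]])
  expect_equal(m$mean_ipi_ms, mean(diff(truth$onset)) * 1000,
               tolerance = 0.01)
})
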