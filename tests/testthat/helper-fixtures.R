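# Shared fixtures built in code.

# A track data.frame as produced by linkTracks, from pixel positions.
makeTrack <- function(rows, cols, dt = 1 / 3, size_px = 8,
                      sharpness = 0.8, t0 = 0) {
  n <- length(rows)
  data.frame(frame_idx = seq_len(n), t = t0 + dt * (seq_len(n) - 1),
             blob_id = 1L, area_px = 20L, row = rows, col = cols,
             size_px = rep_len(size_px, n),
             sharpness = rep_len(sharpness, n))
}

# A pulse table with the given onsets (s); constant spectral parameters.
makePulseTable <- function(onsets, duration_ms = 7, fpeak = 29,
                           fmin = 26, fmax = 36, amp_db = 40) {
  n <- length(onsets)
  data.frame(onset = onsets, duration_ms = rep_len(duration_ms, n),
             fmin_khz = rep_len(fmin, n), fmax_khz = rep_len(fmax, n),
             fpeak_khz = rep_len(fpeak, n), amp_db = rep_len(amp_db, n))
}

# A flat background model for hand-built frames.
flatBackground <- function(h = 48, w = 64, level = 0, sd = 0.01) {
  list(median = matrix(level, h, w), sd = sd)
}

# A single straight pass at closest-approach distance ~d metres.
passAtDepth <- function(d, type = "straight", t0 = 0, seed = 1,
                        camera = cameraModel()) {
  set.seed(seed)
  echoSync:::makePass(1L, type, t0, camera, 7, c(d, d + 1e-3))
}
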