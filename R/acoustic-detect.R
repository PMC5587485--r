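## Echolocation pulse detection on full-spectrum waveforms.
##
## A short-time Fourier transform (256-sample windows, 75% overlap; 1.33 ms
## windows / 0.33 ms hop at 192 kHz) resolves pulse durations in the 1-21
## ms range.  The per-file noise floor is the median spectral magnitude;
## a pulse is a maximal run of STFT frames whose peak bin exceeds the
## noise floor by 15 dB.

#' Detector configuration
#'
#' Recorder settings: 192 kHz sampling, 1 kHz high-pass, 18 dB SNR
#' trigger, 2.0 s trigger window (quiet time that closes a file), 15 s
#' maximum file length.
#'
#' @param sample_rate Hz
#' @param highpass_hz high-pass cutoff, Hz
#' @param trigger_snr dB
#' @param trigger_window_s seconds
#' @param max_file_len_s seconds
#' @return a list of detector settings
#' @export
detectorConfig <- function(sample_rate = 192000, highpass_hz = 1000,
                           trigger_snr = 18, trigger_window_s = 2.0,
                           max_file_len_s = 15) {
  stopifnot(sample_rate > 0, highpass_hz > 0, trigger_snr > 0,
            trigger_window_s > 0, max_file_len_s > trigger_window_s)
  list(sample_rate = sample_rate, highpass_hz = highpass_hz,
       trigger_snr = trigger_snr, trigger_window_s = trigger_window_s,
       max_file_len_s = max_file_len_s)
}

#' Detect echolocation pulses in a waveform
#'
#' @param waveform numeric vector, mono audio at \code{config$sample_rate}
#' @param config from \code{\link{detectorConfig}}
#' @param threshold_db detection threshold above the noise floor, dB
#' @param nfft STFT window (samples); hop is nfft/4 (75% overlap)
#' @return data.frame: onset (s), duration_ms, fmin_khz, fmax_khz,
#'   fpeak_khz, amp_db (peak level above noise floor)
#' @export
detectPulses <- function(waveform, config = detectorConfig(),
                         threshold_db = 15, nfft = 256) {
  if (!length(waveform)) return(emptyPulses())
  fs <- config$sample_rate
  hop <- nfft / 4
  sp <- signal::specgram(waveform, n = nfft, Fs = fs,
                         overlap = nfft - hop)
  mag <- 20 * log10(abs(sp$S) + 1e-12)      # freq x time
  freqs <- sp$f
  keep <- freqs >= config$highpass_hz
  mag <- mag[keep, , drop = FALSE]
  freqs <- freqs[keep]
  noise_floor <- stats::median(mag)
  peak_per_frame <- matrixStats::colMaxs(mag)
  hot <- peak_per_frame > noise_floor + threshold_db
  if (!any(hot)) return(emptyPulses())
  runs <- rle(hot)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  frame_t <- sp$t   # centre times of frames
  for (k in which(runs$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    sub <- mag[, i0:i1, drop = FALSE]
    peak_db <- max(sub)
    pk <- which(sub == peak_db, arr.ind = TRUE)[1, ]
    # fmin/fmax: extreme frequencies reaching within threshold_db of the
    # in-pulse peak
    prof <- matrixStats::rowMaxs(sub)
    inband <- which(prof >= peak_db - threshold_db)
    # a window overlapping any part of the pulse goes hot: the first hot
    # window starts nfft - hop samples before the pulse onset, and the
    # hot run overstates the duration by nfft - hop samples
    out[[length(out) + 1]] <- data.frame(
      onset = frame_t[i0] + (nfft - hop) / fs,
      duration_ms = max(hop, (i1 - i0 + 1) * hop - (nfft - hop)) / fs * 1000,
      fmin_khz = freqs[min(inband)] / 1000,
      fmax_khz = freqs[max(inband)] / 1000,
      fpeak_khz = freqs[pk[1]] / 1000,
      amp_db = peak_db - noise_floor)
  }
  do.call(rbind, out)
}

emptyPulses <- function() {
  data.frame(onset = numeric(), duration_ms = numeric(),
             fmin_khz = numeric(), fmax_khz = numeric(),
             fpeak_khz = numeric(), amp_db = numeric())
}

#' Synthesize a linear FM sweep pulse
#'
#' @param f_start,f_end sweep frequencies, kHz
#' @param duration_ms duration, ms
#' @param sample_rate Hz
#' @param amplitude linear amplitude of the sweep
#' @return numeric waveform of the pulse (Hann-tapered edges)
#' @export
synthesizeSweep <- function(f_start, f_end, duration_ms,
                            sample_rate = 192000, amplitude = 0.5) {
  n <- max(8, round(duration_ms / 1000 * sample_rate))
  t <- seq_len(n) / sample_rate
  dur <- n / sample_rate
  f0 <- f_start * 1000; f1 <- f_end * 1000
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * dur) * t^2)
  env <- sin(pi * seq_len(n) / n)^0.25     # gentle taper, near-flat middle
  amplitude * env * sin(phase)
}

#' Synthesize a waveform from a pulse table
#'
#' Builds a mono waveform with one descending FM sweep per pulse row, at
#' amplitudes set by \code{amp_db} relative to a unit noise floor.
#'
#' @param pulses data.frame with onset (s), duration_ms, fmin_khz,
#'   fmax_khz columns and optionally amp_db
#' @param total_s total length, seconds
#' @param sample_rate Hz
#' @param noise_rms RMS of additive white noise
#' @return numeric waveform
#' @export
synthesizeWaveform <- function(pulses, total_s = NULL,
                               sample_rate = 192000, noise_rms = 1e-3) {
  if (is.null(total_s))
    total_s <- if (nrow(pulses)) max(pulses$onset) + 0.1 else 1
  n <- round(total_s * sample_rate)
  x <- stats::rnorm(n, sd = noise_rms)
  for (k in seq_len(nrow(pulses))) {
    amp <- if ("amp_db" %in% names(pulses))
      noise_rms * 10^(pmin(pulses$amp_db[k], 80) / 20) * 30 else 0.5
    sw <- synthesizeSweep(pulses$fmax_khz[k], pulses$fmin_khz[k],
                          pulses$duration_ms[k], sample_rate, amp)
    i0 <- round(pulses$onset[k] * sample_rate) + 1
    i1 <- min(n, i0 + length(sw) - 1)
    if (i0 >= n) next
    x[i0:i1] <- x[i0:i1] + sw[seq_len(i1 - i0 + 1)]
  }
  x
}
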