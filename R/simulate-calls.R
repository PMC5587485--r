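## Call-emission simulation and the acoustic propagation channel.

#' Simulate echolocation emissions for a set of passes
#'
#' Each pass is silent with probability \code{p_silent}.  A vocal pass
#' emits search-phase pulses in bouts over its flight duration: bout sizes
#' are 3 + Poisson(\code{bout_size_lambda}) pulses, within-bout interpulse
#' intervals are lognormal (moment-matched to \code{ipi_mean}/
#' \code{ipi_sd}), and bouts are separated by multi-second silent gaps.
#' With probability \code{buzz_probability} a terminal buzz (>= 5 pulses at
#' IPI <= 50 ms) is appended; with probability \code{social_probability}
#' low-frequency (< 20 kHz) long-duration social pulses are inserted.
#'
#' @param passes list of \code{\link{BatPass}}
#' @param call_model a \code{\link{CallModel}}
#' @param p_silent probability in [0,1] that a pass emits nothing
#' @param silent optional logical vector (one flag per pass) overriding
#'   the Bernoulli draw — used by balanced-randomization experiments that
#'   fix the silent count at round(n * p_silent)
#' @return a \code{\link{GroundTruthLog}}; the per-pulse table holds the
#'   emitted pulses (channel fields are filled by
#'   \code{\link{applyAcousticChannel}})
#' @export
simulateCallEmissions <- function(passes, call_model = callModel(),
                                  p_silent = 0, silent = NULL) {
  stopifnot(p_silent >= 0, p_silent <= 1)
  validObject(call_model)
  if (is.null(silent)) silent <- stats::runif(length(passes)) < p_silent
  stopifnot(length(silent) == length(passes))
  pulse_rows <- list()
  pass_rows <- lapply(seq_along(passes), function(i) {
    p <- passes[[i]]
    w <- p@waypoints
    d <- sqrt(w$x^2 + w$y^2 + w$z^2)
    data.frame(pass_id = p@pass_id, trajectory_type = p@trajectory_type,
               silent = silent[i], t_start = w$t[1], t_end = w$t[nrow(w)],
               min_distance_m = min(d))
  })
  for (i in seq_along(passes)) {
    if (silent[i]) next
    p <- passes[[i]]
    onsets <- emitBoutTrain(p@waypoints$t[1],
                            p@waypoints$t[nrow(p@waypoints)], call_model)
    if (!length(onsets)) next
    tab <- drawPulseParams(length(onsets), call_model)
    tab$onset <- onsets
    tab$kind <- "search"
    if (stats::runif(1) < call_model@buzz_probability)
      tab <- rbind(tab, makeBuzz(max(onsets), call_model))
    if (stats::runif(1) < call_model@social_probability)
      tab <- rbind(tab, makeSocial(onsets[1], call_model))
    tab$pass_id <- p@pass_id
    pulse_rows[[length(pulse_rows) + 1]] <- tab
  }
  pulses <- if (length(pulse_rows)) do.call(rbind, pulse_rows) else
    emptyPulseTruth()
  pulses <- pulses[order(pulses$onset), , drop = FALSE]
  rownames(pulses) <- NULL
  new("GroundTruthLog", passes = do.call(rbind, pass_rows), pulses = pulses)
}

emptyPulseTruth <- function() {
  data.frame(onset = numeric(), duration_ms = numeric(),
             fmin_khz = numeric(), fmax_khz = numeric(),
             fpeak_khz = numeric(), kind = character(),
             pass_id = integer())
}

# Bout-structured onset train between t0 and t1.
emitBoutTrain <- function(t0, t1, cm) {
  ip <- lognormalPars(cm@ipi_mean, cm@ipi_sd)
  gp <- lognormalPars(cm@bout_gap_mean_s, cm@bout_gap_sd_s)
  onsets <- numeric()
  t <- t0 + stats::runif(1, 0, 0.2)
  repeat {
    n <- 3 + stats::rpois(1, cm@bout_size_lambda)
    ipis <- stats::rlnorm(n - 1, ip["meanlog"], ip["sdlog"]) / 1000
    bout <- t + c(0, cumsum(ipis))
    bout <- bout[bout <= t1]
    onsets <- c(onsets, bout)
    if (!length(bout) || max(bout) >= t1) break
    # silent gaps between bouts always exceed the recorder's 2-s trigger
    # window (observed interpulse intervals top out well below 1 s), so
    # each bout lands in its own trigger file
    t <- max(bout) + 2.2 + stats::rlnorm(1, gp["meanlog"], gp["sdlog"])
    if (t >= t1) break
  }
  onsets
}

# Spectral/duration parameters for n search-phase pulses.  The sweep is
# descending: fmax is the start frequency, fmin the end frequency; the
# peak splits the bandwidth in the ratio observed for shallow FM calls.
drawPulseParams <- function(n, cm) {
  fpeak <- pmax(20.5, stats::rnorm(n, cm@peak_freq_mean, cm@peak_freq_sd))
  bw <- lognormalPars(cm@bandwidth_mean, cm@bandwidth_sd)
  bandwidth <- stats::rlnorm(n, bw["meanlog"], bw["sdlog"])
  up_frac <- 0.68     # fraction of the sweep above the peak frequency
  fmax <- fpeak + up_frac * bandwidth
  fmin <- pmax(1, fpeak - (1 - up_frac) * bandwidth)
  dur <- pmin(21, pmax(1, stats::rnorm(n, cm@pulse_duration_mean,
                                       cm@pulse_duration_sd)))
  data.frame(onset = NA_real_, duration_ms = dur, fmin_khz = fmin,
             fmax_khz = fmax, fpeak_khz = fpeak)
}

makeBuzz <- function(t_last, cm) {
  n <- 5 + stats::rpois(1, 4)
  ipis <- stats::runif(n - 1, 0.015, 0.045)
  tab <- drawPulseParams(n, cm)
  tab$onset <- t_last + 0.15 + c(0, cumsum(ipis))
  tab$duration_ms <- pmax(1, tab$duration_ms / 3)
  tab$kind <- "buzz"
  tab
}

makeSocial <- function(t_first, cm) {
  n <- sample(2:4, 1)
  tab <- drawPulseParams(n, cm)
  tab$onset <- t_first + stats::runif(1, 0, 0.5) +
    c(0, cumsum(stats::runif(n - 1, 0.12, 0.3)))
  tab$fpeak_khz <- stats::runif(n, 12, 18)
  tab$fmax_khz <- tab$fpeak_khz + 3
  tab$fmin_khz <- pmax(1, tab$fpeak_khz - 2)
  tab$duration_ms <- stats::runif(n, 11, 18)
  tab$kind <- "social"
  tab
}

#' Propagate emitted pulses through the acoustic channel
#'
#' Received level = source_level - 20*log10(d) - alpha*d -
#' beam*(1 - cos(theta)), where d is the bat-microphone distance (clamped
#' to 0.1 m) and theta the angle between the bat's heading (sonar beam
#' axis) and the direction to the microphone.  A pulse is recorded iff
#' received level - noise_floor >= trigger_snr.
#'
#' @param truth a \code{\link{GroundTruthLog}} from
#'   \code{\link{simulateCallEmissions}}
#' @param passes the list of \code{\link{BatPass}} the truth was built from
#' @param mic a \code{\link{MicModel}}
#' @param atmosphere an \code{\link{AtmosphereModel}}
#' @param source_level emitted level dB at 1 m
#' @return the \code{GroundTruthLog} with distance, received level/SNR and
#'   the recorded flag filled in
#' @export
applyAcousticChannel <- function(truth, passes, mic = micModel(),
                                 atmosphere = atmosphereModel(),
                                 source_level = 110) {
  validObject(mic); validObject(atmosphere)
  q <- truth@pulses
  if (!nrow(q)) {
    q$distance_m <- numeric(); q$received_level_db <- numeric()
    q$received_snr_db <- numeric(); q$recorded <- logical()
    return(new("GroundTruthLog", passes = truth@passes, pulses = q))
  }
  bypass <- setNames(passes, vapply(passes, function(p)
    as.character(p@pass_id), ""))
  mic_pos <- c(0, 0, mic@height - 2)    # microphone alongside the camera
  n <- nrow(q)
  d <- numeric(n); theta <- numeric(n)
  for (k in seq_len(n)) {
    p <- bypass[[as.character(q$pass_id[k])]]
    pos <- passPosition(p, q$onset[k])
    v <- mic_pos - pos
    d[k] <- max(0.1, sqrt(sum(v^2)))
    head <- passHeading(p, q$onset[k])
    theta[k] <- acos(pmin(1, pmax(-1, sum(head * v) / d[k])))
  }
  loss <- 20 * log10(d) + atmosphere@alpha * d + mic@beam * (1 - cos(theta))
  q$distance_m <- d
  q$received_level_db <- source_level - loss
  q$received_snr_db <- q$received_level_db - mic@noise_floor
  q$recorded <- q$received_snr_db >= mic@trigger_snr
  new("GroundTruthLog", passes = addPassCounts(truth@passes, q), pulses = q)
}

addPassCounts <- function(passes, q) {
  passes$n_emitted <- as.integer(table(factor(q$pass_id,
                                              levels = passes$pass_id)))
  rec <- q[q$recorded, , drop = FALSE]
  passes$n_recorded <- as.integer(table(factor(rec$pass_id,
                                               levels = passes$pass_id)))
  passes
}

#' Recorded pulse stream of a simulated night
#'
#' Extracts the pulses that passed the detector trigger as the pulse-table
#' shape consumed by the acoustic-processing module (onset s, duration ms,
#' frequencies kHz, amplitude dB above noise floor).
#'
#' @param truth a channel-processed \code{\link{GroundTruthLog}}
#' @return data.frame: onset, duration_ms, fmin_khz, fmax_khz, fpeak_khz,
#'   amp_db
#' @export
recordedPulses <- function(truth) {
  q <- truth@pulses
  if (!"recorded" %in% names(q)) stop("apply the acoustic channel first")
  q <- q[q$recorded, , drop = FALSE]
  data.frame(onset = q$onset, duration_ms = q$duration_ms,
             fmin_khz = q$fmin_khz, fmax_khz = q$fmax_khz,
             fpeak_khz = q$fpeak_khz, amp_db = q$received_snr_db)
}
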