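#' @import methods
NULL

## ---- parameter models -------------------------------------------------

#' Thermal camera model
#'
#' Pinhole model of the thermal surveillance camera: a 640x480 sensor with a
#' 57 degree horizontal field of view recording at 30 frames per second.
#' The focal length in pixels is derived as \code{(width_px/2)/tan(hfov/2)}
#' and is the basis of all apparent-size/distance conversions.  Targets
#' beyond \code{max_range_m} (default 80 m) fall below the detection
#' threshold of the imaging chain and are not consistently detectable.
#'
#' @slot width_px,height_px sensor size in pixels
#' @slot hfov_deg horizontal field of view, degrees
#' @slot frame_rate frames per second
#' @slot max_range_m maximum consistent detection range, metres
#' @slot bat_size_m characteristic size of a bat (wingspan-scale), metres
#' @slot psf_px effective edge-spread of the optics, pixels; used to
#'   calibrate apparent blob size back to true angular size
#' @exportClass CameraModel
setClass("CameraModel",
  representation(width_px = "numeric", height_px = "numeric",
                 hfov_deg = "numeric", frame_rate = "numeric",
                 max_range_m = "numeric", bat_size_m = "numeric",
                 psf_px = "numeric"),
  prototype(width_px = 640, height_px = 480, hfov_deg = 57,
            frame_rate = 30, max_range_m = 80, bat_size_m = 0.35,
            psf_px = 1.9),
  validity = function(object) {
    v <- c(object@width_px, object@height_px, object@hfov_deg,
           object@frame_rate, object@max_range_m, object@bat_size_m)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all camera parameters must be finite and positive")
    if (object@hfov_deg >= 180) return("hfov_deg must be < 180")
    TRUE
  })

#' @rdname CameraModel-class
#' @param width_px,height_px,hfov_deg,frame_rate,max_range_m,bat_size_m,psf_px
#'   see slots
#' @return a \code{CameraModel}
#' @export
cameraModel <- function(width_px = 640, height_px = 480, hfov_deg = 57,
                        frame_rate = 30, max_range_m = 80,
                        bat_size_m = 0.35, psf_px = 1.9) {
  new("CameraModel", width_px = width_px, height_px = height_px,
      hfov_deg = hfov_deg, frame_rate = frame_rate,
      max_range_m = max_range_m, bat_size_m = bat_size_m, psf_px = psf_px)
}

#' Focal length in pixels of a camera model
#' @param camera a \code{CameraModel}
#' @return focal length in pixels
#' @export
focalPx <- function(camera) {
  (camera@width_px / 2) / tan(camera@hfov_deg * pi / 360)
}

#' Ultrasonic microphone / detector model
#'
#' Omnidirectional ultrasonic detector at 2 m height aimed 45 degrees above
#' the horizon.  A pulse is recorded when its received level exceeds the
#' noise floor by at least \code{trigger_snr} dB (factory trigger setting
#' 18 dB SNR).  \code{beam} is the coefficient k of the smooth off-axis
#' loss k*(1 - cos(theta)) dB applied to the emitting bat's sonar beam.
#'
#' @slot trigger_snr trigger threshold, dB above noise floor
#' @slot noise_floor ambient noise floor, dB
#' @slot beam directivity loss coefficient, dB
#' @slot height microphone height, m
#' @slot elevation_angle aim above horizon, degrees
#' @exportClass MicModel
setClass("MicModel",
  representation(trigger_snr = "numeric", noise_floor = "numeric",
                 beam = "numeric", height = "numeric",
                 elevation_angle = "numeric"),
  prototype(trigger_snr = 18, noise_floor = 30, beam = 20, height = 2,
            elevation_angle = 45),
  validity = function(object) {
    if (!is.finite(object@trigger_snr) || object@trigger_snr <= 0)
      return("trigger_snr must be positive")
    if (object@beam < 0) return("beam coefficient must be >= 0")
    TRUE
  })

#' @rdname MicModel-class
#' @param trigger_snr,noise_floor,beam,height,elevation_angle see slots
#' @export
micModel <- function(trigger_snr = 18, noise_floor = 30, beam = 20,
                     height = 2, elevation_angle = 45) {
  new("MicModel", trigger_snr = trigger_snr, noise_floor = noise_floor,
      beam = beam, height = height, elevation_angle = elevation_angle)
}

#' Ideal acoustic channel microphone
#'
#' A microphone with a very low noise floor and no directivity loss, so that
#' every emitted pulse is recorded within any realistic range.  Used for
#' identifiability experiments where the silent fraction must be recovered
#' without confounding from the acoustic channel.
#' @export
idealMic <- function() micModel(trigger_snr = 18, noise_floor = -150, beam = 0)

#' Atmospheric propagation model
#'
#' One-way transmission loss: spherical spreading \code{20*log10(d)} plus
#' linear atmospheric absorption \code{alpha} dB/m.  The default 0.3 dB/m
#' is representative of ~30 kHz sound in warm humid air and gives an
#' on-axis detection radius of roughly 80 m for a 110 dB source with the
#' default detector settings.
#'
#' @slot alpha absorption, dB per metre (>= 0)
#' @exportClass AtmosphereModel
setClass("AtmosphereModel",
  representation(alpha = "numeric"),
  prototype(alpha = 0.3),
  validity = function(object) {
    if (!is.finite(object@alpha) || object@alpha < 0)
      return("alpha must be finite and >= 0")
    TRUE
  })

#' @rdname AtmosphereModel-class
#' @param alpha absorption dB/m
#' @export
atmosphereModel <- function(alpha = 0.3) new("AtmosphereModel", alpha = alpha)

#' Echolocation call-structure model
#'
#' Parametric model of search-phase echolocation of an open-air hawking
#' bat with low-frequency calls (peak ~29 kHz).  Pulses are emitted in
#' short bouts; within a bout the interpulse interval is lognormal
#' (moment-matched to \code{ipi_mean}/\code{ipi_sd}), and bouts are
#' separated by multi-second gaps.  With probability
#' \code{buzz_probability} a pass ends in a terminal buzz (>= 5 pulses at
#' IPI <= 50 ms); with probability \code{social_probability} low-frequency
#' (< 20 kHz) long-duration social pulses are inserted.
#'
#' @slot ipi_mean,ipi_sd interpulse interval mean and SD, ms
#' @slot pulse_duration_mean,pulse_duration_sd pulse duration, ms
#' @slot peak_freq_mean,peak_freq_sd peak frequency, kHz
#' @slot bandwidth_mean,bandwidth_sd sweep bandwidth, kHz
#' @slot source_level emitted level at 1 m, dB
#' @slot buzz_probability,social_probability per-pass probabilities
#' @slot bout_size_lambda Poisson parameter: bout holds 3 + Pois(lambda)
#'   pulses
#' @slot bout_gap_mean_s,bout_gap_sd_s lognormal part of the inter-bout
#'   silent gap, seconds; a floor of 2.2 s (above the trigger window) is
#'   always added
#' @exportClass CallModel
setClass("CallModel",
  representation(ipi_mean = "numeric", ipi_sd = "numeric",
                 pulse_duration_mean = "numeric", pulse_duration_sd = "numeric",
                 peak_freq_mean = "numeric", peak_freq_sd = "numeric",
                 bandwidth_mean = "numeric", bandwidth_sd = "numeric",
                 source_level = "numeric",
                 buzz_probability = "numeric", social_probability = "numeric",
                 bout_size_lambda = "numeric",
                 bout_gap_mean_s = "numeric", bout_gap_sd_s = "numeric"),
  prototype(ipi_mean = 217, ipi_sd = 98,
            pulse_duration_mean = 6.9, pulse_duration_sd = 3.5,
            peak_freq_mean = 29.3, peak_freq_sd = 5.0,
            bandwidth_mean = 10.1, bandwidth_sd = 6.7,
            source_level = 110,
            buzz_probability = 0.10, social_probability = 0.02,
            bout_size_lambda = 1.0,
            bout_gap_mean_s = 2.5, bout_gap_sd_s = 2.0),
  validity = function(object) {
    pos <- c(object@ipi_mean, object@ipi_sd, object@pulse_duration_mean,
             object@peak_freq_mean, object@peak_freq_sd,
             object@bandwidth_mean, object@source_level)
    if (any(!is.finite(pos)) || any(pos <= 0))
      return("call model parameters must be finite and positive")
    if (object@peak_freq_mean >= 96)
      return("peak_freq_mean must be below the 96 kHz Nyquist frequency")
    for (p in c(object@buzz_probability, object@social_probability))
      if (p < 0 || p > 1) return("probabilities must lie in [0, 1]")
    TRUE
  })

#' @rdname CallModel-class
#' @param ... slot values overriding the defaults
#' @export
callModel <- function(...) new("CallModel", ...)

#' Simulation configuration for a night of bat activity
#'
#' @slot night_duration length of the night, seconds (default 12 h)
#' @slot pass_rate expected bat passes through the camera frustum per hour
#' @slot flight_mix weights over straight/curved/erratic trajectories
#'   (default 0.53/0.37/0.10)
#' @slot p_silent probability that a pass emits no calls at all
#' @slot speed_mps flight speed, m/s (default 7)
#' @slot call_model a \code{CallModel}
#' @slot camera a \code{CameraModel}
#' @slot mic a \code{MicModel}
#' @slot atmosphere an \code{AtmosphereModel}
#' @slot insect_rate nuisance insect targets per hour
#' @slot seed root seed; child streams are derived per subsystem
#' @exportClass SimConfig
setClass("SimConfig",
  representation(night_duration = "numeric", pass_rate = "numeric",
                 flight_mix = "numeric", p_silent = "numeric",
                 speed_mps = "numeric",
                 call_model = "CallModel", camera = "CameraModel",
                 mic = "MicModel", atmosphere = "AtmosphereModel",
                 insect_rate = "numeric", seed = "numeric"),
  prototype(night_duration = 12 * 3600, pass_rate = 3.3,
            flight_mix = c(straight = 0.53, curved = 0.37, erratic = 0.10),
            p_silent = 0.69, speed_mps = 7,
            insect_rate = 20, seed = 1),
  validity = function(object) {
    if (length(object@flight_mix) != 3 ||
        abs(sum(object@flight_mix) - 1) > 1e-9)
      return("flight_mix must be 3 weights summing to 1")
    if (any(object@flight_mix < 0)) return("flight_mix weights must be >= 0")
    if (!is.finite(object@p_silent) ||
        object@p_silent < 0 || object@p_silent > 1)
      return("p_silent must lie in [0, 1]")
    rates <- c(object@night_duration, object@pass_rate, object@insect_rate)
    if (any(!is.finite(rates)) || any(rates < 0))
      return("durations and rates must be finite and >= 0")
    if (object@speed_mps <= 0 || object@speed_mps > 12)
      return("speed_mps must be in (0, 12]")
    TRUE
  })

#' @rdname SimConfig-class
#' @param ... slot values overriding the defaults
#' @export
simConfig <- function(...) {
  args <- list(...)
  if (is.null(args$call_model)) args$call_model <- callModel()
  if (is.null(args$camera)) args$camera <- cameraModel()
  if (is.null(args$mic)) args$mic <- micModel()
  if (is.null(args$atmosphere)) args$atmosphere <- atmosphereModel()
  do.call(new, c(list("SimConfig"), args))
}

## ---- data containers --------------------------------------------------

#' A single simulated bat flight pass
#'
#' Waypoints are in a camera-centred world frame: origin at the camera,
#' optical axis along +y, x to the right, z up, metres.
#'
#' @slot pass_id integer id
#' @slot trajectory_type "straight", "curved" or "erratic"
#' @slot waypoints data.frame with columns t, x, y, z (t strictly increasing)
#' @slot speed flight speed m/s
#' @exportClass BatPass
setClass("BatPass",
  representation(pass_id = "integer", trajectory_type = "character",
                 waypoints = "data.frame", speed = "numeric"),
  validity = function(object) {
    if (!object@trajectory_type %in% c("straight", "curved", "erratic"))
      return("trajectory_type must be straight/curved/erratic")
    w <- object@waypoints
    if (!all(c("t", "x", "y", "z") %in% names(w)))
      return("waypoints need columns t, x, y, z")
    if (nrow(w) >= 2 && any(diff(w$t) <= 0))
      return("waypoint times must be strictly increasing")
    if (object@speed > 12) return("speed must be <= 12 m/s")
    TRUE
  })

#' Timestamped grayscale frame stack
#'
#' @slot frames list of numeric matrices in [0, 1] (rows x cols =
#'   height_px x width_px)
#' @slot times frame timestamps, seconds
#' @slot camera the \code{CameraModel} that produced the frames
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(frames = "list", times = "numeric", camera = "CameraModel"),
  validity = function(object) {
    if (length(object@frames) != length(object@times))
      return("one timestamp per frame required")
    if (length(object@frames)) {
      d <- dim(object@frames[[1]])
      if (is.null(d) ||
          any(d != c(object@camera@height_px, object@camera@width_px)))
        return("frame dimensions must match the camera model")
      if (any(diff(object@times) <= 0))
        return("frame times must be strictly increasing")
    }
    TRUE
  })

#' @rdname FrameSequence-class
#' @param frames list of matrices
#' @param times timestamps (s)
#' @param camera CameraModel
#' @export
FrameSequence <- function(frames, times, camera = cameraModel()) {
  new("FrameSequence", frames = frames, times = as.numeric(times),
      camera = camera)
}

#' Ground-truth log of a simulated night
#'
#' @slot passes data.frame: pass_id, trajectory_type, silent, t_start,
#'   t_end, min_distance_m, n_emitted, n_recorded
#' @slot pulses data.frame, one row per emitted pulse: pass_id, onset,
#'   duration_ms, fmin_khz, fmax_khz, fpeak_khz, kind, distance_m,
#'   received_level_db, received_snr_db, recorded
#' @exportClass GroundTruthLog
setClass("GroundTruthLog",
  representation(passes = "data.frame", pulses = "data.frame"),
  validity = function(object) {
    p <- object@passes; q <- object@pulses
    if (nrow(q)) {
      sil <- p$pass_id[p$silent]
      if (any(q$pass_id %in% sil))
        return("silent passes must have no emitted pulses")
      if ("recorded" %in% names(q) && !all(q$pass_id %in% p$pass_id))
        return("every pulse must trace to a logged pass")
    }
    TRUE
  })

## ---- show methods ------------------------------------------------------

setMethod("show", "CameraModel", function(object) {
  cat(sprintf(
    "CameraModel: %dx%d px, hfov %.1f deg (focal %.1f px), %g fps, range %g m\n",
    object@width_px, object@height_px, object@hfov_deg, focalPx(object),
    object@frame_rate, object@max_range_m))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    paste0("SimConfig: %.1f h night, %.2f passes/h, mix %s, ",
           "p_silent %.2f, seed %d\n"),
    object@night_duration / 3600, object@pass_rate,
    paste(sprintf("%.2f", object@flight_mix), collapse = "/"),
    object@p_silent, as.integer(object@seed)))
})

setMethod("show", "FrameSequence", function(object) {
  n <- length(object@frames)
  if (n) cat(sprintf("FrameSequence: %d frames (%.2f-%.2f s), %dx%d px\n",
                     n, object@times[1], object@times[n],
                     object@camera@width_px, object@camera@height_px))
  else cat("FrameSequence: empty\n")
})

setMethod("show", "BatPass", function(object) {
  w <- object@waypoints
  cat(sprintf("BatPass %d (%s): %d waypoints, %.2f-%.2f s, %.1f m/s\n",
              object@pass_id, object@trajectory_type, nrow(w),
              if (nrow(w)) w$t[1] else NA, if (nrow(w)) w$t[nrow(w)] else NA,
              object@speed))
})

setMethod("show", "GroundTruthLog", function(object) {
  cat(sprintf(
    "GroundTruthLog: %d passes (%d silent), %d emitted pulses (%d recorded)\n",
    nrow(object@passes), sum(object@passes$silent), nrow(object@pulses),
    if (nrow(object@pulses)) sum(object@pulses$recorded) else 0L))
})

## ---- accessors ---------------------------------------------------------

#' Number of frames in a FrameSequence
#' @param x a FrameSequence
#' @export
nFrames <- function(x) length(x@frames)

#' Frame timestamps
#' @param x a FrameSequence
#' @export
frameTimes <- function(x) x@times

#' Extract one frame matrix
#' @param x a FrameSequence
#' @param i frame index
#' @export
getFrame <- function(x, i) x@frames[[i]]

#' Waypoints of a pass
#' @param x a BatPass
#' @export
waypoints <- function(x) x@waypoints

#' Trajectory type of a pass
#' @param x a BatPass
#' @export
trajectoryType <- function(x) x@trajectory_type

#' Per-pass truth table of a simulation
#' @param x a GroundTruthLog
#' @export
truthPasses <- function(x) x@passes

#' Per-pulse truth table of a simulation
#' @param x a GroundTruthLog
#' @export
truthPulses <- function(x) x@pulses
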