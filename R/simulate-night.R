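## Orchestration: whole-night simulation, the clip-based end-to-end
## analysis, and the parameter-recovery experiments.

#' Simulate one night of bat activity
#'
#' Runs the flight, insect, emission and channel stages under independent
#' child random streams derived from the config's root seed, so each
#' subsystem is reproducible in isolation.
#'
#' @param config a \code{\link{SimConfig}}
#' @param start_times optional fixed pass start times (overrides the
#'   Poisson arrival process)
#' @param depth_range closest-approach range for the passes, metres
#' @param silent optional per-pass silence flags forwarded to
#'   \code{\link{simulateCallEmissions}}
#' @return list: config, passes (list of \code{\link{BatPass}}), insects
#'   (data.frame), truth (\code{\link{GroundTruthLog}} with channel
#'   fields), recorded (recorded pulse stream data.frame)
#' @export
simulateNight <- function(config, start_times = NULL,
                          depth_range = c(5, 70), silent = NULL) {
  validObject(config)
  seed <- config@seed
  passes <- withChildSeed(seed, "flight",
    simulateFlightPaths(config, start_times, depth_range))
  insects <- withChildSeed(seed, "insects", simulateInsects(config))
  truth <- withChildSeed(seed, "calls",
    simulateCallEmissions(passes, config@call_model, config@p_silent,
                          silent = silent))
  truth <- applyAcousticChannel(truth, passes, config@mic,
                                config@atmosphere,
                                config@call_model@source_level)
  list(config = config, passes = passes, insects = insects, truth = truth,
       recorded = recordedPulses(truth))
}

#' Clip-based end-to-end analysis of a simulated night
#'
#' Renders a short video clip around each pass at the analyzed-frame
#' cadence (every 10th frame of 30 fps, i.e. 3 frames/s), runs the video
#' detection pipeline on each clip on the night's common clock, groups the
#' recorded pulse stream into trigger files, and matches the two event
#' streams.  Rendering only around activity keeps a full night tractable
#' while leaving every detection step identical to processing a
#' continuous stack.
#'
#' @param sim output of \code{\link{simulateNight}}
#' @param night night key
#' @param analyzed_fps analysis cadence, frames per second
#' @param window matching window, s
#' @param render_insects include the insect channel in the clips
#' @return list: video_events, call_files, matches, tally
#' @export
analyzeNightClips <- function(sim, night = "night1", analyzed_fps = 3,
                              window = 30, render_insects = TRUE) {
  cam <- sim$config@camera
  ev_list <- list()
  withChildSeed(sim$config@seed, "noise", {
    for (p in sim$passes) {
      w <- p@waypoints
      times <- seq(w$t[1], w$t[nrow(w)], by = 1 / analyzed_fps)
      if (length(times) < 3) next
      clip <- renderThermalFrames(list(p), cam, times = times,
                                  insects = if (render_insects)
                                    sim$insects else NULL)
      ev <- detectVideoEvents(clip, step = 1, night = night)
      if (nrow(ev)) ev_list[[length(ev_list) + 1]] <- ev
    }
  })
  video_events <- if (length(ev_list)) do.call(rbind, ev_list) else
    emptyEvents()
  if (nrow(video_events)) {
    video_events <- video_events[order(video_events$t_start), , drop = FALSE]
    video_events$event_id <- seq_len(nrow(video_events))
  }
  call_files <- callFileTable(groupPulseFiles(sim$recorded), night = night)
  matches <- matchEvents(video_events, call_files, window = window)
  tally <- nightlyTally(video_events, call_files, matches)
  list(video_events = video_events, call_files = call_files,
       matches = matches, tally = tally)
}

#' Recover the silent-flight fraction from the full pipeline
#'
#' Identifiability experiment: passes at near range on a regular time grid
#' (spacing well beyond twice the matching window, so a silent pass cannot
#' borrow a neighbour's calls), an ideal acoustic channel (every emitted
#' pulse recorded), and the complete video + acoustic + matching pipeline.
#' The proportion of near-range video events with synchronous acoustics
#' estimates (1 - p_silent) * 100.  Silence is assigned by balanced
#' randomization (exactly round(n * p_silent) passes silent, in random
#' order), so the estimate's error reflects the pipeline rather than the
#' binomial noise of the silence draw.
#'
#' @param p_silent silent-pass probability to simulate
#' @param n_passes number of passes
#' @param seed root seed
#' @param spacing_s grid spacing between pass starts, seconds
#' @return list: proportion_pct (near-range synchronous proportion),
#'   n_events (near-range video events), truth_silent_pct (realized
#'   silent share), analysis (full analyzeNightClips output)
#' @export
recoverSilentFraction <- function(p_silent, n_passes = 500, seed = 1,
                                  spacing_s = 90) {
  config <- simConfig(p_silent = p_silent, mic = idealMic(),
                      atmosphere = atmosphereModel(alpha = 0),
                      night_duration = n_passes * spacing_s, seed = seed,
                      insect_rate = 0)
  starts <- spacing_s * (seq_len(n_passes) - 1) + spacing_s / 2
  silent <- withChildSeed(seed, "silence", {
    flags <- rep(FALSE, n_passes)
    flags[sample.int(n_passes, round(n_passes * p_silent))] <- TRUE
    flags
  })
  sim <- simulateNight(config, start_times = starts,
                       depth_range = c(8, 20), silent = silent)
  ana <- analyzeNightClips(sim, render_insects = FALSE)
  ev <- ana$video_events
  near <- ev[ev$proximity == "near", , drop = FALSE]
  syn <- ana$matches$synchronous[match(near$event_id,
                                       ana$matches$event_id)]
  list(proportion_pct = if (nrow(near)) 100 * mean(syn) else NA_real_,
       n_events = nrow(near),
       truth_silent_pct = 100 * mean(truthPasses(sim$truth)$silent),
       analysis = ana)
}

#' Recover the call-structure summary from simulated emissions
#'
#' Simulates vocal passes from the call model, records them through an
#' ideal channel, groups the stream into trigger files, extracts
#' search-phase sequences and summarizes their metrics — the simulation
#' counterpart of characterizing field recordings.
#'
#' @param n_pulses_min stop once at least this many search-phase member
#'   pulses are collected
#' @param seed root seed
#' @param call_model a \code{\link{CallModel}}
#' @return the \code{\link{summarizeCallMetrics}} table
#' @export
recoverCallMetrics <- function(n_pulses_min = 584, seed = 1,
                               call_model = callModel()) {
  config <- simConfig(p_silent = 0, call_model = call_model,
                      mic = idealMic(), atmosphere = atmosphereModel(0),
                      seed = seed, insect_rate = 0)
  seqs <- list()
  total <- 0
  batch <- 0
  while (total < n_pulses_min && batch < 50) {
    batch <- batch + 1
    starts <- 40 * (seq_len(40) - 1)
    cfg <- config
    cfg@seed <- childSeed(seed, paste0("batch", batch))
    sim <- simulateNight(cfg, start_times = starts)
    grouped <- groupPulseFiles(sim$recorded)
    for (g in split(grouped, grouped$file_id)) {
      for (s in extractSearchPhase(g)) {
        seqs[[length(seqs) + 1]] <- s
        total <- total + nrow(s)
      }
    }
  }
  summarizeCallMetrics(seqs)
}
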