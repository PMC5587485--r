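## Classification of tracked video targets: bat vs insect, proximity,
## flight-path type, conspecific interaction, and assembly into events.

PROX_NEAR_M <- 25
PROX_MID_M <- 50

#' Track summary statistics
#'
#' Per-step displacement (px per analyzed frame), headings and turning
#' angles, duration, and median border sharpness.
#'
#' @param track a track data.frame from \code{\link{linkTracks}}
#' @return list of summary statistics
#' @export
trackStats <- function(track) {
  n <- nrow(track)
  dx <- diff(track$col); dy <- diff(-track$row)   # x right, y up
  step_px <- sqrt(dx^2 + dy^2)
  head <- atan2(dy, dx)
  turns <- if (length(head) >= 2) wrapAngle(diff(head)) else numeric(0)
  list(n = n, duration_s = track$t[n] - track$t[1],
       step_px = step_px, headings = head, turns_deg = turns * 180 / pi,
       median_speed_px = if (length(step_px)) stats::median(step_px) else 0,
       median_sharpness = stats::median(track$sharpness))
}

#' Discriminate bat from insect tracks
#'
#' A track is called an insect only when both nuisance signatures are
#' present: blurry borders (median sharpness below \code{s_min}) and fast
#' transit (median angular speed above \code{v_max} px per analyzed
#' frame).  Ties favour the bat call (conservative).
#'
#' @param track a track data.frame
#' @param s_min sharpness threshold
#' @param v_max angular speed threshold, px/analyzed frame
#' @return "bat" or "insect"
#' @export
discriminateBatInsect <- function(track, s_min = 0.4, v_max = 100) {
  st <- trackStats(track)
  if (st$median_sharpness < s_min && st$median_speed_px > v_max)
    "insect" else "bat"
}

#' Apparent-size distance estimate
#'
#' Pinhole inversion d = focal_px * bat_size_m / size_px.  The apparent
#' blob size is first corrected for the optics' edge spread
#' (\code{psf_px} and a fixed scale calibrated against rendered targets
#' of known size at known distance).
#'
#' @param size_px apparent major-axis length, px
#' @param camera a \code{\link{CameraModel}}
#' @return distance in metres (Inf for vanishing size)
#' @export
sizeToDistance <- function(size_px, camera) {
  eff <- pmax(size_px - camera@psf_px, 1e-6)
  focalPx(camera) * camera@bat_size_m / eff
}

#' Classify track proximity from nearest approach
#'
#' Per-blob distances are estimated from apparent size; the event distance
#' is the minimum (nearest approach).  Classes: near <= 25 m, mid (25, 50],
#' far (50, 80]; beyond the camera range the track is out_of_range.
#'
#' @param track a track data.frame
#' @param camera a \code{\link{CameraModel}}
#' @return list(class, distance_m)
#' @export
classifyProximity <- function(track, camera) {
  ok <- track$size_px > 0
  if (!any(ok)) stop("no usable blob sizes on track")
  d <- min(sizeToDistance(track$size_px[ok], camera))
  list(class = proximityClass(d, camera), distance_m = d)
}

# boundary comparisons carry a small tolerance so that a distance computed
# as exactly 25 m (up to floating point) stays in the nearer class
proximityClass <- function(d, camera, eps = 1e-9) {
  if (d <= PROX_NEAR_M * (1 + eps)) "near"
  else if (d <= PROX_MID_M * (1 + eps)) "mid"
  else if (d <= camera@max_range_m * (1 + eps)) "far"
  else "out_of_range"
}

#' Classify flight-path type of a track
#'
#' Erratic: at least two sign reversals among turning angles exceeding
#' 45 degrees.  Straight: net heading change below 30 degrees.  Otherwise
#' curved.  Tracks with fewer than 3 points default to straight (flagged
#' low confidence via attribute).
#'
#' @param track a track data.frame
#' @param straight_deg,reversal_deg thresholds in degrees
#' @return "straight", "curved" or "erratic"
#' @export
classifyFlight <- function(track, straight_deg = 30, reversal_deg = 45) {
  st <- trackStats(track)
  if (st$n < 3) {
    out <- "straight"
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  if (countReversals(st$turns_deg, reversal_deg) >= 2) return("erratic")
  net <- abs(sum(st$turns_deg))
  if (net < straight_deg) "straight" else "curved"
}

# number of sign alternations among turning angles larger than the
# reversal threshold
countReversals <- function(turns_deg, reversal_deg) {
  big <- turns_deg[abs(turns_deg) > reversal_deg]
  if (length(big) < 2) return(0L)
  sum(diff(sign(big)) != 0)
}

# 3D position estimates along a track (image unprojection through the
# apparent-size range estimate).
trackPositions <- function(track, camera) {
  f <- focalPx(camera)
  d <- sizeToDistance(pmax(track$size_px, 1e-6), camera)
  x <- (track$col - camera@width_px / 2) * d / f
  z <- (camera@height_px / 2 - track$row) * d / f
  y <- sqrt(pmax(d^2 - x^2 - z^2, 0.01))
  data.frame(t = track$t, x = x, y = y, z = z)
}

#' Classify the interaction of concurrent tracks
#'
#' Agonistic: the minimum inter-bat distance falls below
#' \code{agonistic_m} metres while both tracks are non-straight during the
#' overlap (sharp turns and chases).  Otherwise noninteracting.  A single
#' track yields "none".
#'
#' @param tracks list of track data.frames overlapping in time
#' @param camera a \code{\link{CameraModel}}
#' @param agonistic_m distance threshold, metres
#' @return "none", "noninteracting" or "agonistic"
#' @export
classifyInteraction <- function(tracks, camera, agonistic_m = 3) {
  if (length(tracks) < 2) return("none")
  for (i in seq_len(length(tracks) - 1)) for (j in (i + 1):length(tracks)) {
    a <- tracks[[i]]; b <- tracks[[j]]
    t0 <- max(a$t[1], b$t[1]); t1 <- min(a$t[nrow(a)], b$t[nrow(b)])
    if (t1 <= t0) next
    pa <- trackPositions(a, camera); pb <- trackPositions(b, camera)
    tt <- seq(t0, t1, length.out = 20)
    dx <- stats::approx(pa$t, pa$x, tt)$y - stats::approx(pb$t, pb$x, tt)$y
    dy <- stats::approx(pa$t, pa$y, tt)$y - stats::approx(pb$t, pb$y, tt)$y
    dz <- stats::approx(pa$t, pa$z, tt)$y - stats::approx(pb$t, pb$z, tt)$y
    mind <- min(sqrt(dx^2 + dy^2 + dz^2))
    if (mind < agonistic_m &&
        classifyFlight(a) != "straight" && classifyFlight(b) != "straight")
      return("agonistic")
  }
  "noninteracting"
}

#' Assemble tracks into video events
#'
#' Temporally overlapping bat tracks merge into one multi-bat event (a
#' single visual detection); the event's proximity is its overall nearest
#' approach, the flight class comes from the longest member track, and
#' interaction is assessed over concurrent members.  Out-of-range events
#' are dropped.
#'
#' @param tracks list of track data.frames (bat tracks)
#' @param camera a \code{\link{CameraModel}}
#' @param night night key attached to each event
#' @return data.frame: event_id, night, t_start, t_end, proximity,
#'   distance_m, flight, n_bats, interaction
#' @export
buildVideoEvents <- function(tracks, camera, night = "night1") {
  if (!length(tracks)) return(emptyEvents())
  spans <- t(vapply(tracks, function(tr) range(tr$t), numeric(2)))
  ord <- order(spans[, 1])
  tracks <- tracks[ord]; spans <- spans[ord, , drop = FALSE]
  # group tracks whose time spans overlap (chained)
  grp <- integer(length(tracks)); g <- 0L; gend <- -Inf
  for (i in seq_along(tracks)) {
    if (spans[i, 1] > gend) { g <- g + 1L; gend <- spans[i, 2] }
    else gend <- max(gend, spans[i, 2])
    grp[i] <- g
  }
  rows <- lapply(seq_len(g), function(e) {
    mem <- tracks[grp == e]
    prox <- lapply(mem, classifyProximity, camera = camera)
    d <- min(vapply(prox, function(p) p$distance_m, 0))
    cls <- proximityClass(d, camera)
    main <- mem[[which.max(vapply(mem, nrow, 0L))]]
    data.frame(event_id = e, night = night,
               t_start = min(vapply(mem, function(x) x$t[1], 0)),
               t_end = max(vapply(mem, function(x) x$t[nrow(x)], 0)),
               proximity = cls, distance_m = d,
               flight = as.character(classifyFlight(main)),
               n_bats = length(mem),
               interaction = if (length(mem) >= 2)
                 classifyInteraction(mem, camera) else "none")
  })
  ev <- do.call(rbind, rows)
  ev <- ev[ev$proximity != "out_of_range", , drop = FALSE]
  ev$event_id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev
}

emptyEvents <- function() {
  data.frame(event_id = integer(), night = character(), t_start = numeric(),
             t_end = numeric(), proximity = character(),
             distance_m = numeric(), flight = character(),
             n_bats = integer(), interaction = character())
}

#' Full video detection pipeline
#'
#' Subsamples the stack, builds the background model, detects and links
#' blobs, removes insect-signature tracks and assembles video events.
#'
#' @param frames a \code{\link{FrameSequence}} (full frame rate)
#' @param step analyze every step-th frame
#' @param night night key for the events
#' @param gate_px tracking gate, px per analyzed frame; the pipeline
#'   default (200) accommodates near-range bats, which at 7 m/s and
#'   8-15 m distance subtend well over 100 px per analyzed frame
#' @return data.frame of video events (see \code{\link{buildVideoEvents}})
#' @export
detectVideoEvents <- function(frames, step = 10, night = "night1",
                              gate_px = 200) {
  analyzed <- subsampleFrames(frames, step)
  blobs <- detectAllBlobs(analyzed)
  tracks <- linkTracks(blobs, gate_px = gate_px)
  bats <- tracks[vapply(tracks, discriminateBatInsect, "") == "bat"]
  buildVideoEvents(bats, frames@camera, night = night)
}
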