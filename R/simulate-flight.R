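## Synthetic flight-path generation.
##
## Passes are generated in a camera-centred world frame (origin at the
## camera, optical axis +y, x right, z up, metres).  Each pass is anchored
## at a closest-approach point drawn inside the camera frustum and follows
## one of three trajectory archetypes seen in field video review:
##   straight - constant heading segment
##   curved   - single circular arc, 30-180 degrees of one-signed turn
##   erratic  - piecewise segments with >= 2 heading reversals > 45 degrees

FLIGHT_TYPES <- c("straight", "curved", "erratic")

#' Simulate bat flight passes for one night
#'
#' Draws a Poisson number of passes (mean \code{pass_rate * night_duration})
#' and assigns each a trajectory type according to \code{flight_mix}.
#' Trajectories pass through the camera frustum; waypoints are sampled at
#' the camera frame rate.
#'
#' @param config a \code{\link{SimConfig}}
#' @param start_times optional vector of pass start times (seconds); when
#'   given, overrides the Poisson draw (used for identifiability
#'   experiments that need temporally separated passes)
#' @param depth_range closest-approach distance range, metres
#' @return list of \code{\link{BatPass}} objects, ordered by start time
#' @export
simulateFlightPaths <- function(config, start_times = NULL,
                                depth_range = c(5, 70)) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (is.null(start_times)) {
    n <- stats::rpois(1, config@pass_rate * config@night_duration / 3600)
    start_times <- sort(stats::runif(n, 0, config@night_duration))
  }
  n <- length(start_times)
  if (n == 0) return(list())
  types <- sample(FLIGHT_TYPES, n, replace = TRUE, prob = config@flight_mix)
  lapply(seq_len(n), function(i)
    makePass(i, types[i], start_times[i], config@camera, config@speed_mps,
             depth_range))
}

# Build one pass of the given type anchored inside the frustum.
makePass <- function(id, type, t0, camera, speed, depth_range) {
  f <- focalPx(camera)
  d0 <- stats::runif(1, depth_range[1], depth_range[2])
  halfw <- d0 * (camera@width_px / 2) / f
  halfh <- d0 * (camera@height_px / 2) / f
  anchor <- c(x = stats::runif(1, -0.6, 0.6) * halfw, y = d0,
              z = stats::runif(1, -0.5, 0.5) * halfh)
  dt <- 1 / camera@frame_rate
  xyz <- switch(type,
    straight = straightPath(anchor, speed, halfw, dt),
    curved   = curvedPath(anchor, speed, dt),
    erratic  = erraticPath(anchor, speed, dt))
  w <- data.frame(t = t0 + dt * (seq_len(nrow(xyz)) - 1),
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  new("BatPass", pass_id = as.integer(id), trajectory_type = type,
      waypoints = w, speed = speed)
}

straightPath <- function(anchor, speed, halfw, dt) {
  phi <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(phi), sin(phi), stats::runif(1, -0.05, 0.05))
  u <- u / sqrt(sum(u^2))
  dur <- min(6, max(1.5, (2 * halfw + 4) / speed))
  s <- speed * (seq(0, dur, by = dt) - dur / 2)
  cbind(anchor[1] + u[1] * s, anchor[2] + u[2] * s, anchor[3] + u[3] * s)
}

curvedPath <- function(anchor, speed, dt) {
  r <- stats::runif(1, 5, 15)
  dpsi <- stats::runif(1, 30, 180) * pi / 180 * sample(c(-1, 1), 1)
  dur <- min(6, max(1.5, abs(dpsi) * r / speed))
  phi0 <- stats::runif(1, 0, 2 * pi)
  tt <- seq(0, dur, by = dt)
  ang <- phi0 + sign(dpsi) * speed * (tt - dur / 2) / r
  ctr <- c(anchor[1] - r * cos(phi0), anchor[2] - r * sin(phi0))
  cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang),
        anchor[3] + stats::runif(1, -0.2, 0.2) * tt)
}

erraticPath <- function(anchor, speed, dt) {
  nseg <- sample(4:7, 1)
  segdur <- stats::runif(nseg, 0.4, 0.8)
  # alternate-signed large turns guarantee >= 2 heading reversals > 45 deg
  turns <- stats::runif(nseg - 1, 50, 120) * pi / 180 *
    rep_len(c(1, -1), nseg - 1) * sample(c(-1, 1), 1)
  phi <- stats::runif(1, 0, 2 * pi)
  pos <- c(anchor[1], anchor[2], anchor[3])
  out <- list()
  for (k in seq_len(nseg)) {
    u <- c(cos(phi), sin(phi), stats::runif(1, -0.05, 0.05))
    u <- u / sqrt(sum(u^2))
    s <- speed * seq(dt, segdur[k], by = dt)
    seg <- cbind(pos[1] + u[1] * s, pos[2] + u[2] * s, pos[3] + u[3] * s)
    out[[k]] <- seg
    pos <- seg[nrow(seg), ]
    if (k < nseg) phi <- phi + turns[k]
  }
  xyz <- do.call(rbind, out)
  # recentre so the midpoint sits at the anchor (keeps the pass in frustum)
  mid <- xyz[ceiling(nrow(xyz) / 2), ]
  sweep(xyz, 2, mid - anchor)
}

#' Simulate nuisance insect targets
#'
#' Insects are modelled directly in image space as small, blurred, fast
#' transients: a Gaussian spot of random width and modest contrast crossing
#' the frame at high angular speed.
#'
#' @param config a \code{\link{SimConfig}}
#' @return data.frame: insect_id, t0, duration_s, row0, col0, vrow, vcol
#'   (px/s), sigma_px, contrast
#' @export
simulateInsects <- function(config) {
  n <- stats::rpois(1, config@insect_rate * config@night_duration / 3600)
  cam <- config@camera
  if (n == 0)
    return(data.frame(insect_id = integer(), t0 = numeric(),
                      duration_s = numeric(), row0 = numeric(),
                      col0 = numeric(), vrow = numeric(), vcol = numeric(),
                      sigma_px = numeric(), contrast = numeric()))
  ang <- stats::runif(n, 0, 2 * pi)
  spd <- stats::runif(n, 300, 700)        # px/s: 100-230 px per analyzed frame
  # two nuisance populations: distant specks (tiny, removed by the size
  # filter) and close out-of-focus insects (larger, blurred, fast)
  close_by <- stats::runif(n) < 0.5
  data.frame(insect_id = seq_len(n),
             t0 = stats::runif(n, 0, config@night_duration),
             duration_s = stats::runif(n, 0.5, 2),
             row0 = stats::runif(n, 0, cam@height_px - 1),
             col0 = stats::runif(n, 0, cam@width_px - 1),
             vrow = spd * sin(ang), vcol = spd * cos(ang),
             sigma_px = ifelse(close_by, stats::runif(n, 2, 3.5),
                               stats::runif(n, 0.6, 1.6)),
             contrast = ifelse(close_by, stats::runif(n, 0.12, 0.20),
                               stats::runif(n, 0.05, 0.10)))
}
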