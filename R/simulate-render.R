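## Thermal-frame rendering of simulated passes.
##
## Radiometry is deliberately simple: a uniform warm background with
## additive Gaussian sensor noise, bats as bright sharp-edged ellipses
## whose pixel extent follows the pinhole projection of a characteristic
## body size, and insects as small blurred Gaussian spots.  Targets beyond
## the camera's consistent detection range are rendered below the
## detection threshold.

BG_LEVEL <- 0.2
NOISE_SD <- 0.01
BAT_CONTRAST <- 0.25
OUT_OF_RANGE_CONTRAST <- 0.02
BAT_ASPECT <- 0.55      # minor/major axis ratio of the rendered ellipse
BAT_EDGE_PX <- 0.3      # logistic edge width of the optics, pixels

#' Render simulated passes into a thermal frame stack
#'
#' @param passes list of \code{\link{BatPass}} objects (may be empty)
#' @param camera a \code{\link{CameraModel}}
#' @param times frame timestamps (s); default: the span of the passes at
#'   the camera frame rate
#' @param insects optional data.frame from \code{\link{simulateInsects}}
#' @param t_range time range to render when \code{times} is NULL and
#'   \code{passes} is empty
#' @param bg,noise_sd background level and sensor noise SD (intensity units
#'   in [0,1])
#' @return a \code{\link{FrameSequence}}
#' @export
renderThermalFrames <- function(passes, camera = cameraModel(), times = NULL,
                                insects = NULL, t_range = NULL,
                                bg = BG_LEVEL, noise_sd = NOISE_SD) {
  if (is.null(times)) {
    if (length(passes)) {
      span <- range(unlist(lapply(passes, function(p)
        range(p@waypoints$t))))
    } else if (!is.null(t_range)) {
      span <- t_range
    } else stop("need passes, times or t_range")
    times <- seq(span[1], span[2], by = 1 / camera@frame_rate)
  }
  h <- camera@height_px; w <- camera@width_px
  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    fr <- matrix(bg + stats::rnorm(h * w, sd = noise_sd), nrow = h)
    for (p in passes) fr <- paintBat(fr, p, times[i], camera)
    if (!is.null(insects) && nrow(insects))
      fr <- paintInsects(fr, insects, times[i])
    frames[[i]] <- pmin(fr, 1)
  }
  FrameSequence(frames, times, camera)
}

# Add one bat to a frame if its pass is active at time t.
paintBat <- function(fr, pass, t, camera) {
  w <- pass@waypoints
  if (t < w$t[1] || t > w$t[nrow(w)]) return(fr)
  pos <- passPosition(pass, t)
  if (pos["y"] <= 0.5) return(fr)
  d <- sqrt(sum(pos^2))
  f <- focalPx(camera)
  major <- f * camera@bat_size_m / d
  ctr <- projectPoint(pos["x"], pos["y"], pos["z"], camera)
  if (any(is.na(ctr))) return(fr)
  contrast <- if (d <= camera@max_range_m) BAT_CONTRAST else
    OUT_OF_RANGE_CONTRAST
  # orientation from image velocity
  pos2 <- passPosition(pass, t + 0.05)
  ctr2 <- projectPoint(pos2["x"], pos2["y"], pos2["z"], camera)
  dvec <- ctr2 - ctr
  if (any(is.na(dvec)) || sum(dvec^2) < 1e-12) dvec <- c(0, 1)
  dvec <- dvec / sqrt(sum(dvec^2))
  paintEllipse(fr, ctr[1], ctr[2], major / 2, BAT_ASPECT * major / 2,
               dvec, contrast)
}

paintEllipse <- function(fr, r0, c0, a, b, dvec, contrast) {
  h <- nrow(fr); w <- ncol(fr)
  ext <- ceiling(a) + 3
  rlo <- max(1, floor(r0 + 1 - ext)); rhi <- min(h, ceiling(r0 + 1 + ext))
  clo <- max(1, floor(c0 + 1 - ext)); chi <- min(w, ceiling(c0 + 1 + ext))
  if (rlo > rhi || clo > chi) return(fr)
  rows <- rlo:rhi; cols <- clo:chi
  dr <- rows - 1 - r0
  dc <- cols - 1 - c0
  # components along (dvec) and across the motion direction
  along <- outer(dr, dc, function(R, C) R * dvec[1] + C * dvec[2])
  across <- outer(dr, dc, function(R, C) -R * dvec[2] + C * dvec[1])
  rho <- sqrt((along / a)^2 + (across / b)^2)
  # distance (px) outside the ellipse boundary, approximately (rho - 1) * b
  edge_px <- (rho - 1) * b
  fr[rows, cols] <- fr[rows, cols] +
    contrast * stats::plogis(-edge_px / BAT_EDGE_PX)
  fr
}

paintInsects <- function(fr, insects, t) {
  h <- nrow(fr); w <- ncol(fr)
  act <- insects[t >= insects$t0 & t <= insects$t0 + insects$duration_s, ,
                 drop = FALSE]
  for (k in seq_len(nrow(act))) {
    r0 <- act$row0[k] + act$vrow[k] * (t - act$t0[k])
    c0 <- act$col0[k] + act$vcol[k] * (t - act$t0[k])
    if (r0 < -5 || r0 > h + 5 || c0 < -5 || c0 > w + 5) next
    ext <- ceiling(3 * act$sigma_px[k])
    rlo <- max(1, floor(r0 + 1 - ext)); rhi <- min(h, ceiling(r0 + 1 + ext))
    clo <- max(1, floor(c0 + 1 - ext)); chi <- min(w, ceiling(c0 + 1 + ext))
    if (rlo > rhi || clo > chi) next
    rows <- rlo:rhi; cols <- clo:chi
    d2 <- outer((rows - 1 - r0)^2, (cols - 1 - c0)^2, "+")
    fr[rows, cols] <- fr[rows, cols] +
      act$contrast[k] * exp(-d2 / (2 * act$sigma_px[k]^2))
  }
  fr
}
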