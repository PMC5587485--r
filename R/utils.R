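## Internal helpers shared across modules.

# Deterministic child seed derived from a root seed and a label, so that
# flight, call, channel and noise streams are independently reproducible.
childSeed <- function(root, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(root) * 48271 + h * 16807) %% 2147483647)
}

withChildSeed <- function(root, label, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(childSeed(root, label))
  force(expr)
}

# Round half away from zero (the printing convention for table percentages;
# base round() rounds half to even).
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Lognormal parameters moment-matched to a given mean and SD.
lognormalPars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Project a world point (camera at origin, +y optical axis, z up) to pixel
# coordinates (0-based, origin top-left).  Returns c(row, col) or NA if the
# point is behind the camera.
projectPoint <- function(x, y, z, camera) {
  if (y <= 0) return(c(NA_real_, NA_real_))
  f <- focalPx(camera)
  col <- camera@width_px / 2 + f * x / y
  row <- camera@height_px / 2 - f * z / y
  c(row = row, col = col)
}

# Is a world point inside the camera frustum (ignoring max range)?
inFrustum <- function(x, y, z, camera, margin = 0) {
  if (y <= 0) return(FALSE)
  f <- focalPx(camera)
  halfw <- y * (camera@width_px / 2 - margin) / f
  halfh <- y * (camera@height_px / 2 - margin) / f
  abs(x) <= halfw && abs(z) <= halfh
}

# Linear interpolation of a pass position at time t.
passPosition <- function(pass, t) {
  w <- pass@waypoints
  c(x = stats::approx(w$t, w$x, t, rule = 2)$y,
    y = stats::approx(w$t, w$y, t, rule = 2)$y,
    z = stats::approx(w$t, w$z, t, rule = 2)$y)
}

# Heading (unit velocity vector) of a pass at time t.
passHeading <- function(pass, t) {
  w <- pass@waypoints
  i <- findInterval(t, w$t, all.inside = TRUE)
  v <- c(w$x[i + 1] - w$x[i], w$y[i + 1] - w$y[i], w$z[i + 1] - w$z[i])
  n <- sqrt(sum(v^2))
  if (n == 0) c(0, 1, 0) else v / n
}

wrapAngle <- function(a) ((a + pi) %% (2 * pi)) - pi
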