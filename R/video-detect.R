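## Video target detection: frame subsampling, background subtraction,
## blob extraction and track linking.

#' Subsample a frame stack for analysis
#'
#' Retains every \code{step}-th frame (indices 0, step, 2*step, ... in
#' 0-based terms), preserving timestamps.  At 30 fps and the default
#' step of 10 this yields 3 analyzed frames per second, so a target seen
#' in two consecutive analyzed frames spans at least 0.3 s.
#'
#' @param frames a \code{\link{FrameSequence}}
#' @param step keep every step-th frame (>= 1)
#' @return a \code{\link{FrameSequence}} of the analyzed frames
#' @export
subsampleFrames <- function(frames, step = 10) {
  stopifnot(step >= 1)
  idx <- seq(1, length.out = max(0, nFrames(frames)))
  keep <- idx[(idx - 1) %% step == 0]
  FrameSequence(frames@frames[keep], frames@times[keep], frames@camera)
}

#' Rolling-median background model
#'
#' Per-pixel temporal median over a window of analyzed frames, with a
#' pooled robust (MAD-based) noise scale.  Moving targets occupy any
#' pixel only briefly, so the temporal median converges to the static
#' background.
#'
#' @param frames a \code{\link{FrameSequence}} of analyzed frames
#' @param window number of analyzed frames in the rolling window
#' @return list with matrix \code{median} and scalar \code{sd}
#' @export
backgroundModel <- function(frames, window = 90) {
  n <- nFrames(frames)
  stopifnot(n >= 1)
  use <- seq_len(min(n, window))
  stack <- matrix(unlist(frames@frames[use], use.names = FALSE),
                  ncol = length(use))
  med <- matrixStats::rowMedians(stack)
  # pooled robust noise scale: MAD of the residuals on a pixel subsample
  # (the sensor noise is spatially homogeneous; pooling is far more stable
  # than a per-pixel MAD over a short window)
  sub <- seq(1, nrow(stack), length.out = min(20000, nrow(stack)))
  sdv <- max(1e-4, stats::mad(stack[sub, ] - med[sub]))
  h <- frames@camera@height_px
  list(median = matrix(med, nrow = h), sd = sdv)
}

#' Detect above-background blobs in one frame
#'
#' Pixels exceeding background + \code{k_sigma} robust SDs are grouped by
#' 8-connectivity; components smaller than \code{min_area} pixels (default
#' 5, the small-target size filter) are discarded.  For each retained blob
#' the centroid, area, major-axis length and a border-sharpness statistic
#' (mean boundary step / blob contrast) are computed.
#'
#' @param frame numeric matrix
#' @param background list from \code{\link{backgroundModel}}
#' @param k_sigma detection threshold in robust SDs
#' @param min_area minimum contiguous pixels (absolute filter)
#' @return data.frame: blob_id, area_px, row, col, size_px, sharpness
#' @export
detectBlobs <- function(frame, background, k_sigma = 4, min_area = 5) {
  if (!identical(dim(frame), dim(background$median)))
    stop("frame and background dimensions differ")
  mask <- frame > background$median + k_sigma * background$sd
  if (!any(mask)) return(emptyBlobs())
  labm <- label8(mask)
  areas <- tabulate(labm[labm > 0])
  keep <- which(areas >= min_area)
  if (!length(keep)) return(emptyBlobs())
  hot <- which(labm > 0, arr.ind = TRUE)
  hot_id <- labm[hot]
  res <- lapply(seq_along(keep), function(j) {
    id <- keep[j]
    blobFeatures(frame, background$median,
                 hot[hot_id == id, , drop = FALSE], labm, id, j)
  })
  do.call(rbind, res)
}

# 8-connected component labelling of a sparse logical mask.  Hot pixels
# are indexed in a hash of linear indices and grown breadth-first over
# their 8-neighbourhoods; returns an integer label matrix (0 background).
label8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lin <- which(mask)
  labm <- matrix(0L, h, w)
  if (!length(lin)) return(labm)
  lab_of <- integer(length(lin))
  pos <- match(seq_len(h * w), lin)   # linear index -> hot rank (NA if cold)
  rowi <- (lin - 1L) %% h + 1L
  coli <- (lin - 1L) %/% h + 1L
  offs <- c(-1L, 1L, -h, h, -h - 1L, -h + 1L, h - 1L, h + 1L)
  cur <- 0L
  queue <- integer(length(lin))
  for (s in seq_along(lin)) {
    if (lab_of[s] > 0L) next
    cur <- cur + 1L
    queue[1] <- s
    head <- 1L; tail <- 1L
    lab_of[s] <- cur
    while (head <= tail) {
      i <- queue[head]; head <- head + 1L
      r <- rowi[i]
      for (o in offs) {
        # guard against row wrap-around at matrix edges
        j <- lin[i] + o
        if (j < 1L || j > h * w) next
        jr <- (j - 1L) %% h + 1L
        if (abs(jr - r) > 1L) next
        k <- pos[j]
        if (!is.na(k) && lab_of[k] == 0L) {
          lab_of[k] <- cur
          tail <- tail + 1L
          queue[tail] <- k
        }
      }
    }
  }
  labm[lin] <- lab_of
  labm
}

emptyBlobs <- function() {
  data.frame(blob_id = integer(), area_px = integer(), row = numeric(),
             col = numeric(), size_px = numeric(), sharpness = numeric())
}

# Features of one connected component: centroid and major axis from image
# moments, border sharpness from boundary steps relative to blob contrast.
blobFeatures <- function(frame, bgmed, idx, labm, lab_id, id) {
  rows <- idx[, 1]; cols <- idx[, 2]
  r0 <- mean(rows); c0 <- mean(cols)
  # second moments -> major axis length (4 sigma of the pixel distribution,
  # the full extent of an equivalent filled ellipse)
  crr <- mean((rows - r0)^2); ccc <- mean((cols - c0)^2)
  crc <- mean((rows - r0) * (cols - c0))
  eig <- (crr + ccc) / 2 + sqrt(((crr - ccc) / 2)^2 + crc^2)
  major <- 4 * sqrt(max(eig, 0) + 1 / 12)  # + pixel-sampling variance
  vals <- frame[idx]
  contrast <- max(vals) - stats::median(bgmed[idx])
  # border sharpness: intensity drop from just inside to just outside the
  # boundary, relative to the blob contrast, over all boundary pixels.
  # Work on a 1-px-padded crop of the blob's bounding box.
  h <- nrow(frame); w <- ncol(frame)
  rr <- max(1, min(rows) - 1):min(h, max(rows) + 1)
  cc <- max(1, min(cols) - 1):min(w, max(cols) + 1)
  M <- frame[rr, cc, drop = FALSE]
  S <- labm[rr, cc, drop = FALSE] == lab_id
  nr <- nrow(M); nc <- ncol(M)
  in_val <- ifelse(S, M, -Inf)
  out_val <- ifelse(S, Inf, M)
  shift <- function(x, dr, dc, fill) {
    y <- matrix(fill, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    y[okr, okc] <- x[rs[okr], cs[okc]]
    y
  }
  in_max <- pmax(shift(in_val, -1, 0, -Inf), shift(in_val, 1, 0, -Inf),
                 shift(in_val, 0, -1, -Inf), shift(in_val, 0, 1, -Inf),
                 ifelse(S, M, -Inf))
  out_min <- pmin(shift(out_val, -1, 0, Inf), shift(out_val, 1, 0, Inf),
                  shift(out_val, 0, -1, Inf), shift(out_val, 0, 1, Inf))
  boundary <- S & is.finite(out_min)
  steps <- (in_max - out_min)[boundary]
  sharp <- if (length(steps) && contrast > 0)
    stats::median(steps) / contrast else 0
  data.frame(blob_id = id, area_px = nrow(idx), row = r0 - 1, col = c0 - 1,
             size_px = major, sharpness = sharp)
}

#' Detect blobs across an analyzed frame stack
#'
#' Convenience wrapper: builds the background model and runs
#' \code{\link{detectBlobs}} on every analyzed frame.
#'
#' @param frames a \code{\link{FrameSequence}} of analyzed frames
#' @param ... passed to \code{\link{detectBlobs}}
#' @return data.frame of blobs with columns frame_idx and t prepended
#' @export
detectAllBlobs <- function(frames, ...) {
  bgm <- backgroundModel(frames)
  out <- lapply(seq_len(nFrames(frames)), function(i) {
    b <- detectBlobs(getFrame(frames, i), bgm, ...)
    if (nrow(b)) cbind(frame_idx = i, t = frames@times[i], b) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(cbind(frame_idx = integer(), t = numeric(),
                                 emptyBlobs()))
  do.call(rbind, out)
}

#' Link blobs across analyzed frames into tracks
#'
#' Greedy nearest-neighbour association within a displacement gate; one
#' skipped analyzed frame is tolerated (with a proportionally larger
#' gate).  Tracks spanning at least \code{min_frames} analyzed frames are
#' returned; at the default analysis cadence (3 frames/s) two analyzed
#' frames correspond to >= 0.3 s.
#'
#' @param blobs data.frame from \code{\link{detectAllBlobs}}
#' @param gate_px maximum displacement per analyzed frame, pixels
#' @param min_frames minimum analyzed frames per track
#' @return list of track data.frames (columns as blobs)
#' @export
linkTracks <- function(blobs, gate_px = 60, min_frames = 2) {
  if (!nrow(blobs)) return(list())
  frames_idx <- sort(unique(blobs$frame_idx))
  open <- list()    # each: list(rows = data.frame, last_idx)
  done <- list()
  for (fi in frames_idx) {
    cur <- blobs[blobs$frame_idx == fi, , drop = FALSE]
    taken <- rep(FALSE, nrow(cur))
    still <- rep(FALSE, length(open))
    for (j in seq_along(open)) {
      tr <- open[[j]]
      lag <- fi - tr$last_idx
      if (lag > 2) next       # > one skipped frame: track ends
      still[j] <- TRUE
      if (!nrow(cur)) next
      last <- tr$rows[nrow(tr$rows), ]
      d <- sqrt((cur$row - last$row)^2 + (cur$col - last$col)^2)
      d[taken] <- Inf
      best <- which.min(d)
      if (length(best) && is.finite(d[best]) && d[best] <= gate_px * lag) {
        open[[j]]$rows <- rbind(tr$rows, cur[best, ])
        open[[j]]$last_idx <- fi
        taken[best] <- TRUE
      }
    }
    done <- c(done, lapply(open[!still], function(tr) tr$rows))
    open <- open[still]
    for (k in which(!taken))
      open[[length(open) + 1]] <- list(rows = cur[k, , drop = FALSE],
                                       last_idx = fi)
  }
  done <- c(done, lapply(open, function(tr) tr$rows))
  done <- lapply(done, function(d) { rownames(d) <- NULL; d })
  done[vapply(done, nrow, 0L) >= min_frames]
}
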