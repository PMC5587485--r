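## Time-synchronization of the video and acoustic event streams, and the
## per-night correspondence tallies.

#' Match video events with acoustic call files
#'
#' A video event is synchronous when at least one call file starts within
#' \code{window} seconds (two-sided) of the event's start time.  Each
#' video event is evaluated independently; a call file may match several
#' events.  \code{delta_t} is the signed offset (call - video) of the
#' nearest match.
#'
#' @param video_events data.frame with event_id, night, t_start
#' @param call_files data.frame with file_id, night, t_start
#' @param window matching window, seconds
#' @return data.frame: event_id, night, synchronous, n_matches, delta_t,
#'   matched_files (comma-separated ids)
#' @export
matchEvents <- function(video_events, call_files, window = 30) {
  stopifnot(window > 0)
  video_events <- video_events[order(video_events$night,
                                     video_events$t_start), , drop = FALSE]
  rows <- lapply(seq_len(nrow(video_events)), function(i) {
    ev <- video_events[i, ]
    cf <- call_files[call_files$night == ev$night, , drop = FALSE]
    dt <- cf$t_start - ev$t_start
    hit <- abs(dt) <= window
    data.frame(event_id = ev$event_id, night = ev$night,
               synchronous = any(hit), n_matches = sum(hit),
               delta_t = if (any(hit)) dt[hit][which.min(abs(dt[hit]))]
                 else NA_real_,
               matched_files = paste(cf$file_id[hit], collapse = ","))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median absolute synchronization offset
#'
#' Diagnostic for clock agreement between the two sensors: the median of
#' |delta_t| over matched events.
#'
#' @param matches data.frame from \code{\link{matchEvents}}
#' @return median absolute offset, seconds (NA when nothing matched)
#' @export
offsetDiagnostics <- function(matches) {
  d <- abs(matches$delta_t[matches$synchronous])
  if (!length(d)) return(NA_real_)
  stats::median(d)
}

#' Nightly correspondence tally
#'
#' Per night: number of call files (acoustic_n), number of video events
#' (visual_n), number of video events with a synchronous acoustic match
#' (synchronous_n), and the proportion 100 * synchronous_n / visual_n
#' (NA when visual_n is 0).
#'
#' @param video_events data.frame with event_id, night
#' @param call_files data.frame with file_id, night
#' @param matches data.frame from \code{\link{matchEvents}}
#' @param append_summary append "Total" and "Average" rows (the printed
#'   table layout)
#' @return data.frame: night, acoustic_n, visual_n, synchronous_n,
#'   proportion_pct
#' @export
nightlyTally <- function(video_events, call_files, matches,
                         append_summary = FALSE) {
  nights <- sort(unique(c(video_events$night, call_files$night)))
  rows <- lapply(nights, function(nk) {
    vis <- sum(video_events$night == nk)
    syn <- sum(matches$synchronous[matches$night == nk])
    data.frame(night = nk,
               acoustic_n = sum(call_files$night == nk),
               visual_n = vis, synchronous_n = syn,
               proportion_pct = if (vis > 0) 100 * syn / vis else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (append_summary && nrow(out)) {
    tot <- data.frame(night = "Total",
                      acoustic_n = sum(out$acoustic_n),
                      visual_n = sum(out$visual_n),
                      synchronous_n = sum(out$synchronous_n),
                      proportion_pct = NA_real_)
    avg <- data.frame(night = "Average",
                      acoustic_n = mean(out$acoustic_n),
                      visual_n = mean(out$visual_n),
                      synchronous_n = mean(out$synchronous_n),
                      proportion_pct =
                        mean(out$proportion_pct, na.rm = TRUE))
    out <- rbind(out, tot, avg)
  }
  rownames(out) <- NULL
  out
}
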