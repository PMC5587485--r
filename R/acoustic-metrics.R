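## Call-file grouping, call-structure metrics, search-phase extraction and
## call-type classification.

#' Group a pulse stream into trigger files
#'
#' Emulates the recorder's trigger logic: a file opens at a triggering
#' pulse, stays open while inter-pulse gaps are shorter than the trigger
#' window (2.0 s), and closes after that much quiet or when the file
#' reaches its maximum length (15 s); the next pulse opens a new file.
#'
#' @param pulses data.frame with at least an \code{onset} column (s),
#'   time-ordered (sorted internally)
#' @param config from \code{\link{detectorConfig}}
#' @return the pulse table with a \code{file_id} column prepended
#' @export
groupPulseFiles <- function(pulses, config = detectorConfig()) {
  if (!nrow(pulses)) return(cbind(file_id = integer(), pulses))
  pulses <- pulses[order(pulses$onset), , drop = FALSE]
  fid <- integer(nrow(pulses))
  cur <- 1L; t_open <- pulses$onset[1]
  fid[1] <- cur
  for (k in seq_len(nrow(pulses))[-1]) {
    gap <- pulses$onset[k] - pulses$onset[k - 1]
    if (gap >= config$trigger_window_s ||
        pulses$onset[k] - t_open > config$max_file_len_s) {
      cur <- cur + 1L
      t_open <- pulses$onset[k]
    }
    fid[k] <- cur
  }
  out <- cbind(file_id = fid, pulses)
  rownames(out) <- NULL
  out
}

#' Summarize grouped pulses into a call-file table
#'
#' @param grouped output of \code{\link{groupPulseFiles}}
#' @param night night key
#' @return data.frame: file_id, night, t_start, n_pulses, search,
#'   terminal, social (logical flags)
#' @export
callFileTable <- function(grouped, night = "night1") {
  if (!nrow(grouped))
    return(data.frame(file_id = integer(), night = character(),
                      t_start = numeric(), n_pulses = integer(),
                      search = logical(), terminal = logical(),
                      social = logical()))
  rows <- lapply(split(grouped, grouped$file_id), function(g) {
    fl <- classifyCallType(g)
    data.frame(file_id = g$file_id[1], night = night,
               t_start = min(g$onset), n_pulses = nrow(g),
               search = "search" %in% fl, terminal = "terminal" %in% fl,
               social = "social" %in% fl)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-pulse spectral metrics
#'
#' Bandwidth is the frequency sweep extent (fmax - fmin, kHz); modulation
#' is the bandwidth as a percentage of the maximum (start) frequency.
#'
#' @param pulses data.frame with fmin_khz and fmax_khz
#' @return the table with bandwidth_khz and modulation_pct appended
#' @export
computePulseMetrics <- function(pulses) {
  if (any(pulses$fmax_khz <= 0)) stop("fmax must be positive")
  pulses$bandwidth_khz <- pulses$fmax_khz - pulses$fmin_khz
  pulses$modulation_pct <- 100 * pulses$bandwidth_khz / pulses$fmax_khz
  pulses
}

#' Extract search-phase sequences from one call file
#'
#' Among pulses with amplitude at least \code{min_amp_db} (15 dB at the
#' frequency of maximum energy), maximal runs whose successive onset gaps
#' are all at least \code{min_ipi_ms} (100 ms) and that contain at least
#' \code{min_pulses} (3) members qualify as search-phase sequences.
#'
#' @param file_pulses data.frame of one call file's pulses (onset s,
#'   duration_ms, amp_db)
#' @param min_pulses,min_ipi_ms,min_amp_db the three defining constraints
#' @return list of data.frames (subsets of \code{file_pulses})
#' @export
extractSearchPhase <- function(file_pulses, min_pulses = 3,
                               min_ipi_ms = 100, min_amp_db = 15) {
  q <- file_pulses[order(file_pulses$onset), , drop = FALSE]
  if ("amp_db" %in% names(q)) q <- q[q$amp_db >= min_amp_db, , drop = FALSE]
  if (nrow(q) < min_pulses) return(list())
  gaps_ms <- diff(q$onset) * 1000
  brk <- c(0, cumsum(gaps_ms < min_ipi_ms))
  segs <- split(q, brk)
  segs <- segs[vapply(segs, nrow, 0L) >= min_pulses]
  names(segs) <- NULL
  lapply(segs, function(s) { rownames(s) <- NULL; s })
}

#' Sequence-level call metrics
#'
#' Interpulse intervals are onset differences of successive pulses (ms).
#' The pulse rate is the number of pulses divided by the sequence span in
#' seconds, the span running from the onset of the first pulse to the end
#' of the last.
#'
#' @param seq_pulses data.frame of one search-phase sequence (>= 3 rows)
#' @return list(ipis_ms, mean_ipi_ms, span_ms, pulse_rate_hz)
#' @export
computeSequenceMetrics <- function(seq_pulses) {
  n <- nrow(seq_pulses)
  stopifnot(n >= 3)
  on_ms <- seq_pulses$onset * 1000
  if (any(diff(on_ms) <= 0)) stop("onsets must be strictly increasing")
  ipis <- diff(on_ms)
  span <- on_ms[n] + seq_pulses$duration_ms[n] - on_ms[1]
  list(ipis_ms = ipis, mean_ipi_ms = mean(ipis), span_ms = span,
       pulse_rate_hz = n / (span / 1000))
}

#' Classify the call types present in a file
#'
#' Terminal (feeding buzz): at least 5 consecutive pulses at IPI <= 50 ms
#' (the rapid rate increase of prey capture).  Social: at least 2 pulses
#' with peak frequency below 20 kHz and duration above 10 ms.  Search: at
#' least one search-phase sequence.  Flags are not mutually exclusive.
#'
#' @param file_pulses data.frame of one call file's pulses
#' @return character vector, subset of c("search", "terminal", "social")
#' @export
classifyCallType <- function(file_pulses) {
  stopifnot(nrow(file_pulses) > 0)
  q <- file_pulses[order(file_pulses$onset), , drop = FALSE]
  flags <- character(0)
  if (nrow(q) >= 5) {
    fast <- diff(q$onset) * 1000 <= 50
    r <- rle(fast)
    if (any(r$values & r$lengths >= 4)) flags <- c(flags, "terminal")
  }
  if (sum(q$fpeak_khz < 20 & q$duration_ms > 10) >= 2)
    flags <- c(flags, "social")
  if (length(extractSearchPhase(q))) flags <- c(flags, "search")
  flags
}

#' Summary table of call-structure metrics
#'
#' Mean, SD, SE, minimum, quartiles, median and maximum for the interpulse
#' interval and pulse rate (over sequences) and for duration, start/peak/
#' end frequency, bandwidth and modulation (over all member pulses).
#'
#' @param sequences list of search-phase sequence data.frames
#' @return data.frame with one row per statistic and one column per metric
#' @export
summarizeCallMetrics <- function(sequences) {
  stopifnot(length(sequences) >= 1)
  mets <- lapply(sequences, computeSequenceMetrics)
  ipis <- unlist(lapply(mets, `[[`, "ipis_ms"))
  rates <- vapply(mets, `[[`, 0, "pulse_rate_hz")
  pulses <- computePulseMetrics(do.call(rbind, sequences))
  cols <- list(ipi_ms = ipis, rate_hz = rates,
               duration_ms = pulses$duration_ms,
               start_khz = pulses$fmax_khz, peak_khz = pulses$fpeak_khz,
               end_khz = pulses$fmin_khz,
               bandwidth_khz = pulses$bandwidth_khz,
               modulation_pct = pulses$modulation_pct)
  stat <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        se = stats::sd(x) / sqrt(length(x)),
                        min = min(x),
                        q1 = unname(stats::quantile(x, 0.25)),
                        median = stats::median(x),
                        q3 = unname(stats::quantile(x, 0.75)),
                        max = max(x))
  out <- as.data.frame(lapply(cols, stat))
  out <- cbind(statistic = rownames(out), out)
  rownames(out) <- NULL
  attr(out, "n_pulses") <- nrow(pulses)
  attr(out, "n_sequences") <- length(sequences)
  out
}
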