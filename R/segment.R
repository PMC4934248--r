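#' Short-time energy of a multichannel stream
#'
#' Frame energy pooled across channels: frame `n` covers samples
#' `[(n-1)*hop + 1, (n-1)*hop + window_len]` and its energy is the sum of
#' squared amplitudes over that window and all channels.
#'
#' @param stream A `sensor_stream` (or a plain numeric `M x T` matrix).
#' @param window_len,hop Window length and hop in samples; defaults 0.5 s
#'   and 0.25 s at the stream's rate.
#' @return Object of class `energy_series` with fields `frame_energies`,
#'   `window_len`, `hop`.
#' @export
short_time_energy <- function(stream, window_len = NULL, hop = NULL) {
  vals <- if (inherits(stream, "sensor_stream")) stream$values else as.matrix(stream)
  fs <- if (inherits(stream, "sensor_stream")) stream$sampling_rate else NULL
  if (is.null(window_len))
    window_len <- if (is.null(fs)) stop("window_len required") else round(0.5 * fs)
  if (is.null(hop))
    hop <- if (is.null(fs)) stop("hop required") else max(1L, round(0.25 * fs))
  stopifnot(window_len >= 1, hop >= 1)
  T_ <- ncol(vals)
  if (window_len > T_) stop("window longer than stream")
  sq <- colSums(as.matrix(vals)^2)       # per-sample energy across channels
  csum <- c(0, cumsum(sq))
  n_frames <- floor((T_ - window_len) / hop) + 1
  starts <- (seq_len(n_frames) - 1L) * hop
  e <- csum[starts + window_len + 1] - csum[starts + 1]
  structure(list(frame_energies = e, window_len = as.integer(window_len),
                 hop = as.integer(hop)),
            class = "energy_series")
}

#' Detect activity segments by thresholding short-time energy
#'
#' Frames with energy above the threshold are kept; runs of kept frames are
#' merged across gaps shorter than the hangover, and runs spanning less than
#' the minimum duration are dropped. The default threshold is five times the
#' noise-floor energy, where the noise floor is estimated as the median
#' energy of the quietest fifth of the frames.
#'
#' @param energy An [short_time_energy()] result.
#' @param threshold Energy threshold; `NULL` for the noise-floor default.
#' @param min_duration_s Minimum segment span (s), default 0.6.
#' @param hangover_s Gaps shorter than this (s) are bridged, default 0.5.
#' @param sampling_rate Hz.
#' @return Data frame with columns `start`, `end` (sample indices, 1-based,
#'   `end` inclusive), sorted and non-overlapping; zero rows when nothing
#'   crosses the threshold.
#' @export
detect_segments <- function(energy, threshold = NULL, min_duration_s = 0.6,
                            hangover_s = 0.5, sampling_rate = 25) {
  stopifnot(inherits(energy, "energy_series"))
  e <- energy$frame_energies
  if (is.null(threshold)) {
    quiet <- e[e <= stats::quantile(e, 0.2, names = FALSE)]
    threshold <- 5 * max(stats::median(quiet), .Machine$double.eps)
  }
  if (threshold <= 0) stop("threshold must be > 0")
  active <- e > threshold
  if (!any(active)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(f1 = starts[r$values], f2 = ends[r$values])
  # bridge short gaps between consecutive active runs
  hang_frames <- hangover_s * sampling_rate / energy$hop
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$f1[i] - merged$f2[nrow(merged)] - 1
      if (gap < hang_frames) {
        merged$f2[nrow(merged)] <- runs$f2[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  # frame run -> sample span
  start <- (merged$f1 - 1L) * energy$hop + 1L
  end <- (merged$f2 - 1L) * energy$hop + energy$window_len
  keep <- (end - start + 1L) >= min_duration_s * sampling_rate
  data.frame(start = as.integer(start[keep]), end = as.integer(end[keep]))
}

#' Extract segment sub-streams
#'
#' @param stream A `sensor_stream`.
#' @param segments Data frame from [detect_segments()].
#' @return List of `sensor_stream` objects, one per segment, metadata
#'   carried over.
#' @export
extract_segments <- function(stream, segments) {
  stopifnot(inherits(stream, "sensor_stream"))
  T_ <- ncol(stream$values)
  lapply(seq_len(nrow(segments)), function(i) {
    s <- max(1L, segments$start[i])
    e <- min(T_, segments$end[i])
    out <- stream
    out$values <- stream$values[, s:e, drop = FALSE]
    out
  })
}

#' Segment a stream into activity samples
#'
#' Convenience wrapper: short-time energy with default window/hop at the
#' stream's rate, threshold detection, and extraction.
#'
#' @param stream A `sensor_stream`.
#' @param ... Passed to [detect_segments()].
#' @return List of `sensor_stream` samples.
#' @export
segment_stream <- function(stream, ...) {
  en <- short_time_energy(stream)
  seg <- detect_segments(en, sampling_rate = stream$sampling_rate, ...)
  extract_segments(stream, seg)
}
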