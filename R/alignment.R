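#' Matching configuration
#'
#' Controls how minute-resolution pain reports are matched to one-minute
#' sensor segments. A report matches the segment starting at the same minute
#' when one exists (lag 0); otherwise the nearest segment within
#' `tolerance_min` minutes, ties broken toward the earlier segment. The
#' 10-minute default reflects the assumption that pain changes slowly
#' relative to the reporting cadence.
#'
#' @param tolerance_min Maximum allowed |report minute - segment start
#'   minute| (inclusive, integer minutes; default 10).
#' @param min_coverage Fraction of the nominal per-minute sample count a
#'   channel must reach to be included in a segment (default 0.8).
#' @param nearest_only If `FALSE`, any admissible segment may be returned by
#'   alternative strategies; the default matches nearest-in-time.
#' @return An object of class `match_config`.
#' @export
match_config <- function(tolerance_min = 10L, min_coverage = 0.8,
                         nearest_only = TRUE) {
  stopifnot(tolerance_min >= 0, min_coverage > 0, min_coverage <= 1)
  structure(list(tolerance_min = as.integer(tolerance_min),
                 min_coverage = min_coverage,
                 nearest_only = isTRUE(nearest_only)),
            class = "match_config")
}

#' Cut sensor streams into one-minute segments
#'
#' Splits each channel of a session into windows `[m, m+1)` minutes. A
#' channel enters a segment only if it contributes at least
#' `min_coverage * sampling_hz * 60` samples in that window; segments where
#' no channel qualifies are dropped. At the nominal 1 Hz a full
#' eight-channel segment holds 480 samples.
#'
#' @param bundle A [session_bundle()].
#' @param cfg A [match_config()] (supplies `min_coverage`).
#' @param sampling_hz Nominal sampling rate used for the coverage rule.
#' @return List of `sensor_segment` objects, sorted by `start_min`. Each has
#'   `start_min`, `samples` (named list of per-channel value vectors) and
#'   `dt` (named per-channel median sampling interval, seconds).
#' @export
segment_streams <- function(bundle, cfg = match_config(), sampling_hz = 1) {
  bundle <- validate_session_bundle(bundle)
  nominal <- sampling_hz * 60
  chs <- intersect(pain_channels(), names(bundle$streams))
  chs <- chs[vapply(bundle$streams[chs], nrow, integer(1)) > 0L]
  if (length(chs) == 0L) return(list())
  span <- max(vapply(bundle$streams[chs], function(s) max(s$t_sec),
                     numeric(1)))
  minutes <- 0:floor(span / 60)
  per_ch <- lapply(bundle$streams[chs], function(s) {
    m <- floor(s$t_sec / 60)
    list(v = split(s$value, m), t = split(s$t_sec, m))
  })
  segs <- lapply(minutes, function(m) {
    key <- as.character(m)
    samples <- list(); dts <- numeric(0)
    for (ch in chs) {
      v <- per_ch[[ch]]$v[[key]]
      if (!is.null(v) && length(v) >= cfg$min_coverage * nominal) {
        samples[[ch]] <- v
        tt <- per_ch[[ch]]$t[[key]]
        dts[ch] <- if (length(tt) > 1L) stats::median(diff(tt))
                   else 1 / sampling_hz
      }
    }
    if (length(samples) == 0L) return(NULL)
    structure(list(session_id = bundle$session_id, start_min = m,
                   samples = samples, dt = dts),
              class = "sensor_segment")
  })
  segs[!vapply(segs, is.null, logical(1))]
}

#' @export
print.sensor_segment <- function(x, ...) {
  cat(sprintf("sensor_segment [%d, %d) min: %s\n", x$start_min,
              x$start_min + 1, paste(names(x$samples), collapse = ", ")))
  invisible(x)
}

#' Match pain reports to sensor segments
#'
#' Implements the timestamp-matching rule: an exact same-minute segment wins
#' (lag 0); otherwise the nearest segment with lag at most
#' `cfg$tolerance_min` minutes, ties broken toward the earlier segment.
#' Each pain record yields at most one match; several records may share a
#' segment. Records with no admissible segment are returned separately —
#' being unmatched is a normal outcome, so matched plus unmatched always
#' partition the input.
#'
#' @param pain `data.frame` of pain records (`t_min`, `score`, `source`).
#' @param segments List of `sensor_segment` from [segment_streams()].
#' @param cfg A [match_config()].
#' @return List with `matched` (a `data.frame`: `t_min`, `score`, `source`,
#'   `segment_start_min`, `lag_min`, `segment_index` into `segments`) and
#'   `unmatched` (the pain rows that found no segment).
#' @export
match_pain_to_segments <- function(pain, segments, cfg = match_config()) {
  pain <- validate_pain_records(pain)
  starts <- vapply(segments, function(s) s$start_min, numeric(1))
  stopifnot(!is.unsorted(starts))
  hit <- integer(0); lag <- integer(0); rows <- integer(0)
  for (i in seq_len(nrow(pain))) {
    tm <- pain$t_min[i]
    if (length(starts) == 0L) next
    d <- abs(starts - tm)
    j <- which.min(d)  # ties -> earlier segment (first index)
    if (d[j] <= cfg$tolerance_min) {
      rows <- c(rows, i); hit <- c(hit, j); lag <- c(lag, as.integer(d[j]))
    }
  }
  matched <- cbind(pain[rows, , drop = FALSE],
                   data.frame(segment_start_min = as.integer(starts[hit]),
                              lag_min = lag, segment_index = hit))
  rownames(matched) <- NULL
  unmatched <- pain[setdiff(seq_len(nrow(pain)), rows), , drop = FALSE]
  rownames(unmatched) <- NULL
  list(matched = matched, unmatched = unmatched)
}
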