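#' Moving-average filter configuration
#'
#' @param window Odd positive window length in samples (default 5, i.e. 5 s
#'   at 1 Hz — short enough to keep minute-scale structure).
#' @param steps_as_increments Difference the cumulative `STEPS` counter into
#'   per-sample increments before filtering and statistics (default `TRUE`;
#'   statistics on a monotone counter are largely degenerate).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(window = 5L, steps_as_increments = TRUE) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  structure(list(window = window,
                 steps_as_increments = isTRUE(steps_as_increments)),
            class = "filter_config")
}

#' Centered moving average with truncated edges
#'
#' Element `i` of the output is the mean of the input over the window
#' centered at `i`, truncated at the sequence edges, so the output has the
#' same length as the input and a constant sequence is unchanged.
#'
#' @param x Numeric sequence (length >= 1).
#' @param window Odd positive window length in samples.
#' @return Filtered numeric sequence, same length as `x`.
#' @export
#' @examples
#' moving_average(c(0, 3, 0), window = 3)  # 1.5 1.0 1.5
moving_average <- function(x, window = 5L) {
  if (length(x) == 0L) stop("moving_average: empty input")
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(as.numeric(x))
  n <- length(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Compute one segment statistic
#'
#' The per-channel descriptors computed on each (filtered) one-minute
#' segment:
#' \describe{
#'   \item{mean}{average value}
#'   \item{std}{population standard deviation (the `1/n` form, matching the
#'     `rms`/`power` family)}
#'   \item{mean_derivative}{mean of successive differences divided by the
#'     sampling interval `dt` (channel units per second)}
#'   \item{rms}{root mean square, `sqrt(sum(x^2)/n)`}
#'   \item{peak_to_peak}{max - min}
#'   \item{peak_to_rms}{max(|x|) / rms; undefined on an all-zero signal}
#'   \item{n_peaks}{number of interior local maxima; a plateau (run of equal
#'     values strictly greater than both neighbours) counts once, endpoints
#'     never count}
#'   \item{power}{mean squared amplitude, `sum(|x|^2)/n` (so `rms^2 ==
#'     power` identically)}
#' }
#'
#' @param stat One of [pain_statistics()].
#' @param x Numeric sequence (length >= 2 for `std`, `mean_derivative` and
#'   `n_peaks`, >= 1 otherwise).
#' @param dt Sampling interval in seconds (used by `mean_derivative`).
#' @return Scalar value of the statistic.
#' @export
#' @examples
#' compute_statistic("rms", c(1, 2, 3, 4))
#' compute_statistic("n_peaks", c(0, 2, 2, 0))  # plateau counts once
compute_statistic <- function(stat, x, dt = 1) {
  stat <- match.arg(stat, pain_statistics())
  n <- length(x)
  if (n < 1L || (n < 2L && stat %in% c("std", "mean_derivative", "n_peaks")))
    stop("compute_statistic: input too short for '", stat, "'")
  switch(stat,
    mean = mean(x),
    std = sqrt(mean((x - mean(x))^2)),
    mean_derivative = mean(diff(x)) / dt,
    rms = sqrt(mean(x^2)),
    peak_to_peak = max(x) - min(x),
    peak_to_rms = {
      r <- sqrt(mean(x^2))
      if (r == 0) stop("peak_to_rms undefined: signal is identically zero")
      max(abs(x)) / r
    },
    n_peaks = count_peaks(x),
    power = mean(abs(x)^2)
  )
}

# interior runs of equal values strictly above both neighbours; runs that
# touch an endpoint never count
count_peaks <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(0L)
  v <- r$values
  sum(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k])
}

#' Extract the statistical feature vector of a segment
#'
#' Per channel: the cumulative `STEPS` counter is first differenced into
#' per-sample increments (if configured), the signal is moving-average
#' filtered, and all eight statistics of [pain_statistics()] are computed on
#' the filtered sequence. A channel/statistic whose precondition fails (for
#' instance `peak_to_rms` of an all-zero signal) is reported as `NA`, never
#' silently zero.
#'
#' @param segment A `sensor_segment` from [segment_streams()].
#' @param fcfg A [filter_config()].
#' @return Named numeric vector, names `<channel>__<statistic>` in canonical
#'   order, one entry per channel present times eight statistics.
#' @export
extract_features <- function(segment, fcfg = filter_config()) {
  stopifnot(inherits(segment, "sensor_segment"))
  chs <- intersect(pain_channels(), names(segment$samples))
  out <- numeric(0)
  for (ch in chs) {
    x <- segment$samples[[ch]]
    dt <- unname(segment$dt[ch])
    if (ch == "STEPS" && fcfg$steps_as_increments && length(x) > 1L)
      x <- diff(x)
    xf <- moving_average(x, fcfg$window)
    vals <- vapply(pain_statistics(), function(s) {
      tryCatch(compute_statistic(s, xf, dt = dt),
               error = function(e) NA_real_)
    }, numeric(1))
    names(vals) <- paste(ch, pain_statistics(), sep = "__")
    out <- c(out, vals)
  }
  out
}

#' Build the matched feature table for one or more sessions
#'
#' Runs the full preprocessing chain — segment the streams, match the pain
#' reports, extract per-segment features — and stacks the results into a
#' wide modelling table: one row per matched pain report, feature columns in
#' canonical order, plus `session_id`, `t_min`, `lag_min`, `score`,
#' `source`. Feature columns absent from some sessions are filled with `NA`.
#'
#' @param cohort A [session_bundle()] or list of them.
#' @param mcfg A [match_config()].
#' @param fcfg A [filter_config()].
#' @param sampling_hz Nominal sampling rate for the coverage rule.
#' @return `data.frame`; unmatched pain-report counts are attached as
#'   attribute `n_unmatched`.
#' @export
build_feature_table <- function(cohort, mcfg = match_config(),
                                fcfg = filter_config(), sampling_hz = 1) {
  if (inherits(cohort, "session_bundle")) cohort <- list(cohort)
  rows <- list(); n_unmatched <- 0L
  for (b in cohort) {
    segs <- segment_streams(b, mcfg, sampling_hz)
    m <- match_pain_to_segments(b$pain, segs, mcfg)
    n_unmatched <- n_unmatched + nrow(m$unmatched)
    if (nrow(m$matched) == 0L) next
    for (i in seq_len(nrow(m$matched))) {
      fv <- extract_features(segs[[m$matched$segment_index[i]]], fcfg)
      rows[[length(rows) + 1L]] <- c(
        list(session_id = b$session_id,
             t_min = m$matched$t_min[i],
             lag_min = m$matched$lag_min[i]),
        as.list(fv),
        list(score = m$matched$score[i], source = m$matched$source[i]))
    }
  }
  all_feats <- intersect(pain_feature_names(),
                         unique(unlist(lapply(rows, names))))
  cols <- c("session_id", "t_min", "lag_min", all_feats, "score", "source")
  out <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    r <- r[cols[cols %in% names(r)]]
    miss <- setdiff(cols, names(r))
    r[miss] <- NA
    r[cols]
  })), stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(cols)), cols))
  } else {
    for (cn in setdiff(cols, c("session_id", "source")))
      out[[cn]] <- as.numeric(unlist(out[[cn]]))
    out$session_id <- as.character(unlist(out$session_id))
    out$source <- as.character(unlist(out$source))
    out$t_min <- as.integer(out$t_min)
  }
  attr(out, "n_unmatched") <- n_unmatched
  out
}
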