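# CSV dialects:
#   sensor:  session_id,channel,t_sec,value
#   pain:    session_id,t_min,score,source
#   feature: session_id,t_min,<channel>__<statistic>...,score,source
# UTF-8, comma separated, "." decimal point, numbers at 9 significant digits.

#' Construct a session bundle
#'
#' A session bundle holds everything recorded for one day-hospital stay: one
#' timestamped value series per available wearable channel plus the session's
#' subjective pain reports. Timestamps are seconds since session start
#' (sensor) and whole minutes since session start (pain); conversion from
#' wall clock happens at ingest.
#'
#' @param session_id Opaque session identifier (single string).
#' @param streams Named list, one element per channel, each a `data.frame`
#'   with columns `t_sec` (strictly increasing, non-negative) and `value`.
#'   Names must be a subset of [pain_channels()]; `STEPS` values must be
#'   non-decreasing (cumulative counter).
#' @param pain `data.frame` with columns `t_min` (non-negative integer
#'   minutes), `score` (in \[0, 10\]) and `source` (`"app"` or `"nurse"`).
#' @param latent Optional `data.frame` with columns `t_sec`, `pain`: the
#'   simulator's latent pain trajectory. Carried for parameter-recovery
#'   checks only; no analysis stage reads it.
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, streams = list(),
                           pain = empty_pain_records(), latent = NULL) {
  obj <- structure(
    list(session_id = as.character(session_id), streams = streams,
         pain = pain, latent = latent),
    class = "session_bundle")
  validate_session_bundle(obj)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("session_bundle '%s': %d channel(s), %d pain record(s)\n",
              x$session_id, length(x$streams), nrow(x$pain)))
  for (ch in names(x$streams)) {
    s <- x$streams[[ch]]
    cat(sprintf("  %-6s n=%d  t=[%.0f, %.0f] s\n", ch, nrow(s),
                min(s$t_sec), max(s$t_sec)))
  }
  invisible(x)
}

empty_pain_records <- function() {
  data.frame(t_min = integer(), score = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

validate_pain_records <- function(pain) {
  stopifnot(is.data.frame(pain),
            all(c("t_min", "score", "source") %in% names(pain)))
  if (nrow(pain) == 0L) return(pain)
  if (any(pain$t_min < 0) || any(pain$t_min != round(pain$t_min)))
    stop("pain 't_min' must be non-negative whole minutes")
  bad <- which(pain$score < 0 | pain$score > 10)
  if (length(bad))
    stop("pain score out of [0, 10] at row(s): ", paste(bad, collapse = ", "))
  bad_src <- setdiff(unique(pain$source), pain_sources())
  if (length(bad_src))
    stop("unknown pain source(s): ", paste(bad_src, collapse = ", "))
  pain[order(pain$t_min), , drop = FALSE]
}

validate_session_bundle <- function(b) {
  stopifnot(inherits(b, "session_bundle"), length(b$session_id) == 1L)
  bad <- setdiff(names(b$streams), pain_channels())
  if (length(bad))
    stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(b$streams)))
    stop("at most one stream per channel")
  for (ch in names(b$streams)) {
    s <- b$streams[[ch]]
    stopifnot(is.data.frame(s), all(c("t_sec", "value") %in% names(s)))
    if (nrow(s) == 0L) next
    if (any(s$t_sec < 0))
      stop(ch, ": timestamps must be non-negative")
    if (any(diff(s$t_sec) <= 0))
      stop(ch, ": timestamps must be strictly increasing")
    if (ch == "STEPS" && any(diff(s$value) < 0))
      stop("STEPS values must be non-decreasing")
  }
  b$pain <- validate_pain_records(b$pain)
  b
}

fmt_num <- function(x) formatC(x, digits = 9, format = "g")

#' Read a sensor CSV for one session
#'
#' Reads the sensor dialect (`session_id,channel,t_sec,value`), groups rows
#' into one stream per channel and sorts each stream by timestamp. Rows with
#' non-numeric or missing `t_sec`/`value` are rejected with a warning; the
#' counts of accepted and rejected rows always add up to the number of input
#' rows (attached as attributes `n_accepted` / `n_rejected`).
#'
#' @param path Path to a CSV file holding exactly one session.
#' @return A [session_bundle()] carrying the streams (no pain records).
#' @export
read_sensor_csv <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("session_id", "channel", "t_sec", "value")
  if (!identical(names(raw), need))
    stop("sensor CSV header must be: ", paste(need, collapse = ","))
  sid <- unique(raw$session_id)
  if (length(sid) > 1L)
    stop("sensor CSV contains multiple sessions: ",
         paste(sid, collapse = ", "))
  if (length(sid) == 0L) sid <- "session"
  bad_ch <- setdiff(unique(raw$channel), pain_channels())
  if (length(bad_ch)) {
    row <- which(raw$channel %in% bad_ch)[1L]
    stop("unknown channel '", raw$channel[row], "' at data row ", row)
  }
  t_sec <- suppressWarnings(as.numeric(raw$t_sec))
  value <- suppressWarnings(as.numeric(raw$value))
  ok <- is.finite(t_sec) & is.finite(value)
  if (any(!ok))
    warning(sum(!ok), " malformed row(s) rejected in ", basename(path))
  streams <- lapply(split(seq_len(nrow(raw))[ok], raw$channel[ok]), function(i) {
    o <- order(t_sec[i])
    data.frame(t_sec = t_sec[i][o], value = value[i][o])
  })
  b <- session_bundle(sid, streams = streams)
  attr(b, "n_accepted") <- sum(ok)
  attr(b, "n_rejected") <- sum(!ok)
  b
}

#' Write a session's sensor streams as CSV
#'
#' @param bundle A [session_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(bundle, path) {
  bundle <- validate_session_bundle(bundle)
  chs <- intersect(pain_channels(), names(bundle$streams))
  rows <- lapply(chs, function(ch) {
    s <- bundle$streams[[ch]]
    data.frame(session_id = bundle$session_id, channel = ch,
               t_sec = fmt_num(s$t_sec), value = fmt_num(s$value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(session_id = character(), channel = character(),
                      t_sec = character(), value = character())
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pain-score CSV
#'
#' Reads the pain dialect (`session_id,t_min,score,source`): minute-resolution
#' subjective 0-10 pain reports from the patient app (fractional scores
#' allowed) or nursing notes (typically integer). Scores outside \[0, 10\]
#' or unknown sources are validation errors, never silently dropped.
#'
#' @param path Path to the CSV.
#' @return `data.frame` with columns `session_id`, `t_min` (integer),
#'   `score`, `source`, sorted by `t_min` within session.
#' @export
read_pain_csv <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "t_min", "score", "source")
  if (!identical(names(raw), need))
    stop("pain CSV header must be: ", paste(need, collapse = ","))
  if (nrow(raw) == 0L)
    return(cbind(data.frame(session_id = character()), empty_pain_records()))
  chk <- validate_pain_records(raw[c("t_min", "score", "source")])
  raw$t_min <- as.integer(raw$t_min)
  raw[order(raw$session_id, raw$t_min), , drop = FALSE]
}

#' Write pain records as CSV
#'
#' @param pain `data.frame` with columns `session_id`, `t_min`, `score`,
#'   `source` (a bundle's `pain` slot plus its id also works, see
#'   [session_pain_frame()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pain_csv <- function(pain, path) {
  stopifnot(all(c("session_id", "t_min", "score", "source") %in% names(pain)))
  validate_pain_records(pain[c("t_min", "score", "source")])
  out <- pain[c("session_id", "t_min", "score", "source")]
  out$score <- fmt_num(out$score)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pain records of a bundle with the session id attached
#' @param bundle A [session_bundle()].
#' @return `data.frame` with `session_id,t_min,score,source` columns.
#' @export
session_pain_frame <- function(bundle) {
  p <- bundle$pain
  if (nrow(p) == 0L)
    return(cbind(data.frame(session_id = character()), empty_pain_records()))
  cbind(data.frame(session_id = bundle$session_id, stringsAsFactors = FALSE), p)
}

#' Write a feature table as wide CSV
#'
#' One row per matched record; columns are `session_id`, `t_min`, the
#' feature columns in canonical order (channel-major, see
#' [pain_feature_names()]), then `score` and `source`. All rows must carry
#' the same feature set.
#'
#' @param tbl Feature table as returned by [build_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  meta <- c("session_id", "t_min", "score", "source")
  stopifnot(all(meta %in% names(tbl)))
  feats <- setdiff(names(tbl), c(meta, "lag_min"))
  bad <- setdiff(feats, pain_feature_names())
  if (length(bad))
    stop("unknown feature column(s): ", paste(bad, collapse = ", "))
  ord <- intersect(pain_feature_names(), feats)
  out <- tbl[c("session_id", "t_min", ord, "score", "source")]
  for (cn in c("t_min", ord, "score"))
    out[[cn]] <- fmt_num(out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature-table CSV
#' @param path Path written by [write_feature_table()].
#' @return `data.frame` in the [build_feature_table()] layout.
#' @export
read_feature_table <- function(path) {
  stopifnot(file.exists(path))
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- c("session_id", "t_min", "score", "source")
  if (!all(meta %in% names(tbl)))
    stop("feature CSV must carry columns: ", paste(meta, collapse = ","))
  feats <- setdiff(names(tbl), meta)
  bad <- setdiff(feats, pain_feature_names())
  if (length(bad))
    stop("unknown feature column(s): ", paste(bad, collapse = ", "))
  tbl$t_min <- as.integer(tbl$t_min)
  tbl
}
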