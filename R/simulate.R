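#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated day-hospital cohort:
#' session durations, a latent 0-10 pain trajectory that starts high (severe
#' skew) and steps downward at simulated medication times, wearable channels
#' coupled linearly to that trajectory on top of AR(1) noise, and sparse
#' app/nurse pain reports drawn from the same trajectory.
#'
#' Defaults emulate an acute sickle-cell pain cohort: 20 sessions of mean
#' duration 3.79 h (SD 2.23 h, truncated at 0.5 h) at 1 Hz, a mean in-stay
#' pain decrease of 2.75 points (SD 2.34), a reported-score severity mix
#' weighted 2/4/34/67 (none/mild/moderate/severe), 2 app and 3-4 nurse
#' reports per session. Per-channel baselines and noise levels are
#' generator placeholders, not measurements.
#'
#' @param n_sessions Number of sessions (patients).
#' @param mean_duration_hr,sd_duration_hr Session duration distribution in
#'   hours (normal, truncated below at 0.5 h).
#' @param sampling_hz Sensor sampling rate (Hz).
#' @param class_weights Severity-mix weights (none, mild, moderate, severe)
#'   of the pooled reported scores. Each session draws a severity anchor
#'   from these weights (uniform within the level's score interval); the
#'   anchor is the level the stay settles at after treatment, and
#'   presentation pain sits the session's total decrease above it (capped
#'   at 10), so pooled reports remain severe-dominated as configured.
#' @param mean_pain_decrease,sd_pain_decrease Total in-stay decrease of the
#'   latent pain (points on the 0-10 scale; draw truncated at 0 and capped
#'   at the starting pain).
#' @param n_med_events Range (length-2 integer) of simulated medication
#'   events per session; the total decrease is split across them so the
#'   latent trajectory is piecewise constant with downward jumps.
#' @param baseline Named per-channel baseline levels (channel units; the
#'   `STEPS` baseline is the counter's start value).
#' @param coupling Named per-channel pain-effect coefficients (channel units
#'   per pain point). For `STEPS` the coefficient couples the step *rate*:
#'   increments are Poisson with rate `max(0, -coupling * (10 - pain))` per
#'   sample, so a negative value means patients in more pain walk less and a
#'   zero coefficient freezes the counter.
#' @param noise_sd Named per-channel stationary noise SD (ignored for
#'   `STEPS`, whose Poisson increments carry their own noise).
#' @param ar_coef AR(1) coefficient of the channel noise.
#' @param n_app_scores App-logged pain reports per session.
#' @param n_nurse_scores Range (length-2 integer) of nurse-charted reports
#'   per session.
#' @param report_noise_sd SD of the reporting noise added to the latent pain
#'   before clamping to \[0, 10\] (app reports keep 2 decimals, nurse
#'   reports are rounded to integers).
#' @param source_bias Additive bias applied to nurse reports before
#'   rounding (default 0; nonzero probes the app-equals-nurse assumption).
#' @param seed Integer seed; session `i` uses `seed + i`, so the seed fully
#'   determines the cohort.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_sessions = 2, mean_duration_hr = 0.6, seed = 1)
#' cohort <- generate_cohort(cfg)
sim_config <- function(n_sessions = 20,
                       mean_duration_hr = 3.79,
                       sd_duration_hr = 2.23,
                       sampling_hz = 1,
                       class_weights = c(none = 2, mild = 4,
                                         moderate = 34, severe = 67),
                       mean_pain_decrease = 2.75,
                       sd_pain_decrease = 2.34,
                       n_med_events = c(2L, 4L),
                       baseline = c(HR = 85, RR = 0.75, GSR = 300,
                                    TEMP = 33, ACC_Z = -1, GYR_Y = 0,
                                    GYR_Z = 0, STEPS = 0),
                       coupling = c(HR = 2, RR = 0, GSR = 15, TEMP = 0,
                                    ACC_Z = 0, GYR_Y = 0, GYR_Z = 0,
                                    STEPS = -0.05),
                       noise_sd = c(HR = 3, RR = 0.05, GSR = 10,
                                    TEMP = 0.2, ACC_Z = 0.05, GYR_Y = 5,
                                    GYR_Z = 5, STEPS = 0),
                       ar_coef = 0.9,
                       n_app_scores = 2L,
                       n_nurse_scores = c(3L, 4L),
                       report_noise_sd = 0.5,
                       source_bias = 0,
                       seed = 1L) {
  chs <- pain_channels()
  fill <- function(x) { y <- stats::setNames(numeric(8), chs); y[names(x)] <- x; y }
  cfg <- structure(list(
    n_sessions = as.integer(n_sessions),
    mean_duration_hr = mean_duration_hr, sd_duration_hr = sd_duration_hr,
    sampling_hz = sampling_hz,
    class_weights = class_weights,
    mean_pain_decrease = mean_pain_decrease,
    sd_pain_decrease = sd_pain_decrease,
    n_med_events = as.integer(n_med_events),
    baseline = fill(baseline), coupling = fill(coupling),
    noise_sd = fill(noise_sd), ar_coef = ar_coef,
    n_app_scores = as.integer(n_app_scores),
    n_nurse_scores = as.integer(n_nurse_scores),
    report_noise_sd = report_noise_sd, source_bias = source_bias,
    seed = as.integer(seed)), class = "sim_config")
  stopifnot(cfg$n_sessions >= 0, cfg$mean_duration_hr > 0,
            cfg$sd_duration_hr >= 0, cfg$sampling_hz > 0,
            length(cfg$class_weights) == 4, all(cfg$class_weights >= 0),
            cfg$mean_pain_decrease >= 0, cfg$sd_pain_decrease >= 0,
            length(cfg$n_med_events) == 2, cfg$n_med_events[1] >= 1,
            cfg$n_med_events[1] <= cfg$n_med_events[2],
            abs(cfg$ar_coef) < 1, cfg$n_app_scores >= 0,
            length(cfg$n_nurse_scores) == 2,
            all(cfg$n_nurse_scores >= 0),
            cfg$n_nurse_scores[1] <= cfg$n_nurse_scores[2],
            cfg$report_noise_sd >= 0)
  cfg
}

# sample one element of x (safe for length-1 x)
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# session severity anchor: level drawn by weight, then uniform within the
# level's score interval (none [0,1), mild [1,4), moderate [4,7),
# severe [7,10]). The weights describe the severity mix of reported scores;
# the anchor is the level a stay settles at after treatment, and
# presentation pain sits the session's total decrease above it (capped at
# 10), so reports spread over the stay stay severe-dominated.
draw_severity_anchor <- function(cfg) {
  lo <- c(0, 1, 4, 7); hi <- c(1, 4, 7, 10)
  k <- sample.int(4L, 1L, prob = cfg$class_weights / sum(cfg$class_weights))
  stats::runif(1, lo[k], hi[k])
}

# latent piecewise-constant trajectory over n samples
draw_latent_pain <- function(cfg, n) {
  anchor <- draw_severity_anchor(cfg)
  drop_total <- max(0, stats::rnorm(1, cfg$mean_pain_decrease,
                                    cfg$sd_pain_decrease))
  p0 <- min(10, anchor + drop_total)
  drop_total <- p0 - anchor  # stay ends at the anchor, never below 0
  k <- sample1(seq(cfg$n_med_events[1], cfg$n_med_events[2]))
  ev <- sort(sample.int(n, min(k, n - 1L)))
  w <- stats::rexp(length(ev)); w <- w / sum(w)
  p <- rep(p0, n)
  for (j in seq_along(ev))
    p[ev[j]:n] <- p[ev[j]:n] - drop_total * w[j]
  pmax(p, 0)
}

ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0L) return(numeric(n))
  z <- stats::rnorm(n)
  e1 <- sd * z[1]  # stationary start
  if (n == 1L) return(e1)
  innov <- sd * sqrt(1 - rho^2) * z[-1]
  c(e1, e1 * rho^seq_len(n - 1L) +
      as.numeric(stats::filter(innov, rho, method = "recursive")))
}

#' Simulate one wearable session
#'
#' Draws a session duration, a latent pain trajectory `p(t)` (piecewise
#' constant, stepping down at simulated medication times), then generates
#' every channel as `baseline + coupling * p(t) + AR(1) noise`. `STEPS` is a
#' cumulative counter whose Poisson increment rate decreases with pain.
#' Pain reports sample `p(t)` at distinct random minutes with reporting
#' noise; nurse scores are rounded to integers, app scores kept to two
#' decimals. The latent trajectory is returned in the bundle's `latent`
#' slot for parameter-recovery checks; the pipeline never reads it.
#'
#' @param cfg A [sim_config()].
#' @param session_index 1-based session number; the RNG is seeded with
#'   `cfg$seed + session_index`, so each call is reproducible in isolation.
#' @return A [session_bundle()] with all eight channels, pain records and
#'   the latent truth.
#' @export
generate_session <- function(cfg, session_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + as.integer(session_index))
  dur_hr <- max(0.5, stats::rnorm(1, cfg$mean_duration_hr, cfg$sd_duration_hr))
  dt <- 1 / cfg$sampling_hz
  n <- max(2L, round(dur_hr * 3600 * cfg$sampling_hz))
  t_sec <- (seq_len(n) - 1) * dt
  p <- draw_latent_pain(cfg, n)

  streams <- list()
  for (ch in pain_channels()) {
    if (ch == "STEPS") {
      rate <- pmax(0, -cfg$coupling[["STEPS"]] * (10 - p)) * dt
      inc <- stats::rpois(n, rate)
      value <- cfg$baseline[["STEPS"]] + cumsum(inc)
    } else {
      value <- cfg$baseline[[ch]] + cfg$coupling[[ch]] * p +
        ar1_noise(n, cfg$noise_sd[[ch]], cfg$ar_coef)
    }
    streams[[ch]] <- data.frame(t_sec = t_sec, value = value)
  }

  n_minutes <- floor(max(t_sec) / 60) + 1
  n_nurse <- sample1(seq(cfg$n_nurse_scores[1], cfg$n_nurse_scores[2]))
  n_rep <- min(cfg$n_app_scores + n_nurse, n_minutes)
  mins <- sort(sample.int(n_minutes, n_rep) - 1L)
  src <- sample(rep(pain_sources(), c(cfg$n_app_scores, n_nurse))[seq_len(n_rep)])
  idx <- pmin(mins * 60 / dt + 1, n)  # latent value at the report minute
  raw <- p[idx] + stats::rnorm(n_rep, 0, cfg$report_noise_sd) +
    ifelse(src == "nurse", cfg$source_bias, 0)
  score <- pmin(10, pmax(0, raw))
  score <- ifelse(src == "nurse", round(score), round(score, 2))
  pain <- data.frame(t_min = as.integer(mins), score = score, source = src,
                     stringsAsFactors = FALSE)

  session_bundle(sprintf("S%02d", as.integer(session_index)),
                 streams = streams, pain = pain,
                 latent = data.frame(t_sec = t_sec, pain = p))
}

#' Simulate a cohort of sessions
#'
#' @param cfg A [sim_config()].
#' @return List of [session_bundle()], one per session; session `i` is
#'   seeded as `cfg$seed + i` so the whole cohort is reproducible.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(seq_len(cfg$n_sessions), function(i) generate_session(cfg, i))
}

#' Write a cohort to per-session CSV files
#'
#' Emits `<dir>/<session_id>_sensor.csv`, `<dir>/<session_id>_pain.csv` and
#' `<dir>/<session_id>_latent.csv` for each session.
#'
#' @param cohort List of [session_bundle()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in cohort) {
    write_sensor_csv(b, file.path(dir, paste0(b$session_id, "_sensor.csv")))
    write_pain_csv(session_pain_frame(b),
                   file.path(dir, paste0(b$session_id, "_pain.csv")))
    if (!is.null(b$latent)) {
      lat <- b$latent
      lat$t_sec <- fmt_num(lat$t_sec); lat$pain <- fmt_num(lat$pain)
      utils::write.csv(lat, file.path(dir, paste0(b$session_id, "_latent.csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
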