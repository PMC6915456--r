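# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# a small randomized session bundle (irregular lengths, all channels)
random_bundle <- function(seed, n_min = 20, n_max = 400) {
  set.seed(seed)
  streams <- list()
  for (ch in pain_channels()) {
    n <- sample(n_min:n_max, 1)
    t_sec <- sort(sample(0:(4 * n_max), n))
    value <- if (ch == "STEPS") cumsum(rpois(n, 0.3)) else rnorm(n, 50, 10)
    streams[[ch]] <- data.frame(t_sec = as.numeric(t_sec), value = value)
  }
  pain <- data.frame(
    t_min = sort(sample(0:20, 4)),
    score = round(runif(4, 0, 10), 2),
    source = sample(c("app", "nurse"), 4, replace = TRUE),
    stringsAsFactors = FALSE)
  session_bundle(paste0("RB", seed), streams = streams, pain = pain)
}

# a bundle with continuous 1 Hz coverage on chosen channels
uniform_bundle <- function(minutes = 3, channels = pain_channels(),
                           values = NULL, session_id = "U1",
                           pain = NULL) {
  n <- minutes * 60
  t_sec <- seq_len(n) - 1
  streams <- lapply(channels, function(ch) {
    v <- if (!is.null(values)) rep_len(values[[ch]], n)
         else if (ch == "STEPS") cumsum(rep(1, n)) else sin(t_sec / 7) + 2
    data.frame(t_sec = as.numeric(t_sec), value = v)
  })
  names(streams) <- channels
  if (is.null(pain)) pain <- empty_pain_df()
  session_bundle(session_id, streams = streams, pain = pain)
}

empty_pain_df <- function() {
  data.frame(t_min = integer(), score = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

pain_df <- function(t_min, score, source = "nurse") {
  data.frame(t_min = t_min, score = score,
             source = rep_len(source, length(t_min)),
             stringsAsFactors = FALSE)
}

# segment built directly from per-channel sample vectors
make_segment <- function(samples, start_min = 0, dt = 1) {
  structure(list(session_id = "T", start_min = start_min, samples = samples,
                 dt = stats::setNames(rep(dt, length(samples)),
                                      names(samples))),
            class = "sensor_segment")
}

# a fast small-cohort config for pipeline-level tests
tiny_sim_config <- function(seed, n_sessions = 4, ...) {
  sim_config(n_sessions = n_sessions, mean_duration_hr = 0.8,
             sd_duration_hr = 0.2, seed = seed, ...)
}

# brute-force statistic oracle, coded independently of compute_statistic()
oracle_stat <- function(stat, x, dt = 1) {
  n <- length(x)
  if (stat == "mean") return(sum(x) / n)
  if (stat == "std") {
    m <- sum(x) / n
    return(sqrt(sum((x - m)^2) / n))
  }
  if (stat == "mean_derivative") {
    d <- x[-1] - x[-n]
    return((sum(d) / (n - 1)) / dt)
  }
  if (stat == "rms") return(sqrt(sum(x * x) / n))
  if (stat == "peak_to_peak") return(max(x) - min(x))
  if (stat == "peak_to_rms") return(max(abs(x)) / sqrt(sum(x * x) / n))
  if (stat == "power") return(sum(abs(x)^2) / n)
  if (stat == "n_peaks") {
    # scan runs of equal values; count interior runs above both neighbours
    cnt <- 0L; i <- 2L
    while (i <= n - 1L) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j <= n - 1L && x[i] > x[i - 1L] && x[i] > x[j + 1L])
        cnt <- cnt + 1L
      i <- j + 1L
    }
    return(cnt)
  }
  stop("unknown stat")
}
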