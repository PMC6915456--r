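#' Wearable channel registry
#'
#' The pipeline works on eight wearable signals recorded at a nominal 1 Hz:
#' heart rate (`HR`, beats/min), R-R interval (`RR`, s), galvanic skin
#' response (`GSR`, kOhm), skin temperature (`TEMP`, degC), acceleration in
#' the Z direction (`ACC_Z`, g), angular velocity about Y and Z (`GYR_Y`,
#' `GYR_Z`, deg/s), and a cumulative step counter (`STEPS`). The order
#' returned here is the canonical channel order used for feature-column
#' layout everywhere in the package.
#'
#' @return Character vector of the eight channel names, in canonical order.
#' @export
#' @examples
#' pain_channels()
pain_channels <- function() {
  c("HR", "RR", "GSR", "TEMP", "ACC_Z", "GYR_Y", "GYR_Z", "STEPS")
}

#' Segment statistic registry
#'
#' The eight statistics computed per channel on each one-minute segment, in
#' canonical order: `mean`, `std` (population standard deviation),
#' `mean_derivative` (mean first difference per second), `rms`,
#' `peak_to_peak`, `peak_to_rms`, `n_peaks` (interior local maxima, a
#' plateau counting once), and `power` (mean squared amplitude).
#'
#' @return Character vector of the eight statistic names, in canonical order.
#' @export
#' @examples
#' pain_statistics()
pain_statistics <- function() {
  c("mean", "std", "mean_derivative", "rms", "peak_to_peak",
    "peak_to_rms", "n_peaks", "power")
}

#' Canonical feature names
#'
#' Feature names are `<channel>__<statistic>`, channel-major: all eight
#' statistics of `HR`, then of `RR`, and so on. A full eight-channel segment
#' yields 64 features.
#'
#' @param channels Channels to include (default all eight).
#' @return Character vector of feature names.
#' @export
#' @examples
#' head(pain_feature_names(), 8)
pain_feature_names <- function(channels = pain_channels()) {
  channels <- match.arg(channels, pain_channels(), several.ok = TRUE)
  as.vector(t(outer(channels, pain_statistics(), paste, sep = "__")))
}

#' Pain source levels
#' @return Character vector `c("app", "nurse")`.
#' @keywords internal
pain_sources <- function() c("app", "nurse")
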