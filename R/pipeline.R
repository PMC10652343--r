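#' End-to-end beating analysis of one video
#'
#' Runs block matching over every consecutive frame pair, aggregates the
#' motion-magnitude trace, and computes all beating metrics.
#'
#' @param stack a [frame_stack()] (or a path accepted by [read_frames()],
#'   in which case `frame_rate_hz` must be given).
#' @param match_params a [block_match_params()].
#' @param beat_params a [beat_detection_params()].
#' @param frame_rate_hz,pixel_size_um acquisition metadata, used only when
#'   `stack` is a path.
#' @return List of class `video_analysis`: `metrics` (a [beat_metrics()]),
#'   `trace` (the [motion_trace()]), `fields` (displacement fields),
#'   `beat_times`.
#' @export
analyze_video <- function(stack, match_params = block_match_params(),
                          beat_params = beat_detection_params(),
                          frame_rate_hz = NULL, pixel_size_um = 1.0) {
  if (is.character(stack)) {
    if (is.null(frame_rate_hz))
      stop_beatkit("bad_frame_rate", "frame_rate_hz is required when reading from a path")
    stack <- read_frames(stack, frame_rate_hz, pixel_size_um)
  }
  fields <- compute_fields(stack, match_params)
  trace <- motion_magnitude_trace(fields, stack$frame_rate_hz, stack$pixel_size_um)
  beats <- detect_beats(trace, beat_params)
  metrics <- beat_metrics(trace, fields, stack_duration(stack),
                          stack$pixel_size_um, beat_params)
  structure(list(metrics = metrics, trace = trace, fields = fields,
                 beat_times = beats),
            class = "video_analysis")
}

#' End-to-end calcium-transient analysis of one trace
#'
#' Normalizes a raw fluorescence trace to dF/F0, detects transients, and
#' extracts the kinetic features.
#'
#' @param trace an [intensity_trace()] of raw fluorescence, or a CSV path
#'   accepted by [read_trace()].
#' @param beat_params a [beat_detection_params()].
#' @param baseline_percentile percentile for the F0 baseline. Default 10.
#' @return List of class `trace_analysis`: `features` (a
#'   [transient_features()]), `norm` (the normalized trace), `events`.
#' @export
analyze_trace <- function(trace, beat_params = beat_detection_params(),
                          baseline_percentile = 10) {
  if (is.character(trace)) trace <- read_trace(trace)
  norm <- normalize_dff(trace, baseline_percentile)
  events <- detect_transients(norm, beat_params)
  features <- transient_features(norm, events)
  structure(list(features = features, norm = norm, events = events),
            class = "trace_analysis")
}

#' Flatten a metrics object for serialization
#'
#' Keeps the scalar numeric/logical entries of a [beat_metrics()] or
#' [transient_features()] object as a plain named list, the form written to
#' metrics JSON files.
#'
#' @param m a metrics object.
#' @return A named list of scalars.
#' @export
metrics_to_list <- function(m) {
  keep <- vapply(m, function(v) (is.numeric(v) || is.logical(v)) && length(v) == 1,
                 logical(1))
  lapply(m[keep], function(v) if (is.logical(v)) v else as.numeric(v))
}
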