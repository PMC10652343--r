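#' Beat-detection parameters
#'
#' @param prominence_frac required peak prominence as a fraction of the
#'   trace's 5th-95th percentile span, in (0, 1]. Default 0.3.
#' @param min_interbeat_s refractory interval: two retained beats must be at
#'   least this far apart in seconds (> 0). Default 0.25. This also merges
#'   the contraction/relaxation speed-peak pair of a single beat into one
#'   event.
#' @param area_amp_frac per-block amplitude threshold for the beat area, as
#'   a fraction of the maximum per-block amplitude over the grid, in
#'   (0, 1]. Default 0.2.
#' @param min_peak_px_per_frame noise floor for motion traces, in pixels of
#'   mean block displacement per frame pair (>= 0). Block displacements are
#'   whole pixels, so an isolated wrong match of a single block produces a
#'   spike of `1/n_blocks` px; requiring a beat peak to reach this mean
#'   displacement rejects such quantization noise while any genuine beat
#'   (many blocks moving >= 1 px) clears it easily. Applied only to traces
#'   that carry the pixel-to-velocity conversion (see
#'   [motion_magnitude_trace()]). Default 0.05.
#' @return A list of class `beat_detection_params`.
#' @export
beat_detection_params <- function(prominence_frac = 0.3, min_interbeat_s = 0.25,
                                  area_amp_frac = 0.2,
                                  min_peak_px_per_frame = 0.05) {
  if (prominence_frac <= 0 || prominence_frac > 1)
    stop_beatkit("bad_params", "prominence_frac must be in (0, 1]")
  if (min_interbeat_s <= 0)
    stop_beatkit("bad_params", "min_interbeat_s must be positive")
  if (area_amp_frac <= 0 || area_amp_frac > 1)
    stop_beatkit("bad_params", "area_amp_frac must be in (0, 1]")
  if (min_peak_px_per_frame < 0)
    stop_beatkit("bad_params", "min_peak_px_per_frame must be >= 0")
  structure(list(prominence_frac = prominence_frac,
                 min_interbeat_s = min_interbeat_s,
                 area_amp_frac = area_amp_frac,
                 min_peak_px_per_frame = min_peak_px_per_frame),
            class = "beat_detection_params")
}

# Plateau-aware local maxima with topographic prominence.
# Runs of equal values are one candidate at the run midpoint; runs touching
# either end of the series are not maxima. Prominence of a peak is its
# height minus the higher of the two minima separating it from higher
# ground (or from the series edge).
find_peaks <- function(v) {
  n <- length(v)
  if (n < 3) return(data.frame(index = integer(), height = numeric(),
                               prominence = numeric()))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  idx <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
        idx <- c(idx, (starts[j] + ends[j]) %/% 2L)
    }
  }
  if (length(idx) == 0) return(data.frame(index = integer(), height = numeric(),
                                          prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- v[i]
    lmin <- h
    for (j in seq(i - 1L, 1L)) {
      if (v[j] > h) break
      if (v[j] < lmin) lmin <- v[j]
    }
    rmin <- h
    for (j in seq(i + 1L, n)) {
      if (v[j] > h) break
      if (v[j] < rmin) rmin <- v[j]
    }
    h - max(lmin, rmin)
  }, numeric(1))
  data.frame(index = idx, height = v[idx], prominence = prom)
}

# Shared peak picker: prominence threshold relative to the 5th-95th
# percentile span (a degenerate zero span imposes no relative threshold),
# an optional absolute height floor, then a refractory rule keeping the
# higher (earlier on ties) of any two candidates closer than
# min_interbeat_s.
pick_events <- function(times, values, params, min_height = 0) {
  keep <- is.finite(values) & is.finite(times)
  times <- times[keep]; values <- values[keep]
  if (length(values) < 3) return(data.frame(index = integer(), time_s = numeric(),
                                            height = numeric()))
  pk <- find_peaks(values)
  span <- diff(quantile(values, c(0.05, 0.95), names = FALSE))
  pk <- pk[pk$prominence > 0 &
             pk$prominence >= params$prominence_frac * span &
             pk$height >= min_height, , drop = FALSE]
  if (nrow(pk) == 0) return(data.frame(index = integer(), time_s = numeric(),
                                       height = numeric()))
  ord <- order(-pk$height, times[pk$index])
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(times[pk$index[i]] - times[pk$index[kept]]) >= params$min_interbeat_s))
      kept <- c(kept, i)
  }
  kept <- kept[order(pk$index[kept])]
  orig_index <- which(keep)[pk$index[kept]]
  data.frame(index = orig_index, time_s = times[pk$index[kept]],
             height = pk$height[kept])
}

#' Detect beats in a motion trace
#'
#' Beats are local maxima of the aggregate motion speed whose topographic
#' prominence reaches `prominence_frac` times the trace's 5th-95th
#' percentile span, thinned so that no two retained beats are closer than
#' `min_interbeat_s` (the higher peak wins; the earlier on exact ties).
#' Traces produced by [motion_magnitude_trace()] additionally apply the
#' `min_peak_px_per_frame` noise floor to reject single-block quantization
#' spikes. Deterministic for fixed input; a flat trace yields no beats.
#'
#' @param trace a [motion_trace()].
#' @param params a [beat_detection_params()].
#' @return Numeric vector of beat times in seconds (possibly empty).
#' @export
detect_beats <- function(trace, params = beat_detection_params()) {
  if (nrow(trace) < 3)
    stop_beatkit("too_short", "motion trace needs at least 3 samples")
  um_per_px_frame <- attr(trace, "um_per_px_frame")
  floor_um_s <- if (is.null(um_per_px_frame)) 0 else
    params$min_peak_px_per_frame * um_per_px_frame
  pick_events(trace$times_s, trace$velocity_um_s, params, floor_um_s)$time_s
}

#' Spontaneous beating frequency
#'
#' The reciprocal mean inter-beat interval: `(n_beats - 1)` divided by the
#' time from first to last beat. With one beat or none there is no period to
#' define, the recording is classified as not beating and 0 is returned.
#'
#' @param beat_times numeric beat times in seconds.
#' @param duration_s recording duration (> 0); used only for validation.
#' @return Frequency in Hz (0 when not beating).
#' @export
beating_frequency <- function(beat_times, duration_s) {
  if (duration_s <= 0) stop_beatkit("bad_params", "duration_s must be positive")
  n <- length(beat_times)
  if (n <= 1) return(0)
  (n - 1) / (max(beat_times) - min(beat_times))
}

#' Beating velocity
#'
#' The mean over detected beats of the aggregate motion speed at the beat
#' peak (peak systolic speed, the standard contractility surrogate);
#' 0 when there are no beats.
#'
#' @param trace a [motion_trace()].
#' @param beat_times numeric beat times from [detect_beats()].
#' @return Mean peak speed in um/s.
#' @export
beating_velocity <- function(trace, beat_times) {
  if (length(beat_times) == 0) return(0)
  peaks <- vapply(beat_times, function(t) {
    trace$velocity_um_s[which.min(abs(trace$times_s - t))]
  }, numeric(1))
  mean(peaks)
}

#' Maximum displacement
#'
#' The maximum over all frame pairs and valid blocks of the per-frame-pair
#' displacement magnitude `sqrt(dx^2 + dy^2)`.
#'
#' @param fields displacement fields from [compute_fields()].
#' @param pixel_size_um pixel edge length in micrometers.
#' @return List with `px` and `um`.
#' @export
max_displacement <- function(fields, pixel_size_um = 1.0) {
  mags <- unlist(lapply(fields, function(f) {
    if (!any(f$valid)) return(numeric(0))
    sqrt(f$dx[f$valid]^2 + f$dy[f$valid]^2)
  }))
  if (length(mags) == 0)
    stop_beatkit("no_valid_blocks", "no valid blocks in any frame pair")
  list(px = max(mags), um = max(mags) * pixel_size_um)
}

#' Beat area
#'
#' Each valid block's amplitude is its maximum displacement magnitude over
#' the recording. Blocks with amplitude at least `area_amp_frac` times the
#' largest per-block amplitude are classified as beating; the beat area is
#' the percentage of valid blocks so classified. When nothing moves at all
#' (every amplitude 0) the beat area is 0.
#'
#' @param fields displacement fields from [compute_fields()].
#' @param params a [beat_detection_params()].
#' @return Percentage in `[0, 100]`.
#' @export
beat_area <- function(fields, params = beat_detection_params()) {
  valid <- Reduce(`|`, lapply(fields, function(f) f$valid))
  if (!any(valid))
    stop_beatkit("no_valid_blocks", "no valid blocks in any frame pair")
  amp <- Reduce(pmax, lapply(fields, function(f) {
    m <- sqrt(f$dx^2 + f$dy^2)
    m[!f$valid] <- 0
    m
  }))
  amp <- amp[valid]
  if (max(amp) == 0) return(0)
  100 * sum(amp >= params$area_amp_frac * max(amp)) / length(amp)
}

#' All beat metrics for one recording
#'
#' Convenience wrapper computing every beating read-out from a motion trace
#' and its displacement fields.
#'
#' @param trace a [motion_trace()].
#' @param fields displacement fields from [compute_fields()].
#' @param duration_s recording duration in seconds.
#' @param pixel_size_um pixel edge length in micrometers.
#' @param params a [beat_detection_params()].
#' @return A list of class `beat_metrics`: `frequency_hz`, `velocity_um_s`,
#'   `max_displacement_px`, `max_displacement_um`, `beat_area_pct`,
#'   `n_beats`, `is_beating`.
#' @export
beat_metrics <- function(trace, fields, duration_s, pixel_size_um = 1.0,
                         params = beat_detection_params()) {
  beats <- detect_beats(trace, params)
  md <- max_displacement(fields, pixel_size_um)
  structure(list(
    frequency_hz = beating_frequency(beats, duration_s),
    velocity_um_s = beating_velocity(trace, beats),
    max_displacement_px = md$px,
    max_displacement_um = md$um,
    beat_area_pct = beat_area(fields, params),
    n_beats = length(beats),
    is_beating = length(beats) > 1
  ), class = "beat_metrics")
}

#' Normalize beat metrics to a pre-stress baseline
#'
#' Each metric is divided by its own-sample baseline value (so the baseline
#' recording normalizes to exactly 1.0), expressing recovery as a
#' dimensionless fraction of the initial value. A metric whose baseline is
#' zero or missing has no defined ratio and is flagged undefined (`NA`),
#' never infinity.
#'
#' @param metrics_t a [beat_metrics()] at the timepoint of interest.
#' @param metrics_baseline the same sample's pre-stress [beat_metrics()].
#' @param which character vector of metric names to normalize.
#' @return List with `ratios` (named numeric, `NA` where undefined) and
#'   `undefined` (named logical).
#' @export
normalize_to_baseline <- function(metrics_t, metrics_baseline,
                                  which = c("frequency_hz", "velocity_um_s",
                                            "max_displacement_um",
                                            "beat_area_pct")) {
  ratios <- setNames(rep(NA_real_, length(which)), which)
  undef <- setNames(rep(FALSE, length(which)), which)
  for (m in which) {
    b <- metrics_baseline[[m]]
    v <- metrics_t[[m]]
    if (is.null(b) || is.null(v) || !is.finite(b) || !is.finite(v) || b <= 0) {
      undef[m] <- TRUE
    } else {
      ratios[m] <- v / b
    }
  }
  list(ratios = ratios, undefined = undef)
}
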