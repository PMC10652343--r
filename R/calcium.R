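#' Normalize a fluorescence trace to dF/F0
#'
#' The baseline fluorescence `F0` is a low percentile of the raw intensity
#' samples (default the 10th: robust to the transients themselves, which
#' occupy the upper tail) and the normalized signal is `(F - F0) / F0`.
#'
#' @param trace an [intensity_trace()] of raw fluorescence (values > 0).
#' @param baseline_percentile percentile (0-100) used for `F0`. Default 10.
#' @return A list of class `normalized_trace`: `times_s`, `dff`, `f0`.
#' @export
normalize_dff <- function(trace, baseline_percentile = 10) {
  f0 <- quantile(trace$values, baseline_percentile / 100, names = FALSE)
  if (!is.finite(f0) || f0 <= 0)
    stop_beatkit("nonpositive_f0", "baseline fluorescence F0 must be positive")
  structure(list(times_s = trace$times_s, dff = (trace$values - f0) / f0,
                 f0 = f0, label = trace$label),
            class = "normalized_trace")
}

# Centered running mean used only to stabilize peak *detection* on noisy
# traces; all kinetic features are measured on the raw signal. The window
# is short (default 0.1 s) relative to any physiological transient.
running_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect calcium transients
#'
#' Transient peaks are found with the same prominence/refractory rule as
#' [detect_beats()], applied to a lightly smoothed copy of the signal
#' (running mean over `smooth_window_s`) so that single-sample noise does
#' not create events; each detected peak is then refined to the raw-signal
#' maximum in its neighbourhood. For each peak, the local baseline is the
#' minimum dF/F0 between the previous peak (or the trace start) and the
#' peak; the onset is the last sample before the peak at which the signal
#' is within `onset_frac` (10%) of the amplitude above that local baseline,
#' walked back to the start of the monotone rise; the reported amplitude is
#' `dff(peak) - local baseline`.
#'
#' @param norm a [normalize_dff()] result.
#' @param params a [beat_detection_params()].
#' @param smooth_window_s width of the detection smoothing window in
#'   seconds (0 disables smoothing). Default 0.1.
#' @param onset_frac rise fraction defining the onset. Default 0.1.
#' @return Data frame of class `transient_events` with one row per
#'   transient: `onset_index`, `onset_s`, `peak_index`, `peak_s`,
#'   `amplitude`.
#' @export
detect_transients <- function(norm, params = beat_detection_params(),
                              smooth_window_s = 0.1, onset_frac = 0.1) {
  n <- length(norm$dff)
  if (n < 5)
    stop_beatkit("too_short", "normalized trace needs at least 5 samples")
  dt <- stats::median(diff(norm$times_s))
  k <- max(1L, round(smooth_window_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  sm <- running_mean(norm$dff, k)
  ev <- pick_events(norm$times_s, sm, params)
  sigma <- stats::mad(diff(norm$dff)) / sqrt(2)
  out <- data.frame(onset_index = integer(0), onset_s = numeric(0),
                    peak_index = integer(0), peak_s = numeric(0),
                    amplitude = numeric(0))
  prev_peak <- 0L
  for (i in seq_len(nrow(ev))) {
    # smoothed apex, refined to the raw maximum among immediate neighbours
    lo_w <- max(1L, ev$index[i] - 1L)
    hi_w <- min(n, ev$index[i] + 1L)
    p <- lo_w + which.max(norm$dff[lo_w:hi_w]) - 1L
    lo <- prev_peak + 1L
    if (p <= lo) next
    # local baseline: median of raw samples statistically indistinguishable
    # from the smoothed minimum (robust to pixel noise, unlike the raw
    # min); the band scales with the measured noise so that on noisy data
    # enough samples enter the median while a noise-free tail keeps the
    # band tight against residual-decay contamination
    seg <- lo:p
    sm_min <- min(sm[seg])
    band <- max(0.05 * (sm[ev$index[i]] - sm_min), sigma / sqrt(k))
    near_min <- seg[sm[seg] <= sm_min + band]
    local_base <- stats::median(norm$dff[near_min])
    amp <- norm$dff[p] - local_base
    if (amp <= 0) next
    thresh <- local_base + onset_frac * amp
    before <- lo:(p - 1L)
    cand <- before[norm$dff[before] <= thresh]
    onset <- if (length(cand)) max(cand) else lo
    # walk back over the monotone foot of the rise to its start; steps
    # smaller than the noise scale do not count as part of the rise
    while (onset > lo && norm$dff[onset - 1L] < norm$dff[onset] - sigma)
      onset <- onset - 1L
    out <- rbind(out, data.frame(
      onset_index = onset, onset_s = norm$times_s[onset],
      peak_index = p, peak_s = norm$times_s[p],
      amplitude = amp))
    prev_peak <- p
  }
  structure(out, class = c("transient_events", "data.frame"))
}

# First time after the peak (within [peak_index, bound]) at which the
# signal decays to `level`, located by linear interpolation between the
# bracketing samples. A crossing must be confirmed by the following sample
# also lying at or below the level (unless it is the last in range), so an
# isolated noise dip does not end a transient early. NA when the segment
# never reaches the level (truncated).
decay_crossing <- function(times, dff, peak_index, level, bound = length(dff)) {
  if (peak_index >= bound) return(NA_real_)
  for (j in (peak_index + 1L):bound) {
    if (dff[j] <= level && (j == bound || dff[j + 1L] <= level)) {
      v0 <- dff[j - 1L]; v1 <- dff[j]
      if (v0 <= level || v0 == v1) return(times[j])
      return(times[j - 1L] + (v0 - level) / (v0 - v1) * (times[j] - times[j - 1L]))
    }
  }
  NA_real_
}

# Interpolated time at which the rising edge (onset..peak) passes `level`:
# the last sample at or below the level, interpolated toward the next.
rise_crossing <- function(times, dff, onset, peak_index, level) {
  if (peak_index <= onset) return(times[onset])
  idx <- onset:(peak_index - 1L)
  below <- idx[dff[idx] <= level]
  if (!length(below)) return(times[onset])
  j <- max(below)
  v0 <- dff[j]; v1 <- dff[j + 1L]
  if (v1 <= v0) return(times[j + 1L])
  times[j] + (level - v0) / (v1 - v0) * (times[j + 1L] - times[j])
}

#' Calcium-transient kinetic features
#'
#' Per transient: `apd50` is the time from the peak to the decay crossing
#' at 50% of the amplitude below the peak (linearly interpolated between
#' the bracketing samples, confirmed by the following sample so isolated
#' noise dips do not count, and bounded by the next transient's onset),
#' `apd90` analogously at 90%; triangulation is the ratio `apd90 / apd50`;
#' time-to-peak is the rise duration measured by the interpolated 10% and
#' 90% rise crossings, `ttp = (t90 - t10) / 0.8`, the standard rise-time
#' convention, which is robust to sampling-grid quantization of the apex.
#' Decay levels are referenced to the raw peak sample (exact on noise-free
#' data); the steep rise crossings instead use a 1-2-1-weighted peak value
#' when pixel noise is measurable, since there a noisy single-sample
#' amplitude would bias the rise-time. Recording-level features are medians
#' across transients (robust to irregular transient shapes); frequency uses
#' the peak times as in [beating_frequency()]. Transients truncated before
#' the 90% (50%) decay are excluded from apd90 and triangulation (apd50)
#' with a warning.
#'
#' @param norm a [normalize_dff()] result.
#' @param events a [detect_transients()] result.
#' @return A list of class `transient_features`: `frequency_hz`, `ttp_s`,
#'   `apd50_s`, `apd90_s`, `triangulation`, `n_transients`, and
#'   `per_transient_table`.
#' @export
transient_features <- function(norm, events) {
  if (nrow(events) < 1)
    stop_beatkit("no_transients", "no transients to characterize")
  n <- length(norm$dff)
  tab <- events
  tab$ttp_s <- NA_real_
  tab$apd50_s <- NA_real_
  tab$apd90_s <- NA_real_
  sigma <- stats::mad(diff(norm$dff)) / sqrt(2)
  for (i in seq_len(nrow(tab))) {
    p <- tab$peak_index[i]
    onset <- tab$onset_index[i]
    bound <- if (i < nrow(tab)) max(tab$onset_index[i + 1L] - 1L, p + 1L) else n
    peak_v <- norm$dff[p]
    a <- tab$amplitude[i]
    base <- peak_v - a
    # rise-time levels from a noise-damped peak estimate
    pv_rise <- if (is.finite(sigma) && sigma > 0.01 * a) {
      i0 <- max(1L, p - 1L); i1 <- min(n, p + 1L)
      wts <- c(1, 2, 1)[seq_len(i1 - i0 + 1L)]
      sum(norm$dff[i0:i1] * wts) / sum(wts)
    } else peak_v
    a_rise <- pv_rise - base
    t10 <- rise_crossing(norm$times_s, norm$dff, onset, p, base + 0.1 * a_rise)
    t90 <- rise_crossing(norm$times_s, norm$dff, onset, p, base + 0.9 * a_rise)
    tab$ttp_s[i] <- if (is.finite(t10) && is.finite(t90) && t90 > t10)
      (t90 - t10) / 0.8 else tab$peak_s[i] - tab$onset_s[i]
    c50 <- decay_crossing(norm$times_s, norm$dff, p, peak_v - 0.5 * a, bound)
    c90 <- decay_crossing(norm$times_s, norm$dff, p, peak_v - 0.9 * a, bound)
    tab$apd50_s[i] <- c50 - norm$times_s[p]
    tab$apd90_s[i] <- c90 - norm$times_s[p]
  }
  if (anyNA(tab$apd90_s))
    warning(sprintf("%d transient(s) truncated before 90%% decay; excluded from apd90/triangulation",
                    sum(is.na(tab$apd90_s))))
  tri <- tab$apd90_s / tab$apd50_s
  structure(list(
    frequency_hz = if (nrow(tab) >= 2)
      beating_frequency(tab$peak_s, diff(range(norm$times_s))) else 0,
    ttp_s = median(tab$ttp_s),
    apd50_s = median(tab$apd50_s, na.rm = TRUE),
    apd90_s = if (all(is.na(tab$apd90_s))) NA_real_ else median(tab$apd90_s, na.rm = TRUE),
    triangulation = if (all(is.na(tri))) NA_real_ else median(tri, na.rm = TRUE),
    n_transients = nrow(tab),
    per_transient_table = tab
  ), class = "transient_features")
}

#' Compare pre/post drug transient features
#'
#' Per-feature absolute and percent change (post minus pre) for the same
#' sample, plus a chronotropic "responder" flag raised when the beating
#' frequency increases by more than `responder_frac`. A feature missing on
#' either side has an undefined delta (`NA`).
#'
#' @param pre,post [transient_features()] for the same sample before and
#'   after treatment.
#' @param responder_frac minimum fractional frequency increase to call the
#'   sample a responder. Default 0.1 (+10%).
#' @return A list of class `drug_response`: `delta` and `percent` (named
#'   numeric vectors over the kinetic features) and `responder`.
#' @export
compare_drug_response <- function(pre, post, responder_frac = 0.1) {
  feats <- c("frequency_hz", "ttp_s", "apd50_s", "apd90_s", "triangulation")
  delta <- setNames(rep(NA_real_, length(feats)), feats)
  pct <- delta
  for (f in feats) {
    a <- pre[[f]]; b <- post[[f]]
    if (is.null(a) || is.null(b) || !is.finite(a) || !is.finite(b)) next
    delta[f] <- b - a
    pct[f] <- if (a != 0) 100 * (b - a) / a else NA_real_
  }
  responder <- is.finite(delta["frequency_hz"]) && is.finite(pre$frequency_hz) &&
    pre$frequency_hz > 0 &&
    (post$frequency_hz - pre$frequency_hz) / pre$frequency_hz > responder_frac
  structure(list(delta = delta, percent = pct, responder = unname(responder)),
            class = "drug_response")
}
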