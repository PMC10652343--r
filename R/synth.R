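#' Synthetic beating-video configuration
#'
#' Describes a textured monolayer displaced by a spatially enveloped,
#' approximately periodic motion field: the stand-in for a brightfield
#' recording of spontaneously beating cardiomyocytes, with every ground
#' truth parameter known.
#'
#' @param frequency_hz beating frequency (> 0). Default 0.5.
#' @param amplitude_px peak displacement of the motion field in pixels
#'   (>= 0). Default 3.
#' @param duration_s recording length in seconds. Default 30.
#' @param frame_rate_hz frames per second. Default 30.
#' @param frame_size `c(H, W)` in pixels. Default `c(256, 256)`.
#' @param envelope spatial weighting of the motion: `"uniform"` (the whole
#'   sheet contracts synchronously, the default) or `"gaussian"` (focal
#'   beating center).
#' @param envelope_sigma Gaussian envelope SD in pixels; default
#'   `min(H, W) / 4`.
#' @param texture_grain_px correlation length of the random texture
#'   (Gaussian smoothing sigma is half of this). Default 8.
#' @param noise_sd additive Gaussian pixel noise SD, in intensity units of
#'   the texture (which is standardized to mean 100, SD 10, so the default
#'   1 gives texture-contrast SNR 10). Default 1.
#' @param irregularity coefficient of variation of inter-beat intervals
#'   (0 = perfectly periodic). Default 0.05.
#' @param pulse_width_s duration of one raised-cosine contraction/
#'   relaxation cycle. Default 0.4.
#' @param direction_deg direction of the motion in degrees (0 = rightward
#'   along x). Default 30.
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_video_config`.
#' @export
synthetic_video_config <- function(frequency_hz = 0.5, amplitude_px = 3,
                                   duration_s = 30, frame_rate_hz = 30,
                                   frame_size = c(256, 256),
                                   envelope = c("uniform", "gaussian"),
                                   envelope_sigma = NULL,
                                   texture_grain_px = 8, noise_sd = 1,
                                   irregularity = 0.05, pulse_width_s = 0.4,
                                   direction_deg = 30, seed = 1L) {
  envelope <- match.arg(envelope)
  if (frequency_hz <= 0) stop_beatkit("bad_params", "frequency_hz must be positive")
  if (amplitude_px < 0) stop_beatkit("bad_params", "amplitude_px must be >= 0")
  if (duration_s * frame_rate_hz < 3)
    stop_beatkit("bad_params", "need at least 3 frames")
  if (amplitude_px > min(frame_size) / 4)
    stop_beatkit("amplitude_too_large", "amplitude_px too large for the frame size")
  structure(list(frequency_hz = frequency_hz, amplitude_px = amplitude_px,
                 duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 frame_size = frame_size, envelope = envelope,
                 envelope_sigma = envelope_sigma %||% (min(frame_size) / 4),
                 texture_grain_px = texture_grain_px, noise_sd = noise_sd,
                 irregularity = irregularity, pulse_width_s = pulse_width_s,
                 direction_deg = direction_deg, seed = as.integer(seed)),
            class = "synthetic_video_config")
}

#' Synthetic calcium-trace configuration
#'
#' Emulates a Fluo-4 intensity recording: transients with a linear rise of
#' duration `ttp_s` to `amplitude_dff`, exponential decay with time
#' constant `decay_tau_s`, superposed on baseline fluorescence. Defaults
#' follow a 30 ms exposure for 30 s (33.3 Hz).
#'
#' @param frequency_hz transient rate (> 0). Default 0.5.
#' @param ttp_s rise time from onset to peak. Default 0.15.
#' @param decay_tau_s exponential decay time constant. Default 0.4.
#' @param amplitude_dff peak dF/F0 of one transient. Default 2.
#' @param baseline_f0 baseline raw fluorescence. Default 100.
#' @param noise_sd additive Gaussian noise SD in raw fluorescence units
#'   (default 20: one tenth of the default raw transient amplitude, SNR 10).
#' @param irregularity coefficient of variation of inter-transient
#'   intervals. Default 0.
#' @param duration_s recording length. Default 30.
#' @param sample_rate_hz sampling rate. Default 100/3 (30 ms frames).
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_trace_config`.
#' @export
synthetic_trace_config <- function(frequency_hz = 0.5, ttp_s = 0.15,
                                   decay_tau_s = 0.4, amplitude_dff = 2,
                                   baseline_f0 = 100, noise_sd = 20,
                                   irregularity = 0, duration_s = 30,
                                   sample_rate_hz = 100 / 3, seed = 1L) {
  if (frequency_hz <= 0) stop_beatkit("bad_params", "frequency_hz must be positive")
  if (ttp_s <= 0 || decay_tau_s <= 0)
    stop_beatkit("bad_params", "ttp_s and decay_tau_s must be positive")
  if (baseline_f0 <= 0) stop_beatkit("bad_params", "baseline_f0 must be positive")
  if (ttp_s + 3 * decay_tau_s >= 1 / frequency_hz)
    stop_beatkit("overlapping_transients",
                 "transients would overlap: require ttp_s + 3*decay_tau_s < 1/frequency_hz")
  structure(list(frequency_hz = frequency_hz, ttp_s = ttp_s,
                 decay_tau_s = decay_tau_s, amplitude_dff = amplitude_dff,
                 baseline_f0 = baseline_f0, noise_sd = noise_sd,
                 irregularity = irregularity, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, seed = as.integer(seed)),
            class = "synthetic_trace_config")
}

# Event times with a given rate and inter-event coefficient of variation.
# First event at half a period; intervals are truncated normal draws.
draw_event_times <- function(frequency_hz, duration_s, irregularity) {
  period <- 1 / frequency_hz
  t <- period / 2
  out <- numeric(0)
  while (t < duration_s) {
    out <- c(out, t)
    gap <- if (irregularity > 0)
      max(0.2 * period, rnorm(1, period, irregularity * period)) else period
    t <- t + gap
  }
  out
}

# Seeded random texture: white noise smoothed by circular (FFT) convolution
# with a Gaussian kernel of sigma = grain/2, standardized to mean 100, SD 10.
make_texture <- function(h, w, grain_px) {
  tex <- matrix(rnorm(h * w), h, w)
  if (grain_px > 0) {
    circ_gauss <- function(n, sigma) {
      x <- 0:(n - 1)
      k <- stats::dnorm(pmin(x, n - x), sd = sigma)
      k / sum(k)
    }
    sigma <- grain_px / 2
    K <- outer(circ_gauss(h, sigma), circ_gauss(w, sigma))
    tex <- Re(stats::fft(stats::fft(tex) * stats::fft(K), inverse = TRUE)) / (h * w)
  }
  100 + 10 * (tex - mean(tex)) / sd(tex)
}

# Raised-cosine contraction/relaxation pulse train evaluated at times t.
pulse_train <- function(t, beat_times, width) {
  d <- numeric(length(t))
  for (tb in beat_times) {
    u <- (t - tb) / width
    inside <- u >= 0 & u <= 1
    d[inside] <- d[inside] + 0.5 * (1 - cos(2 * pi * u[inside]))
  }
  d
}

#' Generate a synthetic beating video
#'
#' Builds a seeded smoothed random texture, then warps it frame by frame by
#' the displacement `d(t) * envelope(x, y)` along a fixed direction, where
#' `d(t)` is `amplitude_px` times a raised-cosine pulse train at the drawn
#' beat times. Warping uses inverse mapping with bilinear interpolation;
#' Gaussian pixel noise is added last. Fully reproducible from the seed.
#'
#' @param config a [synthetic_video_config()].
#' @return A list with `stack` (a [frame_stack()]) and `truth` (class
#'   `synthetic_ground_truth`: the config, realized `beat_times`, the
#'   per-frame scalar displacement series `displacement_px`, the motion
#'   `direction` unit vector, and the spatial `envelope` matrix).
#' @export
generate_beating_video <- function(config) {
  set.seed(config$seed)
  H <- config$frame_size[1]; W <- config$frame_size[2]
  margin <- as.integer(ceiling(config$amplitude_px) + 2)
  tex <- make_texture(H + 2 * margin, W + 2 * margin, config$texture_grain_px)
  env <- if (config$envelope == "uniform") {
    matrix(1, H, W)
  } else {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    r2 <- outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`)
    exp(-r2 / (2 * config$envelope_sigma^2))
  }
  theta <- config$direction_deg * pi / 180
  ux <- cos(theta); uy <- sin(theta)
  beat_times <- draw_event_times(config$frequency_hz, config$duration_s,
                                 config$irregularity)
  n_frames <- round(config$duration_s * config$frame_rate_hz)
  t_frames <- (seq_len(n_frames) - 1) / config$frame_rate_hz
  d <- config$amplitude_px * pulse_train(t_frames, beat_times, config$pulse_width_s)
  frames <- gen_frames_cpp(tex, env, d, ux, uy, margin, config$noise_sd,
                           config$envelope == "uniform")
  truth <- structure(list(config = config, beat_times = beat_times,
                          displacement_px = data.frame(time_s = t_frames,
                                                       d_px = d),
                          direction = c(ux = ux, uy = uy), envelope = env),
                     class = "synthetic_ground_truth")
  list(stack = frame_stack(frames, config$frame_rate_hz,
                           source_id = sprintf("synthetic(seed=%d)", config$seed)),
       truth = truth)
}

#' Generate a synthetic calcium trace
#'
#' Each transient rises linearly for `ttp_s` to `amplitude_dff`, then
#' decays exponentially with time constant `decay_tau_s`; the dF/F0 signal
#' is converted to raw fluorescence `F = F0 * (1 + dff)` and Gaussian noise
#' is added. Reproducible from the seed.
#'
#' @param config a [synthetic_trace_config()].
#' @return A list with `trace` (an [intensity_trace()] of raw fluorescence)
#'   and `truth` (class `synthetic_ground_truth` with the config, realized
#'   `beat_times`, and the noise-free `dff`).
#' @export
generate_calcium_trace <- function(config) {
  set.seed(config$seed)
  n <- round(config$duration_s * config$sample_rate_hz)
  t <- (seq_len(n) - 1) / config$sample_rate_hz
  beat_times <- draw_event_times(config$frequency_hz, config$duration_s,
                                 config$irregularity)
  dff <- numeric(n)
  for (tb in beat_times) {
    rel <- t - tb
    rise <- rel >= 0 & rel < config$ttp_s
    decay <- rel >= config$ttp_s
    dff[rise] <- dff[rise] + config$amplitude_dff * rel[rise] / config$ttp_s
    dff[decay] <- dff[decay] +
      config$amplitude_dff * exp(-(rel[decay] - config$ttp_s) / config$decay_tau_s)
  }
  values <- config$baseline_f0 * (1 + dff)
  if (config$noise_sd > 0) values <- values + rnorm(n, sd = config$noise_sd)
  truth <- structure(list(config = config, beat_times = beat_times,
                          dff_clean = dff),
                     class = "synthetic_ground_truth")
  list(trace = intensity_trace(t, values,
                               label = sprintf("synthetic(seed=%d)", config$seed)),
       truth = truth)
}

# Deterministic 31-bit seed from the master seed, a group label and a
# sample index (djb2-style string hash), so batches are reproducible and
# insensitive to generation order.
derive_seed <- function(master_seed, label, index) {
  s <- paste(master_seed, label, index, sep = "/")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Generate a grouped batch of synthetic recordings
#'
#' Emulates a multi-group experimental design (for example three age
#' groups): every sample gets a deterministically derived seed and a true
#' frequency drawn from its group's distribution, and the batch manifest is
#' the ground-truth table against which pipeline estimates can be scored.
#'
#' @param group_specs list of group specifications, each a list with
#'   `label` (unique), `config` (a [synthetic_video_config()] or
#'   [synthetic_trace_config()] giving the group mean parameters),
#'   `n_samples` (>= 1), and optionally `frequency_sd_hz` (between-sample
#'   SD of the true frequency; default 0).
#' @param master_seed integer master seed.
#' @return A list with `samples` (per sample: `sample_id`, `group`,
#'   `seed`, the generated `recording` and its `truth`) and `manifest`
#'   (data frame: `sample_id`, `group`, `seed`, `true_frequency_hz`).
#' @export
generate_group_dataset <- function(group_specs, master_seed = 1L) {
  labels <- vapply(group_specs, function(g) g$label, character(1))
  if (anyDuplicated(labels))
    stop_beatkit("duplicate_labels", "group labels must be unique")
  samples <- list()
  rows <- list()
  for (g in group_specs) {
    if (g$n_samples < 1) stop_beatkit("bad_params", "n_samples must be >= 1")
    fsd <- g$frequency_sd_hz %||% 0
    for (i in seq_len(g$n_samples)) {
      seed_i <- derive_seed(master_seed, g$label, i)
      cfg <- g$config
      cfg$seed <- seed_i
      if (fsd > 0) {
        set.seed(seed_i)
        cfg$frequency_hz <- max(0.05, rnorm(1, g$config$frequency_hz, fsd))
      }
      rec <- if (inherits(cfg, "synthetic_video_config"))
        generate_beating_video(cfg) else generate_calcium_trace(cfg)
      sid <- sprintf("%s_%02d", g$label, i)
      samples[[sid]] <- list(sample_id = sid, group = g$label, seed = seed_i,
                             recording = rec[[1]], truth = rec$truth)
      rows[[sid]] <- data.frame(sample_id = sid, group = g$label, seed = seed_i,
                                true_frequency_hz = cfg$frequency_hz)
    }
  }
  list(samples = samples, manifest = do.call(rbind, c(rows, make.row.names = FALSE)))
}
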