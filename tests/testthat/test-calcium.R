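test_that("dF/F0 normalization uses the percentile baseline", {
  t <- seq(0, 3, by = 0.03)
  const <- intensity_trace(t, rep(100, length(t)))
  n <- normalize_dff(const)
  expect_equal(n$f0, 100)
  expect_equal(n$dff, rep(0, length(t)))

  # baseline 100 with excursions to 300: peak dff = 2
  v <- rep(100, length(t)); v[30:35] <- 300
  n2 <- normalize_dff(intensity_trace(t, v))
  expect_equal(n2$f0, 100)
  expect_equal(max(n2$dff), 2.0)

  zero <- intensity_trace(t, c(rep(0, 30), rep(100, length(t) - 30)))
  expect_error(normalize_dff(zero), class = "beatkit_error_nonpositive_f0")
})

# Noise-free single transient: linear rise over ttp then exponential decay.
one_transient_trace <- function(ttp = 0.2, tau = 0.4, amp = 2, f0 = 100,
                                rate = 100, duration = 8, onset = 1) {
  t <- seq(0, duration, by = 1 / rate)
  dff <- numeric(length(t))
  rel <- t - onset
  rise <- rel >= 0 & rel < ttp
  dec <- rel >= ttp
  dff[rise] <- amp * rel[rise] / ttp
  dff[dec] <- amp * exp(-(rel[dec] - ttp) / tau)
  intensity_trace(t, f0 * (1 + dff))
}

test_that("detect_transients locates onsets and counts events", {
  t <- seq(0, 10, by = 0.03)
  flat <- normalize_dff(intensity_trace(t, rep(100, length(t))))
  expect_equal(nrow(detect_transients(flat)), 0)

  tr <- one_transient_trace(ttp = 0.2, onset = 1)
  ev <- detect_transients(normalize_dff(tr))
  expect_equal(nrow(ev), 1)
  # onset within a couple of samples of the programmed rise start
  expect_equal(ev$onset_s, 1.0, tolerance = 0.05)
  expect_equal(ev$peak_s, 1.2, tolerance = 0.02)
  expect_equal(ev$amplitude, 2, tolerance = 0.1)

  # two transients 2 s apart
  g <- generate_calcium_trace(synthetic_trace_config(frequency_hz = 0.5,
                                                     duration_s = 5, noise_sd = 0,
                                                     seed = 1))
  ev2 <- detect_transients(normalize_dff(g$trace))
  expect_equal(nrow(ev2), 2)
})

test_that("exponential decay gives the closed-form APDs and triangulation", {
  for (tau in c(0.1, 0.25, 0.4, 0.7, 1.0)) {
    tr <- one_transient_trace(ttp = 0.15, tau = tau, rate = 100, duration = 4 + 8 * tau)
    res <- analyze_trace(tr)
    f <- res$features
    expect_equal(f$apd50_s, tau * log(2), tolerance = 0.03 * tau * log(2))
    expect_equal(f$apd90_s, tau * log(10), tolerance = 0.03 * tau * log(10))
    expect_equal(f$triangulation, log(10) / log(2),
                 tolerance = 0.03 * log(10) / log(2))
    expect_equal(f$ttp_s, 0.15, tolerance = 0.05)
  }
})

test_that("triangular (linear) decay gives triangulation 1.8", {
  t <- seq(0, 6, by = 0.01)
  dff <- numeric(length(t))
  rise <- t >= 1 & t < 1.2
  dec <- t >= 1.2 & t < 3.2
  dff[rise] <- 2 * (t[rise] - 1) / 0.2
  dff[dec] <- 2 * (1 - (t[dec] - 1.2) / 2)
  tr <- intensity_trace(t, 100 * (1 + pmax(dff, 0)))
  f <- analyze_trace(tr)$features
  expect_equal(f$triangulation, 0.9 / 0.5, tolerance = 0.01)
})

test_that("transient frequency follows the peak times", {
  g <- generate_calcium_trace(synthetic_trace_config(frequency_hz = 0.5,
                                                     duration_s = 10, noise_sd = 0,
                                                     seed = 2))
  f <- analyze_trace(g$trace)$features
  expect_equal(f$frequency_hz, 0.5, tolerance = 0.02)
})

test_that("transients truncated before the 90% decay are excluded with a warning", {
  # decay tail cut right after the peak: 50% crossing exists, 90% does not
  tr <- one_transient_trace(ttp = 0.2, tau = 0.8, duration = 1.8, onset = 1)
  norm <- normalize_dff(tr)
  ev <- detect_transients(norm)
  expect_equal(nrow(ev), 1)
  expect_warning(f <- transient_features(norm, ev), "truncated")
  expect_true(is.finite(f$apd50_s))
  expect_true(is.na(f$apd90_s))
  expect_true(is.na(f$triangulation))
})

test_that("apd90 >= apd50 and triangulation >= 1 for monotone decays", {
  set.seed(5)
  for (i in 1:8) {
    tau <- runif(1, 0.15, 0.8)
    g <- generate_calcium_trace(synthetic_trace_config(
      frequency_hz = 0.3, decay_tau_s = tau, ttp_s = 0.12, noise_sd = 0,
      duration_s = 15, seed = 50 + i))
    f <- analyze_trace(g$trace)$features
    expect_gte(f$apd90_s, f$apd50_s)
    expect_gte(f$triangulation, 1)
  }
})

test_that("kinetic features are invariant to positive amplitude scaling", {
  g <- generate_calcium_trace(synthetic_trace_config(frequency_hz = 0.4,
                                                     duration_s = 12, noise_sd = 0,
                                                     seed = 9))
  a <- analyze_trace(g$trace)$features
  scaled <- intensity_trace(g$trace$times_s,
                            (g$trace$values - 100) * 4 + 100) # dff scaled by 4
  b <- analyze_trace(scaled)$features
  for (k in c("ttp_s", "apd50_s", "apd90_s", "triangulation"))
    expect_equal(a[[k]], b[[k]], tolerance = 1e-6)
})

test_that("generator ground truth is recovered within 5% median error across seeds", {
  err <- list(f = c(), ttp = c(), apd50 = c(), apd90 = c())
  for (seed in 1:20) {
    # amplitude-to-noise ratio 10 (noise_sd = 20 on a raw amplitude of 200)
    cfg <- synthetic_trace_config(frequency_hz = 0.5, ttp_s = 0.15,
                                  decay_tau_s = 0.4, noise_sd = 20, seed = seed)
    g <- generate_calcium_trace(cfg)
    f <- suppressWarnings(analyze_trace(g$trace)$features)
    err$f <- c(err$f, abs(f$frequency_hz - 0.5) / 0.5)
    err$ttp <- c(err$ttp, abs(f$ttp_s - 0.15) / 0.15)
    err$apd50 <- c(err$apd50, abs(f$apd50_s - 0.4 * log(2)) / (0.4 * log(2)))
    err$apd90 <- c(err$apd90, abs(f$apd90_s - 0.4 * log(10)) / (0.4 * log(10)))
  }
  expect_lte(median(err$f), 0.05)
  expect_lte(median(err$ttp), 0.05)
  expect_lte(median(err$apd50), 0.05)
  expect_lte(median(err$apd90), 0.05)
})

test_that("drug response deltas and the responder flag behave as documented", {
  f1 <- structure(list(frequency_hz = 0.5, ttp_s = 0.2, apd50_s = 0.3,
                       apd90_s = 0.9, triangulation = 3), class = "transient_features")
  same <- compare_drug_response(f1, f1)
  expect_equal(unname(same$delta), rep(0, 5))
  expect_false(same$responder)

  f2 <- f1; f2$frequency_hz <- 0.75
  r <- compare_drug_response(f1, f2)
  expect_equal(unname(r$percent["frequency_hz"]), 50)
  expect_true(r$responder)

  f3 <- f2; f3$apd90_s <- NA_real_; f3$triangulation <- NA_real_
  r2 <- compare_drug_response(f1, f3)
  expect_true(is.na(r2$delta["apd90_s"]))
  expect_true(r2$responder)
})
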