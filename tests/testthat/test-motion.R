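test_that("MAD matches hand arithmetic and is a symmetric dissimilarity", {
  a <- matrix(c(0, 4, 2, 6), 2, 2)
  b <- matrix(1, 2, 2)
  expect_equal(mad_score(a, a), 0)
  expect_equal(mad_score(matrix(0, 2, 2), matrix(1, 2, 2)), 1.0)
  expect_equal(mad_score(a, b), 2.5) # mean(|-1|, |1|, |3|, |5|)
  expect_error(mad_score(a, matrix(0, 3, 3)), class = "beatkit_error_shape_mismatch")

  set.seed(1)
  for (i in 1:20) {
    p <- matrix(rnorm(64), 8, 8); q <- matrix(rnorm(64), 8, 8)
    expect_gte(mad_score(p, q), 0)
    expect_equal(mad_score(p, q), mad_score(q, p))
  }
})

test_that("match_block recovers known shifts and respects the search window", {
  fk <- noise_frame(64, 64, 101)
  p <- block_match_params(block_size_px = 16, search_radius_px = 4)

  # static scene
  m0 <- match_block(c(17, 17), fk, fk, p)
  expect_equal(c(m0$dx, m0$dy, m0$mad), c(0, 0, 0))

  # content shifted by (+2, 0): interior blocks find it
  fk1 <- circ_shift(fk, 2, 0)
  m2 <- match_block(c(17, 17), fk, fk1, p)
  expect_equal(c(m2$dx, m2$dy), c(2, 0))

  # true shift (+6, 0) beyond w = 4: answer stays inside the window and
  # agrees with the exhaustive scan
  fk6 <- circ_shift(fk, 6, 0)
  m6 <- match_block(c(17, 17), fk, fk6, p)
  expect_lte(abs(m6$dx), 4)
  expect_lte(abs(m6$dy), 4)
  o <- oracle_match_block(c(17, 17), fk, fk6, 16, 4)
  expect_equal(c(m6$dx, m6$dy, m6$mad), c(o$dx, o$dy, o$mad))

  expect_error(match_block(c(60, 60), fk, fk, p),
               class = "beatkit_error_block_out_of_frame")
})

test_that("compute_fields equals the exhaustive brute-force oracle on random textured pairs", {
  set.seed(202)
  for (rep in 1:6) {
    w <- sample(1:4, 1)
    fk <- noise_frame(64, 64, 300 + rep)
    fk1 <- circ_shift(fk, sample(-w:w, 1), sample(-w:w, 1)) +
      matrix(rnorm(64 * 64, sd = 2), 64, 64)
    st <- frame_stack(array(c(fk, fk1), dim = c(64, 64, 2)), 30)
    p <- block_match_params(16, w)
    f <- compute_fields(st, p)[[1]]
    for (i in 1:4) for (j in 1:4) {
      o <- oracle_match_block(c((i - 1) * 16 + 1, (j - 1) * 16 + 1), fk, fk1, 16, w)
      expect_identical(f$dx[i, j], as.integer(o$dx))
      expect_identical(f$dy[i, j], as.integer(o$dy))
      expect_equal(f$mad[i, j], o$mad, tolerance = 1e-12)
    }
  }
})

test_that("the R matcher and the C++ field computation agree block-for-block", {
  fk <- noise_frame(48, 48, 77)
  fk1 <- circ_shift(fk, -1, 2) + matrix(rnorm(48 * 48), 48, 48)
  st <- frame_stack(array(c(fk, fk1), dim = c(48, 48, 2)), 30)
  p <- block_match_params(16, 3)
  f <- compute_fields(st, p)[[1]]
  for (i in 1:3) for (j in 1:3) {
    m <- match_block(c((i - 1) * 16 + 1, (j - 1) * 16 + 1), fk, fk1, p)
    expect_identical(f$dx[i, j], m$dx)
    expect_identical(f$dy[i, j], m$dy)
  }
})

test_that("compute_fields handles static, stepping and flat stacks", {
  fk <- noise_frame(32, 32, 5)
  st <- frame_stack(array(rep(fk, 3), dim = c(32, 32, 3)), 30)
  fields <- compute_fields(st, block_match_params(16, 2))
  expect_length(fields, 2)
  for (f in fields) {
    expect_true(all(f$dx == 0) && all(f$dy == 0))
    expect_true(all(f$valid))
  }

  # frame 1 -> 2 shifted by (0, +1), frame 3 static; blocks whose true
  # match would leave the frame (the bottom row) are excluded
  f2 <- circ_shift(fk, 0, 1)
  st2 <- frame_stack(array(c(fk, f2, f2), dim = c(32, 32, 3)), 30)
  fl <- compute_fields(st2, block_match_params(16, 2))
  expect_true(all(fl[[1]]$dy[1, ] == 1) && all(fl[[1]]$dx[1, ] == 0))
  expect_true(all(fl[[2]]$dy == 0) && all(fl[[2]]$dx == 0))

  # flat frames carry no texture: every block invalid
  st3 <- frame_stack(array(7, dim = c(32, 32, 3)), 30)
  fl3 <- compute_fields(st3, block_match_params(16, 2, min_block_std = 1e-6))
  expect_false(any(fl3[[1]]$valid))
  expect_error(motion_magnitude_trace(fl3, 30),
               class = "beatkit_error_no_valid_blocks")
  expect_error(compute_fields(frame_stack(array(1, c(8, 8, 2)), 30),
                              block_match_params(16, 2)),
               class = "beatkit_error_frame_too_small")
})

test_that("no emitted displacement ever exceeds the search radius", {
  set.seed(42)
  for (rep in 1:5) {
    w <- sample(1:3, 1)
    frames <- array(runif(48 * 48 * 3, 0, 100), dim = c(48, 48, 3))
    fl <- compute_fields(frame_stack(frames, 30), block_match_params(16, w))
    for (f in fl) {
      expect_lte(max(abs(f$dx)), w)
      expect_lte(max(abs(f$dy)), w)
    }
  }
})

test_that("integer translations are recovered exactly on almost all interior blocks", {
  set.seed(314)
  hits <- 0; total <- 0
  for (rep in 1:10) {
    w <- 4
    dx <- sample(-w:w, 1); dy <- sample(-w:w, 1)
    fk <- noise_frame(96, 96, 4000 + rep)
    fk1 <- circ_shift(fk, dx, dy)
    st <- frame_stack(array(c(fk, fk1), dim = c(96, 96, 2)), 30)
    f <- compute_fields(st, block_match_params(16, w))[[1]]
    interior <- 2:5 # blocks untouched by the circular wrap for |d| <= 4
    for (i in interior) for (j in interior) {
      total <- total + 1
      if (f$dx[i, j] == dx && f$dy[i, j] == dy) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("motion_magnitude_trace converts block motion to um/s", {
  z <- lapply(0:2, function(k) fake_field(k, 0, 0))
  tr <- motion_magnitude_trace(z, 30)
  expect_equal(tr$velocity_um_s, rep(0, 3))
  expect_equal(tr$times_s, (0:2 + 0.5) / 30)

  # every block (3, 4) px at 1 um/px, 30 fps -> 5 * 30 = 150 um/s
  f34 <- list(fake_field(0, 3, 4))
  expect_equal(motion_magnitude_trace(f34, 30, 1)$velocity_um_s, 150)

  # half (2, 0), half (0, 0) -> mean magnitude 1 px/frame-pair
  fhalf <- list(fake_field(0, matrix(c(2, 2, 0, 0), 2, 2), 0))
  expect_equal(motion_magnitude_trace(fhalf, 1, 1)$velocity_um_s, 1)

  expect_error(motion_magnitude_trace(list(), 30), class = "beatkit_error_no_fields")
})

test_that("scaling all intensities leaves displacements unchanged", {
  g <- generate_beating_video(small_video_config(0.8, seed = 9, duration_s = 5))
  st <- g$stack
  st_scaled <- frame_stack(st$frames * 3.7, st$frame_rate_hz, st$pixel_size_um)
  p <- block_match_params()
  f1 <- compute_fields(st, p)
  f2 <- compute_fields(st_scaled, p)
  for (k in seq_along(f1)) {
    expect_identical(f1[[k]]$dx, f2[[k]]$dx)
    expect_identical(f1[[k]]$dy, f2[[k]]$dy)
    expect_identical(f1[[k]]$valid, f2[[k]]$valid)
  }
})
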