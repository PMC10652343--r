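# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by the most literal route available
# (exhaustive enumeration, explicit sums of squares) and share no code with
# the implementation they check.

# Exhaustive MAD scan over all (2w+1)^2 candidates with the documented
# tie-break (smaller norm, then lexicographic (dy, dx)) applied explicitly
# via order() on the full candidate table.
oracle_match_block <- function(origin, fk, fk1, N, w) {
  H <- nrow(fk); W <- ncol(fk)
  by <- origin[1]; bx <- origin[2]
  ref <- fk[by:(by + N - 1), bx:(bx + N - 1)]
  rows <- expand.grid(dy = -w:w, dx = -w:w)
  rows$mad <- NA_real_
  for (i in seq_len(nrow(rows))) {
    ty <- by + rows$dy[i]; tx <- bx + rows$dx[i]
    if (ty < 1 || tx < 1 || ty + N - 1 > H || tx + N - 1 > W) next
    rows$mad[i] <- mean(abs(ref - fk1[ty:(ty + N - 1), tx:(tx + N - 1)]))
  }
  rows <- rows[!is.na(rows$mad), ]
  rows <- rows[order(rows$mad, rows$dx^2 + rows$dy^2, rows$dy, rows$dx), ]
  list(dx = rows$dx[1], dy = rows$dy[1], mad = rows$mad[1])
}

# Brute-force one-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- length(unique(groups)); N <- length(values)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Seeded white-noise texture frame (textured enough that every block is
# valid and matches are unambiguous).
noise_frame <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w, 0, 100), h, w)
}

# Circular integer shift of a matrix: content moves by (+dx, +dy)
# (columns right, rows down).
circ_shift <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 - dy) %% h) + 1
  ci <- ((seq_len(w) - 1 - dx) %% w) + 1
  m[ri, ci]
}

# Hand-built displacement field for metric-level tests.
fake_field <- function(k, dx, dy, valid = NULL) {
  dxm <- if (is.matrix(dx)) dx else matrix(dx, 2, 2)
  dym <- if (is.matrix(dy)) dy else matrix(dy, 2, 2)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(dxm), ncol(dxm))
  structure(list(frame_pair_index = k, dx = dxm, dy = dym,
                 mad = matrix(0, nrow(dxm), ncol(dxm)), valid = valid),
            class = "displacement_field")
}

# Small but realistic synthetic video configuration for recovery tests:
# quarter-size frames keep the full pipeline behaviour at a fraction of the
# cost.
small_video_config <- function(frequency_hz, seed, duration_s = 20,
                               amplitude_px = 3, noise_sd = 1, ...) {
  synthetic_video_config(frequency_hz = frequency_hz, seed = seed,
                         duration_s = duration_s, amplitude_px = amplitude_px,
                         frame_size = c(128, 128), noise_sd = noise_sd, ...)
}

cli_path <- function() system.file("cli", "beatkit.R", package = "beatkit")

run_cli <- function(...) {
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- suppressWarnings(system2("Rscript", c(cli_path(), ...), stdout = TRUE,
                                  stderr = TRUE, env = env))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
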