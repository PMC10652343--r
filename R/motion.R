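#' Block-matching parameters
#'
#' Controls the motion estimator: each frame is divided into square `N x N`
#' blocks and every block in frame `k` is matched against frame `k+1` within
#' a square search window extending `search_radius_px` pixels from each side
#' of its origin. The matching criterion is the Mean Absolute Difference
#' (MAD) of intensities. Blocks whose intensity standard deviation falls
#' below `min_block_std` carry no texture to match (every offset ties) and
#' are masked out of all aggregates.
#'
#' @param block_size_px block side `N` in pixels (>= 2). Default 16.
#' @param search_radius_px maximum displacement searched per axis, in
#'   pixels (>= 1). Default 4.
#' @param min_block_std minimum sample SD of a block's intensities for the
#'   block to be tracked. Default 1e-6.
#' @return A list of class `block_match_params`.
#' @export
block_match_params <- function(block_size_px = 16, search_radius_px = 4,
                               min_block_std = 1e-6) {
  if (block_size_px < 2) stop_beatkit("bad_params", "block_size_px must be >= 2")
  if (search_radius_px < 1) stop_beatkit("bad_params", "search_radius_px must be >= 1")
  if (min_block_std < 0) stop_beatkit("bad_params", "min_block_std must be >= 0")
  structure(list(block_size_px = as.integer(block_size_px),
                 search_radius_px = as.integer(search_radius_px),
                 min_block_std = min_block_std),
            class = "block_match_params")
}

#' Mean Absolute Difference between two intensity patches
#'
#' The block dissimilarity used for matching: the mean over all positions of
#' the absolute intensity difference. Symmetric, non-negative, and zero
#' exactly when the patches are identical.
#'
#' @param block_a,block_b numeric matrices of identical shape.
#' @return A single non-negative number.
#' @export
mad_score <- function(block_a, block_b) {
  if (!identical(dim(block_a), dim(block_b)))
    stop_beatkit("shape_mismatch", "patches differ in shape")
  mean(abs(block_a - block_b))
}

# Search offsets ordered by (squared norm, dy, dx); shared by the R and C++
# matchers so tie-breaking is identical.
candidate_offsets <- function(w) {
  g <- expand.grid(dx = -w:w, dy = -w:w)
  g <- g[order(g$dx^2 + g$dy^2, g$dy, g$dx), ]
  rownames(g) <- NULL
  g
}

#' Match one block between consecutive frames
#'
#' Exhaustively scans every offset `(dx, dy)` with `|dx|, |dy| <=
#' search_radius_px`, excluding candidates that would place the block
#' outside the target frame, and returns the offset minimizing the MAD.
#' Ties are broken by smaller Euclidean norm of the offset, then by
#' lexicographic `(dy, dx)`.
#'
#' @param origin `c(row, col)` of the block's top-left pixel, 1-based.
#' @param frame_k,frame_k1 numeric matrices (the consecutive frames).
#' @param params a [block_match_params()].
#' @return A list with `dx`, `dy` (integer pixels) and `mad` (the winning
#'   score). `(dx, dy)` means the block content is found at
#'   `origin + (dy, dx)` in `frame_k1`.
#' @export
match_block <- function(origin, frame_k, frame_k1, params = block_match_params()) {
  N <- params$block_size_px
  w <- params$search_radius_px
  H <- nrow(frame_k); W <- ncol(frame_k)
  by <- origin[1]; bx <- origin[2]
  if (by < 1 || bx < 1 || by + N - 1 > H || bx + N - 1 > W)
    stop_beatkit("block_out_of_frame", "block does not lie fully inside the frame")
  ref <- frame_k[by:(by + N - 1), bx:(bx + N - 1)]
  cands <- candidate_offsets(w)
  best <- list(dx = 0L, dy = 0L, mad = Inf)
  for (i in seq_len(nrow(cands))) {
    dy <- cands$dy[i]; dx <- cands$dx[i]
    ty <- by + dy; tx <- bx + dx
    if (ty < 1 || tx < 1 || ty + N - 1 > H || tx + N - 1 > W) next
    s <- mean(abs(ref - frame_k1[ty:(ty + N - 1), tx:(tx + N - 1)]))
    if (s < best$mad) best <- list(dx = as.integer(dx), dy = as.integer(dy), mad = s)
  }
  if (!is.finite(best$mad))
    stop_beatkit("block_out_of_frame", "no candidate position lies inside the frame")
  best
}

#' Displacement fields for every consecutive frame pair
#'
#' Runs the block matcher over the fixed block grid (re-anchored each frame
#' pair, no trajectory accumulation) for frames `k -> k+1`,
#' `k = 0 .. T-2`. Low-texture blocks are flagged invalid and excluded from
#' all downstream aggregates.
#'
#' @param stack a [frame_stack()].
#' @param params a [block_match_params()].
#' @return A list of `T-1` displacement fields; each has
#'   `frame_pair_index` (0-based `k`), integer matrices `dx`, `dy` of size
#'   `floor(H/N) x floor(W/N)`, the per-block winning `mad`, and the logical
#'   `valid` mask.
#' @export
compute_fields <- function(stack, params = block_match_params()) {
  d <- dim(stack$frames)
  N <- params$block_size_px
  if (d[1] < N || d[2] < N)
    stop_beatkit("frame_too_small", "frame smaller than one block")
  fields <- compute_fields_cpp(stack$frames, N, params$search_radius_px,
                               params$min_block_std)
  lapply(fields, function(f) structure(f, class = "displacement_field"))
}

#' Aggregate motion-magnitude trace
#'
#' Per frame pair, the mean over valid blocks of the displacement magnitude
#' `sqrt(dx^2 + dy^2)`, converted to micrometers per second via
#' `pixel_size_um * frame_rate_hz`. The sample time is the midpoint of the
#' frame pair. Frame pairs with no valid block yield `NA` samples; if no
#' pair has any valid block the trace is undefined and an error is raised.
#'
#' @param fields list of displacement fields from [compute_fields()].
#' @param frame_rate_hz,pixel_size_um acquisition metadata (see
#'   [frame_stack()]).
#' @return A `motion_trace`: data frame with `times_s`, `velocity_um_s`,
#'   `n_valid_blocks`.
#' @export
motion_magnitude_trace <- function(fields, frame_rate_hz, pixel_size_um = 1.0) {
  if (length(fields) < 1)
    stop_beatkit("no_fields", "need at least one displacement field")
  per_pair <- vapply(fields, function(f) {
    v <- f$valid
    if (!any(v)) return(c(NA_real_, 0))
    mag <- sqrt(f$dx[v]^2 + f$dy[v]^2)
    c(mean(mag), sum(v))
  }, numeric(2))
  if (all(per_pair[2, ] == 0))
    stop_beatkit("no_valid_blocks", "no frame pair has any valid block")
  k <- vapply(fields, function(f) f$frame_pair_index, numeric(1))
  tr <- motion_trace(times_s = (k + 0.5) / frame_rate_hz,
                     velocity_um_s = per_pair[1, ] * pixel_size_um * frame_rate_hz,
                     n_valid_blocks = as.integer(per_pair[2, ]))
  # velocity equivalent of one pixel of block displacement per frame pair;
  # lets the beat detector express its noise floor in displacement quanta
  attr(tr, "um_per_px_frame") <- pixel_size_um * frame_rate_hz
  tr
}

#' Construct a motion trace
#'
#' @param times_s strictly increasing sample times (frame-pair midpoints).
#' @param velocity_um_s aggregate motion magnitude per sample (>= 0 or NA).
#' @param n_valid_blocks per-sample count of contributing blocks.
#' @return A data frame of class `motion_trace`.
#' @export
motion_trace <- function(times_s, velocity_um_s,
                         n_valid_blocks = rep(NA_integer_, length(times_s))) {
  if (any(diff(times_s) <= 0))
    stop_beatkit("non_increasing_times", "times must be strictly increasing")
  if (any(velocity_um_s < 0, na.rm = TRUE))
    stop_beatkit("negative_velocity", "velocity_um_s must be non-negative")
  structure(data.frame(times_s = times_s, velocity_um_s = velocity_um_s,
                       n_valid_blocks = n_valid_blocks),
            class = c("motion_trace", "data.frame"))
}
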