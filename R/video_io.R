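#' Construct a frame stack
#'
#' A frame stack is the in-memory container for a grayscale microscopy
#' recording: a `H x W x T` array of intensities plus the acquisition
#' metadata every downstream computation needs (frame rate, pixel size).
#' Intensities are held as doubles regardless of the source bit depth.
#'
#' @param frames numeric array with dimensions `H x W x T` (rows, columns,
#'   frames) or a list of `H x W` matrices in acquisition order.
#' @param frame_rate_hz acquisition frame rate in frames per second (> 0).
#' @param pixel_size_um physical edge length of one pixel in micrometers.
#' @param source_id free-text provenance label.
#'
#' @return An object of class `frame_stack` with elements `frames`,
#'   `frame_rate_hz`, `pixel_size_um`, `source_id`.
#' @export
frame_stack <- function(frames, frame_rate_hz, pixel_size_um = 1.0,
                        source_id = "") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(frames) == 0) stop_beatkit("zero_frames", "no frames supplied")
    if (length(dims) != 1)
      stop_beatkit("dim_mismatch", "frames do not share identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop_beatkit("bad_frames", "frames must be an H x W x T array")
  if (dim(frames)[3] < 2)
    stop_beatkit("zero_frames", "a frame stack needs at least 2 frames")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1 ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    stop_beatkit("bad_frame_rate", "frame_rate_hz must be a single positive number")
  if (pixel_size_um <= 0)
    stop_beatkit("bad_pixel_size", "pixel_size_um must be positive")
  if (!is.double(frames)) storage.mode(frames) <- "double"
  structure(
    list(frames = frames, frame_rate_hz = frame_rate_hz,
         pixel_size_um = pixel_size_um, source_id = source_id),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d px, %.6g fps (%.3g s), %g um/px\n",
              d[3], d[1], d[2], x$frame_rate_hz, d[3] / x$frame_rate_hz,
              x$pixel_size_um))
  invisible(x)
}

#' Duration of a frame stack in seconds
#' @param stack a [frame_stack()].
#' @return `T / frame_rate_hz` in seconds.
#' @export
stack_duration <- function(stack) {
  dim(stack$frames)[3] / stack$frame_rate_hz
}

# Collapse a single decoded image to a grayscale matrix. Color channels are
# averaged with equal weight: luma weighting carries no meaning for
# brightfield or single-fluorophore content, and the plain mean is exactly
# reproducible.
to_grayscale <- function(img) {
  if (is.matrix(img)) return(img * 1.0)
  if (is.array(img) && length(dim(img)) == 3) {
    nc <- dim(img)[3]
    out <- img[, , 1]
    if (nc > 1) for (k in 2:nc) out <- out + img[, , k]
    return(out / nc)
  }
  stop_beatkit("bad_frames", "unsupported image array layout")
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_beatkit("bad_format", paste0("unsupported image format: ", ext))
  )
  to_grayscale(img)
}

#' Read a recording into a frame stack
#'
#' Accepts either a multi-page TIFF file or a directory of single-frame
#' images (PNG or TIFF, all the same size). Directory frames are ordered by
#' lexicographic filename sort, which is deterministic across platforms.
#' Color frames are converted to grayscale by averaging channels. The frame
#' rate is always user-supplied: container timing metadata is not trusted.
#'
#' @param path multi-page TIFF file or directory of ordered frame images.
#' @inheritParams frame_stack
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, frame_rate_hz, pixel_size_um = 1.0) {
  if (!file.exists(path))
    stop_beatkit("missing_path", paste0("path does not exist: ", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0)
      stop_beatkit("zero_frames", paste0("no frame images found in ", path))
    frames <- lapply(files, read_one_image)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0)
      stop_beatkit("zero_frames", paste0("no pages in TIFF ", path))
    frames <- lapply(pages, to_grayscale)
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1)
    stop_beatkit("dim_mismatch", "frames do not share identical dimensions")
  frame_stack(frames, frame_rate_hz, pixel_size_um, source_id = path)
}

#' Construct an intensity-versus-time trace
#'
#' @param times_s strictly increasing sample times in seconds (length >= 3).
#' @param values intensity samples, same length as `times_s`.
#' @param label free-text label.
#' @return An object of class `intensity_trace` with elements `times_s`,
#'   `values`, `label`.
#' @export
intensity_trace <- function(times_s, values, label = "") {
  if (length(times_s) != length(values))
    stop_beatkit("length_mismatch", "times_s and values differ in length")
  if (length(times_s) < 3)
    stop_beatkit("too_short", "an intensity trace needs at least 3 samples")
  if (any(!is.finite(times_s)) || any(!is.finite(values)))
    stop_beatkit("non_numeric", "times and values must be finite numbers")
  if (any(diff(times_s) <= 0))
    stop_beatkit("non_increasing_times", "sample times must be strictly increasing")
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 label = label),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d samples over %.4g s%s\n",
              length(x$times_s), diff(range(x$times_s)),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Mean-intensity time course over a region of interest
#'
#' One sample per frame: the mean intensity over the ROI, at time
#' `frame index / frame_rate_hz` (first frame at 0 s).
#'
#' @param stack a [frame_stack()].
#' @param roi `c(x, y, w, h)` in pixels, 1-based, `x` = column of the left
#'   edge, `y` = row of the top edge; `NULL` for the full frame.
#' @return An [intensity_trace()].
#' @export
trace_from_stack <- function(stack, roi = NULL) {
  d <- dim(stack$frames)
  if (is.null(roi)) roi <- c(1, 1, d[2], d[1])
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w < 1 || h < 1) stop_beatkit("empty_roi", "roi has zero extent")
  if (x < 1 || y < 1 || x + w - 1 > d[2] || y + h - 1 > d[1])
    stop_beatkit("roi_out_of_bounds", "roi lies outside the frame")
  vals <- apply(stack$frames[y:(y + h - 1), x:(x + w - 1), , drop = FALSE],
                3, mean)
  intensity_trace((seq_len(d[3]) - 1) / stack$frame_rate_hz, vals,
                  label = stack$source_id)
}

#' Read / write an intensity trace as CSV
#'
#' The on-disk format is a two-column CSV with header `time_s,value`.
#' Writing then reading reproduces times and values to better than 1e-9
#' relative tolerance.
#'
#' @param path CSV file path.
#' @return `read_trace` returns an [intensity_trace()]; `write_trace`
#'   returns `path` invisibly.
#' @export
read_trace <- function(path) {
  if (!file.exists(path))
    stop_beatkit("missing_path", paste0("path does not exist: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop_beatkit("bad_format", "trace CSV must have columns time_s,value")
  if (!is.numeric(df$time_s) || !is.numeric(df$value) ||
      any(!is.finite(df$time_s)) || any(!is.finite(df$value)))
    stop_beatkit("non_numeric", "trace CSV contains non-numeric cells")
  intensity_trace(df$time_s, df$value, label = basename(path))
}

#' @rdname read_trace
#' @param trace an [intensity_trace()].
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = format(trace$times_s, digits = 17, trim = TRUE,
                                   scientific = FALSE),
                   value = format(trace$values, digits = 17, trim = TRUE,
                                  scientific = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
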