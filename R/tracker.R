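#' Frame stacks for centroid tracking
#'
#' A frame stack is an ordered sequence of same-shape grayscale images (one
#' fly, one arena) plus the frame rate. Pixel values are on a 0–255 gray
#' scale. `frame_stack()` wraps a list of matrices; [read_frame_stack()]
#' loads a multi-page TIFF or a directory of PNG files.
#'
#' Pixel coordinate convention: the image origin is the top-left corner,
#' `x` runs along columns and `y` along rows, and the center of the pixel in
#' column `j`, row `i` (1-based matrix indices) is at `(j - 0.5, i - 0.5)`.
#'
#' @param frames List of numeric matrices of identical dimensions (>= 2).
#' @param fps Frame rate.
#' @param origin_px Optional `c(x, y)` pixel offset of the arena's top-left
#'   corner inside the image (used by [track()] to convert to arena
#'   coordinates); default `c(0, 0)`.
#' @return A `frame_stack`.
#' @export
frame_stack <- function(frames, fps = 15, origin_px = c(0, 0)) {
  if (length(frames) < 2) stop("a frame stack needs at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have identical dimensions")
  structure(list(frames = frames, fps = fps, origin_px = origin_px),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %g fps\n",
              length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

#' @rdname frame_stack
#' @param path A `.tif`/`.tiff` file or a directory of `.png` frames
#'   (sorted by file name).
#' @export
read_frame_stack <- function(path, fps = 15, origin_px = c(0, 0)) {
  if (dir.exists(path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG stacks requires the 'png' package")
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2) stop("fewer than 2 PNG frames in ", path)
    frames <- lapply(files, function(f) png::readPNG(f) * 255)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF stacks requires the 'tiff' package")
    frames <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(frames, function(f) f * 255)
  }
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3) f <- f[, , 1]   # first channel of RGB input
    f
  })
  frame_stack(frames, fps = fps, origin_px = origin_px)
}

#' Estimate the static background of a stack
#'
#' Per-pixel median over `n_samples` evenly spaced frames. The median is
#' robust to the fly occupying any given pixel in a minority of the sampled
#' frames, which is guaranteed for a moving animal and a modest sample.
#'
#' @param stack A [frame_stack()].
#' @param n_samples Number of frames to sample (>= 2), default 25.
#' @return Background image (matrix).
#' @export
estimate_background <- function(stack, n_samples = 25) {
  stopifnot(inherits(stack, "frame_stack"), n_samples >= 2)
  n <- length(stack$frames)
  idx <- unique(round(seq(1, n, length.out = min(n_samples, n))))
  arr <- simplify2array(stack$frames[idx])
  apply(arr, c(1, 2), stats::median)
}

#' Detect the fly in one frame
#'
#' Background subtraction pipeline: absolute difference from the background,
#' threshold (Otsu's method on the difference image with a floor of
#' `threshold_floor` gray levels, or a fixed numeric threshold), connected
#' components, keep the largest component of at least `min_area` pixels,
#' and return its intensity-weighted centroid (weights = difference values).
#' Returns `NULL` when nothing qualifies — e.g. a frame identical to the
#' background.
#'
#' @param frame,background Same-shape numeric matrices (0–255 gray scale).
#' @param threshold `"otsu"` (default) or a fixed numeric threshold.
#' @param threshold_floor Lower bound on the automatic threshold (gray
#'   levels), default 10; guards against noise-driven thresholds on
#'   fly-free frames.
#' @param min_area Minimum component area in pixels, default 4.
#' @return `c(x, y)` centroid in pixel coordinates, or `NULL`.
#' @export
detect_fly <- function(frame, background, threshold = "otsu",
                       threshold_floor = 10, min_area = 4) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background dimensions differ")
  d <- abs(frame - background)
  thr <- if (is.numeric(threshold)) threshold
  else max(EBImage::otsu(d / 255, range = c(0, 1)) * 255, threshold_floor)
  mask <- d > thr
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_area) return(NULL)
  best <- which.max(sizes)            # single-animal assumption: largest blob
  sel <- lab == best
  w <- d[sel]
  rc <- which(sel, arr.ind = TRUE)
  # pixel centers at (col - 0.5, row - 0.5)
  c(x = sum((rc[, 2] - 0.5) * w) / sum(w),
    y = sum((rc[, 1] - 0.5) * w) / sum(w))
}

#' Track a single fly through a frame stack
#'
#' Runs [estimate_background()] once, then [detect_fly()] on every frame,
#' and converts pixel centroids to arena coordinates through the geometry's
#' calibration. Frames with no detection become invalid trajectory frames
#' (repairable downstream with [repair_gaps()]); the output always has
#' exactly one row per input frame.
#'
#' @param stack A [frame_stack()].
#' @param g An [arena_geometry()] supplying `px_per_unit`.
#' @param fly_id Identifier.
#' @param n_background Frames sampled for the background, default 25.
#' @param ... Passed to [detect_fly()].
#' @return A [trajectory()] in physical units.
#' @export
track <- function(stack, g, fly_id = "tracked", n_background = 25, ...) {
  stopifnot(inherits(stack, "frame_stack"), inherits(g, "arena_geometry"))
  bg <- estimate_background(stack, n_background)
  n <- length(stack$frames)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- detect_fly(stack$frames[[i]], bg, ...)
    if (!is.null(p)) {
      x[i] <- (p[1] - stack$origin_px[1]) / g$px_per_unit
      y[i] <- (p[2] - stack$origin_px[2]) / g$px_per_unit
    }
  }
  trajectory(data.frame(frame = 0:(n - 1L), x = x, y = y),
             fps = stack$fps, fly_id = fly_id,
             meta = list(tracked = TRUE))
}

#' Render synthetic infrared-style frames for a trajectory
#'
#' Fixture generator for validating the tracker: each frame is a uniform
#' bright background with a dark Gaussian-profile blob centered at the
#' fly's true position plus i.i.d. Gaussian pixel noise, clamped to
#' `[0, 255]`. The arena maps onto the image through the geometry's
#' `px_per_unit` with a `pad_px` border; ground-truth pixel centroids are
#' attached to the returned stack.
#'
#' @param traj A [trajectory()] with all frames valid.
#' @param g An [arena_geometry()].
#' @param noise_sd Pixel noise SD in gray levels, default 2.
#' @param blob_sigma Blob Gaussian sigma in pixels, default 2.
#' @param amplitude Blob darkness in gray levels, default 120.
#' @param background Background gray level, default 200.
#' @param pad_px Image border around the arena in pixels, default 5.
#' @return A [frame_stack()] with attribute `"truth_px"` (n x 2 matrix of
#'   true centroids in pixel coordinates).
#' @export
render_frames <- function(traj, g, noise_sd = 2, blob_sigma = 2,
                          amplitude = 120, background = 200, pad_px = 5) {
  fr <- traj$frames
  if (!all(fr$valid)) stop("render_frames needs a fully valid trajectory")
  w_px <- ceiling(g$length * g$px_per_unit) + 2 * pad_px
  h_px <- ceiling(g$width * g$px_per_unit) + 2 * pad_px
  if (6 * blob_sigma > min(w_px, h_px))
    stop("blob larger than the arena image")
  cx_all <- fr$x * g$px_per_unit + pad_px
  cy_all <- fr$y * g$px_per_unit + pad_px
  xc <- seq_len(w_px) - 0.5            # pixel-center coordinates
  yc <- seq_len(h_px) - 0.5
  half <- ceiling(4 * blob_sigma)
  n <- nrow(fr)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f <- matrix(background, h_px, w_px)
    jj <- which(abs(xc - cx_all[i]) <= half)
    ii <- which(abs(yc - cy_all[i]) <= half)
    gx <- exp(-(xc[jj] - cx_all[i])^2 / (2 * blob_sigma^2))
    gy <- exp(-(yc[ii] - cy_all[i])^2 / (2 * blob_sigma^2))
    f[ii, jj] <- f[ii, jj] - amplitude * outer(gy, gx)
    if (noise_sd > 0)
      f <- f + matrix(stats::rnorm(h_px * w_px, 0, noise_sd), h_px, w_px)
    frames[[i]] <- pmin(pmax(f, 0), 255)
  }
  out <- frame_stack(frames, fps = traj$fps, origin_px = c(pad_px, pad_px))
  attr(out, "truth_px") <- cbind(x = cx_all, y = cy_all)
  out
}
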