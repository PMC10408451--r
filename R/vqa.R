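#' Construct a video sequence
#'
#' @param frames List of frames (numeric matrices or H x W x 3 arrays), all
#'   with identical dimensions, in temporal order.
#' @param fps Frame rate, frames per second, strictly positive.
#' @return An object of class `video_sequence` with fields `frames`, `fps`,
#'   `width`, `height`.
#' @export
video_sequence <- function(frames, fps = 30) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("'fps' must be a single positive number", call. = FALSE)
  d1 <- dim(frames[[1L]])
  for (f in frames) {
    if (length(dim(f)) != length(d1) || !all(dim(f) == d1))
      stop("all frames must share dimensions", call. = FALSE)
  }
  structure(list(frames = frames, fps = fps,
                 height = d1[1L], width = d1[2L]),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  cat(sprintf("video_sequence: %d frames, %dx%d, %g fps\n",
              length(x$frames), x$width, x$height, x$fps))
  invisible(x)
}

#' Scale kernel sizes to the video resolution
#'
#' The metric parameters were optimized on images 512 pixels wide; for a
#' frame of different width the three Gaussian standard deviations are
#' multiplied by the width ratio f = frame_width / base_width so the kernels
#' cover the same fraction of the picture.  `lambda` is kept unchanged.  For
#' a 1920-wide (2K) frame f = 1920/512 = 3.75.
#'
#' @param base An [inrf_params()] bundle (sigmas at the base width).
#' @param frame_width Width in pixels of the frames to be scored.
#' @param base_width Width the base parameters refer to (default 512).
#' @return An `inrf_params` object with scaled sigmas and an extra
#'   `scale_factor` field.
#' @export
#' @examples
#' scale_params(inrf_params(), 1920)$scale_factor  # 3.75
scale_params <- function(base, frame_width, base_width = 512) {
  stopifnot(inherits(base, "inrf_params"))
  for (nm in c("frame_width", "base_width")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop("'", nm, "' must be a positive width in pixels", call. = FALSE)
  }
  f <- frame_width / base_width
  p <- inrf_params(sigma_m = base$sigma_m * f,
                   sigma_w = base$sigma_w * f,
                   sigma_g = base$sigma_g * f,
                   lambda = base$lambda, sigmoid = base$sigmoid,
                   truncate = base$truncate, n_levels = base$n_levels)
  p$scale_factor <- f
  p
}

#' Frame-rate alignment plan
#'
#' Pairs the frames of a high-rate reference with those of an equal- or
#' lower-rate distorted video.  `drop_reference` decimates the reference:
#' `ref_indices[i] = floor(i * n_ref / n_dist)` (0-based), keeping every
#' k-th frame when the rate ratio is an integer k.  `duplicate_distorted`
#' repeats distorted frames: `dist_indices[i] = floor(i * n_dist / n_ref)`.
#' Distorted videos with more frames than the reference are not supported.
#'
#' @param n_ref,n_dist Frame counts (n_ref >= n_dist >= 1).
#' @param strategy `"drop_reference"` (default, the better-performing
#'   protocol) or `"duplicate_distorted"`.
#' @return A list with `strategy` and 0-based, equal-length `ref_indices`
#'   and `dist_indices`.
#' @export
#' @examples
#' plan_alignment(120, 60)$ref_indices[1:5]  # 0 2 4 6 8
plan_alignment <- function(n_ref, n_dist,
                           strategy = c("drop_reference",
                                        "duplicate_distorted")) {
  strategy <- match.arg(strategy)
  n_ref <- as.integer(n_ref); n_dist <- as.integer(n_dist)
  if (is.na(n_ref) || is.na(n_dist) || n_ref < 1L || n_dist < 1L)
    stop("frame counts must be positive integers", call. = FALSE)
  if (n_dist > n_ref)
    stop("distorted video has more frames than the reference; ",
         "only equal- or lower-rate distorted videos are supported",
         call. = FALSE)
  if (strategy == "drop_reference") {
    i <- seq_len(n_dist) - 1L
    ref_idx <- as.integer(floor(i * n_ref / n_dist))
    dist_idx <- i
  } else {
    i <- seq_len(n_ref) - 1L
    ref_idx <- i
    dist_idx <- as.integer(floor(i * n_dist / n_ref))
  }
  list(strategy = strategy, ref_indices = ref_idx, dist_indices = dist_idx)
}

#' Full-reference video quality score
#'
#' Aligns frame counts according to `strategy`, scales the kernel sizes to
#' the frame width (see [scale_params()]), scores every aligned frame pair
#' with [inrf_iqa()], and pools by the arithmetic mean.  Per-frame scores
#' and the alignment plan are attached as attributes for diagnostics.
#'
#' @param ref,dist [video_sequence()] objects with matching frame
#'   dimensions; `dist` may have fewer frames (lower frame rate) but not
#'   more.
#' @param base Base [inrf_params()] (at `base_width`).
#' @param strategy Alignment strategy, see [plan_alignment()].
#' @param base_width Width the base parameters refer to (default 512).
#' @param luminance,exact Passed to [inrf_iqa()].
#' @return A single number with attributes `per_frame` (numeric vector),
#'   `plan`, and `scale_factor`.
#' @export
inrf_vqa <- function(ref, dist, base = inrf_params(),
                     strategy = c("drop_reference", "duplicate_distorted"),
                     base_width = 512, luminance = "luma601",
                     exact = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(ref, "video_sequence"), inherits(dist, "video_sequence"))
  if (ref$width != dist$width || ref$height != dist$height)
    stop("reference and distorted frame dimensions differ", call. = FALSE)
  plan <- plan_alignment(length(ref$frames), length(dist$frames), strategy)
  params <- scale_params(base, ref$width, base_width)
  per_frame <- vapply(seq_along(plan$ref_indices), function(i) {
    inrf_iqa(ref$frames[[plan$ref_indices[i] + 1L]],
             dist$frames[[plan$dist_indices[i] + 1L]],
             params, luminance = luminance, exact = exact)
  }, numeric(1))
  score <- mean(per_frame)
  attr(score, "per_frame") <- per_frame
  attr(score, "plan") <- plan
  attr(score, "scale_factor") <- params$scale_factor
  score
}
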