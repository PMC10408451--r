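#' Extract a luminance channel in \[0,1\]
#'
#' Single-channel input passes through, rescaled from 8-bit to \[0,1\] when
#' needed.  Three-channel RGB maps by default through the Rec. 601 luma,
#' Y = 0.299 R + 0.587 G + 0.114 B on \[0,1\] channels (the convention of the
#' classic quality-assessment databases); `standard = "y"` instead
#' linearizes sRGB and takes CIE/Rec. 709 Y
#' (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array (RGB), either
#'   8-bit (values in \[0,255\], detected by a maximum above 1) or already in
#'   \[0,1\].
#' @param standard `"luma601"` (default) or `"y"`.
#' @return Numeric matrix of luminance in \[0,1\].
#' @export
#' @examples
#' to_luminance(array(c(0, 255, 0), dim = c(1, 1, 3)))  # pure green: 0.587
to_luminance <- function(image, standard = c("luma601", "y")) {
  standard <- match.arg(standard)
  if (is.numeric(image) && !all(is.finite(image)))
    stop("luminance values must be finite and in [0,1]", call. = FALSE)
  scale01 <- function(x) if (max(x) > 1) x / 255 else x
  if (is.matrix(image)) {
    img <- scale01(image)
  } else if (is.array(image) && length(dim(image)) == 3L) {
    nch <- dim(image)[3L]
    hw <- dim(image)[1:2]
    # channel extraction that never drops dims (1 x 1 x 3 inputs are legal)
    ch <- function(a, c) matrix(a[, , c], hw[1L], hw[2L])
    if (nch == 1L) {
      img <- scale01(ch(image, 1L))
    } else if (nch == 3L) {
      v <- scale01(image)
      if (standard == "luma601") {
        img <- 0.299 * ch(v, 1L) + 0.587 * ch(v, 2L) + 0.114 * ch(v, 3L)
      } else {
        lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
        dim(lin) <- dim(v)
        img <- 0.2126 * ch(lin, 1L) + 0.7152 * ch(lin, 2L) +
          0.0722 * ch(lin, 3L)
      }
    } else {
      stop("unsupported channel count: ", nch, call. = FALSE)
    }
  } else {
    stop("expected a matrix or an H x W x 3 array", call. = FALSE)
  }
  if (!all(is.finite(img)) || min(img) < 0 || max(img) > 1)
    stop("luminance values must be finite and in [0,1]", call. = FALSE)
  img
}

#' Full-reference image quality score
#'
#' Both images are converted to luminance, transformed by the INRF model
#' under the same parameters, and compared by the mean squared difference in
#' the transformed ("perceptual") domain.  0 means identical transforms;
#' larger values mean stronger perceptual difference.  The score is
#' symmetric in its two arguments.
#'
#' @param ref,dist Reference and distorted images (matrix or H x W x 3
#'   array); dimensions must match exactly — no resizing is performed.
#' @param params An [inrf_params()] bundle.
#' @param luminance Luminance standard, see [to_luminance()].
#' @param exact Use the exact per-pixel transform instead of the level-set
#'   fast path.
#' @param rmse If `TRUE` return the root mean squared difference instead of
#'   the mean squared difference (rank-identical; some related work reports
#'   RMSE).
#' @return A single non-negative number.
#' @export
#' @examples
#' a <- matrix(runif(256), 16, 16)
#' inrf_iqa(a, a)  # 0
inrf_iqa <- function(ref, dist, params = inrf_params(),
                     luminance = c("luma601", "y"), exact = FALSE,
                     rmse = FALSE) {
  luminance <- match.arg(luminance)
  dr <- dim(ref); dd <- dim(dist)
  if (length(dr) != length(dd) || !all(dr == dd))
    stop("reference and distorted images must have identical dimensions (",
         paste(dr, collapse = "x"), " vs ", paste(dd, collapse = "x"), ")",
         call. = FALSE)
  I  <- to_luminance(ref,  luminance)
  ID <- to_luminance(dist, luminance)
  O  <- inrf_transform(I,  params, exact = exact)
  OD <- inrf_transform(ID, params, exact = exact)
  v <- mean((O - OD)^2)
  if (rmse) sqrt(v) else v
}
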