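## Synthetic fixtures: images, parametric distortions, videos, and scored
## datasets with a planted metric-to-MOS relationship.  All generators are
## deterministic under a seed and touch neither filesystem nor network, so
## the whole package is testable without downloading quality databases.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic test image
#'
#' Deterministic given `(kind, size, seed)`.  `"ramp"` is a horizontal
#' luminance ramp from 0 to 1; `"disk"` a bright disk with a soft edge on a
#' dark background; `"sinusoid"` an oblique grating; `"filtered_noise"` is
#' Gaussian noise shaped to a 1/f amplitude spectrum — the classic
#' natural-image surrogate (power-spectrum slope near -2 on log-log axes).
#'
#' @param kind One of `"ramp"`, `"disk"`, `"sinusoid"`, `"filtered_noise"`.
#' @param size Side length in pixels (>= 8); images are square.
#' @param seed Integer seed (only `filtered_noise` consumes randomness, but
#'   the seed is part of every image's identity).
#' @return Numeric `size` x `size` matrix with values in \[0,1\].
#' @export
make_image <- function(kind = c("ramp", "disk", "sinusoid",
                                "filtered_noise"),
                       size = 64, seed = 1) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (is.na(size) || size < 8L) stop("'size' must be >= 8", call. = FALSE)
  xs <- matrix(rep(seq_len(size) - 1, each = size), size, size)  # column idx
  ys <- matrix(rep(seq_len(size) - 1, times = size), size, size) # row idx
  switch(kind,
    ramp = xs / (size - 1),
    disk = {
      cx <- (size - 1) / 2
      r <- sqrt((xs - cx)^2 + (ys - cx)^2)
      edge <- size / 4
      1 / (1 + exp((r - edge) / (size / 40)))
    },
    sinusoid = 0.5 + 0.5 * sin(2 * pi * (3 * xs + 2 * ys) / size),
    filtered_noise = with_seed(seed, {
      z <- matrix(rnorm(size^2), size, size)
      Z <- stats::fft(z)
      fx <- ((seq_len(size) - 1 + size %/% 2) %% size) - size %/% 2
      f <- sqrt(outer(fx^2, fx^2, "+"))
      f[f == 0] <- 1
      amp <- 1 / f
      out <- Re(stats::fft(Z * amp, inverse = TRUE)) / size^2
      out <- out - min(out)
      out / max(out)
    }))
}

#' Apply a parametric distortion
#'
#' `level = 0` always reproduces the input bit for bit, and for every kind
#' a higher level produces a stronger distortion by construction.  Outputs
#' are clipped to \[0,1\].
#'
#' Kinds and level units: `gaussian_noise` (additive, level = noise std in
#' luminance units), `gaussian_blur` (level = blur sigma in pixels),
#' `contrast_change` (contrast compressed toward the image mean by the
#' fraction `min(level, 1)`), `quantization` (luminance rounded to a grid
#' of step `level`, so at most `floor(1/level) + 1` distinct values
#' remain), `block_artifact` (each 8x8 block replaced by a blend of itself
#' with its block mean, blend weight `min(level, 1)`).
#'
#' @param image Numeric matrix in \[0,1\].
#' @param kind Distortion tag, see above.
#' @param level Non-negative strength, kind-specific units.
#' @param seed Integer seed (used by `gaussian_noise`).
#' @return Distorted matrix, same size, values in \[0,1\].
#' @export
apply_distortion <- function(image,
                             kind = c("gaussian_noise", "gaussian_blur",
                                      "contrast_change", "quantization",
                                      "block_artifact"),
                             level, seed = 1) {
  kind <- match.arg(kind)
  image <- validate_luminance(image)
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level < 0)
    stop("'level' must be a single non-negative number", call. = FALSE)
  if (level == 0) return(image)
  clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }  # keeps dim
  switch(kind,
    gaussian_noise = with_seed(seed, {
      clip01(image + matrix(rnorm(length(image), sd = level),
                            nrow(image), ncol(image)))
    }),
    gaussian_blur = {
      taps <- gaussian_taps(level, as.integer(ceiling(3 * level)))
      clip01(sep_conv2_symm(image, taps))
    },
    contrast_change = {
      a <- min(level, 1)
      clip01(mean(image) + (image - mean(image)) * (1 - a))
    },
    quantization = clip01(round(image / level) * level),
    block_artifact = {
      a <- min(level, 1)
      bs <- 8L
      h <- nrow(image); w <- ncol(image)
      bi <- (seq_len(h) - 1L) %/% bs
      bj <- (seq_len(w) - 1L) %/% bs
      means <- tapply(image, list(bi[row(image)], bj[col(image)]), mean)
      blocky <- means[cbind(bi[row(image)] + 1L, bj[col(image)] + 1L)]
      dim(blocky) <- dim(image)
      clip01((1 - a) * image + a * blocky)
    })
}

#' Generate a synthetic video
#'
#' `"static"` repeats the base frame; `"pan"` shifts it horizontally by one
#' pixel per frame with wrap-around (circular shift), giving fully
#' predictable motion for alignment tests.
#'
#' @param base Numeric matrix in \[0,1\], the first frame.
#' @param n_frames Number of frames (>= 1).
#' @param motion `"static"` or `"pan"`.
#' @param fps Frame rate, default 30.
#' @return A [video_sequence()].
#' @export
make_video <- function(base, n_frames, motion = c("static", "pan"),
                       fps = 30) {
  motion <- match.arg(motion)
  base <- validate_luminance(base)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L)
    stop("'n_frames' must be >= 1", call. = FALSE)
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    frames[[i]] <- if (motion == "static" || i == 1L) base
      else {
        s <- (i - 1L) %% ncol(base)
        if (s == 0L) base else base[, c((s + 1L):ncol(base), 1L:s)]
      }
  }
  video_sequence(frames, fps = fps)
}

#' Scored dataset with a planted metric-to-MOS relationship
#'
#' Builds reference images, distorts each at `levels` increasing strengths
#' (cycling through image kinds and distortion families so different metric
#' parameters reorder the pairs differently), computes the image metric
#' under `planted_params`, and emits surrogate opinion scores as a fixed
#' monotone-decreasing four-parameter logistic of the metric plus optional
#' Gaussian noise.  With `noise_sd = 0` the metric under the planted
#' parameters is therefore a perfect (anti-)monotone predictor: SRCC = -1
#' and PLCC after the logistic fit = 1, which is what the evaluation and
#' grid-search tests exploit.  The surrogate validates plumbing and
#' optimizer recovery, not perceptual validity.
#'
#' @param n_contents Number of reference images (>= 2).
#' @param levels Distortion levels per content (>= 2).
#' @param planted_params The [inrf_params()] the scores are generated
#'   under.
#' @param noise_sd Std. dev. of Gaussian noise added to the surrogate
#'   scores (0 = noiseless).
#' @param seed Integer seed.
#' @param size Image side length, default 64.
#' @return List with `pairs` (list of `list(ref, dist)`), `subjective`,
#'   `metric` (the planted-parameter scores), and `manifest` (a data frame
#'   describing each pair).
#' @export
make_scored_dataset <- function(n_contents = 4, levels = 4,
                                planted_params = inrf_params(),
                                noise_sd = 0, seed = 1, size = 64) {
  n_contents <- as.integer(n_contents); levels <- as.integer(levels)
  if (is.na(n_contents) || n_contents < 2L)
    stop("'n_contents' must be >= 2", call. = FALSE)
  if (is.na(levels) || levels < 2L)
    stop("'levels' must be >= 2", call. = FALSE)
  img_kinds <- c("disk", "sinusoid", "filtered_noise", "ramp")
  dist_kinds <- c("gaussian_noise", "gaussian_blur", "contrast_change",
                  "block_artifact")
  base_level <- c(gaussian_noise = 0.03, gaussian_blur = 0.6,
                  contrast_change = 0.18, block_artifact = 0.25)
  pairs <- list(); manifest <- NULL
  for (ci in seq_len(n_contents)) {
    ik <- img_kinds[(ci - 1L) %% length(img_kinds) + 1L]
    dk <- dist_kinds[(ci - 1L) %% length(dist_kinds) + 1L]
    ref <- make_image(ik, size = size, seed = seed + ci)
    for (l in seq_len(levels)) {
      lv <- base_level[[dk]] * l
      dist <- apply_distortion(ref, dk, level = lv, seed = seed + 100 * ci + l)
      pairs[[length(pairs) + 1L]] <- list(ref = ref, dist = dist)
      manifest <- rbind(manifest, data.frame(
        content = ci, image_kind = ik, distortion = dk, level = lv))
    }
  }
  metric <- vapply(pairs, function(p)
    inrf_iqa(p$ref, p$dist, planted_params), numeric(1))
  s <- sd(metric); if (!is.finite(s) || s == 0) s <- 1
  # fixed decreasing logistic: best quality 5 at low distance, worst 1
  beta_true <- c(1, 5, median(metric), s / 2)
  subjective <- logistic4(metric, beta_true)
  if (noise_sd > 0)
    subjective <- with_seed(seed + 7L,
      subjective + rnorm(length(subjective), sd = noise_sd))
  manifest$metric <- metric
  manifest$subjective <- subjective
  list(pairs = pairs, subjective = subjective, metric = metric,
       manifest = manifest, beta_true = beta_true)
}
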