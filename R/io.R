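## Image and video I/O.
##
## Netpbm (PGM/PPM, both ASCII and binary) is parsed here directly: the R
## stack available to this package has no PNG reader, and netpbm is the
## plain-text-friendly interchange format the test fixtures use.  Video is
## read from frame directories, Y4M streams, or raw planar YUV with a JSON
## geometry sidecar; for YUV sources the Y plane is taken directly as
## luminance (no RGB round trip).

#' Read a PGM or PPM image
#'
#' Supports P2/P5 (grayscale) and P3/P6 (RGB), 8-bit or 16-bit maxval.
#'
#' @param path File path.
#' @return Numeric matrix in \[0,1\] for PGM; H x W x 3 array in \[0,1\] for
#'   PPM.
#' @export
read_netpbm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported netpbm magic '", magic, "' in ", path, call. = FALSE)
  width <- as.integer(read_pnm_token(con))
  height <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  if (any(is.na(c(width, height, maxval))) || width < 1 || height < 1)
    stop("malformed netpbm header in ", path, call. = FALSE)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- width * height * nch
  if (magic %in% c("P2", "P3")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "raw", n = n))
    } else {
      vals <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                      endian = "big")
    }
  }
  if (length(vals) != n)
    stop("truncated netpbm payload in ", path, call. = FALSE)
  v <- vals / maxval
  if (nch == 1L) {
    matrix(v, nrow = height, ncol = width, byrow = TRUE)
  } else {
    a <- array(0, dim = c(height, width, 3L))
    for (c in 1:3) {
      a[, , c] <- matrix(v[seq(c, n, by = 3L)], nrow = height, ncol = width,
                         byrow = TRUE)
    }
    a
  }
}

read_pnm_token <- function(con) {
  # whitespace-separated token, '#' comments to end of line
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || ch == "") {
      if (length(tok)) break
      stop("unexpected end of netpbm header", call. = FALSE)
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "" || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

#' Write a PGM (grayscale) or PPM (RGB) image
#'
#' @param image Numeric matrix or H x W x 3 array with values in \[0,1\].
#' @param path Output path.
#' @param ascii Write the plain-text variant (P2/P3) instead of binary
#'   (P5/P6).  Default `TRUE` so fixtures stay text.
#' @return `path`, invisibly.
#' @export
write_netpbm <- function(image, path, ascii = TRUE) {
  is_color <- length(dim(image)) == 3L
  q <- function(x) pmin(255L, pmax(0L, as.integer(round(x * 255))))
  if (is_color) {
    h <- dim(image)[1]; w <- dim(image)[2]
    inter <- integer(h * w * 3L)
    for (c in 1:3) inter[seq(c, length(inter), 3L)] <- q(t(image[, , c]))
    if (ascii) {
      writeLines(c("P3", paste(w, h), "255",
                   paste(inter, collapse = " ")), path)
    } else {
      con <- file(path, "wb"); on.exit(close(con))
      writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
      writeBin(as.raw(inter), con)
    }
  } else {
    h <- nrow(image); w <- ncol(image)
    vals <- q(t(image))
    if (ascii) {
      writeLines(c("P2", paste(w, h), "255",
                   paste(vals, collapse = " ")), path)
    } else {
      con <- file(path, "wb"); on.exit(close(con))
      writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
      writeBin(as.raw(vals), con)
    }
  }
  invisible(path)
}

#' Write a video as a Y4M (YUV4MPEG2) stream
#'
#' Frames are converted to luminance and written as 4:2:0 planar YUV with
#' neutral chroma (the chroma planes carry no information; this writer
#' exists to round-trip grayscale test material).
#'
#' @param video A [video_sequence()].
#' @param path Output path.
#' @param luminance Passed to [to_luminance()].
#' @return `path`, invisibly.
#' @export
write_y4m <- function(video, path, luminance = "luma601") {
  stopifnot(inherits(video, "video_sequence"))
  w <- video$width; h <- video$height
  if (w %% 2 != 0 || h %% 2 != 0)
    stop("Y4M 4:2:0 requires even frame dimensions", call. = FALSE)
  fr <- fps_to_ratio(video$fps)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("YUV4MPEG2 W%d H%d F%d:%d Ip A1:1 C420\n",
                    w, h, fr[1], fr[2]), con, eos = NULL)
  neutral <- as.raw(rep(128L, (w / 2) * (h / 2)))
  for (f in video$frames) {
    y <- to_luminance(f, luminance)
    writeChar("FRAME\n", con, eos = NULL)
    writeBin(as.raw(pmin(255L, pmax(0L, as.integer(round(t(y) * 255))))), con)
    writeBin(neutral, con)  # U
    writeBin(neutral, con)  # V
  }
  invisible(path)
}

fps_to_ratio <- function(fps) {
  if (abs(fps - round(fps)) < 1e-9) return(c(as.integer(round(fps)), 1L))
  # NTSC-style rates
  num <- as.integer(round(fps * 1001))
  c(num, 1001L)
}

read_y4m <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- read_binary_line(con)
  if (!startsWith(header, "YUV4MPEG2"))
    stop("not a Y4M stream: ", path, call. = FALSE)
  toks <- strsplit(header, " +")[[1]][-1]
  w <- h <- NA_integer_; fps <- 30; cs <- "420"
  for (t in toks) {
    key <- substr(t, 1, 1); val <- substr(t, 2, nchar(t))
    if (key == "W") w <- as.integer(val)
    if (key == "H") h <- as.integer(val)
    if (key == "F") {
      fr <- as.numeric(strsplit(val, ":")[[1]])
      fps <- fr[1] / fr[2]
    }
    if (key == "C") cs <- val
  }
  if (is.na(w) || is.na(h))
    stop("Y4M header missing geometry: ", path, call. = FALSE)
  chroma_bytes <- if (startsWith(cs, "420")) (w / 2) * (h / 2) * 2L
                  else if (startsWith(cs, "422")) (w / 2) * h * 2L
                  else if (startsWith(cs, "444")) w * h * 2L
                  else if (startsWith(cs, "mono")) 0L
                  else stop("unsupported Y4M chroma mode: ", cs, call. = FALSE)
  frames <- list()
  repeat {
    marker <- read_binary_line(con)
    if (is.null(marker)) break
    if (!startsWith(marker, "FRAME"))
      stop("malformed Y4M frame marker in ", path, call. = FALSE)
    y <- readBin(con, "raw", n = w * h)
    if (length(y) != w * h)
      stop("truncated Y4M frame in ", path, call. = FALSE)
    if (chroma_bytes > 0) invisible(readBin(con, "raw", n = chroma_bytes))
    frames[[length(frames) + 1L]] <-
      matrix(as.integer(y) / 255, nrow = h, ncol = w, byrow = TRUE)
  }
  if (!length(frames)) stop("Y4M stream has no frames: ", path, call. = FALSE)
  video_sequence(frames, fps = fps)
}

read_binary_line <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0) return(if (length(out)) rawToChar(out) else NULL)
    if (b == as.raw(10L)) return(rawToChar(out))
    out <- c(out, b)
  }
}

read_raw_yuv <- function(path, width = NULL, height = NULL, fps = NULL,
                         format = NULL) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    width <- width %||% meta$width
    height <- height %||% meta$height
    fps <- fps %||% meta$fps
    format <- format %||% meta$format
  }
  if (is.null(width) || is.null(height) || is.null(fps))
    stop("raw YUV input needs width/height/fps (sidecar '", sidecar,
         "' or arguments)", call. = FALSE)
  format <- format %||% "yuv420p"
  frame_bytes <- switch(format,
    yuv420p = as.integer(width * height * 1.5),
    yuv444p = as.integer(width * height * 3),
    gray    = as.integer(width * height),
    stop("unsupported raw YUV pixel format: ", format, call. = FALSE))
  sz <- file.size(path)
  if (sz %% frame_bytes != 0)
    stop("raw YUV file size ", sz, " is not a multiple of the frame size ",
         frame_bytes, call. = FALSE)
  n_frames <- sz %/% frame_bytes
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    buf <- readBin(con, "raw", n = frame_bytes)
    y <- buf[seq_len(width * height)]
    frames[[i]] <- matrix(as.integer(y) / 255, nrow = height, ncol = width,
                          byrow = TRUE)
  }
  video_sequence(frames, fps = fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a video from disk
#'
#' @param source A directory of numbered PGM/PPM frames, a `.y4m` file, or
#'   a raw planar YUV file accompanied by a `<file>.json` sidecar with
#'   fields `width`, `height`, `fps` and optionally `format` (`yuv420p`,
#'   `yuv444p`, or `gray`).
#' @param layout `"auto"` (default: directory -> frames, extension
#'   otherwise), `"frames"`, `"y4m"`, or `"yuv"`.
#' @param fps Frame rate for frame directories (default 30) or to override
#'   a missing sidecar value.
#' @param ... Passed to the raw YUV reader (`width`, `height`, `format`).
#' @return A [video_sequence()]; YUV-sourced frames are luminance matrices
#'   (the Y plane rescaled to \[0,1\]).
#' @export
read_video <- function(source, layout = c("auto", "frames", "y4m", "yuv"),
                       fps = NULL, ...) {
  layout <- match.arg(layout)
  if (layout == "auto") {
    layout <- if (dir.exists(source)) "frames"
              else if (grepl("\\.y4m$", source, ignore.case = TRUE)) "y4m"
              else "yuv"
  }
  switch(layout,
    frames = {
      files <- list.files(source, pattern = "\\.(pgm|ppm|pnm)$",
                          ignore.case = TRUE, full.names = TRUE)
      if (!length(files))
        stop("no PGM/PPM frames found in ", source, call. = FALSE)
      files <- files[order(basename(files))]
      video_sequence(lapply(files, read_netpbm), fps = fps %||% 30)
    },
    y4m = read_y4m(source),
    yuv = read_raw_yuv(source, fps = fps, ...))
}
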