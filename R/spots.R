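# Nascent-transcription spot detection and quantification.
#
# Coordinate convention: images are matrices indexed [row, col]; reported
# spot coordinates are 0-based pixel-centre with x = column - 1, y = row - 1.

#' Maximum z-projection
#'
#' @param stack A 3-D array (rows x cols x z) or a list of equally sized
#'   matrices (z-planes).
#' @return A matrix: the per-pixel maximum over z.
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    if (!length(stack)) stop("empty stack")
    return(Reduce(pmax, stack))
  }
  if (length(dim(stack)) == 2) return(stack)
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("'stack' must be a rows x cols x z array with at least one plane")
  Reduce(pmax, lapply(seq_len(dim(stack)[3]), function(z) stack[, , z]))
}

# Reflect-pad a matrix by `m` pixels on every side.
pad_reflect <- function(img, m) {
  n <- nrow(img); p <- ncol(img)
  if (m >= n || m >= p) stop("padding exceeds image size")
  ri <- c(seq(m + 1, 2), seq_len(n), seq(n - 1, n - m))
  ci <- c(seq(m + 1, 2), seq_len(p), seq(p - 1, p - m))
  img[ri, ci, drop = FALSE]
}

#' Gaussian blur with reflective boundary handling
#'
#' Separable Gaussian convolution; the image is reflect-padded before
#' filtering so that the boundary introduces no artificial gradients.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian sd in pixels.
#' @param radius Kernel half-width; default `ceiling(4 * sigma)`.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(image, sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  radius <- min(radius, nrow(image) - 1, ncol(image) - 1)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- pad_reflect(image, radius)
  out <- EBImage::filter2(pad, matrix(k, ncol = 1), boundary = "circular")
  out <- EBImage::filter2(out, matrix(k, nrow = 1), boundary = "circular")
  out[(radius + 1):(radius + nrow(image)),
      (radius + 1):(radius + ncol(image)), drop = FALSE]
}

#' Adaptive background subtraction
#'
#' Subtracts a strongly Gaussian-blurred copy of the image from the image
#' itself, removing slowly varying background while preserving
#' diffraction-limited spots. Negative values are preserved.
#'
#' @param image Numeric matrix.
#' @param blur_scale Blur sd in pixels (default 10).
#' @return Background-subtracted matrix.
#' @export
subtract_adaptive_background <- function(image, blur_scale = 10) {
  stopifnot(blur_scale > 0)
  image - gaussian_blur(image, blur_scale)
}

# 3x3 neighbourhood maximum via shifted copies (edges replicate).
max3x3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up <- m[c(1, seq_len(n - 1)), , drop = FALSE]
  dn <- m[c(seq(2, n), n), , drop = FALSE]
  mx <- pmax(m, up, dn)
  lf <- mx[, c(1, seq_len(p - 1)), drop = FALSE]
  rt <- mx[, c(seq(2, p), p), drop = FALSE]
  pmax(mx, lf, rt)
}

#' Multi-scale Laplacian-of-Gaussian spot detection
#'
#' Detects bright diffraction-limited blobs as local maxima of the
#' scale-normalised negative Laplacian-of-Gaussian response across a
#' geometric ladder of scales, with greedy suppression of overlapping
#' detections (stronger response wins). For a Gaussian spot of sd s and
#' amplitude a the matched-scale response peak is about a/2, which anchors
#' the choice of `threshold`.
#'
#' @param image Numeric matrix (background-subtracted recommended).
#' @param min_scale,max_scale Detector scale range (Gaussian sd, pixels).
#' @param n_scales Number of scales on the geometric ladder.
#' @param threshold Minimum normalised response of a detection.
#' @param overlap Suppression: a weaker detection is dropped when its centre
#'   is closer than `overlap * (r1 + r2)` to a stronger one, with
#'   `r = sqrt(2) * scale`.
#' @return data.frame with `x`, `y` (0-based pixel-centre), `scale`
#'   (sd estimate, pixels), `response`; empty on a blank image.
#' @export
detect_spots <- function(image, min_scale = 1.5, max_scale = 4, n_scales = 8,
                         threshold = 20, overlap = 0.5) {
  stopifnot(min_scale > 0, min_scale <= max_scale)
  sigmas <- if (min_scale == max_scale) min_scale
            else exp(seq(log(min_scale), log(max_scale), length.out = n_scales))
  resp <- lapply(sigmas, function(s) {
    g <- gaussian_blur(image, s)
    n <- nrow(g); p <- ncol(g)
    lap <- matrix(0, n, p)
    lap[2:(n - 1), 2:(p - 1)] <-
      g[1:(n - 2), 2:(p - 1)] + g[3:n, 2:(p - 1)] +
      g[2:(n - 1), 1:(p - 2)] + g[2:(n - 1), 3:p] -
      4 * g[2:(n - 1), 2:(p - 1)]
    -s^2 * lap
  })
  cand <- list()
  for (i in seq_along(sigmas)) {
    r <- resp[[i]]
    is_max <- r >= max3x3(r) & r > threshold
    if (length(sigmas) > 1) {
      if (i > 1) is_max <- is_max & r >= resp[[i - 1]]
      if (i < length(sigmas)) is_max <- is_max & r >= resp[[i + 1]]
    }
    is_max[c(1, nrow(r)), ] <- FALSE
    is_max[, c(1, ncol(r))] <- FALSE
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx))
      cand[[length(cand) + 1L]] <-
        data.frame(x = idx[, 2] - 1, y = idx[, 1] - 1, scale = sigmas[i],
                   response = r[idx])
  }
  if (!length(cand))
    return(data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
                      response = numeric(0)))
  d <- do.call(rbind, cand)
  d <- d[order(-d$response), , drop = FALSE]
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    ki <- which(keep)
    if (!length(ki)) { keep[i] <- TRUE; next }
    dist <- sqrt((d$x[ki] - d$x[i])^2 + (d$y[ki] - d$y[i])^2)
    lim <- overlap * sqrt(2) * (d$scale[ki] + d$scale[i])
    keep[i] <- all(dist >= lim)
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median spot intensity within a 3-sigma bounding box
#'
#' Median of the pixel values in the axis-aligned square of edge length
#' `round(3 * scale)`, forced odd and at least 3 px, centred on the spot and
#' clipped at the image borders. The even-count median is the mean of the two
#' middle values (R's default).
#'
#' @param image Numeric matrix.
#' @param x,y Spot centre, 0-based pixel-centre coordinates.
#' @param scale Spot scale estimate (sd, pixels).
#' @return Median intensity (scalar).
#' @export
quantify_spot_median <- function(image, x, y, scale) {
  edge <- max(round(3 * scale), 3)
  if (edge %% 2 == 0) edge <- edge + 1
  half <- (edge - 1) / 2
  rows <- max(1, round(y) + 1 - half):min(nrow(image), round(y) + 1 + half)
  cols <- max(1, round(x) + 1 - half):min(ncol(image), round(x) + 1 + half)
  if (!length(rows) || !length(cols) || rows[1] > nrow(image) || cols[1] > ncol(image))
    stop("spot bounding box lies outside the image")
  median(image[rows, cols])
}

#' Per-frame spot counts and total intensity
#'
#' @param records data.frame of spot records with columns `frame` and
#'   `median_intensity`.
#' @param n_frames Number of frames in the series (frames without spots get
#'   zero count and intensity).
#' @param frame_interval Minutes per frame (frame 1 is t = 0).
#' @return List of two time series: `counts` and `total_intensity`.
#' @export
summarize_spots <- function(records, n_frames, frame_interval = 0.5) {
  tm <- (seq_len(n_frames) - 1) * frame_interval
  cnt <- tabulate(records$frame, nbins = n_frames)
  tot <- vapply(seq_len(n_frames), function(f)
    sum(records$median_intensity[records$frame == f]), numeric(1))
  list(counts = time_series(tm, cnt),
       total_intensity = time_series(tm, tot))
}

#' Full spot-quantification pipeline over a frame series
#'
#' For each frame: maximum z-projection (if stacks are given), adaptive
#' background subtraction, multi-scale LoG detection, and median intensity in
#' a 3-sigma box on the background-subtracted frame.
#'
#' @param frames List of matrices, or list of 3-D arrays (z-stacks).
#' @param frame_interval Minutes per frame.
#' @param blur_scale Background-subtraction blur sd (pixels).
#' @param ... Passed to [detect_spots()].
#' @return Object of class `spot_table`: list with `records` (`frame`,
#'   `time`, `x`, `y`, `scale`, `median_intensity`), `counts`,
#'   `total_intensity`.
#' @export
quantify_spots <- function(frames, frame_interval = 0.5, blur_scale = 10, ...) {
  recs <- list()
  for (f in seq_along(frames)) {
    img <- subtract_adaptive_background(max_project(frames[[f]]), blur_scale)
    det <- detect_spots(img, ...)
    if (nrow(det)) {
      det$median_intensity <- vapply(seq_len(nrow(det)), function(i)
        quantify_spot_median(img, det$x[i], det$y[i], det$scale[i]),
        numeric(1))
      det <- cbind(frame = f, time = (f - 1) * frame_interval, det)
      recs[[length(recs) + 1L]] <- det
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(frame = integer(0), time = numeric(0),
                             x = numeric(0), y = numeric(0),
                             scale = numeric(0), response = numeric(0),
                             median_intensity = numeric(0))
  s <- summarize_spots(records, length(frames), frame_interval)
  structure(list(records = records, counts = s$counts,
                 total_intensity = s$total_intensity),
            class = "spot_table")
}

#' @export
print.spot_table <- function(x, ...) {
  cat("Spot table:", nrow(x$records), "spots across",
      nrow(x$counts), "frames\n")
  cat("  counts per frame:", paste(utils::head(x$counts$value, 10),
                                   collapse = " "),
      if (nrow(x$counts) > 10) "...\n" else "\n")
  invisible(x)
}
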