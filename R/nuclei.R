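# Nuclear segmentation, reporter measurement, bleaching correction and the
# nuclear/total ratio used as the import-export model's data.

#' Segment nuclei from a counter-label image
#'
#' Gaussian smoothing (default sd 2 px) followed by Otsu thresholding of the
#' smoothed image; the mask is the bright (above-threshold) class.
#'
#' @param counter_image Numeric matrix (nuclear counter-label channel).
#' @param smooth_scale Smoothing sd in pixels.
#' @return Logical matrix mask.
#' @export
segment_nuclei <- function(counter_image, smooth_scale = 2) {
  sm <- gaussian_blur(counter_image, smooth_scale)
  rg <- range(sm)
  if (diff(rg) == 0)
    stop("constant image: Otsu threshold undefined")
  thr <- EBImage::otsu(sm, range = rg)
  sm > thr
}

#' Cytoplasmic annulus mask around segmented nuclei
#'
#' Dilates the nuclear mask with a disk-shaped structuring element (exact
#' Euclidean dilation: every pixel within `dilation_radius` of a nuclear
#' pixel) and removes the nuclei, leaving the surrounding cytoplasmic space.
#'
#' @param nuclear_mask Logical matrix.
#' @param dilation_radius Disk radius in pixels (default 10).
#' @return Logical matrix, disjoint from `nuclear_mask`.
#' @export
cytoplasm_mask <- function(nuclear_mask, dilation_radius = 10) {
  if (!any(nuclear_mask)) stop("empty nuclear mask")
  # distance of every pixel to the nearest nuclear pixel
  d <- as.array(EBImage::distmap(1 - nuclear_mask * 1))
  dim(d) <- dim(nuclear_mask)
  d > 0 & d <= dilation_radius
}

#' Measure reporter intensity per compartment and subtract background
#'
#' Computes per-frame mean reporter intensity inside the nuclear and
#' cytoplasmic masks, then subtracts each track's background proxy — the
#' minimum of its nuclear means over time — from both compartments of that
#' track. By default all nuclei are pooled into a single track (population
#' mode); pass per-frame label matrices in `track_labels` for per-track
#' measurements (each track's cytoplasm is its own dilation annulus minus all
#' nuclei).
#'
#' @param reporter_frames List of reporter matrices.
#' @param nuclear_masks Logical matrix or list of per-frame masks.
#' @param cyto_masks Optional cytoplasm masks; computed from the nuclear
#'   masks by default.
#' @param track_labels Optional list of per-frame integer label matrices
#'   (0 = background); labels are track ids.
#' @param dilation_radius Passed to [cytoplasm_mask()].
#' @param erode_radius Disk radius (pixels) by which the nuclear mask is
#'   eroded before the nuclear mean is taken. Thresholded masks carry a ring
#'   of boundary pixels of mixed nuclear/cytoplasmic signal; a small erosion
#'   keeps the mean inside purely nuclear pixels. 0 (default) measures within
#'   the mask as segmented. The cytoplasmic annulus is always built from the
#'   uneroded mask.
#' @param subtract_background If `FALSE`, raw means are returned.
#' @return data.frame (`frame`, `track_id`, `nuclear_mean`,
#'   `cytoplasm_mean`, `background`); empty masks yield `NA` means.
#' @export
measure_and_correct <- function(reporter_frames, nuclear_masks,
                                cyto_masks = NULL, track_labels = NULL,
                                dilation_radius = 10, erode_radius = 0,
                                subtract_background = TRUE) {
  n <- length(reporter_frames)
  get_mask <- function(m, f) if (is.list(m)) m[[f]] else m
  mean_in <- function(img, mask)
    if (any(mask)) mean(img[mask]) else NA_real_
  shrink <- function(mask) {
    if (erode_radius == 0) return(mask)
    er <- EBImage::erode(mask * 1,
                         EBImage::makeBrush(2 * erode_radius + 1, "disc")) > 0
    if (any(er)) er else mask  # never erode a nucleus away entirely
  }

  rows <- list()
  if (is.null(track_labels)) {
    for (f in seq_len(n)) {
      nm <- get_mask(nuclear_masks, f)
      cm <- if (!is.null(cyto_masks)) get_mask(cyto_masks, f)
            else cytoplasm_mask(nm, dilation_radius)
      rows[[f]] <- data.frame(frame = f, track_id = 1L,
                              nuclear_mean = mean_in(reporter_frames[[f]],
                                                     shrink(nm)),
                              cytoplasm_mean = mean_in(reporter_frames[[f]], cm))
    }
  } else {
    ids <- sort(unique(unlist(lapply(track_labels, function(l)
      setdiff(unique(as.vector(l)), 0)))))
    for (f in seq_len(n)) {
      lab <- track_labels[[f]]
      all_nuc <- lab > 0
      for (id in ids) {
        tm <- lab == id
        cm <- if (any(tm)) cytoplasm_mask(tm, dilation_radius) & !all_nuc
              else tm
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, track_id = id,
          nuclear_mean = mean_in(reporter_frames[[f]], shrink(tm)),
          cytoplasm_mean = mean_in(reporter_frames[[f]], cm))
      }
    }
  }
  out <- do.call(rbind, rows)
  bg <- tapply(out$nuclear_mean, out$track_id,
               function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  out$background <- as.numeric(bg[as.character(out$track_id)])
  if (subtract_background) {
    out$nuclear_mean <- out$nuclear_mean - out$background
    out$cytoplasm_mean <- out$cytoplasm_mean - out$background
  }
  out
}

#' Fit an exponential photobleaching decay
#'
#' Least-squares fit of `I(t) = I0 * exp(-b t)` to the mean total intensity
#' within a time window (default 10-20 min, the on-state equilibrium of
#' continuous activation, where the compartment composition is stationary and
#' the decay is a pure exponential). The fit is log-linear: exact for
#' noiseless exponentials and deterministic.
#'
#' @param time,value Time (min) and mean intensity.
#' @param window Inclusive fitting window in minutes.
#' @return Object of class `bleach_fit`: list(`I0`, `b`, `window`, `n`).
#' @export
fit_bleaching <- function(time, value, window = c(10, 20)) {
  sel <- time >= window[1] & time <= window[2] & is.finite(value)
  if (sum(sel) < 3) stop("need at least 3 points in the bleaching window")
  if (any(value[sel] <= 0))
    stop("non-positive intensities in the bleaching window")
  f <- lm(log(value[sel]) ~ time[sel])
  b <- -unname(coef(f)[2])
  if (b < 0) {
    warning("intensity rises over the window; bleaching rate clamped at 0")
    b <- 0
  }
  structure(list(I0 = exp(unname(coef(f)[1])), b = b, window = window,
                 n = sum(sel)),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("Bleaching fit: I0 = %.4g, b = %.4g /min (%d points in [%g, %g] min)\n",
              x$I0, x$b, x$n, x$window[1], x$window[2]))
  invisible(x)
}

#' Correct a series for photobleaching
#'
#' Restores the bleached signal fraction by dividing by the fitted decay:
#' `corrected(t) = value(t) / exp(-b t)` (equivalently, adding the predicted
#' bleached fraction of the signal back onto the signal).
#'
#' @param time,value The series to correct.
#' @param fit A [fit_bleaching()] result (or any list with element `b >= 0`).
#' @return Corrected time series data.frame (`time`, `value`).
#' @export
bleach_correct <- function(time, value, fit) {
  stopifnot(fit$b >= 0)
  time_series(time, value * exp(fit$b * time))
}

#' Nuclear/total intensity ratio
#'
#' `nuclear / (nuclear + cytoplasm)`, the bleaching- and expression-level
#' normalised measure of nuclear enrichment. Points with non-positive total
#' are returned as `NA`.
#'
#' @param nuclear,cytoplasm Aligned numeric vectors.
#' @return Numeric vector of ratios in `[0, 1]` (or `NA`).
#' @export
nuclear_total_ratio <- function(nuclear, cytoplasm) {
  stopifnot(length(nuclear) == length(cytoplasm))
  tot <- nuclear + cytoplasm
  ifelse(is.finite(tot) & tot > 0, nuclear / tot, NA_real_)
}

#' Quantify a two-channel nuclear translocation time-lapse
#'
#' End-to-end nuclear quantification: segment nuclei from the counter
#' channel, build the cytoplasmic annulus, measure and background-correct the
#' reporter, and return the per-frame nuclear/total ratio.
#'
#' @param counter_frames,reporter_frames Lists of matrices (aligned frames).
#' @param times Frame times in minutes.
#' @param smooth_scale,dilation_radius Segmentation settings.
#' @param erode_radius Nuclear-mask erosion before measurement (pixels,
#'   default 2); see [measure_and_correct()].
#' @return data.frame (`time`, `nuclear_mean`, `cytoplasm_mean`, `ratio`).
#' @export
quantify_nuclei <- function(counter_frames, reporter_frames, times,
                            smooth_scale = 2, dilation_radius = 10,
                            erode_radius = 2) {
  masks <- lapply(counter_frames, segment_nuclei, smooth_scale = smooth_scale)
  m <- measure_and_correct(reporter_frames, masks,
                           dilation_radius = dilation_radius,
                           erode_radius = erode_radius)
  data.frame(time = times,
             nuclear_mean = m$nuclear_mean,
             cytoplasm_mean = m$cytoplasm_mean,
             ratio = nuclear_total_ratio(m$nuclear_mean, m$cytoplasm_mean))
}
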