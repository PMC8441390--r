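# Synthetic raw-data generators with ground-truth annotation. Every
# generator is bit-reproducible given its seed and returns the GroundTruth
# needed to validate the downstream quantification modules.

# Rejection-sample n points uniformly in [margin, limit - margin]^2 with a
# minimum pairwise separation. Errors out after bounded retries.
place_points <- function(n, shape, min_separation, margin, max_tries = 200L) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  for (try in seq_len(max_tries)) {
    xs <- runif(n, margin, shape[2] - 1 - margin)
    ys <- runif(n, margin, shape[1] - 1 - margin)
    if (n == 1 || min(stats::dist(cbind(xs, ys))) >= min_separation)
      return(cbind(x = xs, y = ys))
  }
  stop("could not place ", n, " points at minimum separation ",
       min_separation, " within a ", shape[1], "x", shape[2],
       " frame after ", max_tries, " attempts")
}

# Add an isotropic 2-D Gaussian of given amplitude/sd at 0-based centre (x, y).
add_gaussian <- function(img, x, y, sigma, amplitude) {
  rr <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
  cc <- matrix(0:(ncol(img) - 1), nrow(img), ncol(img), byrow = TRUE)
  img + amplitude * exp(-((cc - x)^2 + (rr - y)^2) / (2 * sigma^2))
}

#' Render synthetic nascent-transcription spot frames
#'
#' Generates frames emulating maximum-projected MS2/MCP imaging: each frame
#' carries `spots_per_frame` diffraction-limited spots, rendered as isotropic
#' 2-D Gaussians on a constant background with i.i.d. Gaussian pixel noise.
#' Spot centres are drawn anew per frame with a minimum pairwise separation.
#' The Gaussian point-spread is the standard diffraction-limited
#' approximation; the additive-Gaussian intensity noise is a stand-in (no
#' noise model for MCP::GFP spot intensity is established).
#'
#' @param n_frames Number of frames.
#' @param spots_per_frame Spots per frame (may be 0).
#' @param amplitude Peak spot amplitude above background.
#' @param scale_range Interval of spot Gaussian sd (pixels).
#' @param background Constant background level.
#' @param noise_sd Pixel noise standard deviation.
#' @param shape Frame size `c(rows, cols)` in pixels.
#' @param min_separation Minimum centre-to-centre distance (pixels).
#' @param seed Integer seed; identical seeds reproduce identical pixels.
#' @return List with `frames` (list of matrices) and `truth` (list with a
#'   `spots` data.frame `frame`, `x`, `y`, `scale`, `amplitude` in 0-based
#'   pixel-centre coordinates, plus the generator parameters and seed).
#' @export
render_spot_frames <- function(n_frames, spots_per_frame, amplitude = 200,
                               scale_range = c(1.5, 3), background = 10,
                               noise_sd = 5, shape = c(128, 128),
                               min_separation = 15, seed = 1) {
  stopifnot(spots_per_frame >= 0, min_separation > 0,
            scale_range[1] > 0, scale_range[2] <= min(shape) / 6)
  with_seed(seed, {
    spots <- list()
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      img <- matrix(background, shape[1], shape[2])
      pos <- place_points(spots_per_frame, shape, min_separation,
                          margin = 3 * scale_range[2])
      sig <- runif(spots_per_frame, scale_range[1], scale_range[2])
      for (i in seq_len(spots_per_frame))
        img <- add_gaussian(img, pos[i, "x"], pos[i, "y"], sig[i], amplitude)
      if (noise_sd > 0)
        img <- img + matrix(rnorm(length(img), sd = noise_sd),
                            shape[1], shape[2])
      frames[[f]] <- img
      if (spots_per_frame > 0)
        spots[[f]] <- data.frame(frame = f, x = pos[, "x"], y = pos[, "y"],
                                 scale = sig, amplitude = amplitude)
    }
    truth <- list(
      spots = if (length(spots)) do.call(rbind, spots)
              else data.frame(frame = integer(0), x = numeric(0),
                              y = numeric(0), scale = numeric(0),
                              amplitude = numeric(0)),
      params = list(amplitude = amplitude, background = background,
                    noise_sd = noise_sd, scale_range = scale_range,
                    min_separation = min_separation, shape = shape),
      seed = seed)
    list(frames = frames, truth = truth)
  })
}

# Nucleus centres on a jittered hexagonal grid, guaranteeing non-overlap.
hex_centres <- function(n, shape, radius, jitter_frac = 0.15) {
  pitch <- 2 * radius * 1.25
  xs <- seq(radius + 2, shape[2] - radius - 3, by = pitch)
  ys <- seq(radius + 2, shape[1] - radius - 3, by = pitch * sqrt(3) / 2)
  if (!length(xs) || !length(ys)) stop("frame too small for nucleus radius")
  g <- expand.grid(x = xs, y = ys)
  odd <- (match(g$y, ys) %% 2) == 1
  g$x <- g$x + ifelse(odd, 0, pitch / 2)
  g <- g[g$x <= shape[2] - radius - 2, , drop = FALSE]
  if (nrow(g) < n)
    stop("cannot place ", n, " non-overlapping nuclei of radius ", radius,
         " in a ", shape[1], "x", shape[2], " frame")
  g <- g[sample.int(nrow(g), n), , drop = FALSE]
  g$x <- g$x + runif(n, -1, 1) * jitter_frac * radius
  g$y <- g$y + runif(n, -1, 1) * jitter_frac * radius
  g
}

#' Render a synthetic two-channel nuclear translocation time-lapse
#'
#' Emulates the nuclear-import quantification data: channel 1 shows
#' constant-intensity nuclear disks (the nuclear counter-label used for
#' segmentation) and channel 2 a reporter whose intensity inside/outside
#' nuclei is proportional to the fluorescent nuclear (NF) and cytoplasmic
#' (CF) concentrations from the import-export model simulated under the
#' protocol, plus offset and Gaussian pixel noise.
#'
#' @inheritParams simulate_import_export
#' @param n_nuclei Number of nuclei (placed on a jittered hexagonal grid).
#' @param frame_interval Minutes between frames.
#' @param noise_sd Channel-2 pixel noise sd (intensity units).
#' @param gain Intensity per unit model concentration.
#' @param offset Camera offset added to every channel-2 pixel.
#' @param nucleus_radius Nucleus disk radius (pixels).
#' @param shape Frame size `c(rows, cols)`.
#' @param seed Integer seed.
#' @return List with `counter` and `reporter` (lists of matrices), `times`,
#'   and `truth` (noise-free nuclear/total `ratio` time series, the model
#'   `trajectory`, nucleus centres, generator parameters, seed).
#' @export
render_nuclear_timelapse <- function(protocol, params_light, params_dark = NULL,
                                     initial = ie_state(CF = 1, NF = 0),
                                     n_nuclei = 9, frame_interval = 1,
                                     noise_sd = 0, gain = 100, offset = 0,
                                     nucleus_radius = 9, shape = c(128, 128),
                                     seed = 1) {
  stopifnot(n_nuclei >= 1)
  t_grid <- seq(0, protocol$t_end[nrow(protocol)], by = frame_interval)
  traj <- simulate_import_export(protocol, params_light, params_dark, initial,
                                 t_grid)
  with_seed(seed, {
    cen <- hex_centres(n_nuclei, shape, nucleus_radius)
    rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
    cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
    nuc_mask <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(n_nuclei))
      nuc_mask <- nuc_mask |
        ((cc - cen$x[i])^2 + (rr - cen$y[i])^2 <= nucleus_radius^2)
    counter <- reporter <- vector("list", length(t_grid))
    for (f in seq_along(t_grid)) {
      counter[[f]] <- matrix(10, shape[1], shape[2]) + 90 * nuc_mask
      img <- offset + gain * ifelse(nuc_mask, traj$NF[f], traj$CF[f])
      if (noise_sd > 0)
        img <- img + matrix(rnorm(length(img), sd = noise_sd),
                            shape[1], shape[2])
      reporter[[f]] <- img
    }
    tot <- traj$NF + traj$CF
    truth <- list(ratio = time_series(t_grid,
                                      ifelse(tot > 0, traj$NF / tot, NA)),
                  trajectory = traj, centres = cen,
                  params = list(gain = gain, offset = offset,
                                noise_sd = noise_sd,
                                nucleus_radius = nucleus_radius),
                  seed = seed)
    list(counter = counter, reporter = reporter, times = t_grid, truth = truth)
  })
}

#' Simulate a per-nucleus expression cohort from an adaptation motif
#'
#' Generates the trace-level analogue of per-nucleus nascent-transcription
#' measurements: each nucleus's trace is the motif output shifted by a
#' jittered activation onset, scaled to intensity units, with additive
#' Gaussian noise truncated at zero. Pooled summaries mimic automated spot
#' detection: the count series is the number of nuclei whose trace exceeds a
#' detection threshold, and the total-intensity series is the sum of traces.
#'
#' @param params Generating [motif_params].
#' @param input Nuclear-input profile (`time`, `value`).
#' @param n_nuclei Number of nuclei.
#' @param onset_jitter_sd Per-nucleus activation-onset jitter sd (minutes).
#' @param noise_sd Additive trace noise sd (intensity units).
#' @param t_grid Output time grid; default the input grid.
#' @param intensity_scale Intensity units per unit motif output.
#' @param detection_threshold Trace level above which a nucleus counts as
#'   expressing.
#' @param seed Integer seed.
#' @return List with `traces` (long data.frame `time`, `nucleus_id`,
#'   `value`), `counts`, `total_intensity` (time series), and `truth`
#'   (generating parameters, noise-free base output, seed).
#' @export
simulate_expression_cohort <- function(params, input, n_nuclei = 100,
                                       onset_jitter_sd = 0, noise_sd = 0,
                                       t_grid = NULL,
                                       intensity_scale = 300,
                                       detection_threshold = NULL,
                                       seed = 1) {
  if (is.null(t_grid)) t_grid <- input$time
  sim <- simulate_motif(params, input,
                        t_grid = sort(unique(c(min(input$time), t_grid))))
  base <- sim$output[match(t_grid, sim$time)]
  if (is.null(detection_threshold))
    detection_threshold <- 0.1 * intensity_scale * max(base, 1e-12)
  with_seed(seed, {
    jit <- if (onset_jitter_sd > 0) rnorm(n_nuclei, sd = onset_jitter_sd)
           else rep(0, n_nuclei)
    tr <- vapply(seq_len(n_nuclei), function(i) {
      v <- if (jit[i] == 0) base
           else approx(t_grid + jit[i], base, xout = t_grid,
                       yleft = 0, rule = 2)$y
      v <- intensity_scale * v
      if (noise_sd > 0) v <- pmax(0, v + rnorm(length(v), sd = noise_sd))
      v
    }, numeric(length(t_grid)))
    traces <- data.frame(time = rep(t_grid, n_nuclei),
                         nucleus_id = rep(seq_len(n_nuclei),
                                          each = length(t_grid)),
                         value = as.vector(tr))
    list(traces = traces,
         counts = time_series(t_grid, rowSums(tr > detection_threshold)),
         total_intensity = time_series(t_grid, rowSums(tr)),
         truth = list(params = params, base_output = time_series(t_grid, base),
                      detection_threshold = detection_threshold,
                      intensity_scale = intensity_scale, seed = seed))
  })
}
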