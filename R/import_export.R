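#' Import-export model parameters
#'
#' Rate constants of the two-compartment nucleocytoplasmic transport model
#' with photobleaching. The model tracks four pools: cytoplasmic and nuclear
#' protein, each split into a fluorescent (unbleached) and a bleached
#' fraction. Bleached protein no longer fluoresces but keeps shuttling and
#' signalling.
#'
#' @param ki Import rate constant (1/min), `>= 0`.
#' @param ke Export rate constant (1/min), `>= 0`.
#' @param b Photobleaching rate (1/min), `>= 0`. Bleaching only occurs under
#'   imaging/activation light, so dark-phase parameter sets use `b = 0`.
#' @return An object of class `ie_params` (named numeric vector).
#' @export
ie_params <- function(ki, ke, b = 0) {
  for (nm in c("ki", "ke", "b")) stop_if_not_scalar(get(nm), nm)
  if (ki < 0 || ke < 0 || b < 0)
    stop("import-export rate constants must be non-negative")
  structure(c(ki = ki, ke = ke, b = b), class = "ie_params")
}

#' Compartment state of the import-export model
#'
#' @param CF,NF Cytoplasmic and nuclear fluorescent (unbleached)
#'   concentrations, non-dimensional.
#' @param CB,NB Cytoplasmic and nuclear bleached concentrations.
#' @return Named numeric vector of class `ie_state`.
#' @export
ie_state <- function(CF = 1, NF = 0, CB = 0, NB = 0) {
  y <- c(CF = CF, NF = NF, CB = CB, NB = NB)
  if (any(!is.finite(y)) || any(y < 0))
    stop("compartment concentrations must be finite and non-negative")
  structure(y, class = "ie_state")
}

#' Published import-export parameter sets
#'
#' The fitted rate constants for the light (activating) and dark phases of
#' the optogenetic Notch system, together with the fitted initial state at
#' activation onset and the model state at the end of 10 min of continuous
#' activation (used as the dark-phase initial condition).
#'
#' @return A list with elements `light`, `dark` ([ie_params]), `initial_light`
#'   and `initial_dark` ([ie_state]).
#' @export
ie_reference_params <- function() {
  list(
    light = ie_params(ki = 0.2619, ke = 0.0455, b = 0.1029),
    dark  = ie_params(ki = 10e-6, ke = 0.1419, b = 0),
    initial_light = ie_state(CF = 0.9112, NF = 0.0273, CB = 0, NB = 0),
    initial_dark  = ie_state(CF = 0.0623, NF = 0.2726, CB = 0.1122, NB = 0.4902)
  )
}

#' Activation protocols
#'
#' An activation protocol is an ordered set of contiguous light/dark segments
#' starting at t = 0 (minutes). `protocol_continuous()` gives uninterrupted
#' activating light; `protocol_pulsatile()` alternates light pulses with dark
#' recovery periods (the standard protocol is 5 min light / 10 min dark).
#'
#' @param phases Character vector of `"light"` / `"dark"` phases.
#' @param durations Segment durations in minutes, same length as `phases`.
#' @return A data.frame of class `activation_protocol` with columns
#'   `t_start`, `t_end`, `phase`.
#' @export
activation_protocol <- function(phases, durations) {
  phases <- match.arg(phases, c("light", "dark"), several.ok = TRUE)
  if (length(phases) != length(durations) || length(phases) == 0)
    stop("'phases' and 'durations' must be non-empty and of equal length")
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("segment durations must be positive")
  t_end <- cumsum(durations)
  structure(
    data.frame(t_start = c(0, t_end[-length(t_end)]), t_end = t_end,
               phase = phases, stringsAsFactors = FALSE),
    class = c("activation_protocol", "data.frame")
  )
}

#' @rdname activation_protocol
#' @param duration Total protocol length in minutes.
#' @export
protocol_continuous <- function(duration = 40) {
  activation_protocol("light", duration)
}

#' @rdname activation_protocol
#' @param t_on,t_off Light-pulse and dark-interval durations in minutes.
#' @export
protocol_pulsatile <- function(duration = 40, t_on = 5, t_off = 10) {
  phases <- character(0); durs <- numeric(0); t <- 0; light <- TRUE
  while (t < duration - 1e-12) {
    d <- min(if (light) t_on else t_off, duration - t)
    phases <- c(phases, if (light) "light" else "dark")
    durs <- c(durs, d)
    t <- t + d
    light <- !light
  }
  activation_protocol(phases, durs)
}

# Closed-form solution of the linear import-export system over one
# constant-parameter segment. The fluorescent pool F = CF + NF decays as
# exp(-b t) while its nuclear fraction relaxes towards ki/(ki+ke) at rate
# ki+ke; the total pool T = CF+NF+CB+NB is conserved and the total nuclear
# amount N = NF+NB obeys the same relaxation independently of b.
ie_segment <- function(y0, p, t) {
  ki <- p[["ki"]]; ke <- p[["ke"]]; b <- p[["b"]]
  CF0 <- y0[["CF"]]; NF0 <- y0[["NF"]]; CB0 <- y0[["CB"]]; NB0 <- y0[["NB"]]
  F0 <- CF0 + NF0
  Tt <- F0 + CB0 + NB0
  N0 <- NF0 + NB0
  s <- ki + ke
  Ft <- F0 * exp(-b * t)
  if (s > 0) {
    r <- ki / s
    rho0 <- if (F0 > 0) NF0 / F0 else r
    NF <- Ft * (r + (rho0 - r) * exp(-s * t))
    N <- Tt * r + (N0 - Tt * r) * exp(-s * t)
  } else {
    NF <- NF0 * exp(-b * t)
    N <- rep(N0, length(t))
  }
  out <- cbind(CF = Ft - NF, NF = NF, CB = Tt - Ft - (N - NF), NB = N - NF)
  # floating-point cancellation can leave -1e-17-scale negatives
  out[out < 0 & out > -1e-12] <- 0
  out
}

#' Simulate the import-export model over an activation protocol
#'
#' Integrates the four-species fluorescent/bleached import-export ODE system
#' piecewise over the protocol's light and dark segments, switching parameter
#' sets at phase boundaries with exact state carry-over. Each
#' constant-parameter segment is solved in closed form (the system is linear),
#' so there is no integration error beyond floating point.
#'
#' The equations per segment are
#' \deqn{dCF/dt = ke NF - ki CF - b CF, \quad dNF/dt = ki CF - ke NF - b NF,}
#' \deqn{dCB/dt = ke NB - ki CB + b CF, \quad dNB/dt = ki CB - ke NB + b NF.}
#'
#' @param protocol An [activation_protocol].
#' @param params_light,params_dark [ie_params] for light and dark phases.
#' @param initial [ie_state] at t = 0.
#' @param t_grid Numeric vector of output times (minutes) within the protocol
#'   span; default a 0.1-min grid over the whole protocol.
#' @return A data.frame with columns `time`, `CF`, `NF`, `CB`, `NB`.
#' @export
simulate_import_export <- function(protocol, params_light, params_dark = NULL,
                                   initial = ie_state(), t_grid = NULL) {
  stopifnot(inherits(protocol, "activation_protocol"))
  if (is.null(params_dark)) params_dark <- ie_params(0, 0, 0)
  t_max <- protocol$t_end[nrow(protocol)]
  if (is.null(t_grid)) t_grid <- seq(0, t_max, by = 0.1)
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing")
  if (min(t_grid) < 0 || max(t_grid) > t_max + 1e-9)
    stop("'t_grid' must lie within the protocol span")

  y <- unclass(initial)
  out <- matrix(NA_real_, length(t_grid), 4,
                dimnames = list(NULL, c("CF", "NF", "CB", "NB")))
  for (i in seq_len(nrow(protocol))) {
    p <- if (protocol$phase[i] == "light") params_light else params_dark
    t0 <- protocol$t_start[i]; t1 <- protocol$t_end[i]
    sel <- which(t_grid >= t0 - 1e-12 & t_grid <= t1 + 1e-12 & is.na(out[, 1]))
    if (length(sel))
      out[sel, ] <- ie_segment(y, p, t_grid[sel] - t0)
    y <- drop(ie_segment(y, p, t1 - t0))
  }
  data.frame(time = t_grid, out)
}

#' Predicted nuclear/total fluorescence ratio of a trajectory
#'
#' The fluorescence-visible prediction NF / (NF + CF), the quantity compared
#' against measured nuclear/total intensity ratios. Bleaching affects both
#' fluorescent pools equally, so this ratio is independent of `b`.
#'
#' @param trajectory Output of [simulate_import_export()].
#' @return A time series data.frame (`time`, `value`); points with zero
#'   fluorescent total are `NA`.
#' @export
observed_ratio <- function(trajectory) {
  tot <- trajectory$NF + trajectory$CF
  time_series(trajectory$time, ifelse(tot > 0, trajectory$NF / tot, NA_real_))
}

#' Build the nuclear-input profile driving the adaptation motifs
#'
#' Simulates the import-export model over a protocol and returns the total
#' nuclear concentration N(t) = NF(t) + NB(t). Bleached protein still
#' signals, so the input to the transcriptional machinery includes both the
#' fluorescent and the bleached nuclear pools.
#'
#' @inheritParams simulate_import_export
#' @return A time series data.frame (`time`, `value`).
#' @export
build_input_profile <- function(protocol, params_light, params_dark = NULL,
                                initial = ie_state(), t_grid = NULL) {
  tr <- simulate_import_export(protocol, params_light, params_dark, initial,
                               t_grid)
  time_series(tr$time, tr$NF + tr$NB)
}

#' Fit the import-export model to nuclear/total ratio data
#'
#' Light mode fits the import and export rate constants together with the
#' free initial fluorescent concentrations (NF0, CF0; the bleached pools
#' start at zero) to the nuclear/total ratio measured during continuous
#' activation, by minimising the mean squared error between the model's
#' predicted ratio and the data. The bleaching rate cancels in the ratio and
#' is therefore fixed (default 0) unless a total-fluorescence series is
#' supplied via `total`, in which case the normalised decay of NF + CF is
#' added to the loss and `b` becomes a free parameter.
#'
#' Dark mode fits the dark-phase import and export constants to ratio
#' endpoints measured after the light phase, starting from the supplied
#' end-of-light state with `b = 0`; times in `data` are minutes since dark
#' onset.
#'
#' @param data data.frame with columns `time` (min) and `value` (ratio).
#' @param mode `"light"` or `"dark"`.
#' @param initial For `mode = "dark"`: the end-of-light [ie_state].
#' @param total Optional data.frame (`time`, `value`) of total mean
#'   fluorescence used to make `b` identifiable in light mode.
#' @param rate_bounds Bounds for `ki`, `ke` (and `b`), 1/min.
#' @param conc_bounds Bounds for the free initial concentrations.
#' @param n_starts Number of seeded optimisation starts.
#' @param seed Integer seed controlling the random restarts.
#' @return Object of class `ie_fit` with elements `params` ([ie_params]),
#'   `initial` ([ie_state]), `loss`, `mode`, `bound_hits`, `data`, `seed`.
#' @export
fit_import_export <- function(data, mode = c("light", "dark"), initial = NULL,
                              total = NULL, rate_bounds = c(1e-6, 10),
                              conc_bounds = c(0, 2), n_starts = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(data), all(c("time", "value") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  if (mode == "light" && nrow(data) < 5)
    stop("light-phase fitting needs at least 5 ratio points")
  if (mode == "dark" && is.null(initial))
    stop("dark-phase fitting needs the end-of-light state as 'initial'")
  fit_b <- mode == "light" && !is.null(total)
  lb10 <- log10(rate_bounds[1]); ub10 <- log10(rate_bounds[2])

  unpack <- function(x) {
    if (mode == "light") {
      p <- ie_params(10^x[1], 10^x[2], if (fit_b) 10^x[3] else 0)
      ic <- ie_state(CF = x[length(x) - 1], NF = x[length(x)])
    } else {
      p <- ie_params(10^x[1], 10^x[2], 0)
      ic <- initial
    }
    list(p = p, ic = ic)
  }
  objective <- function(x) {
    u <- unpack(x)
    proto <- protocol_continuous(max(data$time, 1e-6))
    tr <- simulate_import_export(proto, u$p, u$p, u$ic,
                                 t_grid = sort(unique(c(0, data$time))))
    pred <- observed_ratio(tr)
    m <- merge(data, pred, by = "time", suffixes = c("", ".pred"))
    loss <- mean((m$value - m$value.pred)^2)
    if (fit_b) {
      trt <- merge(total, data.frame(time = tr$time, f = tr$NF + tr$CF),
                   by = "time")
      if (nrow(trt) > 0)
        loss <- loss + mean((trt$value / trt$value[1] -
                               trt$f / trt$f[1])^2)
    }
    if (!is.finite(loss)) 1e6 else loss
  }

  n_rates <- 2L + as.integer(fit_b)
  lower <- c(rep(lb10, n_rates), if (mode == "light") rep(conc_bounds[1], 2))
  upper <- c(rep(ub10, n_rates), if (mode == "light") rep(conc_bounds[2], 2))
  starts <- with_seed(seed, {
    s0 <- c(rep(log10(0.1), n_rates),
            if (mode == "light") c(1, max(min(data$value[1], 1), 0.01)))
    more <- lapply(seq_len(max(n_starts - 1, 0)), function(i)
      runif(length(lower), lower, upper))
    c(list(s0), more)
  })
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      optim(s, objective, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("import-export fit failed to converge from any start")
  u <- unpack(best$par)
  at_bound <- abs(best$par - lower) < 1e-6 | abs(upper - best$par) < 1e-6
  par_names <- c("ki", "ke", if (fit_b) "b",
                 if (mode == "light") c("CF0", "NF0"))
  structure(list(params = u$p, initial = u$ic, loss = best$value, mode = mode,
                 bound_hits = par_names[at_bound], data = data, seed = seed,
                 convergence = best$convergence),
            class = "ie_fit")
}

#' @export
print.ie_fit <- function(x, ...) {
  cat("Import-export model fit (", x$mode, " phase)\n", sep = "")
  cat(sprintf("  ki = %.4g  ke = %.4g  b = %.4g (1/min)\n",
              x$params[["ki"]], x$params[["ke"]], x$params[["b"]]))
  if (x$mode == "light")
    cat(sprintf("  initial: NF0 = %.4g, CF0 = %.4g (NB0 = CB0 = 0)\n",
                x$initial[["NF"]], x$initial[["CF"]]))
  cat(sprintf("  MSE loss: %.3g on %d ratio points\n", x$loss, nrow(x$data)))
  if (length(x$bound_hits))
    cat("  at bounds:", paste(x$bound_hits, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ie_fit <- function(object, ...) unclass(object$params)

#' @rdname fit_import_export
#' @param object An `ie_fit`.
#' @param times Prediction times (minutes; for dark fits, since dark onset).
#' @param ... Unused.
#' @export
predict.ie_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time
  proto <- protocol_continuous(max(times, 1e-6))
  tr <- simulate_import_export(proto, object$params, object$params,
                               object$initial, t_grid = sort(unique(c(0, times))))
  r <- observed_ratio(tr)
  r[r$time %in% times, , drop = FALSE]
}
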