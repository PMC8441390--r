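MOTIF_KINDS <- c("negative_feedback", "incoherent_feedforward",
                 "state_dependent_inactivation")
MOTIF_FAMILIES <- c("elementary", "hill")

# State variable names and the output-controlling variable per motif.
motif_state_names <- function(kind) {
  if (kind == "state_dependent_inactivation") c("Aon", "Ain") else c("A", "B")
}

# Which rate constants / Hill exponents a motif actually uses.
motif_free_names <- function(kind, family) {
  ks <- if (kind == "state_dependent_inactivation") paste0("k", 1:4)
        else paste0("k", 1:5)
  hs <- if (family == "hill") {
    if (kind == "state_dependent_inactivation") paste0("h", 1:3)
    else paste0("h", 1:6)
  } else character(0)
  c(ks, hs)
}

#' Adaptation-motif parameters
#'
#' Rate constants (and, for the Hill family, interaction exponents) of one of
#' the three candidate adaptation motifs. In the elementary family all
#' interactions follow mass-action kinetics; the Hill family raises every
#' non-decay interaction term to a fitted exponent. The state-dependent
#' inactivation motif has no separate inhibitor species and uses only
#' `k1`-`k4` (and `h1`-`h3`).
#'
#' @param kind One of `"negative_feedback"`, `"incoherent_feedforward"`,
#'   `"state_dependent_inactivation"`.
#' @param family `"elementary"` or `"hill"`.
#' @param k Named or positional numeric vector of rate constants `k1`-`k5`
#'   (1/min scale); unused entries may be omitted or `NA`.
#' @param h Hill exponents `h1`-`h6` (dimensionless); required for the hill
#'   family, ignored otherwise.
#' @return Object of class `motif_params`.
#' @export
motif_params <- function(kind, family = "elementary", k, h = NULL) {
  kind <- match.arg(kind, MOTIF_KINDS)
  family <- match.arg(family, MOTIF_FAMILIES)
  kk <- setNames(rep(NA_real_, 5), paste0("k", 1:5))
  if (is.null(names(k))) kk[seq_along(k)] <- k else kk[names(k)] <- k
  hh <- setNames(rep(NA_real_, 6), paste0("h", 1:6))
  if (family == "hill") {
    if (is.null(h)) stop("the hill family requires Hill exponents 'h'")
    if (is.null(names(h))) hh[seq_along(h)] <- h else hh[names(h)] <- h
  }
  used <- motif_free_names(kind, family)
  vals <- c(kk, hh)[used]
  if (any(!is.finite(vals)))
    stop("missing or non-finite value for: ",
         paste(used[!is.finite(vals)], collapse = ", "))
  if (any(kk[intersect(used, names(kk))] < 0))
    stop("rate constants must be non-negative")
  structure(list(kind = kind, family = family, k = kk, h = hh),
            class = "motif_params")
}

#' @export
print.motif_params <- function(x, ...) {
  cat("Adaptation motif:", x$kind, "(", x$family, "family )\n")
  used <- motif_free_names(x$kind, x$family)
  print(signif(c(x$k, x$h)[used], 4))
  invisible(x)
}

#' Published fitted motif parameters
#'
#' The rate constants (and Hill exponents) obtained by fitting each motif to
#' total nascent-transcription intensity under continuous optogenetic
#' activation. Note the inhibitor turnover rates are pinned at the lower
#' bound 1e-4: recovery of the adaptive system is slow relative to the
#' observation window.
#'
#' @inheritParams motif_params
#' @return A [motif_params] object.
#' @export
motif_reference_params <- function(kind, family = "elementary") {
  kind <- match.arg(kind, MOTIF_KINDS)
  family <- match.arg(family, MOTIF_FAMILIES)
  tab <- list(
    negative_feedback = list(
      elementary = list(k = c(0.1358, 99.9944, 0.0001, 0.0002, 0.0001)),
      hill = list(k = c(0.6531, 5.6291, 0.1231, 0.0548, 0.0005),
                  h = c(3.5779, 1.4870, 4.0000, 0.2500, 1.4944, 0.2500))),
    incoherent_feedforward = list(
      elementary = list(k = c(0.1515, 99.9999, 0.0001, 0.0001, 0.0001)),
      hill = list(k = c(0.8325, 0.7501, 0.0496, 0.0857, 0.0001),
                  h = c(3.9521, 2.3835, 4.0000, 0.6609, 4.0000, 0.3056))),
    state_dependent_inactivation = list(
      elementary = list(k = c(0.1806, 0.0494, 0.0001, 0.0001)),
      hill = list(k = c(0.4509, 0.0446, 0.0001, 0.0001),
                  h = c(3.4775, 0.9659, 0.7655)))
  )
  e <- tab[[kind]][[family]]
  motif_params(kind, family, k = e$k, h = e$h)
}

#' Motif right-hand side
#'
#' Time derivatives of the motif state at a given input level. For negative
#' feedback and incoherent feedforward the state is `(A, B)` where `A` is the
#' output-controlling activity and `B` the inhibitor; for state-dependent
#' inactivation it is `(Aon, Ain)`, the active and refractory fractions of
#' the controller itself. Elementary family, feedback:
#' \deqn{dA/dt = k1 In (1-A) - k2 B A - k3 A, \quad dB/dt = k4 A (1-B) - k5 B.}
#' Feedforward replaces the activator of B: \eqn{dB/dt = k4 In (1-B) - k5 B}.
#' State-dependent inactivation:
#' \deqn{dAon/dt = k1 In (1-Aon-Ain) - k2 Aon - k3 Aon, \quad
#'       dAin/dt = k2 Aon - k4 Ain.}
#' The Hill family raises each non-decay factor to its exponent; bases are
#' clamped at zero before fractional exponentiation.
#'
#' @param params A [motif_params].
#' @param state Named numeric state vector (`A`,`B` or `Aon`,`Ain`).
#' @param input Non-negative scalar nuclear input concentration.
#' @return Named numeric vector of derivatives.
#' @export
motif_rhs <- function(params, state, input) {
  stopifnot(inherits(params, "motif_params"))
  if (input < 0) input <- 0
  k <- params$k; h <- params$h
  pw <- function(base, e) pmax(base, 0)^e
  hill <- params$family == "hill"
  sn <- motif_state_names(params$kind)
  s <- if (!is.null(names(state))) state[sn] else setNames(state, sn)
  if (params$kind == "state_dependent_inactivation") {
    Aon <- s[["Aon"]]; Ain <- s[["Ain"]]
    if (hill) {
      act <- k[1] * pw(input, h[1]) * pw(1 - Aon - Ain, h[2])
      inact <- k[2] * pw(Aon, h[3])
    } else {
      act <- k[1] * input * (1 - Aon - Ain)
      inact <- k[2] * Aon
    }
    c(Aon = act - inact - k[3] * Aon, Ain = inact - k[4] * Ain)
  } else {
    A <- s[["A"]]; B <- s[["B"]]
    fb <- params$kind == "negative_feedback"
    if (hill) {
      dA <- k[1] * pw(input, h[1]) * pw(1 - A, h[2]) -
        k[2] * pw(B, h[3]) * pw(A, h[4]) - k[3] * A
      dB <- k[4] * pw(if (fb) A else input, h[5]) * pw(1 - B, h[6]) - k[5] * B
    } else {
      dA <- k[1] * input * (1 - A) - k[2] * B * A - k[3] * A
      dB <- k[4] * (if (fb) A else input) * (1 - B) - k[5] * B
    }
    c(A = dA, B = dB)
  }
}

# Pack parameters for the compiled right-hand side.
motif_parms_vec <- function(params) {
  k <- params$k; k[is.na(k)] <- 0
  h <- params$h; h[is.na(h)] <- 1
  c(match(params$kind, MOTIF_KINDS) - 1,
    match(params$family, MOTIF_FAMILIES) - 1, k, h)
}

#' Simulate an adaptation motif driven by a nuclear-input profile
#'
#' Integrates the motif ODEs with a time-varying input, interpolated linearly
#' between the profile's grid points, using the adaptive lsoda integrator
#' with compiled derivatives. The transcriptional output is the
#' output-controlling activity `A` (feedback/feedforward) or `Aon`
#' (state-dependent inactivation), taken as proportional to the rate of
#' target-gene mRNA production.
#'
#' @param params A [motif_params].
#' @param input Input profile: data.frame (`time`, `value`) covering `t_grid`.
#' @param t_grid Output time grid (minutes); default the input grid.
#' @param y0 Initial state; default all state variables 0 (pre-stimulus).
#' @param rtol,atol Integrator tolerances.
#' @return A data.frame with columns `time`, the two state variables and
#'   `output`; attribute `"params"` carries the parameters.
#' @export
simulate_motif <- function(params, input, t_grid = NULL, y0 = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "motif_params"),
            is.data.frame(input), all(c("time", "value") %in% names(input)))
  if (is.null(t_grid)) t_grid <- input$time
  if (min(t_grid) < min(input$time) - 1e-9 ||
      max(t_grid) > max(input$time) + 1e-9)
    stop("'input' must cover the requested time grid")
  sn <- motif_state_names(params$kind)
  if (is.null(y0)) y0 <- setNames(c(0, 0), sn) else y0 <- setNames(y0, sn)
  out <- deSolve::ode(
    y = y0, times = t_grid, func = "motif_derivs",
    parms = motif_parms_vec(params), dllname = "optomotif",
    initfunc = "motif_initpar", initforc = "motif_initforc",
    forcings = cbind(input$time, input$value),
    fcontrol = list(method = "linear", rule = 2),
    method = "lsoda", rtol = rtol, atol = atol)
  res <- data.frame(time = out[, 1], out[, sn, drop = FALSE],
                    output = out[, sn[1]])
  attr(res, "params") <- params
  res
}

#' In-silico molecular perturbations of a fitted motif
#'
#' Rate-constant substitutions representing molecular perturbations:
#' `inhibitor_ko` removes production of the inhibitor B (`k4 = 0`;
#' meaningless for state-dependent inactivation, where the controller itself
#' becomes refractory, hence an error there); `attenuator_ko` removes a
#' putative attenuator of activation (`k1` becomes `10 k1`);
#' `stabilize_active` stabilises the active state (`k2` becomes `0.1 k2`).
#' All other parameters, including Hill exponents, are untouched.
#'
#' @param params A [motif_params].
#' @param perturbation One of `"inhibitor_ko"`, `"attenuator_ko"`,
#'   `"stabilize_active"`.
#' @return The perturbed [motif_params].
#' @export
apply_perturbation <- function(params,
                               perturbation = c("inhibitor_ko",
                                                "attenuator_ko",
                                                "stabilize_active")) {
  stopifnot(inherits(params, "motif_params"))
  perturbation <- match.arg(perturbation)
  k <- params$k
  if (perturbation == "inhibitor_ko") {
    if (params$kind == "state_dependent_inactivation")
      stop("inhibitor knock-out is not applicable to state-dependent ",
           "inactivation: the active species itself transits into the ",
           "inhibited state")
    k["k4"] <- 0
  } else if (perturbation == "attenuator_ko") {
    k["k1"] <- 10 * k["k1"]
  } else {
    k["k2"] <- 0.1 * k["k2"]
  }
  out <- params
  out$k <- k
  out
}

#' Peak, final level and adaptation index of an output trace
#'
#' Quantifies how completely a response returns towards baseline despite
#' sustained input: `peak` is the trace maximum, `final` the mean over the
#' last 10% of points, and `adaptation_index = 1 - final/peak` (1 for perfect
#' adaptation, about 0 for a sustained plateau).
#'
#' @param x Output trace: a data.frame with `time` and `value`/`output`
#'   columns (e.g. from [simulate_motif()]), or a numeric vector.
#' @return List with `peak`, `final`, `adaptation_index` (the index is `NA`
#'   with a warning for an all-zero trace).
#' @export
adaptation_metrics <- function(x) {
  v <- if (is.data.frame(x)) {
    if ("output" %in% names(x)) x$output else x$value
  } else as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v)) stop("empty trace")
  peak <- max(v)
  final <- mean(v[seq.int(length(v) - ceiling(0.1 * length(v)) + 1, length(v))])
  idx <- if (peak > 0) 1 - final / peak else {
    warning("all-zero trace: adaptation index undefined")
    NA_real_
  }
  list(peak = peak, final = final, adaptation_index = idx)
}
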