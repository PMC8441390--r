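# Independent fixed-step RK4 oracles. The right-hand sides here are direct,
# self-contained transcriptions of the model equations -- separate from both
# the package's compiled derivatives and its closed-form solutions -- so that
# agreement validates the implementation rather than restating it.

# Plain-closure motif right-hand side, f(y, input) -> dy.
oracle_motif_rhs <- function(kind, family, k, h = rep(1, 6)) {
  k <- unname(k); k[is.na(k)] <- 0
  h <- unname(h); h[is.na(h)] <- 1
  pw <- function(b, e) pmax(b, 0)^e
  hill <- family == "hill"
  switch(kind,
    negative_feedback = function(y, u) {
      if (hill)
        c(k[1] * pw(u, h[1]) * pw(1 - y[1], h[2]) -
            k[2] * pw(y[2], h[3]) * pw(y[1], h[4]) - k[3] * y[1],
          k[4] * pw(y[1], h[5]) * pw(1 - y[2], h[6]) - k[5] * y[2])
      else
        c(k[1] * u * (1 - y[1]) - k[2] * y[2] * y[1] - k[3] * y[1],
          k[4] * y[1] * (1 - y[2]) - k[5] * y[2])
    },
    incoherent_feedforward = function(y, u) {
      if (hill)
        c(k[1] * pw(u, h[1]) * pw(1 - y[1], h[2]) -
            k[2] * pw(y[2], h[3]) * pw(y[1], h[4]) - k[3] * y[1],
          k[4] * pw(u, h[5]) * pw(1 - y[2], h[6]) - k[5] * y[2])
      else
        c(k[1] * u * (1 - y[1]) - k[2] * y[2] * y[1] - k[3] * y[1],
          k[4] * u * (1 - y[2]) - k[5] * y[2])
    },
    state_dependent_inactivation = function(y, u) {
      if (hill)
        c(k[1] * pw(u, h[1]) * pw(1 - y[1] - y[2], h[2]) -
            k[2] * pw(y[1], h[3]) - k[3] * y[1],
          k[2] * pw(y[1], h[3]) - k[4] * y[2])
      else
        c(k[1] * u * (1 - y[1] - y[2]) - k[2] * y[1] - k[3] * y[1],
          k[2] * y[1] - k[4] * y[2])
    })
}

# Fixed-step RK4 with a time-varying input (linear interpolation of the
# profile, evaluated once per half-step). Returns the state at each
# checkpoint time; checkpoints must be multiples of dt.
rk4_trace <- function(rhs, input, checkpoints, dt = 1e-3, y0 = c(0, 0)) {
  t_end <- max(checkpoints)
  n <- round(t_end / dt)
  tin <- seq(0, t_end, by = dt / 2)
  vin <- approx(input$time, input$value, xout = tin, rule = 2)$y
  chk_idx <- round(checkpoints / dt)
  out <- matrix(NA_real_, length(checkpoints), length(y0))
  y <- y0
  if (any(chk_idx == 0)) out[chk_idx == 0, ] <- rep(y, each = sum(chk_idx == 0))
  for (i in seq_len(n)) {
    j <- 2 * i - 1
    k1 <- rhs(y, vin[j])
    k2 <- rhs(y + dt / 2 * k1, vin[j + 1])
    k3 <- rhs(y + dt / 2 * k2, vin[j + 1])
    k4 <- rhs(y + dt * k3, vin[j + 2])
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- which(chk_idx == i)
    if (length(hit)) out[hit, ] <- rep(y, each = length(hit))
  }
  out
}

# RK4 for the four-species import-export system over a protocol (parameters
# switch at phase boundaries; boundaries and checkpoints must be multiples
# of dt). State order: CF, NF, CB, NB.
rk4_import_export <- function(protocol, params_light, params_dark, y0,
                              checkpoints, dt = 1e-3) {
  rhs <- function(y, p) {
    ki <- p[["ki"]]; ke <- p[["ke"]]; b <- p[["b"]]
    c(ke * y[2] - ki * y[1] - b * y[1],
      ki * y[1] - ke * y[2] - b * y[2],
      ke * y[4] - ki * y[3] + b * y[1],
      ki * y[3] - ke * y[4] + b * y[2])
  }
  t_end <- max(checkpoints)
  n <- round(t_end / dt)
  chk_idx <- round(checkpoints / dt)
  out <- matrix(NA_real_, length(checkpoints), 4)
  y <- as.numeric(y0)
  if (any(chk_idx == 0)) out[chk_idx == 0, ] <- rep(y, each = sum(chk_idx == 0))
  for (i in seq_len(n)) {
    tm <- (i - 0.5) * dt  # phase at the step midpoint
    seg <- which(protocol$t_start <= tm & tm <= protocol$t_end)[1]
    p <- if (protocol$phase[seg] == "light") params_light else params_dark
    k1 <- rhs(y, p)
    k2 <- rhs(y + dt / 2 * k1, p)
    k3 <- rhs(y + dt / 2 * k2, p)
    k4 <- rhs(y + dt * k3, p)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- which(chk_idx == i)
    if (length(hit)) out[hit, ] <- rep(y, each = length(hit))
  }
  colnames(out) <- c("CF", "NF", "CB", "NB")
  out
}

# Shared fixtures: the published parameters and the standard input profiles.
ref_ie <- optomotif::ie_reference_params()

continuous_input <- function(duration = 40, dt = 0.1) {
  build_input_profile(protocol_continuous(duration), ref_ie$light,
                      ref_ie$dark, ref_ie$initial_light,
                      t_grid = seq(0, duration, by = dt))
}

pulsatile_input <- function(duration = 40, dt = 0.1) {
  build_input_profile(protocol_pulsatile(duration), ref_ie$light,
                      ref_ie$dark, ref_ie$initial_light,
                      t_grid = seq(0, duration, by = dt))
}

constant_input <- function(value, duration = 200, dt = 1) {
  data.frame(time = seq(0, duration, by = dt), value = value)
}
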