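test_that("closed-form integration reproduces the published end-of-light state", {
  tr <- simulate_import_export(protocol_continuous(10), ref_ie$light,
                               ref_ie$dark, ref_ie$initial_light,
                               t_grid = c(0, 10))
  end <- unlist(tr[2, c("NF", "CF", "NB", "CB")])
  published <- c(NF = 0.2726, CF = 0.0623, NB = 0.4902, CB = 0.1122)
  expect_lt(max(abs(end / published - 1)), 0.005)
})

test_that("total mass is conserved and the fluorescent pool decays as exp(-b t)", {
  proto <- protocol_pulsatile(40)
  tr <- simulate_import_export(proto, ref_ie$light, ref_ie$dark,
                               ref_ie$initial_light,
                               t_grid = seq(0, 40, by = 0.1))
  tot <- tr$CF + tr$NF + tr$CB + tr$NB
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-9)
  expect_true(all(tr$CF >= 0 & tr$NF >= 0 & tr$CB >= 0 & tr$NB >= 0))

  trc <- simulate_import_export(protocol_continuous(40), ref_ie$light,
                                ref_ie$dark, ref_ie$initial_light,
                                t_grid = seq(0, 40, by = 0.5))
  f0 <- trc$CF[1] + trc$NF[1]
  expect_lt(max(abs((trc$CF + trc$NF) -
                      f0 * exp(-ref_ie$light[["b"]] * trc$time))), 1e-8)
})

test_that("symmetric rates with symmetric initial state keep NF equal to CF", {
  p <- ie_params(ki = 0.2, ke = 0.2, b = 0)
  tr <- simulate_import_export(protocol_continuous(20), p, p,
                               ie_state(CF = 0.5, NF = 0.5),
                               t_grid = seq(0, 20, by = 1))
  expect_equal(tr$NF, tr$CF, tolerance = 1e-12)
})

test_that("closed form matches an independent fixed-step RK4 integration", {
  proto <- protocol_pulsatile(30)
  chk <- seq(0, 30, by = 2.5)
  tr <- simulate_import_export(proto, ref_ie$light, ref_ie$dark,
                               ref_ie$initial_light, t_grid = chk)
  ork <- rk4_import_export(proto, ref_ie$light, ref_ie$dark,
                           ref_ie$initial_light, chk, dt = 5e-3)
  expect_lt(max(abs(as.matrix(tr[, c("CF", "NF", "CB", "NB")]) - ork)), 1e-6)
})

test_that("observed ratio is independent of bleaching and reaches ki/(ki+ke)", {
  base <- NULL
  for (b in c(0, 0.05, 0.1029, 0.3)) {
    p <- ie_params(ki = 0.2619, ke = 0.0455, b = b)
    tr <- simulate_import_export(protocol_continuous(40), p, p,
                                 ref_ie$initial_light,
                                 t_grid = seq(0, 40, by = 1))
    r <- observed_ratio(tr)$value
    if (is.null(base)) base <- r
    expect_equal(r, base, tolerance = 1e-12)
  }
  expect_equal(base[length(base)], 0.2619 / (0.2619 + 0.0455),
               tolerance = 1e-4)
})

test_that("input profile follows the protocol: zero in all-dark, rise/decay in pulses", {
  dark_only <- activation_protocol("dark", 20)
  inp0 <- build_input_profile(dark_only, ref_ie$light, ref_ie$dark,
                              ie_state(CF = 0, NF = 0))
  expect_true(all(inp0$value == 0))

  cont <- continuous_input(40)
  expect_true(all(diff(cont$value) > -1e-12))

  pul <- pulsatile_input(40)
  in_light <- pul$time > 0.1 & pul$time < 4.9
  in_dark <- pul$time > 5.1 & pul$time < 14.9
  expect_true(all(diff(pul$value[in_light]) > 0))
  expect_true(all(diff(pul$value[in_dark]) < 0))
})

test_that("light-phase fit recovers import and export rates from noiseless ratio data", {
  tr <- simulate_import_export(protocol_continuous(10), ref_ie$light,
                               ref_ie$dark, ref_ie$initial_light,
                               t_grid = seq(0, 10, by = 0.5))
  fit <- fit_import_export(observed_ratio(tr), "light", seed = 2)
  expect_lt(abs(coef(fit)[["ki"]] / 0.2619 - 1), 0.02)
  expect_lt(abs(coef(fit)[["ke"]] / 0.0455 - 1), 0.02)
  expect_lt(fit$loss, 1e-8)
})

test_that("constant ratio data identify only the ki/(ki+ke) quotient", {
  data <- data.frame(time = seq(0, 10, by = 1), value = 0.4)
  fit <- fit_import_export(data, "light", seed = 3)
  k <- coef(fit)
  expect_lt(fit$loss, 1e-6)
  expect_equal(unname(k["ki"] / (k["ki"] + k["ke"])), 0.4, tolerance = 0.02)
})

test_that("dark-phase fit recovers the export rate from three endpoints", {
  trd <- simulate_import_export(protocol_continuous(10), ref_ie$dark,
                                ref_ie$dark, ref_ie$initial_dark,
                                t_grid = c(0, 5, 10))
  rd <- observed_ratio(trd)
  fit <- fit_import_export(rd, "dark", initial = ref_ie$initial_dark, seed = 2)
  expect_lt(abs(coef(fit)[["ke"]] / 0.1419 - 1), 0.05)
  expect_identical(coef(fit)[["b"]], 0)
  pred <- predict(fit, times = c(5, 10))
  expect_equal(pred$value, rd$value[2:3], tolerance = 1e-3)

  # endpoints equal to the last light point imply no decay at all
  flat <- data.frame(time = c(0, 5, 10), value = rd$value[1])
  fit0 <- fit_import_export(flat, "dark", initial = ref_ie$initial_dark,
                            seed = 2)
  tr0 <- simulate_import_export(protocol_continuous(10), fit0$params,
                                fit0$params, ref_ie$initial_dark,
                                t_grid = c(0, 10))
  r0 <- observed_ratio(tr0)$value
  expect_lt(abs(r0[2] - r0[1]), 0.005)
})

test_that("invalid protocols and parameters are rejected", {
  expect_error(activation_protocol(c("light", "dark"), c(5, -1)), "positive")
  expect_error(ie_params(-0.1, 0.1), "non-negative")
  expect_error(simulate_import_export(protocol_continuous(10), ref_ie$light,
                                      ref_ie$dark, ref_ie$initial_light,
                                      t_grid = c(0, 11)), "span")
})
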