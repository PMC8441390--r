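all_kinds <- c("negative_feedback", "incoherent_feedforward",
               "state_dependent_inactivation")

test_that("the origin with zero input is absorbing for every motif and family", {
  for (kind in all_kinds) {
    for (family in c("elementary", "hill")) {
      p <- motif_reference_params(kind, family)
      expect_equal(unname(motif_rhs(p, c(0, 0), 0)), c(0, 0),
                   info = paste(kind, family))
    }
  }
})

test_that("state-dependent inactivation loses total mass at the full boundary", {
  p <- motif_reference_params("state_dependent_inactivation", "elementary")
  for (aon in c(0, 0.3, 1)) {
    d <- motif_rhs(p, c(Aon = aon, Ain = 1 - aon), input = 0.7)
    expect_lte(sum(d), 0)
    expect_equal(unname(sum(d)),
                 -p$k[["k3"]] * aon - p$k[["k4"]] * (1 - aon),
                 tolerance = 1e-12)
  }
})

test_that("R and compiled right-hand sides agree with a direct transcription of the equations", {
  set.seed(42)
  for (kind in all_kinds) {
    for (family in c("elementary", "hill")) {
      p <- motif_reference_params(kind, family)
      oracle <- oracle_motif_rhs(kind, family, p$k, p$h)
      for (i in 1:10) {
        y <- runif(2, 0, 0.5)
        u <- runif(1, 0, 1)
        expect_equal(unname(motif_rhs(p, y, u)), oracle(y, u),
                     tolerance = 1e-12, info = paste(kind, family))
      }
    }
  }
})

test_that("zero input from a zero state produces zero output", {
  inp <- constant_input(0, duration = 20, dt = 0.5)
  for (kind in all_kinds) {
    sim <- simulate_motif(motif_reference_params(kind), inp)
    expect_true(all(sim$output == 0), info = kind)
  }
})

test_that("adaptive integration matches the fixed-step RK4 oracle", {
  inp <- continuous_input(40)
  chk <- seq(0, 40, by = 4)
  for (kind in all_kinds) {
    for (family in c("elementary", "hill")) {
      p <- motif_reference_params(kind, family)
      sim <- simulate_motif(p, inp, t_grid = chk)
      ork <- rk4_trace(oracle_motif_rhs(kind, family, p$k, p$h),
                       inp, chk, dt = 5e-3)
      expect_lt(max(abs(as.matrix(sim[, 2:3]) - ork)), 1e-5,
                label = paste(kind, family, "deviation from RK4"))
    }
  }
})

test_that("state-dependent inactivation with blocked recovery adapts perfectly", {
  p <- motif_params("state_dependent_inactivation", "elementary",
                    k = c(k1 = 0.1806, k2 = 0.0494, k3 = 1e-4, k4 = 0))
  sim <- simulate_motif(p, constant_input(1, duration = 200))
  m <- adaptation_metrics(sim)
  expect_gt(m$peak, 0.1)
  expect_lt(sim$Aon[nrow(sim)], 1e-3)
  expect_gt(sim$Ain[nrow(sim)], 0.99)
  expect_gt(m$adaptation_index, 0.99)
})

test_that("feedback without inhibitor production converges to the closed-form plateau", {
  u <- 0.6
  p <- motif_params("negative_feedback", "elementary",
                    k = c(k1 = 0.5, k2 = 2, k3 = 0.1, k4 = 0, k5 = 0.01))
  sim <- simulate_motif(p, constant_input(u, duration = 150))
  expect_true(all(diff(sim$output) > -1e-9))
  expect_equal(sim$output[nrow(sim)], 0.5 * u / (0.5 * u + 0.1),
               tolerance = 1e-4)
  expect_true(all(sim$B == 0))
})

test_that("states stay in the unit box for random in-bound parameters", {
  set.seed(7)
  inp <- continuous_input(40, dt = 0.5)
  for (i in 1:6) {
    kind <- sample(all_kinds, 1)
    family <- sample(c("elementary", "hill"), 1)
    nk <- if (kind == "state_dependent_inactivation") 4 else 5
    k <- 10^runif(nk, -4, 1)
    h <- if (family == "hill") runif(6, 0.25, 4)
    p <- motif_params(kind, family, k = k, h = h)
    sim <- simulate_motif(p, inp)
    expect_true(all(sim[, 2] >= -1e-8 & sim[, 2] <= 1 + 1e-8),
                info = paste(kind, family, i))
    expect_true(all(sim[, 3] >= -1e-8 & sim[, 3] <= 1 + 1e-8))
    if (kind == "state_dependent_inactivation")
      expect_true(all(sim$Aon + sim$Ain <= 1 + 1e-6))
  }
})

test_that("perturbations change exactly the targeted rate constant", {
  p <- motif_reference_params("negative_feedback", "hill")
  ko <- apply_perturbation(p, "inhibitor_ko")
  expect_identical(ko$k[["k4"]], 0)
  expect_identical(ko$k[-4], p$k[-4])
  expect_identical(ko$h, p$h)

  att <- apply_perturbation(apply_perturbation(p, "attenuator_ko"),
                            "attenuator_ko")
  expect_equal(att$k[["k1"]], 100 * p$k[["k1"]])

  stab <- apply_perturbation(p, "stabilize_active")
  expect_equal(stab$k[["k2"]], 0.1 * p$k[["k2"]])
  expect_identical(stab$h, p$h)

  sdi <- motif_reference_params("state_dependent_inactivation")
  expect_error(apply_perturbation(sdi, "inhibitor_ko"), "not applicable")
})

test_that("adaptation metrics behave on canonical traces", {
  rise <- data.frame(time = 0:100, value = 1 - exp(-(0:100) / 5))
  m <- adaptation_metrics(rise)
  expect_lt(abs(m$adaptation_index), 0.01)

  pulse <- data.frame(time = 0:100, value = c(0:10, 10:0, rep(0, 79)))
  expect_equal(adaptation_metrics(pulse)$adaptation_index, 1)

  expect_warning(m0 <- adaptation_metrics(rep(0, 50)), "undefined")
  expect_true(is.na(m0$adaptation_index))
})
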