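disk_image <- function(shape = c(80, 80), centres, radius = 8,
                       fg = 100, bg = 10) {
  img <- matrix(bg, shape[1], shape[2])
  rr <- row(img) - 1; cc <- col(img) - 1
  mask <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(centres)))
    mask <- mask | ((cc - centres[i, 1])^2 + (rr - centres[i, 2])^2 <= radius^2)
  img[mask] <- fg
  list(img = img, mask = mask)
}

test_that("Otsu segmentation recovers two-level disks up to a small smoothing halo", {
  d <- disk_image(centres = rbind(c(20, 20), c(55, 30), c(30, 58)))
  m <- segment_nuclei(d$img)
  # the segmented mask and the true disks differ only in a thin boundary band
  dist_true <- as.array(EBImage::distmap(1 - d$mask * 1))
  dist_mask <- as.array(EBImage::distmap(1 - m * 1))
  expect_true(all(dist_true[m] <= 2))       # mask pixels near true disks
  expect_true(all(dist_mask[d$mask] <= 2))  # true pixels near the mask
  # inverted image: the caller selects the bright class, which is now the
  # complement structure
  m_inv <- segment_nuclei(max(d$img) + min(d$img) - d$img)
  expect_gt(sum(m_inv & !d$mask) / sum(!d$mask), 0.9)
  expect_error(segment_nuclei(matrix(5, 20, 20)), "constant")
})

test_that("the cytoplasmic annulus is the exact Euclidean dilation ring", {
  m <- matrix(FALSE, 41, 41); m[21, 21] <- TRUE
  ann <- cytoplasm_mask(m, 10)
  rr <- row(m) - 21; cc <- col(m) - 21
  expect_identical(unname(ann), rr^2 + cc^2 <= 100 & !(rr == 0 & cc == 0))

  set.seed(8)
  m2 <- matrix(FALSE, 35, 30)
  m2[cbind(sample(35, 6), sample(30, 6))] <- TRUE
  ann2 <- cytoplasm_mask(m2, 5)
  pts <- which(m2, arr.ind = TRUE)
  dmin <- matrix(Inf, 35, 30)
  for (i in seq_len(nrow(pts)))
    dmin <- pmin(dmin, sqrt((row(m2) - pts[i, 1])^2 + (col(m2) - pts[i, 2])^2))
  expect_identical(unname(ann2), dmin > 0 & dmin <= 5)
  expect_false(any(ann2 & m2))
})

test_that("measurement is exact on constants and invariant to per-track offsets", {
  d <- disk_image(centres = rbind(c(20, 20), c(55, 40)))
  frames <- list(matrix(3, 80, 80), matrix(3, 80, 80))
  m <- measure_and_correct(frames, d$mask)
  expect_equal(m$nuclear_mean, c(0, 0))
  expect_equal(m$cytoplasm_mean, c(0, 0))
  expect_equal(unique(m$background), 3)

  set.seed(10)
  f1 <- lapply(1:3, function(i) matrix(runif(80 * 80, 10, 50), 80, 80))
  f2 <- lapply(f1, function(x) x + 17)  # constant offset on every frame
  m1 <- measure_and_correct(f1, d$mask)
  m2 <- measure_and_correct(f2, d$mask)
  expect_equal(m1$nuclear_mean, m2$nuclear_mean, tolerance = 1e-12)
  expect_equal(m1$cytoplasm_mean, m2$cytoplasm_mean, tolerance = 1e-12)
})

test_that("per-track measurement separates nuclei and applies per-track background", {
  d <- disk_image(centres = rbind(c(20, 20), c(55, 40)))
  lab <- matrix(0L, 80, 80)
  rr <- row(lab) - 1; cc <- col(lab) - 1
  lab[(cc - 20)^2 + (rr - 20)^2 <= 64] <- 1L
  lab[(cc - 55)^2 + (rr - 40)^2 <= 64] <- 2L
  img <- matrix(5, 80, 80)
  img[lab == 1L] <- 30; img[lab == 2L] <- 80
  m <- measure_and_correct(list(img), lab > 0, track_labels = list(lab),
                           subtract_background = FALSE)
  expect_equal(m$nuclear_mean[m$track_id == 1], 30)
  expect_equal(m$nuclear_mean[m$track_id == 2], 80)
  expect_equal(m$cytoplasm_mean, c(5, 5))
})

test_that("bleach fitting is exact on noiseless exponentials and robust at 2% noise", {
  t <- seq(0, 25, by = 0.5)
  f <- fit_bleaching(t, 5 * exp(-0.1 * t))
  expect_equal(f$I0, 5, tolerance = 1e-6)
  expect_equal(f$b, 0.1, tolerance = 1e-6)

  fc <- fit_bleaching(t, rep(4, length(t)))
  expect_lt(abs(fc$b), 1e-12)

  set.seed(12)
  td <- seq(0, 30, by = 0.25)
  for (b in c(0.02, 0.1, 0.3)) {
    v <- 8 * exp(-b * td)
    v <- v * (1 + rnorm(length(v), sd = 0.02))
    fb <- fit_bleaching(td, v, window = c(0, 30))
    expect_lt(abs(fb$b / b - 1), 0.05)
  }
  expect_error(fit_bleaching(t, -5 * exp(-0.1 * t)), "non-positive")
  expect_error(fit_bleaching(c(10, 11), c(1, 1)), "at least 3")
})

test_that("bleach correction inverts the fitted decay and cancels in the ratio", {
  t <- seq(0, 20, by = 1)
  fit <- list(I0 = 5, b = 0.12)
  expect_equal(bleach_correct(t, 5 * exp(-0.12 * t), fit)$value,
               rep(5, length(t)), tolerance = 1e-12)
  expect_equal(bleach_correct(t, 3 * t + 1, list(I0 = 1, b = 0))$value,
               3 * t + 1)
  nuc <- exp(-0.12 * t) * (2 + sin(t)); cyt <- exp(-0.12 * t) * (3 - sin(t))
  r_raw <- nuclear_total_ratio(nuc, cyt)
  r_cor <- nuclear_total_ratio(bleach_correct(t, nuc, fit)$value,
                               bleach_correct(t, cyt, fit)$value)
  expect_equal(r_cor, r_raw, tolerance = 1e-12)
})

test_that("the nuclear/total ratio handles degenerate compartments", {
  expect_equal(nuclear_total_ratio(c(1, 2), c(0, 0)), c(1, 1))
  expect_equal(nuclear_total_ratio(c(2, 3), c(2, 3)), c(0.5, 0.5))
  expect_true(is.na(nuclear_total_ratio(0, 0)))
  # scale invariance per frame
  n <- runif(5); c <- runif(5); f <- runif(5, 0.5, 2)
  expect_equal(nuclear_total_ratio(n * f, c * f), nuclear_total_ratio(n, c))
})

test_that("the end-to-end nuclear pipeline recovers the ground-truth ratio", {
  tl <- render_nuclear_timelapse(protocol_continuous(15), ref_ie$light,
                                 ref_ie$dark, n_nuclei = 9, noise_sd = 2,
                                 seed = 3)
  q <- quantify_nuclei(tl$counter, tl$reporter, tl$times)
  truth <- tl$truth$ratio$value
  rel <- abs(q$ratio[-1] - truth[-1]) / truth[-1]
  expect_lt(max(rel), 0.02)
})
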