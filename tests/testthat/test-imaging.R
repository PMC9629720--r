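test_that("bandpass filter is zero on constants and linear", {
  img <- matrix(7, 40, 40)
  expect_equal(max(abs(bandpass_filter(img, 1, 20))), 0, tolerance = 1e-12)
  set.seed(61)
  img <- matrix(runif(1600), 40, 40)
  f1 <- bandpass_filter(img, 1, 20)
  f3 <- bandpass_filter(3 * img, 1, 20)
  expect_equal(f3, 3 * f1, tolerance = 1e-12)
  expect_error(bandpass_filter(img, 20, 1), "configuration error")
})

test_that("maxima detection: constants, single peaks, offsets", {
  expect_equal(nrow(find_maxima(matrix(5, 30, 30), prominence = 20)), 0)
  truth <- list(dim = c(41, 41),
                emitters = data.frame(x = 21, y = 21, intensity = 100 * 2 * pi *
                                        1.5^2))
  img <- render_cells(truth, psf_sigma = 1.5)  # amplitude 100 peak
  pk <- find_maxima(img$raster, prominence = 20)
  expect_equal(nrow(pk), 1)
  expect_lte(max(abs(c(pk$x, pk$y) - 21)), 1)
  # additive offsets leave maxima and prominences unchanged
  pk2 <- find_maxima(img$raster + 50, prominence = 20)
  expect_equal(pk2[, c("x", "y", "prominence")], pk[, c("x", "y", "prominence")])
  # mask removal
  mask <- matrix(FALSE, 41, 41)
  expect_equal(nrow(find_maxima(img$raster, 20, mask = mask)), 0)
})

test_that("prominence maxima match the flood-fill oracle on smooth images", {
  set.seed(62)
  for (rep in 1:2) {
    img <- gaussian_blur(matrix(runif(64 * 64, 0, 255), 64, 64), 3)
    img <- img + outer(seq_len(64), seq_len(64)) * 1e-7  # break ties
    thr <- 2
    got <- find_maxima(img, prominence = thr)
    want <- oracle_prominence(img)
    want <- want[want$prominence >= thr, ]
    key <- function(df) sort(sprintf("%d,%d,%.9f", df$x, df$y, df$prominence))
    expect_equal(key(got), key(want))
  }
})

test_that("bandpass + maxima recovers a pore lattice under a curvature dome", {
  truth <- synth_pore_lattice(dim = c(200, 200))
  img <- render_cells(truth, psf_sigma = 1.5, background = truth$background)
  bp <- bandpass_filter(img$raster, 1, 20)
  pk <- find_maxima(bp, prominence = 20)
  D <- sqrt(outer(truth$emitters$x, pk$x, "-")^2 +
              outer(truth$emitters$y, pk$y, "-")^2)
  recall <- mean(apply(D, 1, min) <= 3)
  precision <- mean(apply(D, 2, min) <= 3)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # the detected pattern recovers the lattice spacing within one bin
  d <- neighbor_distance_distribution(cbind(pk$x, pk$y), k = 1,
                                      bins = seq(0, 30, by = 1))
  mode_bin <- which.max(d$counts)
  expect_lte(abs(d$bin_edges[mode_bin] + 0.5 - 8.5), 1)
})

test_that("cell normalisation gives unit mean and scale invariance", {
  outline <- list(x = 50, y = 50, length = 60, width = 24, angle = 0.4)
  uniform <- normalize_cell(matrix(5, 100, 100), outline)
  expect_equal(range(uniform$raster, na.rm = TRUE), c(1, 1), tolerance = 1e-9)
  set.seed(63)
  img <- gaussian_blur(matrix(runif(10000, 10, 200), 100, 100), 2)
  n1 <- normalize_cell(img, outline)
  n2 <- normalize_cell(7 * img, outline)
  expect_equal(n1$raster, n2$raster, tolerance = 1e-9)
  expect_error(normalize_cell(img, list(x = 50, y = 50, length = 5,
                                        width = 5)), "geometry error")
})

test_that("two cells with the same relative emitter layout normalise to the
           same pattern", {
  mk <- function(cx, cy, L, W) {
    truth <- list(dim = c(160, 160), emitters = data.frame(
      x = cx + c(-0.25, 0.1, 0.3) * L, y = cy + c(0.1, -0.2, 0.25) * W,
      intensity = 500))
    render_cells(truth, psf_sigma = 1.5)$raster
  }
  n1 <- normalize_cell(mk(50, 50, 40, 16),
                       list(x = 50, y = 50, length = 40, width = 16, angle = 0))
  n2 <- normalize_cell(mk(100, 100, 80, 32),
                       list(x = 100, y = 100, length = 80, width = 32,
                            angle = 0))
  p1 <- find_maxima(ifelse(is.na(n1$raster), 0, n1$raster) * 100, 5)
  p2 <- find_maxima(ifelse(is.na(n2$raster), 0, n2$raster) * 100, 5)
  expect_equal(nrow(p1), nrow(p2))
  o1 <- p1[order(p1$x), c("x", "y")]
  o2 <- p2[order(p2$x), c("x", "y")]
  expect_lte(max(abs(as.matrix(o1) - as.matrix(o2))), 1)
})

test_that("ROI sums scale with island copy number", {
  truth <- synth_cell_field(n_cells = 1, islands_per_cell = 2,
                            copies = c(20, 30), dim = c(96, 96), seed = 64)
  # force known copy numbers on the two islands
  isl <- truth$islands
  img <- render_cells(truth, psf_sigma = 1.5)
  s <- vapply(seq_len(nrow(isl)), function(i)
    roi_sum(img, isl$x[i], isl$y[i], 8), numeric(1))
  expect_equal(s[1] / s[2], isl$n_emitters[1] / isl$n_emitters[2],
               tolerance = 0.1)
  # emitters outside the frame are a generation error
  bad <- truth
  bad$emitters$x[1] <- -5
  expect_error(render_cells(bad), "generation error")
})

test_that("copy-number formula and its guards", {
  est <- estimate_copies(2000, 200, 90)
  expect_equal(est$copies, 20)
  expect_equal(estimate_copies(200, 200, 90)$copies, 0)
  expect_error(estimate_copies(2000, 200, 0), "domain error")
})

test_that("blink calibration recovers exact two-level tails", {
  tail_sq <- rep(c(100, 10), 100)
  cal <- blink_calibration(c(rep(500, 600), tail_sq), tail_fraction = 0.25)
  expect_equal(cal$F_i, 90)
  expect_equal(cal$B_i, 10)
  expect_error(blink_calibration(rep(7, 1000)), "calibration error")
  expect_error(blink_calibration(c(1, 2, 3)), "domain error")
})

test_that("blink calibration recovers noisy levels within two sigma", {
  tr <- simulate_bleach_trace(25, noise_frac = 0.05, seed = 65)
  cal <- blink_calibration(tr)
  # noise sd near the off level is ~5% of B; on-level adds ~5% of (B + F)
  sd_f <- 0.05 * sqrt(200^2 + 290^2)
  expect_lt(abs(cal$F_i - 90), 2 * sd_f)
  expect_lt(abs(cal$B_i - 200), 2 * 0.05 * 200)
})

test_that("copy numbers recovered within +-2 for >= 90% of islands", {
  set.seed(66)
  ns <- sample(20:30, 40, replace = TRUE)
  hits <- vapply(seq_along(ns), function(i) {
    tr <- simulate_bleach_trace(ns[i], noise_frac = 0.05, seed = 660 + i)
    est <- copies_from_trace(tr)$copies_rounded
    abs(est - ns[i]) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # noiseless recovery is unbiased
  tr0 <- simulate_bleach_trace(24, seed = 67)
  expect_lt(abs(copies_from_trace(tr0)$copies - 24), 1)
})

test_that("TIFF round trip preserves the image", {
  truth <- synth_cell_field(n_cells = 1, dim = c(64, 64), seed = 68)
  img <- render_cells(truth, psf_sigma = 1.5, background = 10)
  f <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, f)
  back <- read_image_tiff(f)
  expect_equal(dim(back), dim(img$raster))
  expect_lt(max(abs(back - img$raster)) / max(img$raster), 1e-3)
})
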