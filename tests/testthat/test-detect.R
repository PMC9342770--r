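test_that("a blank channel yields zero foci and unknown channels error", {
  sim <- simulate_nucleus(small_config(seed = 4L, n_foci = 0L))
  fs <- detect_foci(sim$image)
  expect_identical(nrow(fs$foci), 0L)
  expect_error(detect_foci(sim$image, "nope"), "unknown channel")
  expect_error(detect_foci(sim$image, params = detect_params(psf_sigma_um = 0)),
               "non-positive")
})

test_that("a single noise-free Gaussian spot is found within half a pixel", {
  px <- 0.064
  img <- matrix(0, 256, 256)
  truth_xy <- c(7.3, 9.1)  # um
  sigma_px <- 0.13 / px
  ci <- truth_xy[2L] / px + 1; cj <- truth_xy[1L] / px + 1
  for (i in 1:256) for (j in max(1, floor(cj - 10)):min(256, ceiling(cj + 10))) {
    img[i, j] <- 200 * exp(-((i - ci)^2 + (j - cj)^2) / (2 * sigma_px^2))
  }
  st <- manual_stack(matrix(10, 256, 256), foci = img + 10, px = px)
  fs <- detect_foci(st)
  expect_identical(nrow(fs$foci), 1L)
  expect_lt(abs(fs$foci$x_um - truth_xy[1L]), 0.5 * px)
  expect_lt(abs(fs$foci$y_um - truth_xy[2L]), 0.5 * px)
})

test_that("detection recall and precision reach 0.95 on simulated nuclei", {
  sim <- simulate_nucleus(study_config(seed = 21L, n_foci = 180L))
  fs <- detect_foci(sim$image)
  matched <- oracle_match_count(as.matrix(fs$foci[, c("x_um", "y_um")]),
                                as.matrix(sim$truth$foci[, c("x_um", "y_um")]),
                                tol = 2 * 0.064)
  recall <- matched / nrow(sim$truth$foci)
  precision <- matched / nrow(fs$foci)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("raising the detection threshold never increases the count", {
  sim <- simulate_nucleus(small_config(seed = 6L))
  counts <- vapply(c(3, 4, 5, 6, 8), function(k)
    nrow(detect_foci(sim$image, params = detect_params(k = k))$foci),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the focus count is stable across noise realizations", {
  cfg <- small_config(seed = 31L)
  base <- simulate_nucleus(cfg)
  counts <- vapply(1:10, function(k) {
    re <- simulate_nucleus(small_config(seed = 31L + k), truth = base$truth)
    nrow(detect_foci(re$image)$foci)
  }, numeric(1))
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.05)
})

test_that("minimum separation is respected in the detected set", {
  sim <- simulate_nucleus(small_config(seed = 12L))
  fs <- detect_foci(sim$image, params = detect_params(min_separation_px = 5L))
  xy <- as.matrix(fs$foci[, c("x_um", "y_um")]) / 0.064
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  expect_gt(min(d), 5)
})
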