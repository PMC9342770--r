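test_that("identical configurations give bit-identical images and truth", {
  cfg <- small_config(seed = 42L)
  s1 <- simulate_nucleus(cfg)
  s2 <- simulate_nucleus(cfg)
  expect_identical(s1$image$channels, s2$image$channels)
  expect_identical(s1$truth$foci, s2$truth$foci)
  expect_identical(s1$truth$axis_polylines, s2$truth$axis_polylines)
})

test_that("degenerate configurations produce empty components, not errors", {
  cfg <- small_config(seed = 3L, n_axis_paths = 0L, n_foci = 0L)
  set.seed(3)
  expect_identical(generate_axis_paths(cfg), list())
  sim <- simulate_nucleus(cfg)
  expect_identical(sim$truth$total_axis_length_um, 0)
  expect_identical(nrow(sim$truth$foci), 0L)
  ## foci channel is pure background + noise: no values near spot amplitude
  expect_lt(max(sim$image$channels$foci),
            cfg$background_level + 10 * sqrt(cfg$background_level))
})

test_that("a nucleus that does not fit the image is rejected", {
  expect_error(sim_config(image_size_px = c(128L, 128L),
                          nucleus_radius_um = 7),
               "does not fit")
})

test_that("planted quantities respect the ground-truth invariants", {
  for (seed in c(2L, 9L)) {
    sim <- simulate_nucleus(small_config(seed = seed, p_on_axis = 0.5),
                            render = FALSE)
    tr <- sim$truth
    expect_identical(nrow(tr$foci), 60L)
    ## recorded total length agrees with an independent length computation
    expect_equal(tr$total_axis_length_um,
                 sum(vapply(tr$axis_polylines, oracle_polyline_length,
                            numeric(1))),
                 tolerance = 1e-9)
    d <- oracle_dist_to_paths(as.matrix(tr$foci[, c("x_um", "y_um")]),
                              tr$axis_polylines)
    expect_true(all(d[tr$foci$on_axis] <= 0.13 / 2))
    expect_true(all(d[!tr$foci$on_axis] > 2 * 0.13))
    ## all foci inside the nucleus mask
    ij <- cbind(round(tr$foci$y_um / 0.064) + 1L,
                round(tr$foci$x_um / 0.064) + 1L)
    expect_true(all(tr$nucleus_mask_reference[ij]))
  }
})

test_that("fragmentation retains approximately the requested length fraction", {
  for (seed in 1:3) {
    intact <- simulate_nucleus(small_config(seed = seed), render = FALSE)
    frag <- simulate_nucleus(small_config(seed = seed,
                                          axis_retained_fraction = 0.5),
                             render = FALSE)
    len_i <- sum(vapply(intact$truth$axis_polylines, oracle_polyline_length,
                        numeric(1)))
    len_f <- sum(vapply(frag$truth$axis_polylines, oracle_polyline_length,
                        numeric(1)))
    expect_gt(len_f / len_i, 0.4)
    expect_lt(len_f / len_i, 0.6)
  }
  ## retained fraction 1 is the identity
  a <- simulate_nucleus(small_config(seed = 5L), render = FALSE)
  b <- simulate_nucleus(small_config(seed = 5L, axis_retained_fraction = 1),
                        render = FALSE)
  expect_identical(a$truth$axis_polylines, b$truth$axis_polylines)
})

test_that("on-axis labels pool to the planted probability (binomial law)", {
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    sim <- simulate_nucleus(
      sim_config(image_size_px = c(512L, 512L), n_foci = 400L,
                 p_on_axis = 0.5, seed = seed),
      render = FALSE)
    hits <- hits + sum(sim$truth$foci$on_axis)
    total <- total + nrow(sim$truth$foci)
  }
  ci <- oracle_binom_interval(total, 0.5, level = 0.99)
  expect_gte(hits / total, ci[1L])
  expect_lte(hits / total, ci[2L])
})

test_that("total axis length scales linearly with the number of paths", {
  for (seed in 1:5) {
    for (n in c(2L, 4L)) {
      sim <- simulate_nucleus(small_config(seed = seed, n_axis_paths = n,
                                           n_foci = 0L), render = FALSE)
      expect_equal(sim$truth$total_axis_length_um, n * 25,
                   tolerance = 0.01)
    }
  }
})

test_that("channels share dimensions and hold integer counts", {
  sim <- simulate_nucleus(small_config(seed = 8L))
  st <- sim$image
  dims <- lapply(st$channels, dim)
  expect_length(unique(dims), 1L)
  for (ch in st$channels) {
    expect_true(all(ch >= 0))
    expect_identical(ch, round(ch))
  }
  expect_error(image_stack(list(bad = matrix(0, 2, 2)), 0.064),
               "unknown channel")
  expect_error(image_stack(list(axis = matrix(0, 2, 2),
                                foci = matrix(0, 3, 3)), 0.064),
               "identical dimensions")
})

test_that("re-rendering a fixed truth redraws only the noise", {
  cfg <- small_config(seed = 13L)
  base <- simulate_nucleus(cfg)
  cfg2 <- small_config(seed = 14L)
  re <- simulate_nucleus(cfg2, truth = base$truth)
  expect_identical(re$truth$foci, base$truth$foci)
  expect_false(identical(re$image$channels$foci, base$image$channels$foci))
  ## same seed, same truth: identical rendering
  re2 <- simulate_nucleus(cfg2, truth = base$truth)
  expect_identical(re$image$channels, re2$image$channels)
})
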