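test_that("planted on-axis foci overlap and distant foci do not (noise-free)", {
  cfg <- small_config(seed = 19L, p_on_axis = 1, shot_noise = FALSE,
                      gaussian_read_noise_sd = 0)
  sim <- simulate_nucleus(cfg)
  seg <- segment_axis(sim$image)
  for (crit in c("profile", "distance")) {
    calls <- score_foci(sim$truth$foci, sim$image, seg, coloc_params(crit))
    expect_true(all(calls$overlaps[calls$in_nucleus]))
  }
  cfg0 <- small_config(seed = 20L, p_on_axis = 0, shot_noise = FALSE,
                       gaussian_read_noise_sd = 0)
  sim0 <- simulate_nucleus(cfg0)
  seg0 <- segment_axis(sim0$image)
  ## planted off-axis foci sit > 2 sigma from every path
  calls0 <- score_foci(sim0$truth$foci, sim0$image, seg0,
                       coloc_params("distance"))
  expect_false(any(calls0$overlaps[calls0$in_nucleus]))
})

test_that("profile and distance criteria agree on nearly all calls", {
  cfg <- small_config(seed = 22L, p_on_axis = 0.5, shot_noise = FALSE,
                      gaussian_read_noise_sd = 0)
  sim <- simulate_nucleus(cfg)
  fs <- detect_foci(sim$image)
  seg <- segment_axis(sim$image)
  a <- score_foci(fs, sim$image, seg, coloc_params("profile"))
  b <- score_foci(fs, sim$image, seg, coloc_params("distance"))
  agree <- mean(a$overlaps == b$overlaps, na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("the estimated overlap fraction tracks the planted probability", {
  sim <- simulate_nucleus(study_config(seed = 27L, p_on_axis = 0.6))
  fs <- detect_foci(sim$image)
  seg <- segment_axis(sim$image)
  calls <- score_foci(fs, sim$image, seg, coloc_params("distance"))
  obs <- mean(calls$overlaps, na.rm = TRUE)
  ci <- oracle_binom_interval(sum(calls$in_nucleus), 0.6, level = 0.95)
  expect_gte(obs, ci[1L])
  expect_lte(obs, ci[2L])
})

test_that("rotation by 180 degrees fixes the centroid and preserves symmetry", {
  ## symmetric scene: two horizontal lines placed symmetrically about the
  ## image centre; every focus and its reflection lie on the axis
  px <- 0.064
  axis <- matrix(0, 255, 255)
  axis[108, 41:215] <- 1
  axis[148, 41:215] <- 1
  axis <- meiofoci:::gaussian_blur(axis * 600, 0.13 / px) + 10
  st <- manual_stack(axis, px = px)
  seg <- segment_axis(st)
  cols <- c(60L, 100L, 128L, 170L, 200L)
  foci <- data.frame(
    x_um = (c(cols, cols) - 1L) * px,
    y_um = (c(rep(108L, 5L), rep(148L, 5L)) - 1L) * px)
  cp <- coloc_params("distance")
  calls <- score_foci(foci, st, seg, cp)
  expect_true(all(calls$overlaps))
  nul <- rotation_null(foci, st, seg, cp)
  expect_identical(nul$n_discarded, 0L)
  expect_equal(nul$random_overlap_fraction,
               mean(calls$overlaps))

  ## a single focus at the reflection centre maps onto itself
  centre_px <- round(seg$nucleus_centroid_um / px)
  one <- data.frame(x_um = centre_px[1L] * px, y_um = centre_px[2L] * px)
  n1 <- rotation_null(one, st, seg, cp)
  expect_equal(n1$calls$x_um, one$x_um)
  expect_equal(n1$calls$y_um, one$y_um)
  expect_error(rotation_null(one[0, ], st, seg, cp), "no foci")
})

test_that("nucleus summaries follow the degenerate-input rules", {
  seg <- segment_axis(manual_stack(matrix(10, 128, 128)))  # empty axis
  mk_calls <- function(n, n_over) data.frame(
    focus_index = seq_len(n), x_um = 0, y_um = 0, in_nucleus = TRUE,
    overlaps = c(rep(TRUE, n_over), rep(FALSE, n - n_over)),
    axis_signal_at_focus = 0, distance_to_skeleton_um = 0,
    criterion = "distance")

  seg20 <- seg; seg20$length_um <- 20
  s <- nucleus_summary(mk_calls(10L, 10L), seg20)
  expect_equal(s$overlap_fraction, 1)
  expect_equal(s$on_axis_density_per_um, 0.5)

  seg160 <- seg; seg160$length_um <- 160
  s2 <- nucleus_summary(mk_calls(100L, 40L), seg160)
  expect_equal(s2$overlap_fraction, 0.40)
  expect_equal(s2$on_axis_density_per_um, 0.25)

  s0 <- nucleus_summary(mk_calls(10L, 0L)[0, ], seg20)
  expect_true(is.na(s0$overlap_fraction))
  expect_identical(s0$on_axis_density_per_um, 0)

  ## overlapping foci with no axis is inconsistent
  expect_error(nucleus_summary(mk_calls(5L, 2L), seg), "inconsistent")
})

test_that("foci outside the image error and outside the nucleus are flagged", {
  sim <- simulate_nucleus(small_config(seed = 25L))
  seg <- segment_axis(sim$image)
  expect_error(score_foci(data.frame(x_um = -5, y_um = 2), sim$image, seg),
               "outside the image")
  corner <- data.frame(x_um = 0.2, y_um = 0.2)  # inside image, outside disc
  calls <- score_foci(corner, sim$image, seg, coloc_params("distance"))
  expect_false(calls$in_nucleus)
  expect_true(is.na(calls$overlaps))
})

test_that("chance correction inverts the chance-mixture of overlap", {
  expect_equal(corrected_overlap_fraction(0.6, 0.2), 0.5)
  expect_equal(corrected_overlap_fraction(0.2, 0.2), 0)
  obs <- 0.7; ch <- 0.25; p <- corrected_overlap_fraction(obs, ch)
  expect_equal(p + (1 - p) * ch, obs)
})
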