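test_that("an empty axis channel yields an empty segmentation", {
  st <- manual_stack(matrix(10, 128, 128))
  seg <- segment_axis(st)
  expect_identical(seg$length_um, 0)
  expect_identical(seg$skeleton_polylines, list())
})

test_that("a straight line of known length is measured within 5 percent", {
  st <- line_stack(12, dim_px = c(256L, 256L))
  seg <- segment_axis(st)
  expect_identical(length(seg$skeleton_polylines), 1L)
  expect_lt(abs(seg$length_um - 12) / 12, 0.05)
})

test_that("two disjoint segments give two components and the summed length", {
  px <- 0.064
  axis <- matrix(0, 256, 256)
  ## horizontal segments of 5 um and 8 um on different rows
  axis[80, 40:(40 + round(5 / px))] <- 1
  axis[170, 60:(60 + round(8 / px))] <- 1
  axis <- meiofoci:::gaussian_blur(axis * 600, 0.13 / px) + 10
  seg <- segment_axis(manual_stack(axis))
  expect_identical(seg$n_components, 2L)
  expect_identical(length(seg$skeleton_polylines), 2L)
  expect_lt(abs(seg$length_um - 13) / 13, 0.05)
})

test_that("skeleton pixels lie inside the segmented mask", {
  sim <- simulate_nucleus(small_config(seed = 17L))
  seg <- segment_axis(sim$image)
  expect_true(all(seg$mask[seg$skeleton > 0]))
  expect_equal(seg$length_um,
               sum(vapply(seg$skeleton_polylines, oracle_polyline_length,
                          numeric(1))),
               tolerance = 1e-9)
})

test_that("simulated axis length is recovered within 5 percent (intact) and
           scales with the retained fraction (fragmented)", {
  rel_err <- vapply(1:4, function(seed) {
    sim <- simulate_nucleus(study_config(seed = 40L + seed, n_foci = 0L))
    seg <- segment_axis(sim$image)
    seg$length_um / sim$truth$total_axis_length_um - 1
  }, numeric(1))
  expect_true(all(abs(rel_err) <= 0.05))

  for (seed in c(45L, 46L)) {
    intact <- simulate_nucleus(study_config(seed = seed, n_foci = 0L))
    frag <- simulate_nucleus(study_config(seed = seed, n_foci = 0L,
                                          axis_retained_fraction = 0.5))
    li <- segment_axis(intact$image)$length_um
    lf <- segment_axis(frag$image)$length_um
    truth_frac <- frag$truth$total_axis_length_um /
      intact$truth$total_axis_length_um
    expect_lt(abs(lf / li - truth_frac), 0.10)
  }
})
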