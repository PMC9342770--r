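test_that("worked examples: complete ties and complete separation", {
  r <- mww_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$u_statistic, 4.5)
  expect_equal(r$p_value, 1)
  expect_identical(r$method, "exact")

  r2 <- mww_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$u_statistic, 0)
  expect_equal(r2$p_value, 0.1)

  expect_error(mww_test(numeric(0), 1:3), "non-empty")
})

test_that("exact p matches full enumeration for all n_a, n_b <= 8", {
  set.seed(101)
  for (trial in 1:24) {
    n_a <- sample(2:8, 1L); n_b <- sample(2:8, 1L)
    with_ties <- trial %% 2L == 0L
    a <- if (with_ties) sample(1:4, n_a, replace = TRUE) else rnorm(n_a)
    b <- if (with_ties) sample(1:4, n_b, replace = TRUE) else rnorm(n_b)
    got <- mww_test(a, b)
    want <- oracle_mww(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$u_statistic, want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("the normal approximation is close to the exact distribution", {
  set.seed(202)
  diffs <- replicate(200, {
    a <- rnorm(10); b <- rnorm(10)
    p_norm <- mww_test(a, b)$p_value
    ## exact two-sided p from the null U distribution (no ties)
    u <- sum(outer(a, b, ">"))
    p_exact <- 2 * min(pwilcox(min(u, 100 - u), 10, 10),
                       1 - pwilcox(max(u, 100 - u) - 1, 10, 10))
    p_exact <- min(p_exact, 1)
    abs(p_norm - p_exact)
  })
  expect_lte(max(diffs), 0.01)
})

test_that("the test is symmetric in its arguments", {
  set.seed(303)
  for (trial in 1:10) {
    a <- sample(1:6, sample(3:12, 1L), replace = TRUE)
    b <- sample(1:6, sample(3:12, 1L), replace = TRUE)
    expect_equal(mww_test(a, b)$p_value, mww_test(b, a)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("percent and fold change reproduce the reported staging figures", {
  expect_equal(round(percent_change(179, 197)), 10)
  expect_equal(round(percent_change(179, 211)), 18)
  expect_equal(percent_change(7, 7), 0)
  expect_error(percent_change(0, 5), "zero reference")

  expect_equal(fold_change(0.5, 0.95), 1.9)
  expect_equal(fold_change(1, 1), 1)
  expect_error(fold_change(0, 1), "non-positive")
  ## algebraic identity between the two summaries
  set.seed(7)
  for (i in 1:10) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(fold_change(a, b), 1 + percent_change(a, b) / 100)
  }
})

test_that("first labelled times follow the pulse-chase table", {
  tab <- data.frame(
    time_h = rep(c(0, 5, 10, 24, 35), 2L),
    stage = rep(c("Lep", "Zyg/Pac"), each = 5L),
    labelled_count = c(0, 2, 3, 1, 0, 0, 0, 4, 2, 1),
    unlabelled_count = 5)
  ft <- first_labelled_times(tab)
  expect_equal(ft[["Lep"]], 5)
  expect_equal(ft[["Zyg/Pac"]], 10)

  none <- tab; none$labelled_count <- 0
  expect_true(all(is.na(first_labelled_times(none))))

  late <- data.frame(time_h = c(10, 24, 35), stage = "Dip/MI",
                     labelled_count = c(0, 3, 5))
  expect_equal(first_labelled_times(late)[["Dip/MI"]], 24)

  bad <- tab[c(2, 1), ]
  expect_error(first_labelled_times(bad), "strictly increasing")
  expect_error(first_labelled_times(data.frame(time_h = 1)), "columns")
})

test_that("group comparison tables cover all pairs of labels", {
  set.seed(11)
  pn <- data.frame(group_label = rep(c("a", "b", "c"), each = 6L),
                   overlap_fraction = runif(18))
  cmp <- compare_groups(pn, "overlap_fraction")
  expect_identical(nrow(cmp), 3L)
  expect_true(all(cmp$method == "exact"))
  expect_error(compare_groups(pn, "nope"), "not found")
  expect_error(compare_groups(pn[pn$group_label == "a", ]), "two groups")
})
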