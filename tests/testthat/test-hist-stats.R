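test_that("binning follows the half-open, multiple-aligned convention", {
  v <- vol3(c(1.02, rep(1.02, 63)))
  h <- build_histogram(v, all_mask(), 0.05)
  expect_equal(length(h$counts), 1)
  expect_equal(h$bin_edges, c(1.00, 1.05))
  expect_equal(h$counts, 64)

  # value exactly on an edge goes to the upper bin
  h2 <- histogram_from_values(c(1.02, 1.05))
  expect_equal(h2$bin_edges, c(1.00, 1.05, 1.10))
  expect_equal(h2$counts, c(1, 1))

  # explicit range clamps outliers into end bins and flags it
  h3 <- histogram_from_values(c(0.2, 1.1, 3.4), range = c(0, 3))
  expect_true(h3$clamped)
  expect_equal(sum(h3$counts), 3)
  expect_equal(h3$counts[length(h3$counts)], 1)
})

test_that("histogram mass equals mask voxel count (conservation)", {
  ph <- small_phantom(seed = 3)
  suvr <- compute_suvr(ph$suv, make_label_mask(ph$labels, 1L))
  for (thr in c(0.5, 0.6)) {
    m <- make_parenchyma_mask(ph$p_gm, ph$p_wm, thr)
    h <- build_histogram(suvr, m)
    expect_equal(sum(h$counts), m$voxel_count)
  }
  expect_error(build_histogram(suvr,
                               binary_mask(array(FALSE, dim(ph$suv))),
                               0.05), "empty")
})

test_that("skewness matches the printed bias-corrected formula", {
  expect_equal(sample_skewness(c(1, 2, 3)), 0)
  # hand evaluation: n=4, m=0.25, s=0.5, sum(((x-m)/s)^3) = 3 -> (4/6)*3 = 2
  expect_equal(sample_skewness(c(0, 0, 0, 1)), 2.0)
  expect_error(sample_skewness(c(1, 2)), "n >= 3")
  expect_error(sample_skewness(c(1, 1, 1)), "zero variance")
})

test_that("excess kurtosis matches hand evaluation and analytic limits", {
  # n=5: 1.25 * 10.4 - 8.0 = 5.0
  expect_equal(sample_excess_kurtosis(c(0, 0, 0, 0, 1)), 5.0)
  # printed-formula variant differs only in the correction term:
  # 13 - 3*4/(3*2) = 13 - 2 = 11
  expect_equal(sample_excess_kurtosis(c(0, 0, 0, 0, 1), formula = "printed"),
               11.0)
  # symmetric two-point mass at +/-1: excess kurtosis -> -2
  x <- rep(c(-1, 1), 5000)
  expect_equal(sample_excess_kurtosis(x), -2, tolerance = 0.01)
  expect_error(sample_excess_kurtosis(c(1, 2, 3)), "n >= 4")
})

test_that("skewness is invariant under positive affine maps, flips sign under negative", {
  set.seed(41)
  x <- rgamma(2000, shape = 2)
  s0 <- sample_skewness(x)
  for (ab in list(c(3, 2), c(-1, 0.1))) {
    expect_equal(sample_skewness(ab[1] + ab[2] * x), s0, tolerance = 1e-9)
  }
  expect_equal(sample_skewness(5 - 2 * x), -s0, tolerance = 1e-9)
})

test_that("mode takes the maximal bin, ties broken toward low SUVR", {
  h <- histogram_from_values(c(1.02, 1.02, 1.52, 1.52, 1.24))
  # bins [1.00,1.05) and [1.50,1.55) tie with 2 counts
  expect_equal(mode_value(h), 1.025)
  h1 <- histogram_from_values(rep(1.02, 5))
  expect_equal(mode_value(h1), 1.025)
  h$counts[] <- 0; h$total <- 0
  expect_error(mode_value(h), "empty")
})

test_that("descriptive_params combines exact moments with the binned mode", {
  set.seed(42)
  vals <- rnorm(4000, 1.2, 0.15)
  v <- vol3(vals, dims = c(20, 20, 10))
  m <- all_mask(c(20, 20, 10))
  h <- build_histogram(v, m)
  p <- descriptive_params(v, m, h)
  expect_equal(p$mean, mean(vals))
  expect_equal(p$mmr, p$mode / p$mean)
  expect_equal(p$n, 4000)
  # binned estimators agree within O(bin_width^2) on smooth data
  pb <- moments_from_histogram(h)
  expect_lt(abs(pb$skewness - p$skewness), 0.02)
  expect_lt(abs(pb$excess_kurtosis - p$excess_kurtosis), 0.02)
  expect_lt(abs(pb$mean - p$mean), 0.05 / 2)
})

test_that("negative-pattern model yields MMR < 1 (peak left of mean)", {
  # piG2 = 0 world: GM at 1.0, WM at 1.5 -> whole-brain peak at G1, mean
  # dragged right by WM; the mode/mean ratio must fall below 1
  sm <- sample_voxels(three_component_spec(piG2 = 0), 2e5, seed = 9)
  h <- histogram_from_values(sm$values)
  expect_lt(mode_value(h) / mean(sm$values), 1)
})

test_that("mixture kurtosis decreases as component separation grows", {
  seps <- c(0.2, 0.4, 0.6, 0.8)
  kurt <- vapply(seps, function(dmu) {
    sm <- sample_voxels(
      three_component_spec(muG2 = 1 + dmu, piG2 = 0.5, gm_fraction = 1 - 1e-9,
                           wm_fraction = 1e-9),
      1e5, seed = 17)
    gm <- sm$values[sm$labels != "wm"]
    sample_excess_kurtosis(gm)
  }, numeric(1))
  expect_true(all(diff(kurt) < 0))
})
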