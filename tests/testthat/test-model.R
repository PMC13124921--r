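test_that("spec validation enforces the model invariants", {
  expect_error(three_component_spec(gm_fraction = 0.5, wm_fraction = 0.6),
               "equal 1")
  expect_error(three_component_spec(sigmaG1 = 0), "positive")
  expect_error(three_component_spec(piG2 = 1.2), "\\[0, 1\\]")
})

test_that("component masses and curves respect the stated fractions", {
  spec <- three_component_spec(piG2 = 0)
  cur <- expected_curves(spec, range = c(-1, 4))
  expect_equal(sum(cur$g2), 0)
  expect_equal(sum(cur$gm_total), 0.43, tolerance = 1e-6)
  expect_equal(sum(cur$wm), 0.57, tolerance = 1e-6)
  expect_equal(sum(cur$whole), 1, tolerance = 1e-6)
  expect_equal(cur$gm_total, cur$g1 + cur$g2)
  expect_equal(cur$whole, cur$gm_total + cur$wm)

  spec1 <- three_component_spec(muG2 = 1.8, piG2 = 1)
  cur1 <- expected_curves(spec1, range = c(-1, 4))
  expect_equal(sum(cur1$g1), 0)
  # gm_total is a single Gaussian at muG2: its mass-weighted mean is muG2
  expect_equal(sum(cur1$bin_centers * cur1$gm_total) / sum(cur1$gm_total),
               1.8, tolerance = 1e-3)
})

test_that("whole-distribution mean matches the closed form", {
  spec <- three_component_spec(piG2 = 0)
  expect_equal(model_whole_mean(spec), 0.43 * 1.0 + 0.57 * 1.5)
  cur <- expected_curves(spec, bin_width = 0.01, range = c(-1, 4))
  # binned mean approximates the closed form to O(bin_width^2)
  expect_equal(sum(cur$bin_centers * cur$whole) / sum(cur$whole),
               1.285, tolerance = 1e-4)
})

test_that("a too-narrow range warns with the mass deficit", {
  expect_warning(expected_curves(three_component_spec(), range = c(0.8, 1.8)),
                 "mass deficit")
})

test_that("sample_voxels: empty case, label fractions, determinism", {
  spec <- three_component_spec(muG2 = 1.6, piG2 = 0.5)
  e <- sample_voxels(spec, 0)
  expect_length(e$values, 0)

  n <- 1e5
  sm <- sample_voxels(spec, n, seed = 12)
  frac <- as.vector(table(sm$labels)) / n
  target <- c(0.43 * 0.5, 0.43 * 0.5, 0.57)
  se <- sqrt(target * (1 - target) / n)
  expect_true(all(abs(frac - target) < 3 * se))

  sm2 <- sample_voxels(spec, n, seed = 12)
  expect_identical(sm$values, sm2$values)
  sm3 <- sample_voxels(spec, n, seed = 13)
  expect_false(identical(sm$values, sm3$values))
})

test_that("GM subsample round-trips through the mixture fit", {
  spec <- three_component_spec(muG2 = 1.6, piG2 = 0.4, sigmaG1 = 0.10,
                               sigmaG2 = 0.15)
  sm <- sample_voxels(spec, 3e5, seed = 8)
  gm <- sm$values[sm$labels %in% c("g1", "g2")]
  fit <- fit_two_gaussians(gm, seed = 1)
  expect_lt(abs(fit$muG1 - 1.0), 0.02)
  expect_lt(abs(fit$muG2 - 1.6), 0.02)
  expect_lt(abs(fit$piG2 - 0.4), 0.03)
})

test_that("empirical histogram converges to the expected curves in L1", {
  spec <- three_component_spec(muG2 = 1.5, piG2 = 0.3)
  n <- 1e6
  sm <- sample_voxels(spec, n, seed = 31)
  h <- histogram_from_values(sm$values, 0.05, range = c(-0.5, 3.5))
  cur <- expected_curves(spec, 0.05, range = c(-0.5, 3.5))
  l1 <- sum(abs(h$counts / n - cur$whole))
  expect_lt(l1, 0.02)
})

test_that("morphology transition: narrow -> wide -> bimodal along the trajectory", {
  sigmas <- list(sigmaG1 = 0.15, sigmaG2 = 0.15)
  traj <- list(c(0.02, 1.2), c(0.5, 1.28), c(0.6, 1.8))
  specs <- lapply(traj, function(pm)
    three_component_spec(muG2 = pm[2], piG2 = pm[1],
                         sigmaG1 = sigmas$sigmaG1, sigmaG2 = sigmas$sigmaG2))
  nmax <- vapply(specs, function(s)
    count_local_maxima(expected_curves(s, range = c(0, 3))$gm_total),
    integer(1))
  expect_equal(nmax, c(1L, 1L, 2L))

  kurt <- vapply(seq_along(specs), function(i) {
    sm <- sample_voxels(specs[[i]], 1e5, seed = 40 + i)
    sample_excess_kurtosis(sm$values[sm$labels != "wm"])
  }, numeric(1))
  expect_true(all(diff(kurt) < 0))
  # wide-peak case clearly platykurtic, bimodal case more so
  expect_lt(kurt[2], -0.2)
  expect_lt(kurt[3], kurt[2])
})
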