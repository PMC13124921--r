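planted_draws <- function(n, seed) {
  set.seed(seed)
  n1 <- rbinom(1, n, 0.6)
  sample(c(rnorm(n1, 1.00, 0.10), rnorm(n - n1, 1.60, 0.15)))
}

test_that("EM recovers planted mixture parameters", {
  x <- planted_draws(2e5, 101)
  fit <- fit_two_gaussians(x, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$muG1 - 1.00), 0.02)
  expect_lt(abs(fit$muG2 - 1.60), 0.02)
  expect_lt(abs(fit$piG2 - 0.40), 0.03)
  expect_false(fit$degenerate)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  for (seed in 1:3) {
    x <- planted_draws(5e3, 200 + seed)
    fit <- fit_two_gaussians(x, seed = seed)
    expect_true(all(diff(fit$loglik_trace) >= -1e-7 *
                      pmax(abs(fit$loglik_trace[-length(fit$loglik_trace)]), 1)))
  }
})

test_that("single-Gaussian input is flagged degenerate", {
  set.seed(55)
  x <- rnorm(2e4, 1.05, 0.12)
  fit <- fit_two_gaussians(x, seed = 2)
  expect_lt(fit$muG2 - fit$muG1, 0.10)
  expect_true(fit$degenerate)
})

test_that("component ordering is invariant to initial labeling", {
  # jittered restarts start from permuted/perturbed configurations; the
  # ordered output must be identical across seeds up to EM tolerance
  x <- planted_draws(2e4, 77)
  fits <- lapply(c(1, 99, 1234), function(s) fit_two_gaussians(x, seed = s))
  for (f in fits) expect_lte(f$muG1, f$muG2)
  mus <- vapply(fits, function(f) c(f$muG1, f$muG2, f$piG2), numeric(3))
  expect_lt(max(mus[1, ]) - min(mus[1, ]), 1e-4)
  expect_lt(max(mus[2, ]) - min(mus[2, ]), 1e-4)
  expect_lt(max(mus[3, ]) - min(mus[3, ]), 1e-3)
})

test_that("binned-weighted fit agrees with the raw-value fit", {
  x <- planted_draws(1e5, 303)
  fr <- fit_two_gaussians(x, seed = 1)
  fb <- fit_two_gaussians(histogram_from_values(x, 0.05), seed = 1)
  expect_lt(abs(fr$muG1 - fb$muG1), 0.01)
  expect_lt(abs(fr$muG2 - fb$muG2), 0.01)
  expect_lt(abs(fr$piG2 - fb$piG2), 0.01)
  expect_lt(abs(fr$sigma1 - fb$sigma1), 0.01)
  expect_lt(abs(fr$sigma2 - fb$sigma2), 0.01)
})

test_that("degenerate flag flips exactly at the separation threshold", {
  base <- structure(
    list(muG1 = 1.00, muG2 = NA_real_, sigma1 = 0.1, sigma2 = 0.1,
         piG2 = 0.4, log_likelihood = 0, loglik_trace = 0, n_iter = 1,
         converged = TRUE, degenerate = FALSE, n_restarts_used = 1,
         n = 1000), class = "mixture_fit")
  for (sep in c(0.02, 0.0999, 0.1, 0.1001, 0.5)) {
    f <- base; f$muG2 <- 1 + sep
    expect_identical(flag_degenerate(f, 0.10)$degenerate, sep < 0.10)
  }
  f <- base; f$muG2 <- 1.06
  expect_true(flag_degenerate(f)$degenerate)   # 1.04/1.06-style case
  f$muG2 <- 1.60
  expect_false(flag_degenerate(f)$degenerate)
})

test_that("fit_two_gaussians enforces its preconditions", {
  expect_error(fit_two_gaussians(rnorm(50)), "too few")
  expect_error(fit_two_gaussians(c(rep(1, 200), NA)), "non-finite|finite")
})

test_that("WM fit is the weighted mean / SD, with sanity limits", {
  expect_equal(fit_wm_gaussian(rep(1.5, 100))$muW, 1.5)
  # symmetric histogram about 1.4
  h <- histogram_from_values(c(rep(1.32, 10), rep(1.47, 10)))
  expect_equal(fit_wm_gaussian(h)$muW, 1.4, tolerance = 1e-9)
  set.seed(66)
  x <- rnorm(1e5, 1.5, 0.2)
  f <- fit_wm_gaussian(x)
  expect_lt(abs(f$muW - 1.5), 3 * 0.2 / sqrt(1e5))
  expect_equal(f$sigmaW, sd(x))
  expect_error(fit_wm_gaussian(numeric(0)), "too few")
})
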