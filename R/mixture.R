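# Two-Gaussian decomposition of the GM histogram. G1 collects gray matter
# without pathological amyloid (mean near the cerebellar level, muG1 ~ 1);
# G2 collects amyloid-bearing cortex (muG2 > muG1); piG2 is the mixing
# proportion of G2. Fitted by expectation-maximization on raw voxel values
# or on binned counts treated as weights at bin centers.

.mix_loglik <- function(x, w, p) {
  dens <- (1 - p$piG2) * stats::dnorm(x, p$muG1, p$sigma1) +
    p$piG2 * stats::dnorm(x, p$muG2, p$sigma2)
  sum(w * log(pmax(dens, 1e-300)))
}

.order_components <- function(p) {
  if (p$muG1 > p$muG2) {
    p <- list(muG1 = p$muG2, muG2 = p$muG1, sigma1 = p$sigma2,
              sigma2 = p$sigma1, piG2 = 1 - p$piG2)
  }
  p
}

.em_run <- function(x, w, init, tol, max_iter, sigma_floor) {
  p <- init
  n <- sum(w)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    d1 <- (1 - p$piG2) * stats::dnorm(x, p$muG1, p$sigma1)
    d2 <- p$piG2 * stats::dnorm(x, p$muG2, p$sigma2)
    tot <- pmax(d1 + d2, 1e-300)
    r2 <- d2 / tot
    # M-step (weighted)
    w2 <- w * r2
    w1 <- w - w2
    s1 <- sum(w1); s2 <- sum(w2)
    if (s1 < 1e-12 || s2 < 1e-12) break  # component collapsed away
    mu1 <- sum(w1 * x) / s1
    mu2 <- sum(w2 * x) / s2
    sd1 <- max(sqrt(sum(w1 * (x - mu1)^2) / s1), sigma_floor)
    sd2 <- max(sqrt(sum(w2 * (x - mu2)^2) / s2), sigma_floor)
    p <- list(muG1 = mu1, muG2 = mu2, sigma1 = sd1, sigma2 = sd2,
              piG2 = s2 / n)
    ll <- .mix_loglik(x, w, p)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(params = p, loglik = if (length(ll_trace)) ll_trace[length(ll_trace)]
       else -Inf,
       trace = ll_trace, n_iter = length(ll_trace), converged = converged)
}

.median_split_init <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  med <- x[o][which(cw >= 0.5)[1]]
  lo <- x <= med
  wl <- w * lo; wh <- w * !lo
  if (sum(wh) == 0) { wh <- w / 2; wl <- w / 2 }
  m1 <- sum(wl * x) / sum(wl)
  m2 <- sum(wh * x) / sum(wh)
  s1 <- sqrt(max(sum(wl * (x - m1)^2) / sum(wl), 1e-6))
  s2 <- sqrt(max(sum(wh * (x - m2)^2) / sum(wh), 1e-6))
  list(muG1 = m1, muG2 = m2, sigma1 = s1, sigma2 = s2,
       piG2 = sum(wh) / sum(w))
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Maximum-likelihood decomposition of the GM SUVR distribution into two
#' Gaussians. Deterministic initialization splits the data at the weighted
#' median; `n_restarts` additional runs jitter that start (seeded), and the
#' best log-likelihood is kept. Components are relabeled so `muG1 <= muG2`;
#' `piG2` is the mixing proportion of the higher-mean component. Fits whose
#' means nearly coincide are flagged degenerate (see [flag_degenerate()]):
#' their `piG2` is an artifact of splitting one Gaussian in two.
#'
#' @param x numeric values, or a `suvr_histogram` (fitted as bin centers
#'   weighted by counts).
#' @param weights optional non-negative weights for numeric `x`.
#' @param n_restarts additional jittered EM starts (default 4).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per start (default 500).
#' @param sigma_floor lower bound on component SDs (default 0.025, half the
#'   0.05 SUVR bin width) preventing single-bin collapse.
#' @param degenerate_delta separation below which the fit is flagged
#'   degenerate (default 0.10 SUVR, two bin widths).
#' @param min_obs minimum effective observations (default 100).
#' @param seed integer seed for the jittered restarts.
#' @return A `mixture_fit`: `muG1`, `muG2`, `sigma1`, `sigma2`, `piG2`,
#'   `log_likelihood`, `loglik_trace`, `n_iter`, `converged`, `degenerate`,
#'   `n_restarts_used`, `n`.
#' @export
fit_two_gaussians <- function(x, weights = NULL, n_restarts = 4L,
                              tol = 1e-8, max_iter = 500L,
                              sigma_floor = 0.025,
                              degenerate_delta = 0.10,
                              min_obs = 100, seed = 1L) {
  if (inherits(x, "suvr_histogram")) {
    keep <- x$counts > 0
    weights <- x$counts[keep]
    x <- x$bin_centers[keep]
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(x) != length(weights) || any(weights < 0))
    stop("weights must be non-negative and match `x`", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values", call. = FALSE)
  n_eff <- sum(weights)
  if (n_eff < min_obs)
    stop(sprintf("too few effective observations (%g < %g)", n_eff, min_obs),
         call. = FALSE)

  base <- .median_split_init(x, weights)
  inits <- list(base)
  if (n_restarts > 0) {
    rng <- .seeded_rng(seed)
    spread <- stats::sd(rep(x, times = pmax(round(weights), 1))[
      seq_len(min(n_eff, 1e4))])
    if (!is.finite(spread) || spread <= 0) spread <- 0.1
    for (r in seq_len(n_restarts)) {
      jit <- base
      jit$muG1 <- base$muG1 + rng$norm(1) * 0.5 * spread
      jit$muG2 <- base$muG2 + rng$norm(1) * 0.5 * spread
      jit$piG2 <- min(max(base$piG2 + rng$unif(1, -0.2, 0.2), 0.05), 0.95)
      inits <- c(inits, list(jit))
    }
  }
  best <- NULL
  for (init in inits) {
    run <- .em_run(x, weights, init, tol, max_iter, sigma_floor)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning("EM did not converge in any restart; returning best run",
            call. = FALSE)
  p <- .order_components(best$params)
  fit <- structure(
    list(muG1 = p$muG1, muG2 = p$muG2, sigma1 = p$sigma1,
         sigma2 = p$sigma2, piG2 = p$piG2,
         log_likelihood = best$loglik, loglik_trace = best$trace,
         n_iter = best$n_iter, converged = best$converged,
         degenerate = FALSE, n_restarts_used = length(inits), n = n_eff),
    class = "mixture_fit"
  )
  flag_degenerate(fit, delta = degenerate_delta)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit> muG1 %.4f (sd %.4f)  muG2 %.4f (sd %.4f)  piG2 %.4f\n",
    x$muG1, x$sigma1, x$muG2, x$sigma2, x$piG2))
  cat(sprintf("  logLik %.4f after %d iter (%sconverged%s)\n",
              x$log_likelihood, x$n_iter,
              if (x$converged) "" else "NOT ",
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Flag a degenerate two-component fit
#'
#' A separation `muG2 - muG1 < delta` means the two components sit almost
#' on top of each other: the decomposition is then splitting a single
#' Gaussian and `piG2` carries no amyloid signal (the mechanism behind
#' visually-negative outliers with high piG2).
#'
#' @param fit a `mixture_fit`.
#' @param delta separation threshold in SUVR units (default 0.10).
#' @return The fit with `degenerate` set.
#' @export
flag_degenerate <- function(fit, delta = 0.10) {
  if (!inherits(fit, "mixture_fit"))
    stop("`fit` must be a mixture_fit", call. = FALSE)
  fit$degenerate <- (fit$muG2 - fit$muG1) < delta
  fit
}

#' Single-Gaussian fit of the WM histogram
#'
#' muW is the (weighted) sample mean of the WM-mask voxels — the
#' maximum-likelihood Gaussian location — and sigmaW the sample standard
#' deviation. WM off-target binding varies widely across individuals, so
#' muW is reported per subject rather than assumed.
#'
#' @param x numeric values or a `suvr_histogram`.
#' @param weights optional non-negative weights for numeric `x`.
#' @param min_obs minimum effective observations (default 10).
#' @return A `wm_fit`: `muW`, `sigmaW`, `n`.
#' @export
fit_wm_gaussian <- function(x, weights = NULL, min_obs = 10) {
  if (inherits(x, "suvr_histogram")) {
    keep <- x$counts > 0
    weights <- x$counts[keep]
    x <- x$bin_centers[keep]
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  n <- sum(weights)
  if (length(x) == 0L || n < min_obs)
    stop(sprintf("too few WM observations (%g < %g)", n, min_obs),
         call. = FALSE)
  m <- sum(weights * x) / n
  s <- sqrt(sum(weights * (x - m)^2) / max(n - 1, 1))
  structure(list(muW = m, sigmaW = s, n = n), class = "wm_fit")
}

#' @export
print.wm_fit <- function(x, ...) {
  cat(sprintf("<wm_fit> muW %.4f, sigmaW %.4f, n %g\n", x$muW, x$sigmaW, x$n))
  invisible(x)
}
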