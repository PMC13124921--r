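# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

# Small scalar volume from a vector (filled in array order).
vol3 <- function(values, dims = c(4, 4, 4), kind = "suv",
                 voxel = c(1, 1, 1)) {
  scalar_volume(array(values, dim = dims), voxel_size_mm = voxel,
                kind = kind)
}

# Probability volume from a vector.
pvol3 <- function(values, dims = c(4, 4, 4), voxel = c(1, 1, 1)) {
  vol3(values, dims, kind = "probability", voxel = voxel)
}

# Full-volume mask.
all_mask <- function(dims = c(4, 4, 4)) {
  binary_mask(array(TRUE, dim = dims))
}

# A small, fast phantom used where geometry details do not matter. The
# probability blur is scaled down with the brain so the >60% masks stay
# non-empty at this grid size.
small_phantom <- function(seed = 1, muG2 = 1.6, piG2 = 0.5,
                          probability_blur_fwhm_mm = 6, ...) {
  generate_phantom(
    phantom_spec(grid_dims = c(32, 36, 20), seed = seed,
                 probability_blur_fwhm_mm = probability_blur_fwhm_mm, ...),
    three_component_spec(muG2 = muG2, piG2 = piG2))
}

# Independent dense-grid + local-refinement maximizer of the two-Gaussian
# (shared sigma) mixture log-likelihood on binned data. Used as the oracle
# for the EM fit; it never calls the EM code path.
grid_search_mixture_loglik <- function(centers, counts,
                                       mu_range = c(0.8, 1.4),
                                       sigma_range = c(0.025, 0.3)) {
  eval_ll <- function(mu1, mu2, sigma, pi2) {
    d <- (1 - pi2) * dnorm(centers, mu1, sigma) +
      pi2 * dnorm(centers, mu2, sigma)
    sum(counts * log(pmax(d, 1e-300)))
  }
  best <- list(ll = -Inf)
  scan <- function(mu1s, mu2s, sigmas, pi2s) {
    for (s in sigmas) {
      D1 <- outer(mu1s, centers, function(m, cc) dnorm(cc, m, s))
      D2 <- outer(mu2s, centers, function(m, cc) dnorm(cc, m, s))
      for (p in pi2s) {
        for (i in seq_along(mu1s)) {
          M <- (1 - p) * matrix(D1[i, ], nrow(D2), length(centers),
                                byrow = TRUE) + p * D2
          ll <- as.vector(log(pmax(M, 1e-300)) %*% counts)
          j <- which.max(ll)
          if (ll[j] > best$ll)
            best <<- list(ll = ll[j], mu1 = mu1s[i], mu2 = mu2s[j],
                          sigma = s, pi2 = p)
        }
      }
    }
  }
  scan(seq(mu_range[1], mu_range[2], by = 0.02),
       seq(mu_range[1], mu_range[2], by = 0.02),
       seq(sigma_range[1], sigma_range[2], by = 0.01),
       seq(0.02, 0.98, by = 0.04))
  for (step in c(4e-3, 4e-4, 4e-5, 4e-6)) {
    scan(best$mu1 + seq(-6, 6) * step,
         best$mu2 + seq(-6, 6) * step,
         pmax(sigma_range[1], best$sigma + seq(-6, 6) * step),
         pmin(pmax(best$pi2 + seq(-6, 6) * step * 5, 1e-4), 1 - 1e-4))
  }
  best
}
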