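# Three-component forward model of the brain-parenchyma SUVR distribution:
# G1 = gray matter without pathological amyloid (mu ~ 1, the cerebellar
# level), G2 = amyloid-bearing gray matter (muG2 > muG1), WM = white matter
# with off-target binding (muW ~ 1.5). GM and WM occupy ~43% / 57% of the
# parenchyma; piG2 is the G2 share of GM. The whole-brain histogram is the
# mass-weighted sum of the three Gaussian curves.

#' Three-component model specification
#'
#' @param muG1 mean of the amyloid-free GM component (SUVR), default 1.0.
#' @param muG2 mean of the amyloid-bearing GM component, `>= muG1` expected.
#' @param muW mean of the WM component, default 1.5.
#' @param sigmaG1,sigmaG2,sigmaW component standard deviations (SUVR),
#'   defaults 0.15 / 0.15 / 0.30.
#' @param piG2 G2 proportion within GM, in \[0, 1\].
#' @param gm_fraction,wm_fraction GM / WM shares of the parenchyma,
#'   defaults 0.43 / 0.57; must sum to 1.
#' @return A `three_component_spec`.
#' @export
three_component_spec <- function(muG1 = 1.0, muG2 = 1.4, muW = 1.5,
                                 sigmaG1 = 0.15, sigmaG2 = 0.15,
                                 sigmaW = 0.30, piG2 = 0.0,
                                 gm_fraction = 0.43, wm_fraction = 0.57) {
  if (abs(gm_fraction + wm_fraction - 1) > 1e-9)
    stop("gm_fraction + wm_fraction must equal 1", call. = FALSE)
  if (any(c(sigmaG1, sigmaG2, sigmaW) <= 0))
    stop("all component standard deviations must be positive", call. = FALSE)
  if (piG2 < 0 || piG2 > 1)
    stop("piG2 must lie in [0, 1]", call. = FALSE)
  structure(
    list(muG1 = muG1, muG2 = muG2, muW = muW, sigmaG1 = sigmaG1,
         sigmaG2 = sigmaG2, sigmaW = sigmaW, piG2 = piG2,
         gm_fraction = gm_fraction, wm_fraction = wm_fraction),
    class = "three_component_spec"
  )
}

#' @export
print.three_component_spec <- function(x, ...) {
  cat(sprintf(
    "<three_component_spec> G1 N(%.3g, %.3g^2)  G2 N(%.3g, %.3g^2)  WM N(%.3g, %.3g^2)\n",
    x$muG1, x$sigmaG1, x$muG2, x$sigmaG2, x$muW, x$sigmaW))
  cat(sprintf("  piG2 %.3g, GM/WM fractions %.3g / %.3g\n",
              x$piG2, x$gm_fraction, x$wm_fraction))
  invisible(x)
}

# Component masses: (G1, G2, WM) shares of the whole parenchyma.
component_masses <- function(spec) {
  c(g1 = spec$gm_fraction * (1 - spec$piG2),
    g2 = spec$gm_fraction * spec$piG2,
    wm = spec$wm_fraction)
}

#' Expected component curves
#'
#' Per-bin probability mass of each component (Gaussian density integrated
#' over the bin, so mass conservation is exact) plus the GM total
#' (g1 + g2) and the whole-parenchyma sum (gm_total + wm). `range` should
#' cover every component's mean +/- 5 SD; a narrower range triggers a
#' warning reporting the mass deficit.
#'
#' @param spec a [three_component_spec].
#' @param bin_width bin width in SUVR units, default 0.05.
#' @param range `c(lo, hi)` bin-edge limits.
#' @return A `component_curves` list: `bin_centers`, `g1`, `g2`, `wm`,
#'   `gm_total`, `whole`, `bin_width`.
#' @export
expected_curves <- function(spec, bin_width = 0.05, range = c(0, 3)) {
  if (range[2] <= range[1]) stop("`range` must be increasing", call. = FALSE)
  need_lo <- min(spec$muG1 - 5 * spec$sigmaG1, spec$muG2 - 5 * spec$sigmaG2,
                 spec$muW - 5 * spec$sigmaW)
  need_hi <- max(spec$muG1 + 5 * spec$sigmaG1, spec$muG2 + 5 * spec$sigmaG2,
                 spec$muW + 5 * spec$sigmaW)
  nbins <- ceiling((range[2] - range[1]) / bin_width - 1e-9)
  edges <- range[1] + (0:nbins) * bin_width
  bin_mass <- function(mu, sigma)
    stats::pnorm(edges[-1], mu, sigma) - stats::pnorm(edges[-(nbins + 1)], mu, sigma)
  mass <- component_masses(spec)
  g1 <- mass["g1"] * bin_mass(spec$muG1, spec$sigmaG1)
  g2 <- mass["g2"] * bin_mass(spec$muG2, spec$sigmaG2)
  wm <- mass["wm"] * bin_mass(spec$muW, spec$sigmaW)
  whole <- g1 + g2 + wm
  if (range[1] > need_lo || range[2] < need_hi) {
    deficit <- 1 - sum(whole)
    warning(sprintf(
      "range [%g, %g] does not cover all components +/- 5 SD; mass deficit %.3g",
      range[1], range[2], deficit), call. = FALSE)
  }
  structure(
    list(bin_centers = edges[-(nbins + 1)] + bin_width / 2,
         g1 = unname(g1), g2 = unname(g2), wm = unname(wm),
         gm_total = unname(g1 + g2), whole = unname(whole),
         bin_width = bin_width),
    class = "component_curves"
  )
}

#' Closed-form mean of the whole-parenchyma distribution
#'
#' Mass-weighted mixture expectation:
#' `gm_fraction * ((1 - piG2) * muG1 + piG2 * muG2) + wm_fraction * muW`.
#'
#' @param spec a [three_component_spec].
#' @return Scalar expected SUVR.
#' @export
model_whole_mean <- function(spec) {
  mass <- component_masses(spec)
  unname(mass["g1"] * spec$muG1 + mass["g2"] * spec$muG2 +
           mass["wm"] * spec$muW)
}

#' Monte-Carlo twin of the forward model
#'
#' Draws `n` voxel values: each draw is assigned to G1 / G2 / WM with
#' probabilities `gm_fraction * (1 - piG2)`, `gm_fraction * piG2`,
#' `wm_fraction`, then sampled from that component's Gaussian.
#'
#' @param spec a [three_component_spec].
#' @param n number of draws.
#' @param seed integer seed; equal seeds give identical output.
#' @return List: `values` (numeric), `labels` (factor in g1/g2/wm).
#' @export
sample_voxels <- function(spec, n, seed = 1L) {
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  lv <- c("g1", "g2", "wm")
  if (n == 0)
    return(list(values = numeric(0), labels = factor(character(0), lv)))
  rng <- .seeded_rng(seed)
  mass <- component_masses(spec)
  comp <- rng$multinom_assign(n, mass)
  mu <- c(spec$muG1, spec$muG2, spec$muW)[comp]
  sd <- c(spec$sigmaG1, spec$sigmaG2, spec$sigmaW)[comp]
  values <- rng$norm(n) * sd + mu
  list(values = values, labels = factor(lv[comp], levels = lv))
}

#' Write model curves as CSV
#'
#' @param curves a `component_curves` object.
#' @param path output path (columns `bin_center`, `g1`, `g2`, `wm`,
#'   `gm_total`, `whole`).
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  utils::write.csv(
    data.frame(bin_center = curves$bin_centers, g1 = curves$g1,
               g2 = curves$g2, wm = curves$wm, gm_total = curves$gm_total,
               whole = curves$whole),
    path, row.names = FALSE)
  invisible(path)
}

#' Count local maxima of a curve
#'
#' Bimodality probe for model or histogram curves: counts strict local
#' maxima exceeding `floor_frac` of the curve's peak (plateaus count once).
#'
#' @param y non-negative numeric curve (e.g. `gm_total` from
#'   [expected_curves()]).
#' @param floor_frac ignore maxima below this fraction of the global peak.
#' @return Integer number of modes.
#' @export
count_local_maxima <- function(y, floor_frac = 0.01) {
  floor_val <- floor_frac * max(y)
  n <- length(y)
  if (n < 3) return(as.integer(max(y) > 0))
  k <- 0L
  i <- 2L
  while (i < n) {
    if (y[i] > floor_val && y[i] > y[i - 1] && y[i] >= y[i + 1]) {
      # flat-top plateau counts once
      j <- i
      while (j < n && y[j + 1] == y[i]) j <- j + 1L
      if (j == n || y[j + 1] < y[i]) k <- k + 1L
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  k
}
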