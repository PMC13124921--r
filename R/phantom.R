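# Seeded 3-D brain-like phantom realizing a three_component_spec: an
# ellipsoidal cerebrum (WM core + GM shell whose volumes follow the 57/43
# parenchyma split), a small cerebellar reference compartment held at
# SUVR 1, contiguous amyloid (G2) patches in the cortex, PET-like Gaussian
# smoothing and additive noise, and blurred-indicator probability maps.
# Everything downstream of a PhantomSpec + ThreeComponentSpec is
# reproducible from the seed.

#' Phantom specification
#'
#' Geometry is scaled to the field of view, so any grid respecting
#' `grid_dims >= 16` per axis yields the same brain-shaped layout. The GM
#' shell is made ~7-9 mm thick — thicker than real cortex — so that
#' >60%-purity GM voxels survive 6 mm PET smoothing; this is a deliberate
#' idealization (see the package vignette).
#'
#' @param grid_dims integer triple, default `c(72, 80, 46)`.
#' @param voxel_size_mm default `c(2.3, 2.3, 4.0)` (PET-typical, anisotropic).
#' @param probability_blur_fwhm_mm blur applied to tissue indicator
#'   functions to emulate probabilistic segmentation maps; the default is
#'   chosen so the >60% purity threshold selects mid-shell voxels only.
#' @param pet_smoothing_fwhm_mm trans-axial (x, y) scanner-resolution
#'   Gaussian applied to the SUV volume, default 6 mm.
#' @param noise_sd additive Gaussian noise SD on the SUVR scale (multiplied
#'   by `suv_scale` in SUV units) after smoothing, default 0.05.
#' @param suv_scale SUV value corresponding to SUVR 1 (exercises SUVR
#'   normalization), default 1.0.
#' @param csf_suvr SUVR level of the CSF rim surrounding the brain,
#'   default 0.30 (low but non-zero tracer content).
#' @param n_g2_patches number of contiguous cortical G2 patch seeds,
#'   default 6.
#' @param seed integer seed.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(72L, 80L, 46L),
                         voxel_size_mm = c(2.3, 2.3, 4.0),
                         probability_blur_fwhm_mm = 14.0,
                         pet_smoothing_fwhm_mm = 6.0,
                         noise_sd = 0.05,
                         suv_scale = 1.0,
                         csf_suvr = 0.30,
                         n_g2_patches = 6L,
                         seed = 1L) {
  if (csf_suvr < 0) stop("`csf_suvr` must be >= 0", call. = FALSE)
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 16L))
    stop("`grid_dims` must be 3 integers >= 16", call. = FALSE)
  if (any(voxel_size_mm <= 0)) stop("voxel size must be positive", call. = FALSE)
  if (probability_blur_fwhm_mm < 0 || pet_smoothing_fwhm_mm < 0 ||
      noise_sd < 0)
    stop("FWHMs and noise_sd must be >= 0", call. = FALSE)
  if (suv_scale <= 0) stop("`suv_scale` must be positive", call. = FALSE)
  structure(
    list(grid_dims = grid_dims, voxel_size_mm = as.numeric(voxel_size_mm),
         probability_blur_fwhm_mm = probability_blur_fwhm_mm,
         pet_smoothing_fwhm_mm = pet_smoothing_fwhm_mm,
         noise_sd = noise_sd, suv_scale = suv_scale, csf_suvr = csf_suvr,
         n_g2_patches = as.integer(n_g2_patches), seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Normalized coordinates u in [-1, 1]^3 over the field of view.
.phantom_coords <- function(pspec) {
  d <- pspec$grid_dims
  vs <- pspec$voxel_size_mm
  half <- d * vs / 2
  ax <- lapply(1:3, function(k) ((seq_len(d[k]) - 0.5) * vs[k] - half[k]) / half[k])
  list(
    x = array(rep(ax[[1]], times = d[2] * d[3]), dim = d),
    y = array(rep(rep(ax[[2]], each = d[1]), times = d[3]), dim = d),
    z = array(rep(ax[[3]], each = d[1] * d[2]), dim = d),
    half_mm = half
  )
}

.inside_ellipsoid <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 < 1
}

#' Generate a brain phantom
#'
#' Builds SUV, GM/WM probability and label volumes realizing `tspec` on the
#' grid described by `pspec`, together with the ground truth needed by
#' round-trip tests. Cortical G2 voxels form contiguous patches grown
#' around seeded centers until the planted `piG2` share of the shell is
#' reached; the cerebellar compartment is drawn at SUVR 1 (times
#' `suv_scale`) so the SUVR normalization truth is known by construction.
#'
#' @param pspec a [phantom_spec].
#' @param tspec a [three_component_spec].
#' @param sigma_ref SD of the cerebellar reference values (SUVR), default
#'   0.05.
#' @return List: `suv`, `p_gm`, `p_wm` ([scalar_volume]s), `labels`
#'   (label volume: 0 background, 1 cerebellum, 2-6 cortical composite
#'   sectors, 7 WM core), and `truth` (a `phantom_truth`: specs, per-voxel
#'   component assignment, planted counts, reference mean, expected
#'   ComSUVR and the GM-mask-diluted piG2).
#' @export
generate_phantom <- function(pspec, tspec, sigma_ref = 0.05) {
  if (!inherits(pspec, "phantom_spec")) stop("`pspec` must be a phantom_spec",
                                             call. = FALSE)
  if (!inherits(tspec, "three_component_spec"))
    stop("`tspec` must be a three_component_spec", call. = FALSE)
  d <- pspec$grid_dims
  co <- .phantom_coords(pspec)
  wm_scale <- tspec$wm_fraction^(1 / 3)

  cerebrum <- .inside_ellipsoid(co, c(0, 0.05, 0.18), c(0.84, 0.86, 0.64))
  core <- .inside_ellipsoid(co, c(0, 0.05, 0.18),
                            c(0.84, 0.86, 0.64) * wm_scale)
  shell <- cerebrum & !core
  # cerebellar compartment large enough that its interior survives PET
  # smoothing; the reference ROI is the interior core (atlas ROIs sit
  # inside the structure), so the reference mean is not eroded by the
  # surrounding cold background
  cb_center <- c(0, -0.45, -0.62)
  cb_semi <- c(0.46, 0.40, 0.28)
  cereb <- .inside_ellipsoid(co, cb_center, cb_semi) & !cerebrum
  ref_core <- .inside_ellipsoid(co, cb_center, cb_semi * 0.65) & !cerebrum
  if (!any(shell)) stop("phantom geometry yields an empty GM shell",
                        call. = FALSE)
  if (!any(ref_core)) stop("phantom geometry yields an empty reference",
                           call. = FALSE)

  rng <- .seeded_rng(pspec$seed)

  # contiguous G2 patches: grow around seed centers by mm distance until
  # the planted piG2 share of shell voxels is reached
  shell_idx <- which(shell)
  n_shell <- length(shell_idx)
  n_g2 <- round(tspec$piG2 * n_shell)
  g2 <- logical(length(cerebrum))
  if (n_g2 > 0) {
    seeds <- shell_idx[rng$int(pspec$n_g2_patches, n_shell)]
    px <- co$x[shell_idx] * co$half_mm[1]
    py <- co$y[shell_idx] * co$half_mm[2]
    pz <- co$z[shell_idx] * co$half_mm[3]
    dmin <- rep(Inf, n_shell)
    for (s in seeds) {
      sx <- co$x[s] * co$half_mm[1]; sy <- co$y[s] * co$half_mm[2]
      sz <- co$z[s] * co$half_mm[3]
      dmin <- pmin(dmin, (px - sx)^2 + (py - sy)^2 + (pz - sz)^2)
    }
    g2[shell_idx[order(dmin)[seq_len(n_g2)]]] <- TRUE
  }

  # component assignment: 0 bg, 1 G1 shell, 2 G2 shell, 3 WM core, 4 reference
  assign <- array(0L, dim = d)
  assign[shell] <- 1L
  assign[g2] <- 2L
  assign[core] <- 3L
  assign[cereb] <- 4L
  # CSF rim around brain and cerebellum: low but non-zero tracer content,
  # excluded from the tissue maps (its job is realistic partial-volume
  # behaviour at the cortical surface, not histogram mass)
  csf <- (.inside_ellipsoid(co, c(0, 0.05, 0.18), c(0.84, 0.86, 0.64) * 1.15) |
            .inside_ellipsoid(co, cb_center, cb_semi * 1.25)) &
    assign == 0L
  assign[csf] <- 5L

  nvox <- prod(d)
  suvr_true <- array(0, dim = d)
  draw <- function(sel, mu, sigma)
    if (any(sel)) suvr_true[sel] <<- rng$norm(sum(sel), mu, sigma)
  draw(assign == 1L, tspec$muG1, tspec$sigmaG1)
  draw(assign == 2L, tspec$muG2, tspec$sigmaG2)
  draw(assign == 3L, tspec$muW, tspec$sigmaW)
  draw(assign == 4L, 1.0, sigma_ref)
  draw(assign == 5L, pspec$csf_suvr, sigma_ref)

  suv <- suvr_true * pspec$suv_scale
  suv_vol <- scalar_volume(suv, pspec$voxel_size_mm, kind = "suv")
  # PET reconstruction blur is applied in the trans-axial plane (x, y),
  # matching how the emulated acquisition chain describes its Gaussian
  # post-filter; axial resolution is left at the voxel sampling
  if (pspec$pet_smoothing_fwhm_mm > 0)
    suv_vol <- gaussian_smooth(suv_vol, c(pspec$pet_smoothing_fwhm_mm,
                                          pspec$pet_smoothing_fwhm_mm, 0))
  if (pspec$noise_sd > 0) {
    # noise_sd is stated on the SUVR scale; scale with suv_scale so SUVR
    # images are invariant to the injected-dose scale factor
    noisy <- suv_vol$data +
      array(rng$norm(nvox, 0, pspec$noise_sd * pspec$suv_scale), dim = d)
    suv_vol <- scalar_volume(noisy, pspec$voxel_size_mm,
                             affine = suv_vol$affine, kind = "suv")
  }

  # cerebellar cortex folia are thin relative to PET resolution, so the
  # compartment is modelled as mixed tissue (0.5 GM / 0.5 WM): it joins the
  # parenchyma (>50%) mask but neither pure-tissue (>60%) mask
  blur_prob <- function(ind) {
    v <- scalar_volume(array(as.double(ind), dim = d), pspec$voxel_size_mm,
                       kind = "probability")
    if (pspec$probability_blur_fwhm_mm > 0)
      v <- gaussian_smooth(v, pspec$probability_blur_fwhm_mm)
    scalar_volume(pmin(pmax(v$data, 0), 1), pspec$voxel_size_mm,
                  affine = v$affine, kind = "probability")
  }
  p_gm <- blur_prob((shell | cereb) - 0.5 * cereb)
  p_wm <- blur_prob(core + 0.5 * cereb)

  # labels: 1 cerebellar reference core; 2-6 cortical sectors by azimuth
  # (the composite "regions"); 7 WM core; 8 peripheral cerebellum
  labels <- array(0L, dim = d)
  labels[cereb] <- 8L
  labels[ref_core] <- 1L
  theta <- atan2(co$y[shell_idx], co$x[shell_idx])
  sector <- pmin(floor((theta + pi) / (2 * pi) * 5), 4)
  labels[shell_idx] <- 2L + as.integer(sector)
  labels[core] <- 7L
  labels_vol <- scalar_volume(array(as.double(labels), dim = d),
                              pspec$voxel_size_mm, kind = "label")

  # planted (pre-smoothing) regional means -> expected ComSUVR
  reg_means <- vapply(2:6, function(l) mean(suvr_true[labels == l]),
                      numeric(1))
  truth <- structure(
    list(phantom_spec = pspec, model_spec = tspec, assignment = assign,
         n_shell = n_shell, n_g2 = n_g2, n_core = sum(core),
         n_reference = sum(ref_core),
         reference_mean_suv = mean(suv[ref_core]),
         expected_com_suvr = mean(reg_means),
         expected_gm_mask_piG2 = n_g2 / n_shell),
    class = "phantom_truth"
  )
  list(suv = suv_vol, p_gm = p_gm, p_wm = p_wm, labels = labels_vol,
       truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> shell %d (G2 %d), core %d, reference %d voxels\n",
    x$n_shell, x$n_g2, x$n_core, x$n_reference))
  cat(sprintf("  expected ComSUVR %.4f, GM-mask piG2 %.4f\n",
              x$expected_com_suvr, x$expected_gm_mask_piG2))
  invisible(x)
}

#' Write phantom volumes to a directory
#'
#' Writes `suv.nii.gz`, `p_gm.nii.gz`, `p_wm.nii.gz`, `labels.nii.gz` and
#' `truth.json` (scalar truth fields only).
#'
#' @param phantom list returned by [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_nifti(phantom$suv, file.path(dir, "suv.nii.gz"))
  write_nifti(phantom$p_gm, file.path(dir, "p_gm.nii.gz"))
  write_nifti(phantom$p_wm, file.path(dir, "p_wm.nii.gz"))
  write_nifti(phantom$labels, file.path(dir, "labels.nii.gz"))
  tr <- phantom$truth
  jsonlite::write_json(
    list(n_shell = tr$n_shell, n_g2 = tr$n_g2, n_core = tr$n_core,
         n_reference = tr$n_reference,
         reference_mean_suv = tr$reference_mean_suv,
         expected_com_suvr = tr$expected_com_suvr,
         expected_gm_mask_piG2 = tr$expected_gm_mask_piG2,
         model_spec = unclass(tr$model_spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
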