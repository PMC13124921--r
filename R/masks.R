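# Voxel-selection rules deriving analysis masks from probabilistic tissue
# maps. Comparisons are strict (>): boundary voxels are excluded, matching
# the "exceeded" / "greater than" inclusion rules.

#' Parenchyma mask from GM + WM probability maps
#'
#' A voxel belongs to the brain parenchyma when the sum of its gray- and
#' white-matter probabilities strictly exceeds `threshold` (default 50%).
#' This excludes CSF space, where both tissue probabilities are low.
#'
#' @param p_gm,p_wm probability [scalar_volume]s on a common grid.
#' @param threshold inclusion threshold on `p_gm + p_wm`, default 0.5.
#' @return A [binary_mask].
#' @export
make_parenchyma_mask <- function(p_gm, p_wm, threshold = 0.5) {
  for (p in list(p_gm, p_wm)) {
    if (!inherits(p, "scalar_volume") || p$kind != "probability")
      stop("inputs must be probability scalar_volumes", call. = FALSE)
  }
  stopifnot_same_grid(p_gm, p_wm, "probability maps")
  binary_mask(p_gm$data + p_wm$data > threshold)
}

#' Single-tissue mask from a probability map
#'
#' A voxel is kept when its tissue probability strictly exceeds `threshold`
#' (default 60%). Used for both the GM-map and the WM-map; the high purity
#' threshold keeps the GM/WM boundary (where PET resolution mixes the two
#' tissues) out of the separated histograms.
#'
#' @param p probability [scalar_volume].
#' @param threshold inclusion threshold in \[0, 1\], default 0.6.
#' @return A [binary_mask].
#' @export
make_tissue_mask <- function(p, threshold = 0.6) {
  if (!inherits(p, "scalar_volume") || p$kind != "probability")
    stop("`p` must be a probability scalar_volume", call. = FALSE)
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  binary_mask(p$data > threshold)
}

#' Mask from a set of region labels
#'
#' @param labels label [scalar_volume].
#' @param which_labels integer vector of label values to select.
#' @return A [binary_mask] of voxels carrying any of the labels.
#' @export
make_label_mask <- function(labels, which_labels) {
  if (!inherits(labels, "scalar_volume") || labels$kind != "label")
    stop("`labels` must be a label scalar_volume", call. = FALSE)
  binary_mask(array(labels$data %in% which_labels, dim = dim(labels$data)))
}
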