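# SUVR normalization against the cerebellar-cortex reference and the
# composite cortical SUVR (ComSUVR) used as the amyloid-burden index.

#' Normalize an SUV volume to SUVR
#'
#' Divides the volume by the arithmetic mean of its values over the
#' reference mask (cerebellar cortex), so the reference region has mean
#' SUVR 1 by construction.
#'
#' @param suv an `"suv"` (or `"suvr"`) [scalar_volume].
#' @param reference_mask non-empty [binary_mask] on the same grid.
#' @return An `"suvr"` [scalar_volume].
#' @export
compute_suvr <- function(suv, reference_mask) {
  if (!inherits(suv, "scalar_volume"))
    stop("`suv` must be a scalar_volume", call. = FALSE)
  if (!inherits(reference_mask, "binary_mask"))
    stop("`reference_mask` must be a binary_mask", call. = FALSE)
  if (reference_mask$voxel_count == 0L)
    stop("reference mask is empty", call. = FALSE)
  ref_mean <- mean(masked_values(suv, reference_mask))
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference region mean must be positive", call. = FALSE)
  scalar_volume(suv$data / ref_mean, voxel_size_mm = suv$voxel_size_mm,
                affine = suv$affine, kind = "suvr")
}

#' Region scheme: labels, reference set, composite set
#'
#' Maps integer region labels to names and declares which named regions form
#' the cerebellar reference and which form the neocortical composite
#' (frontal, posterior cingulate, precuneus, parietal, lateral temporal).
#' Left/right homologues are expected to be merged under one name by
#' listing both labels.
#'
#' @param label_to_name named list: region name -> integer label vector.
#' @param reference_regions character vector of reference region names.
#' @param composite_regions character vector of composite region names.
#' @return A `region_scheme` object.
#' @export
region_scheme <- function(label_to_name, reference_regions,
                          composite_regions) {
  if (length(reference_regions) == 0L || length(composite_regions) == 0L)
    stop("reference and composite region sets must be non-empty",
         call. = FALSE)
  if (length(intersect(reference_regions, composite_regions)) > 0L)
    stop("reference and composite region sets must be disjoint",
         call. = FALSE)
  known <- names(label_to_name)
  missing <- setdiff(c(reference_regions, composite_regions), known)
  if (length(missing) > 0L)
    stop(sprintf("regions without labels: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  label_to_name <- lapply(label_to_name, function(v) as.integer(v))
  structure(
    list(label_to_name = label_to_name,
         reference_regions = as.character(reference_regions),
         composite_regions = as.character(composite_regions)),
    class = "region_scheme"
  )
}

#' Read a region scheme from JSON
#'
#' Expected shape:
#' `{"labels": {"frontal": [2], ...}, "reference": ["cerebellum"],
#'   "composite": ["frontal", ...]}`
#'
#' @param path JSON file path.
#' @return A [region_scheme].
#' @export
read_region_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.list(x$labels)
  region_scheme(labels, x$reference, x$composite)
}

#' Default phantom region scheme
#'
#' Matches the label layout written by [generate_phantom()]: label 1 is the
#' cerebellar reference; labels 2-6 are the five composite cortical regions.
#'
#' @return A [region_scheme].
#' @export
default_region_scheme <- function() {
  region_scheme(
    label_to_name = list(
      cerebellum = 1L, frontal = 2L, posterior_cingulate = 3L,
      precuneus = 4L, parietal = 5L, lateral_temporal = 6L),
    reference_regions = "cerebellum",
    composite_regions = c("frontal", "posterior_cingulate", "precuneus",
                          "parietal", "lateral_temporal")
  )
}

#' Mean regional SUVR per named region
#'
#' @param suvr an `"suvr"` [scalar_volume].
#' @param labels a `"label"` [scalar_volume] on the same grid.
#' @param scheme a [region_scheme].
#' @return Data frame with columns `region`, `rsuvr`, `voxel_count`.
#'   Reference and composite regions must be non-empty; other scheme regions
#'   are included when present.
#' @export
regional_suvr <- function(suvr, labels, scheme) {
  if (!inherits(labels, "scalar_volume") || labels$kind != "label")
    stop("`labels` must be a label scalar_volume", call. = FALSE)
  stopifnot_same_grid(suvr, labels, "SUVR and label volumes")
  required <- c(scheme$reference_regions, scheme$composite_regions)
  rows <- lapply(names(scheme$label_to_name), function(nm) {
    sel <- labels$data %in% scheme$label_to_name[[nm]]
    n <- sum(sel)
    if (n == 0L) {
      if (nm %in% required)
        stop(sprintf("region '%s' has no voxels", nm), call. = FALSE)
      return(NULL)
    }
    data.frame(region = nm, rsuvr = mean(suvr$data[sel]), voxel_count = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Composite SUVR (ComSUVR)
#'
#' Unweighted mean of the composite regions' mean regional SUVRs. A
#' voxel-weighted variant (weights proportional to region voxel counts) is
#' available via `weighted = TRUE`.
#'
#' @param table data frame from [regional_suvr()].
#' @param scheme a [region_scheme].
#' @param weighted if `TRUE`, weight regions by voxel count.
#' @return Scalar ComSUVR.
#' @export
com_suvr <- function(table, scheme, weighted = FALSE) {
  rows <- table[table$region %in% scheme$composite_regions, , drop = FALSE]
  missing <- setdiff(scheme$composite_regions, rows$region)
  if (length(missing) > 0L)
    stop(sprintf("composite regions missing from table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (weighted) {
    sum(rows$rsuvr * rows$voxel_count) / sum(rows$voxel_count)
  } else {
    mean(rows$rsuvr)
  }
}
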