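#' 3-D scalar volume
#'
#' Lightweight container for a 3-D image: a numeric array plus voxel geometry
#' and a `kind` tag describing what the values mean. All pipeline stages pass
#' these around; NIfTI files are read into / written from them.
#'
#' @param data 3-D numeric array of finite values.
#' @param voxel_size_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices). If
#'   `NULL`, a diagonal affine from `voxel_size_mm` is used.
#' @param kind one of `"suv"`, `"suvr"`, `"probability"`, `"label"`.
#'   Probability volumes must lie in \[0, 1\]; label volumes must hold
#'   non-negative integers.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, voxel_size_mm = c(1, 1, 1), affine = NULL,
                          kind = c("suv", "suvr", "probability", "label")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive numbers", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  if (kind == "probability" &&
      (min(data) < -1e-9 || max(data) > 1 + 1e-9))
    stop("probability volume has values outside [0, 1]", call. = FALSE)
  if (kind == "label") {
    if (any(data < 0) || any(abs(data - round(data)) > 1e-9))
      stop("label volume must contain non-negative integers", call. = FALSE)
    data <- round(data)
  }
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, affine = affine,
         kind = kind),
    class = "scalar_volume"
  )
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume %s> %d x %d x %d, voxel %.3g x %.3g x %.3g mm\n",
              x$kind, d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

# Grid equality: same dims and affines agreeing to `tol` mm.
same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  invisible(TRUE)
}

#' Binary voxel mask
#'
#' @param data 3-D logical array.
#' @return Object of class `binary_mask` with fields `data`, `source_shape`,
#'   `voxel_count`.
#' @export
binary_mask <- function(data) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data)) stop("mask contains NA", call. = FALSE)
  structure(
    list(data = data, source_shape = dim(data),
         voxel_count = sum(data)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- x$source_shape
  cat(sprintf("<binary_mask> %d x %d x %d, %d voxels set\n",
              d[1], d[2], d[3], x$voxel_count))
  invisible(x)
}

# Extract masked voxel values as a numeric vector.
masked_values <- function(volume, mask) {
  if (!identical(dim(volume$data), mask$source_shape))
    stop("mask shape does not match volume", call. = FALSE)
  volume$data[mask$data]
}
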