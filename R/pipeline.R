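# Per-subject orchestration: SUVR normalization -> upsampling -> masks ->
# histograms -> descriptive parameters -> mixture fits -> subject record;
# plus cohort-level Spearman correlation reporting.

#' Pipeline configuration
#'
#' Every threshold, factor and seed of the per-subject pipeline, embedded
#' in each record for provenance.
#'
#' @param upsample_factor integer upsampling factor, default 2.
#' @param upsample_method interpolation for the SUVR/probability volumes.
#' @param parenchyma_threshold GM+WM inclusion threshold, default 0.5.
#' @param tissue_threshold GM / WM purity threshold, default 0.6.
#' @param bin_width histogram bin width (SUVR), default 0.05.
#' @param kurtosis_formula `"standard"` or `"printed"`.
#' @param fit_binned fit the mixture on binned counts instead of raw voxel
#'   values, default `FALSE`.
#' @param n_restarts,em_tol,em_max_iter,sigma_floor,degenerate_delta EM
#'   settings, see [fit_two_gaussians()].
#' @param com_suvr_weighted voxel-weighted ComSUVR variant, default `FALSE`.
#' @param exclude_labels optional label values masked out of the
#'   parenchyma/GM/WM masks (e.g. a cerebellum label), default none.
#' @param seed integer seed for the EM restarts.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(upsample_factor = 2L,
                            upsample_method = "cubic",
                            parenchyma_threshold = 0.5,
                            tissue_threshold = 0.6,
                            bin_width = 0.05,
                            kurtosis_formula = "standard",
                            fit_binned = FALSE,
                            n_restarts = 4L, em_tol = 1e-8,
                            em_max_iter = 500L, sigma_floor = 0.025,
                            degenerate_delta = 0.10,
                            com_suvr_weighted = FALSE,
                            exclude_labels = integer(0),
                            seed = 1L) {
  structure(
    list(upsample_factor = as.integer(upsample_factor),
         upsample_method = upsample_method,
         parenchyma_threshold = parenchyma_threshold,
         tissue_threshold = tissue_threshold,
         bin_width = bin_width, kurtosis_formula = kurtosis_formula,
         fit_binned = fit_binned, n_restarts = as.integer(n_restarts),
         em_tol = em_tol, em_max_iter = as.integer(em_max_iter),
         sigma_floor = sigma_floor, degenerate_delta = degenerate_delta,
         com_suvr_weighted = com_suvr_weighted,
         exclude_labels = as.integer(exclude_labels),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

.config_digest <- function(config) {
  flat <- unclass(config)
  paste(names(flat),
        vapply(flat, function(v) paste(format(v, digits = 15),
                                       collapse = ","), character(1)),
        sep = "=", collapse = ";")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Evaluate one subject from in-memory volumes
#'
#' Runs the full histogram pipeline on co-registered volumes. Stages:
#' SUVR normalization against the scheme's reference region, regional
#' SUVR / ComSUVR on the native grid, upsampling, parenchyma (>50%) and
#' GM/WM (>60%) masks, 0.05-bin histograms, whole-brain descriptive
#' parameters, GM two-Gaussian decomposition, WM Gaussian fit.
#'
#' @param suv `"suv"` or `"suvr"` [scalar_volume].
#' @param p_gm,p_wm probability [scalar_volume]s on the same grid.
#' @param labels label [scalar_volume] (reference + composite regions).
#' @param scheme a [region_scheme].
#' @param config a [pipeline_config].
#' @param subject_id identifier carried into the record.
#' @return A `subject_record` list (see package vignette).
#' @export
evaluate_subject_volumes <- function(suv, p_gm, p_wm, labels,
                                     scheme = default_region_scheme(),
                                     config = pipeline_config(),
                                     subject_id = "subject") {
  warnings_seen <- character(0)
  note <- function(w) warnings_seen <<- c(warnings_seen, w)

  ref_labels <- unlist(scheme$label_to_name[scheme$reference_regions])
  suvr <- .stage("suvr", {
    ref_mask <- make_label_mask(labels, ref_labels)
    compute_suvr(suv, ref_mask)
  })
  com <- .stage("com_suvr", {
    tab <- regional_suvr(suvr, labels, scheme)
    com_suvr(tab, scheme, weighted = config$com_suvr_weighted)
  })

  up <- .stage("upsample", {
    if (length(config$exclude_labels) > 0) {
      drop <- labels$data %in% config$exclude_labels
      p_gm <- scalar_volume(ifelse(drop, 0, p_gm$data), p_gm$voxel_size_mm,
                            p_gm$affine, kind = "probability")
      p_wm <- scalar_volume(ifelse(drop, 0, p_wm$data), p_wm$voxel_size_mm,
                            p_wm$affine, kind = "probability")
    }
    list(
      suvr = resample_upsample(suvr, config$upsample_factor,
                               config$upsample_method),
      p_gm = resample_upsample(p_gm, config$upsample_factor,
                               config$upsample_method),
      p_wm = resample_upsample(p_wm, config$upsample_factor,
                               config$upsample_method))
  })

  masks <- .stage("masks", list(
    parenchyma = make_parenchyma_mask(up$p_gm, up$p_wm,
                                      config$parenchyma_threshold),
    gm = make_tissue_mask(up$p_gm, config$tissue_threshold),
    wm = make_tissue_mask(up$p_wm, config$tissue_threshold)))

  hists <- .stage("histograms", list(
    whole = build_histogram(up$suvr, masks$parenchyma, config$bin_width,
                            source = "whole"),
    gm = build_histogram(up$suvr, masks$gm, config$bin_width, source = "gm"),
    wm = build_histogram(up$suvr, masks$wm, config$bin_width, source = "wm")))

  whole_params <- .stage("descriptive", descriptive_params(
    up$suvr, masks$parenchyma, hists$whole,
    kurtosis_formula = config$kurtosis_formula))

  gm_values <- masked_values(up$suvr, masks$gm)
  gm_kurtosis <- .stage("gm_kurtosis", sample_excess_kurtosis(
    gm_values, formula = config$kurtosis_formula))

  mixture <- .stage("gm_mixture", withCallingHandlers(
    {
      if (config$fit_binned) {
        fit_two_gaussians(hists$gm, n_restarts = config$n_restarts,
                          tol = config$em_tol,
                          max_iter = config$em_max_iter,
                          sigma_floor = config$sigma_floor,
                          degenerate_delta = config$degenerate_delta,
                          seed = config$seed)
      } else {
        fit_two_gaussians(gm_values, n_restarts = config$n_restarts,
                          tol = config$em_tol,
                          max_iter = config$em_max_iter,
                          sigma_floor = config$sigma_floor,
                          degenerate_delta = config$degenerate_delta,
                          seed = config$seed)
      }
    },
    warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    }))
  if (mixture$degenerate)
    note("degenerate mixture fit: piG2 unreliable (muG2 - muG1 below delta)")

  wm_fit <- .stage("wm_fit", fit_wm_gaussian(masked_values(up$suvr, masks$wm)))

  structure(
    list(subject_id = subject_id,
         com_suvr = com,
         whole = whole_params,
         gm_kurtosis = gm_kurtosis,
         mixture = mixture,
         wm = wm_fit,
         mask_voxel_counts = list(
           parenchyma = masks$parenchyma$voxel_count,
           gm = masks$gm$voxel_count,
           wm = masks$wm$voxel_count),
         config_digest = .config_digest(config),
         warnings = warnings_seen),
    class = "subject_record"
  )
}

#' Evaluate one subject from NIfTI files
#'
#' File-path front end to [evaluate_subject_volumes()].
#'
#' @param pet_path SUV (or SUVR) NIfTI path.
#' @param p_gm_path,p_wm_path tissue-probability NIfTI paths.
#' @param labels_path region-label NIfTI path.
#' @param scheme a [region_scheme] or path to a scheme JSON.
#' @param config a [pipeline_config].
#' @param subject_id identifier, defaults to the PET file stem.
#' @return A `subject_record`.
#' @export
evaluate_subject <- function(pet_path, p_gm_path, p_wm_path, labels_path,
                             scheme = default_region_scheme(),
                             config = pipeline_config(),
                             subject_id = NULL) {
  for (p in c(pet_path, p_gm_path, p_wm_path, labels_path)) {
    if (!file.exists(p))
      stop(sprintf("input file not found: %s", p), call. = FALSE)
  }
  if (is.character(scheme)) scheme <- read_region_scheme(scheme)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(pet_path))
  suv <- .stage("read_pet", read_nifti(pet_path, kind = "suv"))
  p_gm <- .stage("read_p_gm", read_nifti(p_gm_path, kind = "probability"))
  p_wm <- .stage("read_p_wm", read_nifti(p_wm_path, kind = "probability"))
  labels <- .stage("read_labels", read_nifti(labels_path, kind = "label"))
  evaluate_subject_volumes(suv, p_gm, p_wm, labels, scheme, config,
                           subject_id)
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s\n", x$subject_id))
  cat(sprintf("  ComSUVR %.4f | skewness %.4f MMR %.4f | GM-kurtosis %.4f\n",
              x$com_suvr, x$whole$skewness, x$whole$mmr, x$gm_kurtosis))
  cat(sprintf("  muG1 %.4f muG2 %.4f piG2 %.4f%s | muW %.4f\n",
              x$mixture$muG1, x$mixture$muG2, x$mixture$piG2,
              if (x$mixture$degenerate) " (degenerate)" else "",
              x$wm$muW))
  invisible(x)
}

# Flatten a record for serialization / tabulation.
record_parameters <- function(record) {
  c(com_suvr = record$com_suvr,
    skewness = record$whole$skewness,
    mmr = record$whole$mmr,
    mean = record$whole$mean,
    mode = record$whole$mode,
    gm_kurtosis = record$gm_kurtosis,
    muG1 = record$mixture$muG1,
    muG2 = record$mixture$muG2,
    piG2 = record$mixture$piG2,
    muW = record$wm$muW)
}

#' Write / read a subject record as JSON
#'
#' Round-trips all scalar fields losslessly (`digits = NA`); the EM
#' log-likelihood trace is dropped.
#'
#' @param record a `subject_record`.
#' @param path JSON path.
#' @return `path` (write) / a `subject_record` (read).
#' @export
write_subject_record <- function(record, path) {
  out <- unclass(record)
  out$mixture <- unclass(out$mixture)
  out$mixture$loglik_trace <- NULL
  out$wm <- unclass(out$wm)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_subject_record
#' @export
read_subject_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mixture <- structure(x$mixture, class = "mixture_fit")
  x$wm <- structure(x$wm, class = "wm_fit")
  x$warnings <- as.character(x$warnings)
  structure(x, class = "subject_record")
}

#' Cohort-level correlations against ComSUVR
#'
#' Spearman rank correlation of each histogram parameter against ComSUVR,
#' with the R^2 of the ordinary-least-squares line and a p-value (exact
#' permutation distribution for n <= 9, t-approximation otherwise).
#' Constant parameters yield an NA row flagged in `note`.
#'
#' @param records list of `subject_record`s (>= 3).
#' @param parameters parameter names from the record flattening (default:
#'   skewness, mmr, gm_kurtosis, muG1, muG2, piG2, muW).
#' @return Data frame: `parameter`, `rho`, `r_squared`, `p_value`, `n`,
#'   `note`.
#' @export
cohort_correlations <- function(records,
                                parameters = c("skewness", "mmr",
                                               "gm_kurtosis", "muG1",
                                               "muG2", "piG2", "muW")) {
  if (length(records) < 3L)
    stop("need at least 3 records", call. = FALSE)
  mat <- t(vapply(records, record_parameters, record_parameters(records[[1]])))
  com <- mat[, "com_suvr"]
  rows <- lapply(parameters, function(p) {
    v <- mat[, p]
    if (anyNA(v) || anyNA(com))
      stop(sprintf("missing values for parameter '%s'", p), call. = FALSE)
    if (stats::sd(v) == 0 || stats::sd(com) == 0) {
      return(data.frame(parameter = p, rho = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n = length(v), note = "constant parameter",
                        stringsAsFactors = FALSE))
    }
    rho <- stats::cor(v, com, method = "spearman")
    fit <- stats::lm(com ~ v)
    r2 <- summary(fit)$r.squared
    pv <- .spearman_p(v, com, rho)
    data.frame(parameter = p, rho = rho, r_squared = r2, p_value = pv,
               n = length(v), note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Two-sided Spearman p: exact permutation for n <= 9, else t-approximation.
.spearman_p <- function(x, y, rho) {
  n <- length(x)
  if (n <= 9) {
    perms <- .permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2 + 1e-300))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
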