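# AUC, noise, aSNR, SNR-masked ratio, and tied-rank percentile maps.

#' Area-under-the-dynamic-curve (AUC) map
#'
#' Temporally sums a dynamic 4D metabolite image into a 3D AUC map.
#'
#' @param dynamic 4D array (x-y-z-t) with at least one timepoint.
#' @return 3D numeric array of voxel-wise temporal sums.
#' @export
compute_auc <- function(dynamic) {
  dims <- dim(dynamic)
  if (length(dims) != 4 || dims[4] < 1)
    stop("dynamic must be a 4D array with >= 1 timepoint", call. = FALSE)
  out <- rowSums(matrix(dynamic, nrow = prod(dims[1:3]), ncol = dims[4]))
  array(out, dims[1:3])
}

#' Estimate the noise standard deviation from the image background
#'
#' Pools every non-brain voxel sample across all timepoints and returns
#' their standard deviation. Requires at least 100 background voxels for
#' a stable estimate.
#'
#' @param dynamic 4D array (x-y-z-t).
#' @param brain_mask Logical 3D array on the same spatial grid; the
#'   background is its complement.
#' @return Scalar noise sd in signal units.
#' @export
estimate_noise_sigma <- function(dynamic, brain_mask) {
  dims <- dim(dynamic)
  if (!identical(dim(brain_mask), dims[1:3]))
    stop("brain_mask does not match the image grid", call. = FALSE)
  bg <- which(!brain_mask)
  if (length(bg) < 100)
    stop("insufficient background (< 100 voxels) for noise estimation",
         call. = FALSE)
  samples <- matrix(dynamic, nrow = prod(dims[1:3]), ncol = dims[4])[bg, ]
  stats::sd(samples)
}

#' Apparent signal-to-noise ratio map
#'
#' aSNR of an AUC map given the per-timepoint noise sd: the AUC of T
#' i.i.d. noisy samples has noise sd `sigma * sqrt(T)`, so
#' `aSNR = AUC / (sigma * sqrt(T))`.
#'
#' @param auc 3D AUC map.
#' @param sigma Per-timepoint noise sd (> 0), e.g. from
#'   [estimate_noise_sigma()].
#' @param n_timepoints Number of summed timepoints.
#' @return 3D aSNR map.
#' @export
compute_asnr <- function(auc, sigma, n_timepoints) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  auc / (sigma * sqrt(n_timepoints))
}

#' Threshold an aSNR map into an SNR mask
#'
#' Keeps voxels with aSNR at or above `threshold`; voxels with aSNR
#' strictly below it are filtered out (the boundary value passes).
#'
#' @param asnr 3D aSNR map.
#' @param threshold Minimum aSNR to keep (default 5).
#' @return Logical 3D mask.
#' @export
snr_mask <- function(asnr, threshold = 5) {
  m <- asnr >= threshold
  m[is.na(m)] <- FALSE
  m
}

#' Metabolite AUC ratio maps under joint SNR masking
#'
#' Computes lactate/pyruvate, bicarbonate/pyruvate and bicarbonate/lactate
#' AUC ratios, defined only where both constituent metabolites pass their
#' individual SNR masks; all other voxels are `NA` (missing, never zero,
#' so ROI medians are unaffected by invalid voxels).
#'
#' @param aucs Named list of 3D AUC maps: `pyruvate`, `lactate`,
#'   `bicarbonate`.
#' @param snr_masks Named list of logical 3D masks with the same names.
#' @return List of class `ratio_maps` with 3D maps `lac_pyr`, `bic_pyr`,
#'   `bic_lac` and logical validity masks `valid_lac_pyr`,
#'   `valid_bic_pyr`, `valid_bic_lac`.
#' @export
ratio_maps <- function(aucs, snr_masks) {
  req <- c("pyruvate", "lactate", "bicarbonate")
  if (!all(req %in% names(aucs)) || !all(req %in% names(snr_masks)))
    stop("aucs and snr_masks must contain pyruvate, lactate and bicarbonate",
         call. = FALSE)
  one <- function(num, den) {
    valid <- snr_masks[[num]] & snr_masks[[den]]
    out <- array(NA_real_, dim(aucs[[num]]))
    out[valid] <- aucs[[num]][valid] / aucs[[den]][valid]
    list(map = out, valid = valid)
  }
  lp <- one("lactate", "pyruvate")
  bp <- one("bicarbonate", "pyruvate")
  bl <- one("bicarbonate", "lactate")
  structure(
    list(lac_pyr = lp$map, bic_pyr = bp$map, bic_lac = bl$map,
         valid_lac_pyr = lp$valid, valid_bic_pyr = bp$valid,
         valid_bic_lac = bl$valid),
    class = "ratio_maps"
  )
}

#' Tied-rank percentile map over the brain
#'
#' Ranks the AUC values of all brain-mask voxels with average-rank tie
#' handling, normalizes by the total number of brain voxels (no SNR
#' filtering), and scales to a 0-100 percentile range:
#' `percentile = 100 * rank / N_brain`. Non-brain voxels are `NA`.
#'
#' The result is invariant under any strictly increasing transform of
#' the input values, which is what makes these maps comparable across
#' patients and timepoints despite arbitrary polarization scaling.
#'
#' @param auc 3D AUC map.
#' @param brain_mask Nonempty logical 3D mask.
#' @return 3D percentile map with values in (0, 100] on brain voxels.
#' @export
percentile_rank_map <- function(auc, brain_mask) {
  if (!identical(dim(auc), dim(brain_mask)))
    stop("auc and brain_mask must share a grid", call. = FALSE)
  idx <- which(brain_mask)
  if (length(idx) == 0) stop("empty brain mask", call. = FALSE)
  r <- rank(auc[idx], ties.method = "average")
  out <- array(NA_real_, dim(auc))
  out[idx] <- 100 * r / length(idx)
  out
}
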