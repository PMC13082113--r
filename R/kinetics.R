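# Inputless kinetic modeling: the measured pyruvate signal itself drives
# the product-pool model, so no arterial input function is required.
# Lactate and bicarbonate channels decouple given the pyruvate drive and
# each reduces to a one-parameter linear least-squares problem.

# Shared channel fit on a matrix of voxels.
#
# pyr_sig: voxels x T matrix of pyruvate signals; met_sig: voxels x T of
# the product-metabolite signals. Signals are converted to longitudinal
# magnetization (divide by sin(flip)); the product pool is propagated
# between excitations as
#   M[m+1] = M[m] * cos(flip_met) * E + k * U_m,   E = exp(-dt/T1_met)
# where U_m is the T1-weighted convolution of the pyruvate drive over the
# interval, integrated exactly under linear interpolation of the drive
# between its endpoints (post-flip at m, pre-flip at m+1):
#   U_m = a*T1*(1-E) + ((b-a)/dt) * (T1*dt - T1^2*(1-E)),
#   a = Pz[m]*cos(flip_pyr), b = Pz[m+1].
# The model response is linear in (k, M0), with M0 the initial product
# magnetization treated as a nuisance parameter (its homogeneous
# propagation is d^m, d = cos(flip_met)*E), so the least-squares problem
# is solved in closed form per voxel; k is clamped to `bounds` and M0
# re-optimized at the clamped rate. The relative standard error of k
# comes from the two-parameter linearized residual covariance.
.fit_channel <- function(pyr_sig, met_sig, flip_pyr, flip_met, t1_met, dt,
                         bounds = c(0, 1)) {
  if (is.null(dim(pyr_sig))) pyr_sig <- matrix(pyr_sig, nrow = 1)
  if (is.null(dim(met_sig))) met_sig <- matrix(met_sig, nrow = 1)
  n <- ncol(pyr_sig)
  fp <- flip_pyr * pi / 180
  fm <- flip_met * pi / 180
  Pz <- pyr_sig / sin(fp)
  Mz <- met_sig / sin(fm)

  E <- exp(-dt / t1_met)
  d <- cos(fm) * E
  # per-interval unit-rate drive integrals (voxels x (T-1)), exact for a
  # linearly interpolated drive
  A <- Pz[, -n, drop = FALSE] * cos(fp)
  B <- Pz[, -1, drop = FALSE]
  U <- A * t1_met * (1 - E) +
    (B - A) / dt * (t1_met * dt - t1_met^2 * (1 - E))

  nv <- nrow(Pz)
  X <- matrix(0, nv, n)       # unit-rate convolution response
  for (m in 2:n) X[, m] <- X[, m - 1] * d + U[, m - 1]
  D <- d^(0:(n - 1))          # homogeneous response of unit M0 (shared)

  sxx <- rowSums(X * X)
  sxd <- drop(X %*% D)
  sdd <- sum(D * D)
  sxy <- rowSums(X * Mz)
  sdy <- drop(Mz %*% D)
  det <- sxx * sdd - sxd^2

  converged <- is.finite(det) & det > .Machine$double.eps * (sxx + sdd)^2
  k_raw <- (sxy * sdd - sxd * sdy) / det
  k <- pmin(pmax(k_raw, bounds[1]), bounds[2])
  m0 <- (sdy - k * sxd) / sdd
  resid <- Mz - k * X - tcrossprod(m0, D)
  dof <- max(n - 2, 1)
  s2 <- rowSums(resid^2) / dof
  se <- sqrt(s2 * sdd / det)
  relerr <- se / pmax(k, .Machine$double.eps)
  k[!converged] <- NA_real_
  relerr[!converged] <- NA_real_
  list(k = k, relerr = relerr, converged = converged,
       n_points_used = n)
}

#' Fit apparent conversion rates for one voxel (inputless model)
#'
#' Estimates kPL and kPB from dynamic pyruvate, lactate and bicarbonate
#' signal curves using the measured pyruvate signal as the driving input
#' (no arterial input function). The two product channels are fitted
#' independently. Within each channel the product magnetization is
#' propagated timepoint-to-timepoint with its RF and T1 losses plus the
#' rate constant times the T1-weighted integral of the pyruvate drive
#' over the interval (integrated exactly under linear interpolation of
#' the drive between excitations). The response is linear in the rate
#' and in the initial product magnetization (a nuisance parameter), so
#' the nonnegative least-squares minimizer is computed in closed form
#' and clamped to `bounds`. Fit uncertainty ("modeling error") is the
#' relative standard error of the rate from the linearized residual
#' covariance.
#'
#' @param pyr_curve,lac_curve,bic_curve Numeric signal curves of equal
#'   length >= 3.
#' @param params An [acq_params()]; flips must be nonzero.
#' @param bounds Length-2 numeric, admissible rate range in 1/s.
#' @return A list of class `kinetic_fit`: `kpl`, `kpb` (1/s),
#'   `kpl_relerr`, `kpb_relerr` (fractions), `converged` (logical),
#'   `n_points_used`.
#' @export
#' @examples
#' p <- acq_params()
#' g <- function(t) gamma_variate(t, 1, 2.5, 4, delay = 5)
#' s <- simulate_voxel_dynamics(0.02, 0.005, g, p)
#' fit <- fit_voxel_inputless(s$pyruvate, s$lactate, s$bicarbonate, p)
#' c(fit$kpl, fit$kpb)
fit_voxel_inputless <- function(pyr_curve, lac_curve, bic_curve, params,
                                bounds = c(0, 1)) {
  stopifnot(inherits(params, "acq_params"))
  n <- length(pyr_curve)
  if (length(lac_curve) != n || length(bic_curve) != n || n < 3)
    stop("curves must have equal length >= 3", call. = FALSE)
  if (all(pyr_curve == 0))
    stop("no pyruvate signal: cannot fit an inputless model", call. = FALSE)

  fl <- .fit_channel(pyr_curve, lac_curve, params$flip_pyr,
                     params$flip_lac, params$t1_lac, params$dt, bounds)
  fb <- .fit_channel(pyr_curve, bic_curve, params$flip_pyr,
                     params$flip_bic, params$t1_bic, params$dt, bounds)
  structure(
    list(kpl = fl$k, kpb = fb$k,
         kpl_relerr = fl$relerr, kpb_relerr = fb$relerr,
         converged = fl$converged && fb$converged,
         n_points_used = fl$n_points_used),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("kPL = %.4g 1/s (rel. err %.1f%%), kPB = %.4g 1/s (rel. err %.1f%%)\n",
              x$kpl, 100 * x$kpl_relerr, x$kpb, 100 * x$kpb_relerr))
  invisible(x)
}

#' Voxel-wise kinetic maps with modeling-error masks
#'
#' Fits the inputless model at every voxel of `fit_mask` and assembles
#' kPL/kPB maps together with modeling-error masks: voxels whose
#' relative standard error is at most `kpl_err_max` (kPL) or
#' `kpb_err_max` (kPB) pass. Voxels outside the mask, or whose fit did
#' not converge, are `NA` in the maps — never zero — so they cannot
#' contaminate downstream medians. Voxels below the pyruvate aSNR
#' threshold should be excluded from `fit_mask` by the caller (see
#' [snr_mask()]); [run_pipeline()] composes this automatically.
#'
#' @param dynamics Named list of 4D arrays with elements `pyruvate`,
#'   `lactate`, `bicarbonate` (x-y-z-t).
#' @param fit_mask Logical 3D array choosing the voxels to fit.
#' @param params An [acq_params()].
#' @param kpl_err_max,kpb_err_max Relative-error thresholds for the
#'   modeling-error masks (defaults 0.30 and 0.50).
#' @param bounds Admissible rate range in 1/s.
#' @return A list of class `kinetic_maps`: `kpl`, `kpb`,
#'   `kpl_relerr`, `kpb_relerr` (3D maps, NA where unfit),
#'   `kpl_error_mask`, `kpb_error_mask` (logical 3D maps).
#' @export
fit_map <- function(dynamics, fit_mask, params,
                    kpl_err_max = 0.30, kpb_err_max = 0.50,
                    bounds = c(0, 1)) {
  stopifnot(inherits(params, "acq_params"))
  dims <- dim(dynamics$pyruvate)
  if (!identical(dim(fit_mask), dims[1:3]))
    stop("fit_mask does not match the image grid", call. = FALSE)
  shape <- dims[1:3]
  empty <- array(NA_real_, shape)
  out <- list(kpl = empty, kpb = empty,
              kpl_relerr = empty, kpb_relerr = empty,
              kpl_error_mask = array(FALSE, shape),
              kpb_error_mask = array(FALSE, shape))
  idx <- which(fit_mask)
  if (length(idx) == 0) {
    warning("empty fit mask: returning empty kinetic maps", call. = FALSE)
    return(structure(out, class = "kinetic_maps"))
  }
  n <- dims[4]
  nv <- prod(shape)
  to_mat <- function(a) {
    m <- matrix(a, nrow = nv, ncol = n)
    m[idx, , drop = FALSE]
  }
  P <- to_mat(dynamics$pyruvate)
  L <- to_mat(dynamics$lactate)
  B <- to_mat(dynamics$bicarbonate)

  fl <- .fit_channel(P, L, params$flip_pyr, params$flip_lac,
                     params$t1_lac, params$dt, bounds)
  fb <- .fit_channel(P, B, params$flip_pyr, params$flip_bic,
                     params$t1_bic, params$dt, bounds)
  out$kpl[idx] <- fl$k
  out$kpb[idx] <- fb$k
  out$kpl_relerr[idx] <- fl$relerr
  out$kpb_relerr[idx] <- fb$relerr
  out$kpl_error_mask[idx] <- fl$converged & fl$relerr <= kpl_err_max
  out$kpb_error_mask[idx] <- fb$converged & fb$relerr <= kpb_err_max
  out$kpl_error_mask[is.na(out$kpl_error_mask)] <- FALSE
  out$kpb_error_mask[is.na(out$kpb_error_mask)] <- FALSE
  structure(out, class = "kinetic_maps")
}
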