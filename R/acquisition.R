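#' Acquisition parameters for a dynamic HP-13C study
#'
#' Bundles the constants of the forward signal model: the constant flip
#' angles used to excite each metabolite, the dynamic sampling scheme, and
#' the apparent longitudinal relaxation times assumed for each pool.
#'
#' @param flip_pyr,flip_lac,flip_bic Flip angles in degrees, each in
#'   (0, 90]. Defaults 20/30/30 match a frequency-selective EPI readout
#'   that excites pyruvate at a lower angle to preserve polarization.
#' @param n_timepoints Number of dynamic timepoints (>= 2).
#' @param dt Temporal resolution in seconds between excitations of the
#'   same metabolite.
#' @param t1_pyr,t1_lac,t1_bic Apparent longitudinal relaxation times in
#'   seconds. These are not fitted anywhere in the package; they are
#'   assumed constants of the model and can be overridden here.
#'
#' @return An object of class `acq_params`.
#' @export
#' @examples
#' p <- acq_params()
#' p$dt * p$n_timepoints  # total acquisition window in seconds
acq_params <- function(flip_pyr = 20, flip_lac = 30, flip_bic = 30,
                       n_timepoints = 20, dt = 3,
                       t1_pyr = 30, t1_lac = 25, t1_bic = 25) {
  flips <- c(flip_pyr, flip_lac, flip_bic)
  if (any(!is.finite(flips)) || any(flips <= 0) || any(flips > 90))
    stop("flip angles must lie in (0, 90] degrees", call. = FALSE)
  if (!is.finite(n_timepoints) || n_timepoints < 2)
    stop("n_timepoints must be >= 2", call. = FALSE)
  if (!is.finite(dt) || dt <= 0)
    stop("dt must be positive", call. = FALSE)
  t1s <- c(t1_pyr, t1_lac, t1_bic)
  if (any(!is.finite(t1s)) || any(t1s <= 0))
    stop("all T1 values must be positive", call. = FALSE)
  structure(
    list(flip_pyr = flip_pyr, flip_lac = flip_lac, flip_bic = flip_bic,
         n_timepoints = as.integer(n_timepoints), dt = dt,
         t1_pyr = t1_pyr, t1_lac = t1_lac, t1_bic = t1_bic),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat("Dynamic HP-13C acquisition parameters\n")
  cat(sprintf("  flips (pyr/lac/bic): %g/%g/%g deg\n",
              x$flip_pyr, x$flip_lac, x$flip_bic))
  cat(sprintf("  %d timepoints at dt = %g s\n", x$n_timepoints, x$dt))
  cat(sprintf("  T1 (pyr/lac/bic): %g/%g/%g s\n",
              x$t1_pyr, x$t1_lac, x$t1_bic))
  invisible(x)
}

#' Configuration for the synthetic dynamic-13C phantom
#'
#' Defines the geometry, kinetic ground truth, bolus shape and noise level
#' of a simulated study. The 1H anatomical grid is an integer block
#' refinement of the 13C grid (`upsample_factor` per axis), so that
#' partial-volume overlap fractions between the two grids are exact.
#'
#' Default rates place an elevated-kPL lesion (Warburg-type glycolytic
#' upregulation) inside normal brain with lower kPL, and reduced oxidative
#' flux (kPB) inside the lesion.
#'
#' @param grid_13c Integer triple, 13C matrix size. Default `c(16, 16, 8)`.
#' @param voxel_13c 13C voxel size in mm (isotropic). Default 15.
#' @param upsample_factor Integer >= 1; 1H grid = 13C grid times this
#'   factor per axis. Default 8 (1.875 mm 1H voxels).
#' @param kpl_background,kpl_lesion Pyruvate-to-lactate rates (1/s) for
#'   normal brain and lesion. Lesion must exceed background.
#' @param kpb_background,kpb_lesion Pyruvate-to-bicarbonate rates (1/s).
#' @param bolus_amplitude Peak-scale of the gamma-variate pyruvate inflow
#'   (arbitrary signal units per second).
#' @param bolus_alpha,bolus_beta Gamma-variate shape and scale (seconds
#'   for beta); the inflow peaks `alpha * beta` seconds after `bolus_delay`.
#' @param bolus_delay Arrival delay of the bolus in seconds after the
#'   start of the dynamic acquisition.
#' @param noise_sigma Standard deviation of additive i.i.d. Gaussian
#'   noise applied per voxel per timepoint (signal units).
#' @param seed Integer seed governing every stochastic draw of the
#'   generator.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_13c = c(16L, 16L, 8L), voxel_13c = 15,
                           upsample_factor = 8L,
                           kpl_background = 0.01, kpl_lesion = 0.02,
                           kpb_background = 0.005, kpb_lesion = 0.002,
                           bolus_amplitude = 1, bolus_alpha = 2.5,
                           bolus_beta = 4, bolus_delay = 5,
                           noise_sigma = 0.03, seed = 1L) {
  if (length(grid_13c) != 3 || any(grid_13c < 1))
    stop("grid_13c must be a triple of positive voxel counts", call. = FALSE)
  if (upsample_factor < 1 || upsample_factor != round(upsample_factor))
    stop("upsample_factor must be a positive integer", call. = FALSE)
  rates <- c(kpl_background, kpl_lesion, kpb_background, kpb_lesion)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rate constants must be nonnegative", call. = FALSE)
  if (kpl_lesion <= kpl_background)
    stop("kpl_lesion must exceed kpl_background (tumor Warburg elevation)",
         call. = FALSE)
  if (bolus_alpha <= 0 || bolus_beta <= 0)
    stop("gamma-variate shape and scale must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(
    list(grid_13c = as.integer(grid_13c), voxel_13c = voxel_13c,
         upsample_factor = as.integer(upsample_factor),
         kpl_background = kpl_background, kpl_lesion = kpl_lesion,
         kpb_background = kpb_background, kpb_lesion = kpb_lesion,
         bolus_amplitude = bolus_amplitude, bolus_alpha = bolus_alpha,
         bolus_beta = bolus_beta, bolus_delay = bolus_delay,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Synthetic HP-13C phantom configuration\n")
  cat(sprintf("  13C grid %dx%dx%d at %g mm; 1H refinement x%d\n",
              x$grid_13c[1], x$grid_13c[2], x$grid_13c[3],
              x$voxel_13c, x$upsample_factor))
  cat(sprintf("  kPL lesion/background: %g/%g 1/s; kPB: %g/%g 1/s\n",
              x$kpl_lesion, x$kpl_background, x$kpb_lesion, x$kpb_background))
  cat(sprintf("  noise sigma %g, seed %d\n", x$noise_sigma, x$seed))
  invisible(x)
}
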