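# End-to-end orchestration: configuration, the per-scan analysis chain,
# and a reproducible pipeline run with an artifact manifest.

#' Pipeline configuration
#'
#' Collects the acquisition parameters, processing thresholds and
#' phantom configuration of a full run. Threshold defaults are the
#' pipeline's standard operating point: aSNR >= 5 to keep a voxel,
#' modeling error <= 30% (kPL) and <= 50% (kPB), T2L overlap >= 30% and
#' NAWM overlap >= 50% in ROI downsampling.
#'
#' @param params An [acq_params()].
#' @param phantom A [phantom_config()] used when simulation is requested.
#' @param asnr_threshold Minimum aSNR kept by [snr_mask()].
#' @param kpl_err_max,kpb_err_max Modeling-error thresholds for
#'   [fit_map()].
#' @param t2l_frac,nawm_frac Overlap thresholds for [downsample_rois()].
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Integer seed for the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(params = acq_params(),
                            phantom = phantom_config(),
                            asnr_threshold = 5,
                            kpl_err_max = 0.30, kpb_err_max = 0.50,
                            t2l_frac = 0.30, nawm_frac = 0.50,
                            out_dir = tempfile("hp13c_run_"),
                            seed = 1L) {
  stopifnot(inherits(params, "acq_params"), inherits(phantom, "phantom_config"))
  if (asnr_threshold < 0) stop("asnr_threshold must be >= 0", call. = FALSE)
  for (v in c(kpl_err_max, kpb_err_max, t2l_frac, nawm_frac))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("error and overlap thresholds must lie in [0, 1]", call. = FALSE)
  structure(
    list(params = params, phantom = phantom,
         asnr_threshold = asnr_threshold,
         kpl_err_max = kpl_err_max, kpb_err_max = kpb_err_max,
         t2l_frac = t2l_frac, nawm_frac = nawm_frac,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may carry `params:`, `phantom:` and top-level threshold
#' fields; anything omitted keeps its default.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(acq_params, if (is.null(y$params)) list() else y$params)
  phantom <- do.call(phantom_config, if (is.null(y$phantom)) list() else y$phantom)
  extra <- y[setdiff(names(y), c("params", "phantom"))]
  do.call(pipeline_config, c(list(params = params, phantom = phantom), extra))
}

#' Analyze one dynamic HP-13C scan
#'
#' Runs the per-scan processing chain on a study: AUC maps, background
#' noise estimation per metabolite, aSNR maps and SNR masks, SNR-masked
#' AUC ratio maps, tied-rank percentile maps over the brain, voxel-wise
#' kinetic maps with modeling-error masks (fitted on brain voxels
#' passing the pyruvate SNR mask), ROI derivation and downsampling, and
#' the ROI median summary with NAWM normalization.
#'
#' @param study An `hp13c_study` (or a compatible list with `dynamics`,
#'   `masks`, `config`, `params`, `clinical_row`).
#' @param config A [pipeline_config()]; its `params` are ignored in
#'   favor of the study's own acquisition parameters.
#' @return A list of class `scan_analysis`: `aucs`, `sigmas`, `asnr`,
#'   `snr_masks`, `ratios`, `percentiles`, `kinetics`, `brain_13c`,
#'   `labels`, `maps` (the eight canonical parameter maps with masks
#'   applied as missingness), `summary` (normalized [summarize_scan()]
#'   tibble), and `voxel_counts` (voxels surviving each filtering
#'   stage).
#' @export
analyze_study <- function(study, config = pipeline_config()) {
  params <- study$params
  masks <- derive_rois(study$masks)
  f <- study$config$upsample_factor
  brain_13c <- downsample_mask(masks$brain, f, 0.5)

  mets <- c("pyruvate", "lactate", "bicarbonate")
  aucs <- lapply(study$dynamics[mets], compute_auc)
  sigmas <- vapply(study$dynamics[mets], estimate_noise_sigma,
                   numeric(1), brain_mask = brain_13c)
  asnr <- Map(function(a, s) compute_asnr(a, s, params$n_timepoints),
              aucs, as.list(sigmas))
  snr_masks <- lapply(asnr, snr_mask, threshold = config$asnr_threshold)
  ratios <- ratio_maps(aucs, snr_masks)
  percentiles <- lapply(aucs, percentile_rank_map, brain_mask = brain_13c)

  fit_mask <- brain_13c & snr_masks$pyruvate
  kinetics <- fit_map(study$dynamics, fit_mask, params,
                      kpl_err_max = config$kpl_err_max,
                      kpb_err_max = config$kpb_err_max)

  labels <- downsample_rois(masks$t2l, masks$nawm, f,
                            t2l_frac = config$t2l_frac,
                            nawm_frac = config$nawm_frac)

  mask_na <- function(map, keep) {
    map[!keep] <- NA_real_
    map
  }
  maps <- list(
    pyr_pct = percentiles$pyruvate,
    lac_pct = percentiles$lactate,
    bic_pct = percentiles$bicarbonate,
    lac_pyr = ratios$lac_pyr,
    bic_pyr = ratios$bic_pyr,
    bic_lac = ratios$bic_lac,
    kpl = mask_na(kinetics$kpl, kinetics$kpl_error_mask),
    kpb = mask_na(kinetics$kpb, kinetics$kpb_error_mask)
  )

  summary <- summarize_scan(
    maps, labels,
    patient_id = study$clinical_row$patient_id,
    months_post_treatment = study$clinical_row$months_post_treatment
  )
  summary <- normalize_to_nawm(summary)

  voxel_counts <- c(
    brain_13c = sum(brain_13c),
    snr_pyr = sum(snr_masks$pyruvate),
    snr_lac = sum(snr_masks$lactate),
    snr_bic = sum(snr_masks$bicarbonate),
    fitted = sum(fit_mask),
    kpl_pass = sum(kinetics$kpl_error_mask),
    kpb_pass = sum(kinetics$kpb_error_mask),
    t2l_13c = sum(labels$labels == "T2L"),
    nawm_13c = sum(labels$labels == "NAWM")
  )

  structure(
    list(aucs = aucs, sigmas = sigmas, asnr = asnr, snr_masks = snr_masks,
         ratios = ratios, percentiles = percentiles, kinetics = kinetics,
         brain_13c = brain_13c, labels = labels, maps = maps,
         summary = summary, voxel_counts = voxel_counts),
    class = "scan_analysis"
  )
}

#' Run the full pipeline: simulate, analyze, summarize, write
#'
#' Generates a synthetic study from the configured phantom, runs
#' [analyze_study()], parses a clinical table when supplied, and writes
#' every artifact (NIfTI volumes, CSV summaries, JSON sidecars) below
#' `config$out_dir` together with a `manifest.json` listing each file
#' with its MD5 hash and per-stage status. Two runs with identical
#' configuration and seed produce identical summaries and manifest
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @param clinical_csv Optional path to a clinical summary CSV; its
#'   cohort counts are recorded in the manifest.
#' @return Invisibly, a list with `analysis`, `study`, `manifest` and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), clinical_csv = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()

  phantom <- config$phantom
  phantom$seed <- config$seed
  study <- generate_phantom(phantom, config$params)
  stages$simulate <- "ok"

  analysis <- analyze_study(study, config)
  stages$analyze <- "ok"

  files <- write_study(study, file.path(config$out_dir, "study"))
  wr_map <- function(map, name) {
    path <- file.path(config$out_dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(ifelse(is.na(map), 0, map), path)
    path
  }
  files <- c(files,
             wr_map(analysis$kinetics$kpl, "kpl"),
             wr_map(analysis$kinetics$kpb, "kpb"),
             wr_map(analysis$kinetics$kpl_error_mask * 1, "kpl_error_mask"),
             wr_map(analysis$kinetics$kpb_error_mask * 1, "kpb_error_mask"))
  for (met in names(analysis$aucs))
    files <- c(files, wr_map(analysis$aucs[[met]], paste0("auc_", met)))

  sum_csv <- file.path(config$out_dir, "scan_summary.csv")
  utils::write.csv(analysis$summary, sum_csv, row.names = FALSE)
  files <- c(files, sum_csv)

  sidecar <- file.path(config$out_dir, "map_metadata.json")
  jsonlite::write_json(
    list(asnr_threshold = config$asnr_threshold,
         noise_sigma = as.list(analysis$sigmas),
         kpl_err_max = config$kpl_err_max, kpb_err_max = config$kpb_err_max,
         voxel_counts = as.list(analysis$voxel_counts)),
    sidecar, auto_unbox = TRUE, digits = NA)
  files <- c(files, sidecar)

  cohort_info <- NULL
  if (!is.null(clinical_csv)) {
    cohort <- parse_clinical_table(clinical_csv)
    cohort_info <- cohort_counts(cohort)
    stages$clinical <- "ok"
  }

  manifest <- list(
    seed = config$seed,
    stages = stages,
    cohort_counts = cohort_info,
    artifacts = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(analysis = analysis, study = study, manifest = manifest,
                 out_dir = config$out_dir))
}
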