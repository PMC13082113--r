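# Per-scan ROI medians, NAWM normalization, treatment/PFS grouping,
# group trajectories, and paired voxel-wise serial comparison.

#' Canonical parameter names carried through scan summaries
#'
#' Percentile maps (`pyr_pct`, `lac_pct`, `bic_pct`), AUC ratios
#' (`lac_pyr`, `bic_pyr`, `bic_lac`) and conversion rates (`kpl`,
#' `kpb`).
#'
#' @export
hp13c_parameters <- c("pyr_pct", "lac_pct", "bic_pct",
                      "lac_pyr", "bic_pyr", "bic_lac", "kpl", "kpb")

#' Summarize parameter maps over the 13C ROIs
#'
#' Computes, for every parameter map, the median over valid voxels of
#' each ROI (T2L and NAWM as labeled on the 13C grid). Validity is
#' carried by the maps themselves: voxels filtered by SNR masks or
#' modeling-error masks must already be `NA` (as produced by
#' [ratio_maps()] and [fit_map()]); percentile maps are valid on all
#' brain voxels. An empty ROI yields a missing median with a zero count.
#'
#' @param maps Named list of 3D parameter maps (any subset of
#'   [hp13c_parameters]), all on the 13C grid, invalid voxels `NA`.
#' @param labels A [downsample_rois()] label map on the same grid.
#' @param patient_id,months_post_treatment Scan identity carried into
#'   the summary (months 0 = pre-treatment baseline).
#' @return A tibble of class `scan_summary` with one row per parameter:
#'   `patient_id`, `months`, `parameter`, `t2l_median`, `t2l_n`,
#'   `nawm_median`, `nawm_n`, `t2l_norm` (NA until
#'   [normalize_to_nawm()]).
#' @export
summarize_scan <- function(maps, labels, patient_id = NA_character_,
                           months_post_treatment = NA_real_) {
  stopifnot(inherits(labels, "roi_label_map"))
  roi_median <- function(map, roi) {
    if (!identical(dim(map), dim(labels$labels)))
      stop("parameter map does not share the 13C grid with the labels",
           call. = FALSE)
    v <- map[labels$labels == roi]
    v <- v[is.finite(v)]
    list(median = if (length(v)) stats::median(v) else NA_real_,
         n = length(v))
  }
  rows <- lapply(names(maps), function(par) {
    t2l <- roi_median(maps[[par]], "T2L")
    nawm <- roi_median(maps[[par]], "NAWM")
    tibble::tibble(patient_id = patient_id,
                   months = months_post_treatment,
                   parameter = par,
                   t2l_median = t2l$median, t2l_n = t2l$n,
                   nawm_median = nawm$median, nawm_n = nawm$n,
                   t2l_norm = NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("scan_summary", class(out))
  out
}

#' Normalize lesion medians by the patient's NAWM reference
#'
#' Fills `t2l_norm = t2l_median / nawm_median` per parameter. The
#' normalized value is missing whenever the NAWM median is missing,
#' zero, or non-finite. Because both numerator and denominator come
#' from the same scan, the result is invariant under any global
#' rescaling of the maps (e.g. polarization level).
#'
#' @param summary A [summarize_scan()] tibble.
#' @return The summary with `t2l_norm` filled.
#' @export
normalize_to_nawm <- function(summary) {
  summary$t2l_norm <- ifelse(
    is.finite(summary$nawm_median) & summary$nawm_median != 0,
    summary$t2l_median / summary$nawm_median,
    NA_real_
  )
  summary
}

#' Assign treatment groups and progressor class
#'
#' Classifies each patient's free-text treatment regimen with the
#' priority: any bevacizumab-containing regimen is `BEV+`; otherwise any
#' everolimus-containing regimen is `EVER+`; otherwise multi-agent
#' regimens (combinations built on alkylating agents) are `ALKYL+`;
#' single-agent temozolomide or lomustine (CCNU) is `control`. Anything
#' unrecognizable is labeled `unclassified` rather than guessed.
#' The progressor class is `early` when the PFS6 flag indicates
#' progression within 6 months of baseline, `late` otherwise.
#'
#' @param clinical A data frame with columns `treatment` and
#'   `pfs6_flag` (1 = progressed within 6 months).
#' @return The input with `treatment_group` and `progressor` columns
#'   added.
#' @export
assign_groups <- function(clinical) {
  stopifnot(all(c("treatment", "pfs6_flag") %in% names(clinical)))
  classify <- function(tx) {
    tl <- tolower(tx)
    if (!nzchar(trimws(tl))) return("unclassified")
    if (grepl("bevacizumab", tl)) return("BEV+")
    if (grepl("everolimus", tl)) return("EVER+")
    # split the regimen string into agent tokens
    agents <- unlist(strsplit(gsub("[][]", ",", tl), "[+,]"))
    agents <- trimws(agents)
    agents <- agents[nzchar(agents)]
    single_alkyl <- c("tmz", "temozolomide", "ccnu", "lomustine")
    if (length(agents) == 1)
      return(if (agents %in% single_alkyl) "control" else "unclassified")
    if (any(agents %in% single_alkyl) ||
        any(grepl("tmz|temozolomide|ccnu|lomustine", agents)))
      return("ALKYL+")
    "unclassified"
  }
  clinical$treatment_group <- vapply(clinical$treatment, classify, character(1),
                                     USE.NAMES = FALSE)
  clinical$progressor <- ifelse(clinical$pfs6_flag == 1, "early", "late")
  clinical
}

#' Parse the clinical summary table
#'
#' Reads a cohort CSV with columns `patient_id`, `treatment`,
#' `pfs6_flag`, `baseline_acquired` ("Yes"/"No"), `followup_months`
#' (comma-separated tokens like `"2m, 4m"`), and optionally `age`,
#' `sex`, `diagnosis`, `os_years`. Every follow-up token must match
#' `<integer>m`; a malformed token raises an error naming the patient.
#' Each patient contributes one exam per follow-up token plus one if a
#' pre-treatment baseline was acquired.
#'
#' @param path Path to the CSV file, or a data frame already read.
#' @return A tibble with parsed columns: `baseline_acquired` as logical,
#'   `followup_months` as a list of integer month offsets,
#'   `n_followups`, `n_scans`, plus `treatment_group` and `progressor`
#'   from [assign_groups()].
#' @export
#' @examples
#' csv <- system.file("extdata", "glioma_cohort.csv", package = "hp13c")
#' cohort <- parse_clinical_table(csv)
#' cohort_counts(cohort)
parse_clinical_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("patient_id", "treatment", "pfs6_flag", "baseline_acquired",
           "followup_months")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("clinical table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab <- tibble::as_tibble(tab)
  tab$baseline_acquired <- tolower(trimws(tab$baseline_acquired)) %in%
    c("yes", "y", "true", "1")
  parse_months <- function(field, pid) {
    field <- trimws(field)
    if (is.na(field) || !nzchar(field)) return(integer(0))
    toks <- trimws(unlist(strsplit(field, ",")))
    bad <- !grepl("^[0-9]+m$", toks)
    if (any(bad))
      stop(sprintf("malformed follow-up token '%s' for patient %s",
                   toks[bad][1], pid), call. = FALSE)
    as.integer(sub("m$", "", toks))
  }
  tab$followup_months <- unname(Map(parse_months, tab$followup_months,
                                    tab$patient_id))
  tab$n_followups <- vapply(tab$followup_months, length, integer(1))
  tab$n_scans <- tab$n_followups + as.integer(tab$baseline_acquired)
  assign_groups(tab)
}

#' Headline counts of a parsed cohort
#'
#' @param cohort Output of [parse_clinical_table()].
#' @return A list: `n_patients`, `n_baseline` (pre-treatment baselines
#'   acquired), `n_scans` (total exams = baselines + follow-ups),
#'   `n_early_progressors`, `n_controls`.
#' @export
cohort_counts <- function(cohort) {
  list(
    n_patients = nrow(cohort),
    n_baseline = sum(cohort$baseline_acquired),
    n_scans = sum(cohort$n_scans),
    n_early_progressors = sum(cohort$pfs6_flag == 1),
    n_controls = sum(cohort$treatment_group == "control")
  )
}

#' Group-level longitudinal trajectories
#'
#' Bins scans to integer month offsets (baseline = 0), keeps the first
#' scan per patient per bin, and computes per group, per month, per
#' parameter the mean of the patient-level values, their SD and
#' SE = SD/sqrt(N) (reported only when N > 1), and N.
#'
#' @param cohort A tibble of scan-level values: columns `patient_id`,
#'   `months`, `parameter`, a value column, and a grouping column.
#' @param value Name of the value column (e.g. `"t2l_norm"`,
#'   `"nawm_median"`).
#' @param group Name of the grouping column (e.g. `"treatment_group"`
#'   or `"progressor"`).
#' @return A tibble: group, `months`, `parameter`, `mean`, `sd`, `se`,
#'   `n`. Empty group-month bins are omitted.
#' @export
group_trajectories <- function(cohort, value = "t2l_norm",
                               group = "treatment_group") {
  stopifnot(all(c("patient_id", "months", "parameter", value, group) %in%
                  names(cohort)))
  dat <- cohort
  dat$months <- round(dat$months)
  dat$.value <- dat[[value]]
  dat$.group <- dat[[group]]
  dat <- dat[is.finite(dat$.value), , drop = FALSE]
  dat <- dat |>
    dplyr::arrange(.data$patient_id, .data$parameter, .data$months) |>
    dplyr::distinct(.data$patient_id, .data$parameter, .data$months,
                    .keep_all = TRUE)
  out <- dat |>
    dplyr::group_by(.data$.group, .data$months, .data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$.value),
      sd = if (dplyr::n() > 1) stats::sd(.data$.value) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = .data$sd / sqrt(.data$n))
  names(out)[names(out) == ".group"] <- group
  out[, c(group, "months", "parameter", "mean", "sd", "se", "n")]
}

#' Paired voxel-wise serial comparison
#'
#' For two scans of the same patient on an identical template grid,
#' compares parameter values voxel by voxel within an ROI. Only voxels
#' classified in the ROI at both timepoints, valid (non-missing) in
#' both, and nonzero in both contribute, so the selected voxel set is
#' symmetric in scan order. Per-voxel percent change is
#' `100 * (b - a) / a`.
#'
#' @param maps_a,maps_b Named lists of 3D parameter maps for the two
#'   timepoints (invalid voxels `NA`).
#' @param labels_a,labels_b [downsample_rois()] label maps for the two
#'   timepoints on the same grid.
#' @param roi ROI label to compare within (default `"T2L"`).
#' @return A list of class `paired_voxel_comparison`: `voxels` (tibble
#'   `parameter`, `voxel`, `value_a`, `value_b`, `pct_change`) and
#'   `summary` (tibble `parameter`, `n_voxels`, `mean_pct_change`).
#' @export
paired_voxel_change <- function(maps_a, maps_b, labels_a, labels_b,
                                roi = "T2L") {
  stopifnot(inherits(labels_a, "roi_label_map"),
            inherits(labels_b, "roi_label_map"))
  if (!identical(dim(labels_a$labels), dim(labels_b$labels)))
    stop("scans are not on a shared template grid", call. = FALSE)
  in_roi <- labels_a$labels == roi & labels_b$labels == roi
  pars <- intersect(names(maps_a), names(maps_b))
  vox <- lapply(pars, function(par) {
    a <- maps_a[[par]]; b <- maps_b[[par]]
    ok <- in_roi & is.finite(a) & is.finite(b) & a != 0 & b != 0
    idx <- which(ok)
    if (!length(idx)) return(NULL)
    tibble::tibble(parameter = par, voxel = idx,
                   value_a = a[idx], value_b = b[idx],
                   pct_change = 100 * (b[idx] - a[idx]) / a[idx])
  })
  voxels <- dplyr::bind_rows(vox)
  if (nrow(voxels) == 0) {
    summary <- tibble::tibble(parameter = pars, n_voxels = 0L,
                              mean_pct_change = NA_real_)
  } else {
    summary <- voxels |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(n_voxels = dplyr::n(),
                       mean_pct_change = mean(.data$pct_change),
                       .groups = "drop")
    absent <- setdiff(pars, summary$parameter)
    if (length(absent))
      summary <- dplyr::bind_rows(
        summary,
        tibble::tibble(parameter = absent, n_voxels = 0L,
                       mean_pct_change = NA_real_))
  }
  structure(list(voxels = voxels, summary = summary),
            class = "paired_voxel_comparison")
}
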