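# Small label-map constructor for summary tests.
toy_labels <- function(labels) {
  structure(list(labels = labels,
                 frac_t2l = array(0, dim(labels)),
                 frac_nawm = array(0, dim(labels)),
                 factor = 1L),
            class = "roi_label_map")
}

test_that("ROI medians are robust masked medians with honest counts", {
  dims <- c(3, 2, 1)
  labels <- toy_labels(array(c("T2L", "T2L", "T2L", "NAWM", "NAWM", "NONE"),
                             dims))
  map <- array(c(1, 2, 100, 4, NA, 9), dims)
  s <- summarize_scan(list(kpl = map), labels, "P1", 0)
  expect_equal(s$t2l_median, 2)      # median of {1, 2, 100}: outlier-proof
  expect_equal(s$t2l_n, 3L)
  expect_equal(s$nawm_median, 4)     # NA voxel excluded from count
  expect_equal(s$nawm_n, 1L)
  # single-voxel ROI: median is that voxel
  one <- toy_labels(array(c("T2L", rep("NONE", 5)), dims))
  expect_equal(summarize_scan(list(kpl = map), one)$t2l_median, 1)
  # empty ROI: missing value, zero count
  none <- toy_labels(array("NONE", dims))
  s0 <- summarize_scan(list(kpl = map), none)
  expect_true(is.na(s0$t2l_median))
  expect_equal(s0$t2l_n, 0L)
})

test_that("scan summaries equal a brute-force masked-median oracle on a phantom", {
  st <- test_phantom()
  an <- analyze_study(st)
  for (par in names(an$maps)) {
    row <- an$summary[an$summary$parameter == par, ]
    for (roi in c("T2L", "NAWM")) {
      v <- an$maps[[par]][an$labels$labels == roi]
      v <- v[is.finite(v)]
      want <- if (length(v)) median(v) else NA_real_
      got <- if (roi == "T2L") row$t2l_median else row$nawm_median
      expect_equal(got, want, info = paste(par, roi))
    }
  }
})

test_that("NAWM normalization divides, guards zero, and is scale-covariant", {
  s <- tibble::tibble(patient_id = "P1", months = 0,
                      parameter = c("a", "b", "c", "d"),
                      t2l_median = c(0.3, 5, 1, 2),
                      t2l_n = 3L,
                      nawm_median = c(0.2, 5, 0, NA),
                      nawm_n = 4L, t2l_norm = NA_real_)
  n <- normalize_to_nawm(s)
  expect_equal(n$t2l_norm[1], 1.5)
  expect_equal(n$t2l_norm[2], 1)
  expect_true(is.na(n$t2l_norm[3]))  # zero reference
  expect_true(is.na(n$t2l_norm[4]))  # missing reference
  scaled <- s
  scaled$t2l_median <- s$t2l_median * 4.2
  scaled$nawm_median <- s$nawm_median * 4.2
  expect_equal(normalize_to_nawm(scaled)$t2l_norm, n$t2l_norm)
})

test_that("treatment grouping follows the declared priority", {
  clin <- data.frame(
    treatment = c("Bevacizumab + CCNU",
                  "Everolimus + [TMZ, Olaparib]",
                  "TMZ + [Olaparib, Abemaciclib]",
                  "TMZ",
                  "CCNU",
                  "Bevacizumab",
                  "",
                  "Vitamin C"),
    pfs6_flag = c(1, 1, 0, 0, 1, 0, 0, 1))
  g <- assign_groups(clin)
  expect_equal(g$treatment_group,
               c("BEV+", "EVER+", "ALKYL+", "control", "control", "BEV+",
                 "unclassified", "unclassified"))
  expect_equal(g$progressor,
               c("early", "early", "late", "late", "early", "late", "late",
                 "early"))
})

test_that("the shipped cohort table parses to the expected counts", {
  csv <- system.file("extdata", "glioma_cohort.csv", package = "hp13c")
  cohort <- parse_clinical_table(csv)
  expect_equal(nrow(cohort), 20)
  counts <- cohort_counts(cohort)
  expect_equal(counts$n_baseline, 12)
  expect_equal(counts$n_scans, 41)
  # one baseline plus tokens "1m, 3m" -> 3 exams for that patient
  p19 <- cohort[cohort$patient_id == "P19", ]
  expect_equal(p19$n_scans, 3L)
  expect_equal(p19$followup_months[[1]], c(1L, 3L))
  # empty follow-up field: baseline-only patient
  solo <- data.frame(patient_id = "PX", treatment = "TMZ", pfs6_flag = 0,
                     baseline_acquired = "Yes", followup_months = "")
  expect_equal(parse_clinical_table(solo)$n_scans, 1L)
  solo$baseline_acquired <- "No"
  expect_equal(parse_clinical_table(solo)$n_scans, 0L)
})

test_that("malformed follow-up tokens raise an error naming the patient", {
  bad <- data.frame(patient_id = "PX", treatment = "TMZ", pfs6_flag = 0,
                    baseline_acquired = "Yes", followup_months = "2x, 3m")
  expect_error(parse_clinical_table(bad), "2x.*PX|PX.*2x")
})

test_that("group trajectories report mean, SD, SE and N per month bin", {
  cohort <- tibble::tibble(
    patient_id = c("A", "B", "C", "A", "B"),
    months = c(0, 0, 0, 2, 2),
    parameter = "lac_pyr",
    t2l_norm = c(1.0, 1.2, 3.0, 1.1, 1.1),
    treatment_group = c("BEV+", "BEV+", "EVER+", "BEV+", "BEV+"))
  tr <- group_trajectories(cohort)
  bev0 <- tr[tr$treatment_group == "BEV+" & tr$months == 0, ]
  expect_equal(bev0$mean, 1.1)
  expect_equal(bev0$n, 2L)
  expect_equal(bev0$se, sd(c(1.0, 1.2)) / sqrt(2))
  # single-patient bin: mean equals the value, SD/SE absent
  ever0 <- tr[tr$treatment_group == "EVER+", ]
  expect_equal(ever0$mean, 3.0)
  expect_true(is.na(ever0$sd) && is.na(ever0$se))
  expect_equal(ever0$n, 1L)
  # identical values: SD = 0
  bev2 <- tr[tr$treatment_group == "BEV+" & tr$months == 2, ]
  expect_equal(bev2$sd, 0)
})

test_that("two scans in one month bin keep the first scan only", {
  cohort <- tibble::tibble(
    patient_id = "A", months = c(1.2, 1.4), parameter = "kpl",
    t2l_norm = c(2, 9), treatment_group = "BEV+")
  tr <- group_trajectories(cohort)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$mean, 2)
  expect_equal(tr$n, 1L)
})

test_that("paired voxel comparison is exact, symmetric and ROI-restricted", {
  dims <- c(4, 4, 1)
  lab_a <- array("NONE", dims); lab_a[1:8] <- "T2L"
  lab_b <- array("NONE", dims); lab_b[5:12] <- "T2L"
  la <- toy_labels(lab_a); lb <- toy_labels(lab_b)
  set.seed(6)
  a <- array(runif(prod(dims), 1, 2), dims)
  # identical scans: all changes zero
  same <- paired_voxel_change(list(kpl = a), list(kpl = a), la, lb)
  expect_equal(same$summary$mean_pct_change, 0)
  expect_equal(same$summary$n_voxels, 4L)     # overlap of the two ROIs
  # uniform +10%
  up <- paired_voxel_change(list(kpl = a), list(kpl = 1.1 * a), la, lb)
  expect_equal(up$summary$mean_pct_change, 10)
  # voxel selection symmetric in scan order
  fwd <- paired_voxel_change(list(kpl = a), list(kpl = 1.1 * a), la, lb)
  rev <- paired_voxel_change(list(kpl = 1.1 * a), list(kpl = a), lb, la)
  expect_identical(sort(fwd$voxels$voxel), sort(rev$voxels$voxel))
  # no shared voxels: empty comparison with n = 0
  lab_c <- array("NONE", dims); lc <- toy_labels(lab_c)
  none <- paired_voxel_change(list(kpl = a), list(kpl = a), la, lc)
  expect_equal(none$summary$n_voxels, 0L)
  expect_true(is.na(none$summary$mean_pct_change))
})
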