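test_that("a flat lactate channel yields kPL = 0", {
  p <- acq_params()
  s <- simulate_voxel_dynamics(0.02, 0.005, ref_bolus(), p)
  fit <- fit_voxel_inputless(s$pyruvate, numeric(p$n_timepoints),
                             numeric(p$n_timepoints), p)
  expect_lt(fit$kpl, 1e-10)
  expect_lt(fit$kpb, 1e-10)
})

test_that("all-zero pyruvate raises a no-signal error", {
  p <- acq_params()
  z <- numeric(p$n_timepoints)
  expect_error(fit_voxel_inputless(z, z + 1, z, p), "pyruvate")
})

test_that("noiseless forward-simulated rates are recovered within 5%", {
  p <- acq_params()
  g <- ref_bolus()
  for (kpl in c(0.005, 0.02, 0.05)) for (kpb in c(0.002, 0.01)) {
    s <- simulate_voxel_dynamics(kpl, kpb, g, p)
    fit <- fit_voxel_inputless(s$pyruvate, s$lactate, s$bicarbonate, p)
    expect_lt(abs(fit$kpl - kpl) / kpl, 0.05)
    expect_lt(abs(fit$kpb - kpb) / kpb, 0.05)
    expect_true(fit$converged)
  }
})

test_that("fitted rates are invariant to overall signal scaling", {
  p <- acq_params()
  s <- simulate_voxel_dynamics(0.02, 0.005, ref_bolus(), p)
  set.seed(5)
  noisy <- lapply(s, function(x) x + rnorm(length(x), 0, 0.05))
  f1 <- fit_voxel_inputless(noisy$pyruvate, noisy$lactate, noisy$bicarbonate, p)
  c <- 7.3
  f2 <- fit_voxel_inputless(c * noisy$pyruvate, c * noisy$lactate,
                            c * noisy$bicarbonate, p)
  expect_equal(f1$kpl, f2$kpl)
  expect_equal(f1$kpb, f2$kpb)
  expect_equal(f1$kpl_relerr, f2$kpl_relerr)
})

test_that("the discrete fitting propagation matches a fine-step ODE oracle", {
  # propagate the lactate channel at the true rate, driven by the
  # noiseless measured pyruvate, and compare to fine-step integration of
  # the same interpolated-drive model
  p <- acq_params()
  kpl <- 0.02
  s <- simulate_voxel_dynamics(kpl, 0.005, ref_bolus(), p)
  fp <- p$flip_pyr * pi / 180; fm <- p$flip_lac * pi / 180
  t1 <- p$t1_lac; dt <- p$dt
  Pz <- s$pyruvate / sin(fp); E <- exp(-dt / t1)
  pred <- numeric(p$n_timepoints)
  for (m in 2:p$n_timepoints) {
    a <- Pz[m - 1] * cos(fp); b <- Pz[m]
    u <- a * t1 * (1 - E) + (b - a) / dt * (t1 * dt - t1^2 * (1 - E))
    pred[m] <- pred[m - 1] * cos(fm) * E + kpl * u
  }
  oracle <- lin_drive_oracle(s$pyruvate, kpl, p$flip_pyr, p$flip_lac, t1, dt)
  expect_lt(max_rel_err(pred * sin(fm), oracle), 1e-3)
  # and the end-to-end model mismatch against the true continuous
  # dynamics stays below 1%
  expect_lt(max_rel_err(pred * sin(fm), s$lactate), 0.01)
})

test_that("Monte-Carlo recovery at aSNR ~ 20 keeps median kPL error under 10%", {
  p <- acq_params()
  s <- simulate_voxel_dynamics(0.02, 0.005, ref_bolus(), p)
  # noise calibrated so each metabolite curve carries aSNR = 20
  sig <- vapply(s, function(x) sum(x) / (20 * sqrt(p$n_timepoints)),
                numeric(1))
  set.seed(101)
  errs <- replicate(200, {
    fit <- fit_voxel_inputless(
      s$pyruvate + rnorm(p$n_timepoints, 0, sig["pyruvate"]),
      s$lactate + rnorm(p$n_timepoints, 0, sig["lactate"]),
      s$bicarbonate + rnorm(p$n_timepoints, 0, sig["bicarbonate"]), p)
    abs(fit$kpl - 0.02) / 0.02
  })
  expect_lt(median(errs), 0.10)
})

test_that("fit_map agrees with the single-voxel fit and handles empty masks", {
  p <- acq_params()
  st <- test_phantom()
  mask <- array(FALSE, dim(st$truth_kpl))
  vox <- which(st$masks_13c$t2l)[3]
  mask[vox] <- TRUE
  maps <- fit_map(st$dynamics, mask, p)
  nv <- prod(dim(mask))
  curve <- function(arr) arr[vox + (seq_len(p$n_timepoints) - 1) * nv]
  single <- fit_voxel_inputless(curve(st$dynamics$pyruvate),
                                curve(st$dynamics$lactate),
                                curve(st$dynamics$bicarbonate), p)
  expect_equal(maps$kpl[vox], single$kpl)
  expect_equal(maps$kpb[vox], single$kpb)
  expect_equal(maps$kpl_relerr[vox], single$kpl_relerr)
  expect_true(all(is.na(maps$kpl[-vox])))

  expect_warning(empty <- fit_map(st$dynamics, array(FALSE, dim(mask)), p),
                 "empty")
  expect_true(all(is.na(empty$kpl)))
  expect_false(any(empty$kpl_error_mask))
})

test_that("every lesion voxel passes both error masks on a noiseless phantom", {
  cfg <- phantom_config(noise_sigma = 0, seed = 2)
  st <- generate_phantom(cfg, acq_params())
  maps <- fit_map(st$dynamics, st$masks_13c$brain, acq_params())
  les <- st$masks_13c$t2l
  expect_true(all(maps$kpl_error_mask[les]))
  expect_true(all(maps$kpb_error_mask[les]))
  expect_lt(max(abs(maps$kpl[les] - cfg$kpl_lesion)) / cfg$kpl_lesion, 0.05)
})

test_that("tightening the modeling-error threshold never adds voxels", {
  st <- test_phantom(noise_sigma = 0.2, seed = 9)
  p <- acq_params()
  thresholds <- c(0.30, 0.20, 0.10, 0.0)
  masks <- lapply(thresholds, function(th)
    fit_map(st$dynamics, st$masks_13c$brain, p, kpl_err_max = th)$kpl_error_mask)
  for (i in seq_along(masks)[-1])
    expect_true(all(!masks[[i]] | masks[[i - 1]]))
})

test_that("fitted lesion kPL exceeds background in nearly all seeds", {
  p <- acq_params()
  hits <- vapply(1:10, function(seed) {
    st <- generate_phantom(phantom_config(seed = seed), p)
    maps <- fit_map(st$dynamics, st$masks_13c$brain, p)
    median(maps$kpl[st$masks_13c$t2l], na.rm = TRUE) >
      median(maps$kpl[st$masks_13c$brain & !st$masks_13c$t2l], na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
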