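# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately brute-force and kept separate from the
# package's own numerical paths.

# Fine-step forward-Euler integration of the three-pool exchange model
# with RF sampling losses. Also tracks the label balance: cumulative
# inflow vs current magnetization plus cumulative relaxation and RF
# losses, which must close to numerical tolerance at every timepoint.
euler_oracle <- function(kpl, kpb, inflow_fun, params, n_substeps = 4000) {
  fp <- params$flip_pyr * pi / 180
  fl <- params$flip_lac * pi / 180
  fb <- params$flip_bic * pi / 180
  h <- params$dt / n_substeps
  P <- L <- B <- 0
  inflow_total <- relax_loss <- rf_loss <- 0
  n <- params$n_timepoints
  sp <- sl <- sb <- balance <- numeric(n)
  for (m in seq_len(n)) {
    sp[m] <- P * sin(fp); sl[m] <- L * sin(fl); sb[m] <- B * sin(fb)
    rf_loss <- rf_loss + P * (1 - cos(fp)) + L * (1 - cos(fl)) + B * (1 - cos(fb))
    P <- P * cos(fp); L <- L * cos(fl); B <- B * cos(fb)
    balance[m] <- inflow_total - (P + L + B + relax_loss + rf_loss)
    if (m == n) break
    t0 <- (m - 1) * params$dt
    for (s in seq_len(n_substeps)) {
      g <- inflow_fun(t0 + (s - 1) * h)
      dP <- -(1 / params$t1_pyr + kpl + kpb) * P + g
      dL <- kpl * P - L / params$t1_lac
      dB <- kpb * P - B / params$t1_bic
      inflow_total <- inflow_total + h * g
      relax_loss <- relax_loss +
        h * (P / params$t1_pyr + L / params$t1_lac + B / params$t1_bic)
      P <- P + h * dP; L <- L + h * dL; B <- B + h * dB
    }
  }
  list(pyruvate = sp, lactate = sl, bicarbonate = sb, balance = balance)
}

# Fine-step integration of the product-channel model used in fitting:
# dM/dt = k * P(t) - M/T1 with the pyruvate drive linearly interpolated
# between its per-excitation endpoints (post-flip start, pre-flip end),
# and RF loss cos(flip_met) applied at each excitation. Returns the
# measured product signal at each timepoint.
lin_drive_oracle <- function(pyr_sig, k, flip_pyr, flip_met, t1_met, dt,
                             n_substeps = 2000) {
  fp <- flip_pyr * pi / 180
  fm <- flip_met * pi / 180
  Pz <- pyr_sig / sin(fp)
  n <- length(Pz)
  h <- dt / n_substeps
  M <- numeric(n)
  cur <- 0
  for (m in 2:n) {
    a <- Pz[m - 1] * cos(fp)
    b <- Pz[m]
    cur <- cur * cos(fm)
    for (s in seq_len(n_substeps)) {
      Pt <- a + (b - a) * (s - 0.5) / n_substeps
      cur <- cur + h * (k * Pt - cur / t1_met)
    }
    M[m] <- cur
  }
  M * sin(fm)
}

ref_bolus <- function(config = phantom_config()) {
  function(t) gamma_variate(t, config$bolus_amplitude, config$bolus_alpha,
                            config$bolus_beta, config$bolus_delay)
}

max_rel_err <- function(x, y) max(abs(x - y)) / max(abs(y))

# Brute-force tied-rank percentile: for each brain voxel, average rank =
# (# strictly smaller) + (# equal, incl. self + 1) / 2.
percentile_oracle <- function(auc, brain_mask) {
  vals <- auc[brain_mask]
  n <- length(vals)
  out <- array(NA_real_, dim(auc))
  r <- vapply(vals, function(v) sum(vals < v) + (sum(vals == v) + 1) / 2,
              numeric(1))
  out[which(brain_mask)] <- 100 * r / n
  out
}

# Exhaustive per-block overlap counting for ROI downsampling.
downsample_oracle <- function(t2l, nawm, f, t2l_frac = 0.30, nawm_frac = 0.50) {
  nd <- dim(t2l) / f
  labels <- array("NONE", nd)
  ft <- fn <- array(0, nd)
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    xs <- ((i - 1) * f + 1):(i * f)
    ys <- ((j - 1) * f + 1):(j * f)
    zs <- ((k - 1) * f + 1):(k * f)
    ft[i, j, k] <- sum(t2l[xs, ys, zs]) / f^3
    fn[i, j, k] <- sum(nawm[xs, ys, zs]) / f^3
    if (ft[i, j, k] >= t2l_frac) labels[i, j, k] <- "T2L"
    else if (fn[i, j, k] >= nawm_frac) labels[i, j, k] <- "NAWM"
  }
  list(labels = labels, frac_t2l = ft, frac_nawm = fn)
}

random_mask <- function(dims, p = 0.5) {
  array(stats::runif(prod(dims)) < p, dims)
}

# Small phantom shared across tests; cached per options so the suite
# stays fast without re-simulating.
.fixture_env <- new.env(parent = emptyenv())
test_phantom <- function(noise_sigma = 0.03, seed = 11) {
  key <- paste0("ph_", noise_sigma, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- phantom_config(noise_sigma = noise_sigma, seed = seed)
    .fixture_env[[key]] <- generate_phantom(cfg, acq_params())
  }
  .fixture_env[[key]]
}
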