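# Shared fixtures: tiny in-memory runs and brute-force oracles.

# one run with explicitly placed centroids
toy_run <- function(rt, peaks) {
  hrmsqc:::new_centroid_run(rt,
                   lapply(peaks, function(p) sort(p$mz)),
                   lapply(peaks, function(p) p$intensity[order(p$mz)]))
}

# brute-force EIC oracle: linear scan, the defining ppm inequality
brute_force_eic <- function(run, target_mz, ppm) {
  n <- length(run$rt)
  intensity <- numeric(n)
  matched <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- run$mz[[i]]
    keep <- abs(m - target_mz) / target_mz * 1e6 <= ppm
    if (any(keep)) {
      y <- run$intensity[[i]][keep]
      intensity[i] <- sum(y)
      matched[i] <- sum(m[keep] * y) / sum(y)
    }
  }
  list(intensity = intensity, matched_mz = matched)
}

# random centroid run (no chromatographic structure)
random_run <- function(n_scans = 20, n_peaks = 30, mz_range = c(100, 500)) {
  rt <- seq_len(n_scans)
  mk <- function(i) {
    k <- sample(0:n_peaks, 1)
    list(mz = runif(k, mz_range[1], mz_range[2]), intensity = rexp(k, 1 / 100))
  }
  toy_run(rt, lapply(seq_len(n_scans), mk))
}

# noiseless single-Gaussian EIC trace as a run with one m/z channel
gaussian_run <- function(rt, mu, sigma, amplitude, mz = 200,
                         baseline_noise_sd = 0) {
  y <- amplitude * exp(-(rt - mu)^2 / (2 * sigma^2))
  if (baseline_noise_sd > 0) y <- pmax(0, y + rnorm(length(rt), 0, baseline_noise_sd))
  toy_run(rt, lapply(y, function(v)
    if (v > 0) list(mz = mz, intensity = v) else list(mz = numeric(0), intensity = numeric(0))))
}

# small deterministic campaign spec for fast end-to-end tests
tiny_spec <- function(seed = 3, ...) {
  campaign_spec(
    features = data.frame(name = c("StdA", "StdB"),
                          formula = c("C12H18O3", "C10H10O4"),
                          ion = "[M+H]+", rt_s = c(50, 100), sigma_s = 4,
                          apex_intensity = c(1e5, 8e4),
                          stringsAsFactors = FALSE),
    n_sequences = 2, files_per_category = c(blank = 1, QCstd = 4),
    run_length_s = 150, scan_interval_s = 1, seed = seed, ...)
}
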