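# Deterministic synthetic LC-HRMS campaigns with known ground truth.
#
# Emulates multi-sequence measurement campaigns: per sequence a set of
# files in blank / standard-QC / matrix-QC / sample categories, each
# file a centroided MS1 run in which every target analyte elutes as a
# Gaussian chromatographic peak with an M+1 carbon isotopolog
# companion. Instrument defects can be injected: a per-sequence
# detector sensitivity factor, linear retention-time drift over the
# file order, linear m/z (ppm) drift across each sequence, centroid
# m/z jitter and a random noise-centroid floor.

#' Default synthetic standard-mix features
#'
#' Three small-molecule-like analytes spread over the run, detected as
#' protonated ions, with Gaussian peak widths of a few seconds and apex
#' intensities around 1e5 counts — the regime of a standard QC mix on a
#' high-resolution instrument.
#'
#' @return Data.frame with columns `name`, `formula`, `ion`, `rt_s`,
#'   `sigma_s`, `apex_intensity`.
#' @export
default_campaign_features <- function() {
  data.frame(
    name = c("StdA", "StdB", "StdC"),
    formula = c("C12H18O3", "C10H10O4", "C9H17NO5"),
    ion = c("[M+H]+", "[M+H]+", "[M+H]+"),
    rt_s = c(60, 120, 180),
    sigma_s = c(5, 5, 5),
    apex_intensity = c(1.2e5, 0.8e5, 1.0e5),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic measurement campaign
#'
#' The seed fully determines every generated byte. Defaults follow a
#' two-sequence campaign of 12 standard-QC injections per sequence
#' flanked by blanks and matrix QCs, with no injected defects: unit
#' sensitivity, no retention-time or mass drift, 0.5 ppm centroid
#' jitter (sub-ppm scan-to-scan mass precision, typical of a
#' well-calibrated high-resolution instrument) and a sparse random
#' noise floor.
#'
#' @param features Feature table as in [default_campaign_features()].
#' @param n_sequences Number of measurement sequences.
#' @param files_per_category Named integer vector: files per category in
#'   each sequence. Category names become filename prefixes.
#' @param run_length_s Run length in seconds.
#' @param scan_interval_s Scan spacing in seconds.
#' @param sensitivity_factor Per-sequence detector sensitivity factors
#'   (length `n_sequences`), multiplying all apex intensities.
#' @param file_sensitivity_cv Lognormal coefficient of variation of the
#'   per-file sensitivity (injection-to-injection variability).
#' @param rt_drift_s_per_file Linear retention-time drift in seconds per
#'   file within each sequence.
#' @param mz_ppm_start,mz_ppm_end Per-sequence injected mass deviation
#'   (ppm) at the first and last file; intermediate files are linearly
#'   interpolated. Scalars are recycled.
#' @param jitter_ppm_sd Per-scan centroid m/z jitter (ppm, 1 sd).
#' @param noise_peaks_per_scan Mean number of random noise centroids per
#'   scan (Poisson).
#' @param noise_mean_intensity Mean intensity of noise centroids
#'   (exponential).
#' @param noise_mz_range m/z range over which noise centroids are drawn.
#' @param seed Integer seed determining the whole campaign.
#' @return A list of class `campaign_spec`.
#' @export
campaign_spec <- function(features = default_campaign_features(),
                          n_sequences = 2,
                          files_per_category = c(blank = 2, QCstd = 12, matrixQC = 2),
                          run_length_s = 240,
                          scan_interval_s = 1,
                          sensitivity_factor = rep(1, n_sequences),
                          file_sensitivity_cv = 0.02,
                          rt_drift_s_per_file = 0,
                          mz_ppm_start = 0,
                          mz_ppm_end = 0,
                          jitter_ppm_sd = 0.5,
                          noise_peaks_per_scan = 15,
                          noise_mean_intensity = 60,
                          noise_mz_range = c(100, 600),
                          seed = 1L) {
  stopifnot(nrow(features) >= 1, all(features$sigma_s > 0),
            all(features$apex_intensity > 0),
            length(sensitivity_factor) == n_sequences,
            scan_interval_s > 0, run_length_s > scan_interval_s,
            jitter_ppm_sd >= 0)
  features$theoretical_mz <- vapply(seq_len(nrow(features)), function(i)
    adduct_mz(monoisotopic_mass(features$formula[i]), features$ion[i]), numeric(1))
  features$ria <- vapply(features$formula, theoretical_ria, numeric(1))
  structure(list(
    features = features, n_sequences = n_sequences,
    files_per_category = files_per_category,
    run_length_s = run_length_s, scan_interval_s = scan_interval_s,
    sensitivity_factor = sensitivity_factor,
    file_sensitivity_cv = file_sensitivity_cv,
    rt_drift_s_per_file = rt_drift_s_per_file,
    mz_ppm_start = rep_len(mz_ppm_start, n_sequences),
    mz_ppm_end = rep_len(mz_ppm_end, n_sequences),
    jitter_ppm_sd = jitter_ppm_sd,
    noise_peaks_per_scan = noise_peaks_per_scan,
    noise_mean_intensity = noise_mean_intensity,
    noise_mz_range = noise_mz_range,
    seed = as.integer(seed)), class = "campaign_spec")
}

# deterministic per-file seed; stays far below 2^31 for small user seeds
.file_seed <- function(spec, sequence_index, file_index) {
  as.integer((abs(spec$seed) %% 100000L) * 10000L +
             sequence_index * 500L + file_index)
}

# injected per-file ground truth (defects only, no random jitter)
.file_truth <- function(spec, sequence_index, file_index, n_files) {
  frac <- if (n_files > 1) (file_index - 1) / (n_files - 1) else 0
  list(
    ppm = spec$mz_ppm_start[sequence_index] +
      frac * (spec$mz_ppm_end[sequence_index] - spec$mz_ppm_start[sequence_index]),
    rt_shift_s = spec$rt_drift_s_per_file * (file_index - 1),
    sensitivity = spec$sensitivity_factor[sequence_index])
}

#' Simulate one run of a synthetic campaign
#'
#' Generates the centroided MS1 run for one (sequence, file) position.
#' Each feature contributes a Gaussian intensity profile over retention
#' time with an M+1 isotopolog companion at the theoretical carbon
#' isotopolog ratio; analyte centroid m/z values carry the injected ppm
#' deviation of the file plus per-scan Gaussian jitter; noise centroids
#' are added per scan. Blank-category files contain only noise.
#'
#' @param spec A [campaign_spec()].
#' @param sequence_index 1-based sequence number.
#' @param file_index 1-based file number within the sequence.
#' @param n_files Total files in the sequence (sets the drift ramp);
#'   defaults to `sum(spec$files_per_category)`.
#' @param blank Logical: generate a blank (noise only).
#' @param file_sensitivity Per-file sensitivity multiplier; by default
#'   drawn deterministically from the spec seed.
#' @return A `centroid_run`.
#' @export
simulate_run <- function(spec, sequence_index, file_index,
                         n_files = sum(spec$files_per_category),
                         blank = FALSE, file_sensitivity = NULL) {
  stopifnot(inherits(spec, "campaign_spec"))
  set.seed(.file_seed(spec, sequence_index, file_index))
  truth <- .file_truth(spec, sequence_index, file_index, n_files)
  if (is.null(file_sensitivity)) {
    cv <- spec$file_sensitivity_cv
    file_sensitivity <- if (cv > 0)
      stats::rlnorm(1, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2))) else 1
  }
  rt <- seq(0, spec$run_length_s, by = spec$scan_interval_s)
  nsc <- length(rt)
  feats <- spec$features
  mz_l <- vector("list", nsc)
  int_l <- vector("list", nsc)

  # per-feature Gaussian intensity profile over the whole run
  profiles <- NULL
  if (!blank) {
    profiles <- lapply(seq_len(nrow(feats)), function(k) {
      apex <- feats$apex_intensity[k] * truth$sensitivity * file_sensitivity
      mu <- feats$rt_s[k] + truth$rt_shift_s
      apex * exp(-(rt - mu)^2 / (2 * feats$sigma_s[k]^2))
    })
  }

  for (i in seq_len(nsc)) {
    mzs <- numeric(0); ints <- numeric(0)
    if (!blank) {
      for (k in seq_len(nrow(feats))) {
        y <- profiles[[k]][i]
        if (y < 1) next
        jit <- stats::rnorm(1, 0, spec$jitter_ppm_sd)
        mz_meas <- feats$theoretical_mz[k] * (1 + (truth$ppm + jit) / 1e6)
        mzs <- c(mzs, mz_meas, mz_meas + .C13_C12_DELTA)
        ints <- c(ints, y, y * feats$ria[k])
      }
    }
    n_noise <- stats::rpois(1, spec$noise_peaks_per_scan)
    if (n_noise > 0) {
      mzs <- c(mzs, stats::runif(n_noise, spec$noise_mz_range[1], spec$noise_mz_range[2]))
      ints <- c(ints, stats::rexp(n_noise, 1 / spec$noise_mean_intensity))
    }
    o <- order(mzs)
    mz_l[[i]] <- mzs[o]
    int_l[[i]] <- ints[o]
  }
  new_centroid_run(rt, mz_l, int_l, polarity = "+")
}

#' Write a synthetic campaign to disk
#'
#' Writes per-sequence mzXML files named `<category>_S<s>R<nn>.mzXML`
#' (so that [categorize_samples()] groups them by category prefix), one
#' sequence CSV per sequence, and a `ground_truth.json` recording every
#' injected value for recovery tests.
#'
#' @param spec A [campaign_spec()].
#' @param out_dir Output directory (created if needed).
#' @param precision,compression Passed to [write_mzxml()].
#' @return Invisibly, a list with `sequence_csvs`, `mzxml_files`,
#'   `ground_truth` (the ground-truth list, also written as JSON).
#' @export
write_campaign <- function(spec, out_dir, precision = 64, compression = "none") {
  stopifnot(inherits(spec, "campaign_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fpc <- spec$files_per_category
  n_files <- sum(fpc)
  seq_csvs <- character(spec$n_sequences)
  all_files <- character(0)
  truth_files <- list()
  t0 <- as.POSIXct("2026-01-05 08:00:00", tz = "UTC")

  for (s in seq_len(spec$n_sequences)) {
    # file order: blanks first, then the QC injections, then matrix QCs
    cats <- rep(names(fpc), fpc)
    files <- character(n_files)
    acq <- character(n_files)
    for (f in seq_len(n_files)) {
      run <- simulate_run(spec, s, f, n_files = n_files,
                          blank = identical(cats[f], "blank"))
      fname <- sprintf("%s_S%dR%02d.mzXML", cats[f], s, f)
      write_mzxml(run, file.path(out_dir, fname), precision = precision,
                  compression = compression)
      files[f] <- fname
      acq[f] <- format(t0 + ((s - 1) * n_files + f - 1) * (spec$run_length_s + 60),
                       "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      tr <- .file_truth(spec, s, f, n_files)
      truth_files[[length(truth_files) + 1L]] <- list(
        file = fname, sequence = sprintf("S%d", s), order = f,
        category = cats[f], injected_ppm = tr$ppm,
        injected_rt_shift_s = tr$rt_shift_s,
        sensitivity_factor = tr$sensitivity)
    }
    csv <- file.path(out_dir, sprintf("sequence_S%d.csv", s))
    utils::write.csv(data.frame(file = files, sequence = sprintf("S%d", s),
                                acquisition_time = acq),
                     csv, row.names = FALSE, quote = FALSE)
    seq_csvs[s] <- csv
    all_files <- c(all_files, file.path(out_dir, files))
  }

  truth <- list(
    seed = spec$seed,
    features = spec$features[, c("name", "formula", "ion", "rt_s", "sigma_s",
                                 "apex_intensity", "theoretical_mz", "ria")],
    sensitivity_factor = spec$sensitivity_factor,
    mz_ppm_start = spec$mz_ppm_start, mz_ppm_end = spec$mz_ppm_end,
    rt_drift_s_per_file = spec$rt_drift_s_per_file,
    jitter_ppm_sd = spec$jitter_ppm_sd,
    files = truth_files)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # target table matching the generated features (tR in minutes)
  tf <- data.frame(name = spec$features$name, formula = spec$features$formula,
                   target_mz = "", ion = spec$features$ion,
                   expected_tR_min = spec$features$rt_s / 60,
                   group = spec$features$name)
  utils::write.csv(tf, file.path(out_dir, "targets.csv"), row.names = FALSE,
                   quote = FALSE)

  invisible(list(sequence_csvs = seq_csvs, mzxml_files = all_files,
                 targets_csv = file.path(out_dir, "targets.csv"),
                 ground_truth = truth))
}
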