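# Extracted ion chromatograms and chromatographic peak detection.
#
# EICs sum all centroids within a closed symmetric ppm window per scan.
# Peak picking follows the continuous-wavelet-transform ridge-line
# approach widely used for MS traces: Ricker (Mexican-hat) CWT over a
# geometric scale range, local maxima linked across scales into ridges,
# candidates filtered by ridge length and signal-to-noise ratio.

#' Extract an ion chromatogram
#'
#' For every scan, sums the intensities of all centroids with
#' `|mz - target_mz| / target_mz * 1e6 <= ppm` (closed window) and
#' records the intensity-weighted mean m/z of the matched centroids.
#' Scans with no centroid in the window get intensity 0 and missing
#' matched m/z.
#'
#' @param run A `centroid_run`.
#' @param target_mz Target m/z (Da), positive.
#' @param ppm Half-width of the symmetric m/z window in ppm, positive.
#' @return An object of class `eic`: list with `rt`, `intensity`,
#'   `matched_mz` (NA where no match), `target_mz`, `ppm`.
#' @export
extract_eic <- function(run, target_mz, ppm) {
  stopifnot(inherits(run, "centroid_run"), target_mz > 0, ppm > 0)
  tol <- target_mz * ppm * 1e-6
  # widened pre-filter bounds; exact membership is decided by the ppm
  # inequality itself so results match a brute-force filter bit-exactly
  lo <- target_mz - tol * (1 + 1e-9)
  hi <- target_mz + tol * (1 + 1e-9)
  n <- n_scans(run)
  intensity <- numeric(n)
  matched <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- run$mz[[i]]
    if (length(m) == 0L) next
    # m is sorted ascending: binary search for the window bounds
    i1 <- findInterval(lo, m, left.open = TRUE) + 1L
    i2 <- findInterval(hi, m)
    if (i1 > i2) next
    sel <- (i1:i2)[abs(m[i1:i2] - target_mz) / target_mz * 1e6 <= ppm]
    if (length(sel) == 0L) next
    y <- run$intensity[[i]][sel]
    intensity[i] <- sum(y)
    matched[i] <- if (sum(y) > 0) sum(m[sel] * y) / sum(y) else mean(m[sel])
  }
  structure(list(rt = run$rt, intensity = intensity, matched_mz = matched,
                 target_mz = target_mz, ppm = ppm),
            class = "eic")
}

# Ricker (Mexican hat) wavelet sampled at integer offsets for one scale.
ricker_kernel <- function(scale) {
  hw <- max(2L, ceiling(5 * scale))
  x <- seq(-hw, hw)
  u <- x / scale
  (1 - u^2) * exp(-u^2 / 2) / sqrt(scale)
}

# CWT of y at the given scales; returns length(y) x length(scales) matrix.
cwt_ricker <- function(y, scales) {
  n <- length(y)
  out <- matrix(0, n, length(scales))
  for (j in seq_along(scales)) {
    k <- ricker_kernel(scales[j])
    hw <- (length(k) - 1L) %/% 2L
    padded <- c(numeric(hw), y, numeric(hw))
    conv <- stats::convolve(padded, rev(k), type = "open")
    out[, j] <- conv[(2L * hw + 1L):(2L * hw + n)]
  }
  out
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Default peak-picking settings
#'
#' CWT ridge-line settings: geometric scale grid (scans), minimum ridge
#' length, minimum signal-to-noise ratio (apex CWT coefficient over the
#' 95th percentile of the absolute smallest-scale coefficients), and the
#' boundary cap in units of the best-responding scale.
#'
#' @param scale_min,scale_max Smallest/largest wavelet scale in scans.
#' @param n_scales Number of geometric steps.
#' @param min_ridge Minimum ridge-line length (scales) for a candidate.
#' @param min_snr Minimum signal-to-noise ratio.
#' @param boundary_cap_scales Peak boundaries are capped at apex plus or
#'   minus this many best-scale scan spacings.
#' @return A list of settings.
#' @export
peak_settings <- function(scale_min = 2, scale_max = 32, n_scales = 10,
                          min_ridge = 3, min_snr = 3, boundary_cap_scales = 3) {
  list(scales = exp(seq(log(scale_min), log(scale_max), length.out = n_scales)),
       min_ridge = min_ridge, min_snr = min_snr,
       boundary_cap_scales = boundary_cap_scales)
}

# Link per-scale local maxima into ridge lines, walking from the largest
# scale down and matching the nearest maximum within a scale-dependent
# window. Returns a list of ridges (data.frames of scale index/position).
link_ridges <- function(coef, scales) {
  ns <- length(scales)
  maxima <- lapply(seq_len(ns), function(j) {
    idx <- local_maxima(coef[, j])
    idx[coef[idx, j] > 0]
  })
  ridges <- list()
  active <- list()
  for (j in rev(seq_len(ns))) {    # largest scale first
    pts <- maxima[[j]]
    used <- logical(length(pts))
    win <- max(2, scales[j])
    for (r in seq_along(active)) {
      rd <- active[[r]]
      last_pos <- rd$pos[length(rd$pos)]
      if (length(pts) > 0L) {
        d <- abs(pts - last_pos)
        k <- which.min(d)
        if (d[k] <= win && !used[k]) {
          active[[r]] <- list(scale_idx = c(rd$scale_idx, j),
                              pos = c(rd$pos, pts[k]), gap = 0L)
          used[k] <- TRUE
          next
        }
      }
      rd$gap <- rd$gap + 1L
      active[[r]] <- rd
    }
    # retire ridges with too many consecutive misses
    done <- vapply(active, function(rd) rd$gap > 2L, logical(1))
    ridges <- c(ridges, active[done])
    active <- active[!done]
    # unmatched maxima start new ridges
    for (k in which(!used)) {
      active[[length(active) + 1L]] <- list(scale_idx = j, pos = pts[k], gap = 0L)
    }
  }
  c(ridges, active)
}

#' Detect the target chromatographic peak in an EIC
#'
#' Computes the Ricker-wavelet CWT of the intensity trace, links local
#' CWT maxima across scales into ridge lines, filters candidates by
#' ridge length and SNR, and returns the candidate whose apex lies
#' within `expected_rt` plus/minus `rt_tol` and is nearest to
#' `expected_rt` (ties broken by higher apex intensity). Peak
#' boundaries are the nearest local minima of the smoothed trace
#' flanking the apex, capped at the apex plus/minus
#' `boundary_cap_scales` best-scale scan spacings.
#'
#' @param eic An `eic` from [extract_eic()].
#' @param expected_rt Expected retention time (seconds).
#' @param rt_tol Half-width of the retention-time search window (seconds).
#' @param settings Settings from [peak_settings()].
#' @return A list of class `chrom_peak` with `apex_rt`, `left_rt`,
#'   `right_rt`, `apex_intensity`, `area`, `measured_mz`, `snr`,
#'   `apex_idx`, `left_idx`, `right_idx`, `best_scale` — or `NULL` if no
#'   candidate apex falls inside the window.
#' @export
detect_peak <- function(eic, expected_rt, rt_tol, settings = peak_settings()) {
  stopifnot(inherits(eic, "eic"), rt_tol > 0)
  y <- eic$intensity
  n <- length(y)
  if (n < 5L || all(y <= 0)) return(NULL)
  scales <- settings$scales
  coef <- cwt_ricker(y, scales)

  # noise level: 95th percentile of |coef| at the smallest scale
  noise <- stats::quantile(abs(coef[, 1]), 0.95, names = FALSE)
  noise <- max(noise, .Machine$double.eps)

  ridges <- link_ridges(coef, scales)
  cand <- list()
  for (rd in ridges) {
    if (length(rd$scale_idx) < settings$min_ridge) next
    cc <- coef[cbind(rd$pos, rd$scale_idx)]
    best <- which.max(cc)
    snr <- cc[best] / noise
    if (!is.finite(snr) || snr < settings$min_snr) next
    # apex: refine at the smallest scale on the ridge to the local max of y
    apex0 <- rd$pos[length(rd$pos)]
    nb <- as.integer(max(1, round(scales[rd$scale_idx[length(rd$scale_idx)]])))
    lo <- max(1L, apex0 - nb); hi <- min(n, apex0 + nb)
    apex <- as.integer(lo + which.max(y[lo:hi]) - 1L)
    cand[[length(cand) + 1L]] <- list(apex_idx = apex, snr = snr,
                                      best_scale = scales[rd$scale_idx[best]],
                                      apex_intensity = y[apex])
  }
  if (length(cand) == 0L) return(NULL)
  apex_rt <- eic$rt[vapply(cand, `[[`, integer(1), "apex_idx")]
  in_win <- abs(apex_rt - expected_rt) <= rt_tol
  if (!any(in_win)) return(NULL)
  cand <- cand[in_win]; apex_rt <- apex_rt[in_win]
  d <- abs(apex_rt - expected_rt)
  ai <- vapply(cand, `[[`, numeric(1), "apex_intensity")
  pick <- order(d, -ai)[1]
  best <- cand[[pick]]

  bounds <- peak_boundaries(y, best$apex_idx, best$best_scale,
                            settings$boundary_cap_scales)
  pk <- structure(list(apex_rt = eic$rt[best$apex_idx],
                       left_rt = eic$rt[bounds[1]], right_rt = eic$rt[bounds[2]],
                       apex_intensity = best$apex_intensity, snr = best$snr,
                       apex_idx = best$apex_idx,
                       left_idx = bounds[1], right_idx = bounds[2],
                       best_scale = best$best_scale,
                       area = NA_real_, measured_mz = NA_real_),
                  class = "chrom_peak")
  pk$area <- integrate_area(eic, pk)
  idx <- bounds[1]:bounds[2]
  w <- eic$intensity[idx]
  mm <- eic$matched_mz[idx]
  ok <- !is.na(mm) & w > 0
  pk$measured_mz <- if (any(ok)) sum(mm[ok] * w[ok]) / sum(w[ok]) else NA_real_
  pk
}

# Boundaries: the minimum of the lightly smoothed trace nearest the
# apex on either side, within a window capped at apex +/- cap*scale
# scans. On a monotone flank the minimum sits at the cap; between
# co-eluting peaks it sits in the valley.
peak_boundaries <- function(y, apex, scale, cap) {
  n <- length(y)
  w <- max(1L, round(scale / 3))
  ys <- as.numeric(stats::filter(y, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  lim <- as.integer(max(2, ceiling(cap * scale)))
  li <- max(1L, apex - lim)
  lv <- ys[li:apex]
  left <- li + max(which(lv == min(lv))) - 1L       # nearest minimal point
  ri <- min(n, apex + lim)
  rv <- ys[apex:ri]
  right <- apex + min(which(rv == min(rv))) - 1L
  if (left == apex && apex > 1L) left <- apex - 1L
  if (right == apex && apex < n) right <- apex + 1L
  c(as.integer(left), as.integer(right))
}

#' Integrate the area under a chromatographic peak
#'
#' Trapezoidal integral of the EIC intensity between the peak
#' boundaries, in counts * seconds.
#'
#' @param eic An `eic`.
#' @param peak A `chrom_peak` (or any list with `left_idx`, `right_idx`).
#' @return Area in counts * seconds.
#' @export
integrate_area <- function(eic, peak) {
  i1 <- peak$left_idx; i2 <- peak$right_idx
  stopifnot(i1 >= 1L, i2 <= length(eic$rt))
  if (i2 <= i1) {
    warning("degenerate peak boundaries (left >= right); area is 0", call. = FALSE)
    return(0)
  }
  idx <- i1:i2
  sum(diff(eic$rt[idx]) * (utils::head(eic$intensity[idx], -1) +
                           utils::tail(eic$intensity[idx], -1)) / 2)
}

#' Measure one target feature in one run
#'
#' Extracts the ppm-windowed EIC at the target's theoretical m/z,
#' detects the chromatographic peak nearest the expected retention
#' time, and measures retention time, intensity-weighted m/z and
#' integrated area. When `ria = TRUE` and the target has a known carbon
#' count, the M+1 isotopolog EIC (target m/z + 1.00336 Da, same ppm
#' window) is integrated over the same boundaries and the relative
#' isotopolog abundance M+1/M is reported.
#'
#' @param run A `centroid_run`.
#' @param target One row of a [read_targets()] table (data.frame or list
#'   with `theoretical_mz`, `expected_rt_s`, optionally `n_carbon`).
#' @param ppm m/z window half-width (ppm).
#' @param rt_tol Retention-time window half-width (seconds).
#' @param ria Whether to measure the carbon isotopolog ratio.
#' @param settings Peak-picking settings.
#' @return A list with `found` plus, when found: `rt_s`, `mz`, `area`,
#'   `ria`, `snr`, `peak`, `eic`.
#' @export
measure_feature <- function(run, target, ppm = 5, rt_tol = 30, ria = FALSE,
                            settings = peak_settings()) {
  eic <- extract_eic(run, target$theoretical_mz, ppm)
  pk <- detect_peak(eic, target$expected_rt_s, rt_tol, settings)
  if (is.null(pk))
    return(list(found = FALSE, rt_s = NA_real_, mz = NA_real_, area = NA_real_,
                ria = NA_real_, snr = NA_real_, peak = NULL, eic = eic))
  ria_val <- NA_real_
  if (isTRUE(ria)) {
    eic1 <- extract_eic(run, target$theoretical_mz + .C13_C12_DELTA, ppm)
    a1 <- integrate_area(eic1, pk)
    ria_val <- if (pk$area > 0) a1 / pk$area else NA_real_
  }
  list(found = TRUE, rt_s = pk$apex_rt, mz = pk$measured_mz, area = pk$area,
       ria = ria_val, snr = pk$snr, peak = pk, eic = eic)
}
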