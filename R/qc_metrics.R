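# Quality parameters and four-zone classification.
#
# Each measured parameter (retention time, m/z, feature area) is
# compared against a reference — either a fixed target value or the
# data-based arithmetic mean over a scope — and the absolute deviation
# is classified into four colour zones (green/yellow/orange/red) by
# three ascending tolerance limits.

#' Signed mass accuracy in ppm
#'
#' `(measured - reference) / reference * 1e6`.
#'
#' @param measured_mz,reference_mz m/z values (Da); `reference_mz > 0`.
#' @return Signed ppm deviation.
#' @examples
#' ppm_error(211.1340, 211.1329)  # +5.21 ppm
#' @export
ppm_error <- function(measured_mz, reference_mz) {
  stopifnot(all(reference_mz > 0))
  (measured_mz - reference_mz) / reference_mz * 1e6
}

#' Signed retention-time deviation in seconds
#'
#' @param measured_rt,reference_rt Retention times in seconds.
#' @return `measured - reference` (seconds). User-facing tables report
#'   minutes.
#' @export
rt_deviation <- function(measured_rt, reference_rt) measured_rt - reference_rt

#' Relative feature-area bias in percent
#'
#' @param area Measured area(s).
#' @param reference_area Reference area, positive (typically the
#'   arithmetic mean of the found areas within the reference scope).
#' @return `(area - reference) / reference * 100`.
#' @export
area_bias <- function(area, reference_area) {
  stopifnot(all(reference_area > 0))
  (area - reference_area) / reference_area * 100
}

.ZONES <- c("green", "yellow", "orange", "red")

#' Four-zone classification of an absolute deviation
#'
#' With ascending limits `(g, y, o)`: `|value| <= g` is green,
#' `(g, y]` yellow, `(y, o]` orange, `> o` red (all boundaries
#' inclusive on the greener side). Missing values map to `"missing"`.
#'
#' @param value Signed deviation(s); the absolute value is classified.
#' @param limits Numeric vector of three ascending positive limits.
#' @return Character vector of zones.
#' @examples
#' classify_zone(c(3, 5.21, 8.0001), c(3, 5, 8))
#' @export
classify_zone <- function(value, limits) {
  stopifnot(length(limits) == 3L, all(limits > 0), !is.unsorted(limits, strictly = TRUE))
  v <- abs(value)
  z <- ifelse(is.na(v), "missing",
       ifelse(v <= limits[1], "green",
       ifelse(v <= limits[2], "yellow",
       ifelse(v <= limits[3], "orange", "red"))))
  z
}

#' Tolerance scheme for the four-zone classification
#'
#' Holds the per-parameter zone limits, reference mode and reference
#' scope. Defaults: mass accuracy limits (3, 5, 8) ppm; retention-time
#' deviation limits (6, 12, 30) s; area bias limits (20, 30, 50) %.
#' Retention time and m/z are referenced against the fixed values from
#' the target list; feature area against the data-based arithmetic mean
#' of the found areas within each measurement sequence (there is no
#' theoretical area).
#'
#' @param ppm_limits,rt_limits_s,area_limits_pct Three ascending
#'   positive limits each (ppm, seconds, percent).
#' @param reference Named list: reference mode per parameter, each
#'   `"fixed"` or `"data_mean"` (area has no fixed target and is always
#'   data-based).
#' @param scope Named list: reference scope per parameter, each
#'   `"per_sequence"` or `"global"`; used for `"data_mean"` references.
#' @return A list of class `tolerance_scheme`.
#' @export
tolerance_scheme <- function(ppm_limits = c(3, 5, 8),
                             rt_limits_s = c(6, 12, 30),
                             area_limits_pct = c(20, 30, 50),
                             reference = list(rt = "fixed", mz = "fixed",
                                              area = "data_mean"),
                             scope = list(rt = "global", mz = "global",
                                          area = "per_sequence")) {
  chk <- function(l) length(l) == 3L && all(l > 0) && !is.unsorted(l, strictly = TRUE)
  stopifnot(chk(ppm_limits), chk(rt_limits_s), chk(area_limits_pct))
  stopifnot(reference$rt %in% c("fixed", "data_mean"),
            reference$mz %in% c("fixed", "data_mean"),
            reference$area %in% "data_mean",
            all(unlist(scope) %in% c("per_sequence", "global")))
  structure(list(ppm_limits = ppm_limits, rt_limits_s = rt_limits_s,
                 area_limits_pct = area_limits_pct,
                 reference = reference, scope = scope),
            class = "tolerance_scheme")
}

# scope key per result row: sequence id under per_sequence, "" globally
.scope_key <- function(results, scope) {
  if (identical(scope, "per_sequence")) results$sequence_id else rep("", nrow(results))
}

# group-wise mean of found values; NA groups give NA reference
.group_mean <- function(value, found, key) {
  ref <- rep(NA_real_, length(value))
  for (k in unique(key)) {
    sel <- key == k & found & !is.na(value)
    if (any(sel)) ref[key == k] <- mean(value[sel])
  }
  ref
}

#' Evaluate raw measurements against a tolerance scheme
#'
#' Takes the raw per-(feature, file) measurement table produced by the
#' screening pipeline and adds references, signed deviations and zone
#' codes for retention time, mass accuracy and feature area. Not-found
#' features keep missing values and `"missing"` zones (rendered red in
#' the overview) and are excluded from data-based references.
#'
#' @param results Data.frame with columns `feature`, `sequence_id`,
#'   `category`, `found`, `rt_s`, `mz`, `area`, `expected_rt_s`,
#'   `theoretical_mz`.
#' @param scheme A [tolerance_scheme()].
#' @return `results` with added columns `rt_ref_s`, `rt_dev_s`,
#'   `mz_ref`, `ppm`, `area_ref`, `area_bias_pct`, `zone_rt`, `zone_mz`,
#'   `zone_area`.
#' @export
evaluate_results <- function(results, scheme = tolerance_scheme()) {
  stopifnot(inherits(scheme, "tolerance_scheme"))
  fkey <- results$feature

  ref_for <- function(param, measured, fixed_ref) {
    if (identical(scheme$reference[[param]], "fixed")) return(fixed_ref)
    key <- paste(fkey, .scope_key(results, scheme$scope[[param]]))
    .group_mean(measured, results$found, key)
  }

  results$rt_ref_s <- ref_for("rt", results$rt_s, results$expected_rt_s)
  results$rt_dev_s <- rt_deviation(results$rt_s, results$rt_ref_s)
  results$mz_ref <- ref_for("mz", results$mz, results$theoretical_mz)
  results$ppm <- NA_real_
  ok <- !is.na(results$mz) & !is.na(results$mz_ref) & results$mz_ref > 0
  results$ppm[ok] <- ppm_error(results$mz[ok], results$mz_ref[ok])
  akey <- paste(fkey, .scope_key(results, scheme$scope$area))
  results$area_ref <- .group_mean(results$area, results$found, akey)
  results$area_bias_pct <- NA_real_
  ok <- !is.na(results$area) & !is.na(results$area_ref) & results$area_ref > 0
  results$area_bias_pct[ok] <- area_bias(results$area[ok], results$area_ref[ok])

  results$zone_rt <- classify_zone(results$rt_dev_s, scheme$rt_limits_s)
  results$zone_mz <- classify_zone(results$ppm, scheme$ppm_limits)
  results$zone_area <- classify_zone(results$area_bias_pct, scheme$area_limits_pct)
  results
}

#' Summary statistics per feature, sequence and sample category
#'
#' Arithmetic mean, sample standard deviation (n-1) and relative
#' standard deviation of each parameter over the found results, grouped
#' by (feature, sequence) and by (feature, sample category). Not-found
#' results are excluded from the statistics and counted in `n_missing`.
#'
#' @param results Evaluated results from [evaluate_results()].
#' @return A data.frame with one row per (feature, grouping, group,
#'   parameter): `n`, `n_missing`, `mean`, `sd`, `rsd_pct`.
#' @export
summarize_results <- function(results) {
  params <- c(rt_s = "rt_s", mz = "mz", ppm = "ppm", area = "area", ria = "ria")
  groupings <- list(sequence = results$sequence_id, category = results$category)
  out <- list()
  for (gname in names(groupings)) {
    gval <- groupings[[gname]]
    for (feat in unique(results$feature)) {
      for (grp in unique(gval[results$feature == feat])) {
        sel <- results$feature == feat & gval == grp
        for (p in names(params)) {
          if (!params[p] %in% names(results)) next
          v <- results[[params[p]]][sel & results$found]
          v <- v[!is.na(v)]
          out[[length(out) + 1L]] <- data.frame(
            feature = feat, grouping = gname, group = grp, parameter = p,
            n = length(v), n_missing = sum(sel & !results$found),
            mean = if (length(v)) mean(v) else NA_real_,
            sd = if (length(v) > 1) stats::sd(v) else NA_real_,
            rsd_pct = if (length(v) > 1 && mean(v) != 0)
              stats::sd(v) / mean(v) * 100 else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
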