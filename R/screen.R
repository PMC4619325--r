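# End-to-end screening pipeline: sequences -> measurements -> QC
# evaluation -> tables, overview and plots.

#' Screen target features across measurement sequences
#'
#' Runs the full targeted QC pipeline: read the sequence CSVs,
#' categorise the files by filename prefix, read the target table,
#' measure every target in every file (ppm-windowed EIC, CWT peak
#' picking, area integration, optional M+1 isotopolog ratio), evaluate
#' the measurements against the tolerance scheme and write tabular,
#' overview and graphical output.
#'
#' Unreadable data files are logged, flagged missing for all targets
#' and do not abort the run.
#'
#' @param sequence_csvs Character vector of sequence CSV paths.
#' @param targets_path Path to the target table.
#' @param out_dir Output directory; created if needed. `NULL` skips all
#'   file output and returns the result object only.
#' @param ppm m/z window half-width (ppm).
#' @param rt_tol Retention-time window half-width (seconds).
#' @param separator Filename separator for sample categorisation.
#' @param categories Optional character vector restricting screening to
#'   these sample categories (default: all).
#' @param scheme A [tolerance_scheme()].
#' @param ria Whether to measure carbon isotopolog ratios.
#' @param settings Peak-picking settings from [peak_settings()].
#' @param x_axis `"order"` or `"time"`: x axis of the parameter plots.
#' @param image_format `"png"` or `"svg"`.
#' @param plots Whether to render parameter plots.
#' @param verbose Log per-file progress.
#' @return Invisibly, a list of class `qc_screen` with `entries`,
#'   `targets`, `results` (evaluated), `stats`, `eics`, `scheme`.
#' @export
run_screen <- function(sequence_csvs, targets_path, out_dir = NULL,
                       ppm = 5, rt_tol = 30, separator = "_",
                       categories = NULL, scheme = tolerance_scheme(),
                       ria = FALSE, settings = peak_settings(),
                       x_axis = c("order", "time"),
                       image_format = c("png", "svg"),
                       plots = !is.null(out_dir), verbose = FALSE) {
  x_axis <- match.arg(x_axis)
  image_format <- match.arg(image_format)
  entries <- do.call(rbind, lapply(sequence_csvs, read_sequence_csv))
  entries <- categorize_samples(entries, separator)
  if (!is.null(categories)) {
    entries <- entries[entries$category %in% categories, , drop = FALSE]
    if (nrow(entries) == 0L)
      stop("no sequence entries left after category filtering", call. = FALSE)
  }
  targets <- read_targets(targets_path)

  rows <- list()
  eics <- list()
  for (i in seq_len(nrow(entries))) {
    ent <- entries[i, ]
    fname <- basename(ent$file_path)
    run <- tryCatch(read_mzxml(ent$file_path), error = function(e) {
      message(sprintf("[hrmsqc] %s: read failed (%s); flagged missing",
                      fname, conditionMessage(e)))
      NULL
    })
    if (verbose && !is.null(run))
      message(sprintf("[hrmsqc] %s: %d scans", fname, n_scans(run)))
    for (j in seq_len(nrow(targets))) {
      tg <- targets[j, ]
      m <- if (is.null(run)) list(found = FALSE, rt_s = NA_real_, mz = NA_real_,
                                  area = NA_real_, ria = NA_real_, snr = NA_real_,
                                  eic = NULL)
           else measure_feature(run, tg, ppm = ppm, rt_tol = rt_tol,
                                ria = ria && !is.na(tg$n_carbon),
                                settings = settings)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = tg$name, ion = tg$ion, group = tg$group,
        file = fname, sequence_id = ent$sequence_id,
        order_index = ent$order_index, category = ent$category,
        acquisition_time = ent$acquisition_time,
        found = m$found, rt_s = m$rt_s, mz = m$mz, area = m$area,
        ria = m$ria, snr = m$snr,
        expected_rt_s = tg$expected_rt_s, theoretical_mz = tg$theoretical_mz,
        theoretical_ria = tg$theoretical_ria,
        stringsAsFactors = FALSE)
      eics[[paste(tg$name, fname, sep = "|")]] <- m$eic
    }
  }
  results <- do.call(rbind, rows)
  # global file order: CSV order of the sequences as given
  results$file_order <- match(results$file, unique(results$file))
  results <- evaluate_results(results, scheme)
  stats <- summarize_results(results)

  obj <- structure(list(entries = entries, targets = targets, results = results,
                        stats = stats, eics = eics, scheme = scheme,
                        params = list(ppm = ppm, rt_tol = rt_tol, ria = ria,
                                      x_axis = x_axis)),
                   class = "qc_screen")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(obj, out_dir)
    render_overview(obj, out_dir)
    if (plots) render_parameter_plots(obj, out_dir, x_axis = x_axis,
                                      image_format = image_format)
    zones <- unlist(results[c("zone_rt", "zone_mz", "zone_area")])
    message(sprintf("[hrmsqc] %d features x %d files; zones: %s",
                    nrow(targets), length(unique(results$file)),
                    paste(sprintf("%s=%d", names(table(zones)), table(zones)),
                          collapse = " ")))
  }
  invisible(obj)
}

#' @export
print.qc_screen <- function(x, ...) {
  cat(sprintf("<qc_screen> %d targets x %d files (%d sequences); %d/%d found\n",
              nrow(x$targets), length(unique(x$results$file)),
              length(unique(x$results$sequence_id)),
              sum(x$results$found), nrow(x$results)))
  invisible(x)
}

#' Write per-parameter and summary CSV tables
#'
#' Writes one CSV per quality parameter (retention time, m/z with ppm,
#' area with bias, and isotopolog ratio when measured) with one row per
#' (feature, file) — not-found rows are kept with missing-value markers
#' — plus a `summary.csv` of per-feature means/SDs per sequence and per
#' sample category. Retention times are reported in minutes.
#'
#' @param screen A `qc_screen` object.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(screen, out_dir) {
  r <- screen$results
  base <- r[c("feature", "ion", "file", "sequence_id", "order_index", "category",
              "found")]
  tabs <- list(
    tr = cbind(base, rt_min = r$rt_s / 60, rt_ref_min = r$rt_ref_s / 60,
               rt_dev_min = r$rt_dev_s / 60, zone = r$zone_rt),
    mz = cbind(base, mz = r$mz, mz_ref = r$mz_ref, zone = r$zone_mz),
    ppm = cbind(base, ppm = r$ppm, zone = r$zone_mz),
    area = cbind(base, area = r$area, area_ref = r$area_ref,
                 area_bias_pct = r$area_bias_pct, zone = r$zone_area))
  if (any(!is.na(r$ria)))
    tabs$ria <- cbind(base, ria = r$ria, theoretical_ria = r$theoretical_ria)
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "summary.csv")
  utils::write.csv(screen$stats, p, row.names = FALSE, na = "")
  invisible(c(paths, p))
}
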