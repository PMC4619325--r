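# mzXML input/output for centroided MS1 runs.
#
# A CentroidRun holds the MS1 scans of one file: a retention-time vector
# (seconds, increasing) plus per-scan centroid m/z and intensity vectors.
# Peak blobs are base64-encoded network-byte-order m/z-intensity pairs,
# 32- or 64-bit, optionally zlib-compressed.

.MZXML_NS <- "http://sashimi.sourceforge.net/schema_revision/mzXML_3.2"

new_centroid_run <- function(rt, mz, intensity, source_path = NA_character_,
                             polarity = NA_character_) {
  stopifnot(length(rt) == length(mz), length(mz) == length(intensity))
  structure(list(rt = as.numeric(rt), mz = mz, intensity = intensity,
                 source_path = source_path, polarity = polarity),
            class = "centroid_run")
}

#' @export
print.centroid_run <- function(x, ...) {
  cat(sprintf("<centroid_run> %d MS1 scans, rt %.1f-%.1f s, %d centroids (%s)\n",
              length(x$rt),
              if (length(x$rt)) min(x$rt) else NA, if (length(x$rt)) max(x$rt) else NA,
              sum(lengths(x$mz)),
              if (is.na(x$source_path)) "in memory" else basename(x$source_path)))
  invisible(x)
}

n_scans <- function(run) length(run$rt)

# "PT65.5S" -> 65.5; plain numbers are taken as seconds already.
parse_iso_duration_s <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  iso <- grepl("^PT", x)
  num[iso] <- suppressWarnings(as.numeric(sub("S$", "", sub("^PT", "", x[iso]))))
  num
}

decode_peaks_blob <- function(b64, precision, compression, n_peaks, scan_id = NA) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (!is.na(compression) && compression %in% c("zlib", "gzip")) {
    raw <- tryCatch(memDecompress(raw, type = "gzip"),
                    error = function(e) memDecompress(raw, type = "unknown"))
  }
  size <- if (precision == 32) 4L else 8L
  if (length(raw) %% (2L * size) != 0L)
    stop(sprintf("scan %s: peak blob length %d is not a multiple of %d",
                 scan_id, length(raw), 2L * size), call. = FALSE)
  vals <- readBin(raw, what = "numeric", n = length(raw) %/% size,
                  size = size, endian = "big")
  if (!is.na(n_peaks) && length(vals) != 2L * n_peaks)
    stop(sprintf("scan %s: decoded %d values but peaksCount declares %d peaks",
                 scan_id, length(vals), n_peaks), call. = FALSE)
  k <- length(vals) %/% 2L
  idx <- seq_len(k)
  list(mz = vals[2L * idx - 1L], intensity = vals[2L * idx])
}

encode_peaks_blob <- function(mz, intensity, precision = 64, compression = "none") {
  vals <- as.numeric(rbind(mz, intensity))
  size <- if (precision == 32) 4L else 8L
  raw <- writeBin(vals, raw(), size = size, endian = "big")
  if (compression == "zlib") raw <- memCompress(raw, type = "gzip")
  # unwrapped: some decoders reject whitespace inside peak blobs
  gsub("[\r\n]", "", jsonlite::base64_enc(raw))
}

#' Read a centroided mzXML file
#'
#' Loads MS1 scans of a centroided mzXML file into a `centroid_run`.
#' Retention times (ISO-8601 durations such as `"PT600.5S"`) are
#' converted to seconds; peak blobs (base64, network byte order, 32- or
#' 64-bit, optionally zlib-compressed) are decoded and checked against
#' the declared `peaksCount`. Scans with `msLevel != 1` are dropped.
#'
#' If the data look like profile mode (high median per-scan peak count
#' with quasi-uniform m/z spacing) a warning is emitted; targeted
#' screening assumes centroided input.
#'
#' @param path Path to an mzXML file.
#' @param profile_check_min_peaks Median per-scan peak count above which
#'   the profile-mode heuristic is applied.
#' @return A `centroid_run`.
#' @export
read_mzxml <- function(path, profile_check_min_peaks = 2000) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  scans <- xml2::xml_find_all(doc, ".//*[local-name()='scan']")
  if (length(scans) == 0L)
    stop(sprintf("%s: no <scan> elements found", path), call. = FALSE)
  ms_level <- as.integer(xml2::xml_attr(scans, "msLevel"))
  ms_level[is.na(ms_level)] <- 1L
  scans <- scans[ms_level == 1L]
  rt <- parse_iso_duration_s(xml2::xml_attr(scans, "retentionTime"))
  if (anyNA(rt))
    stop(sprintf("%s: scan without a parseable retentionTime", path), call. = FALSE)
  n_peaks <- as.integer(xml2::xml_attr(scans, "peaksCount"))
  scan_num <- xml2::xml_attr(scans, "num")
  polarity <- xml2::xml_attr(scans[1], "polarity")

  mz <- vector("list", length(scans))
  intensity <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    pk <- xml2::xml_find_first(scans[[i]], ".//*[local-name()='peaks']")
    if (inherits(pk, "xml_missing"))
      stop(sprintf("%s: scan %s has no <peaks> element", path, scan_num[i]),
           call. = FALSE)
    prec <- as.integer(xml2::xml_attr(pk, "precision"))
    if (is.na(prec)) prec <- 32L
    comp <- xml2::xml_attr(pk, "compressionType")
    dec <- decode_peaks_blob(xml2::xml_text(pk), prec, comp, n_peaks[i],
                             scan_id = scan_num[i])
    o <- order(dec$mz)
    mz[[i]] <- dec$mz[o]
    intensity[[i]] <- dec$intensity[o]
  }

  o <- order(rt)
  run <- new_centroid_run(rt[o], mz[o], intensity[o], source_path = path,
                          polarity = polarity)
  med_peaks <- stats::median(lengths(run$mz))
  if (is.finite(med_peaks) && med_peaks > profile_check_min_peaks) {
    sp <- unlist(lapply(run$mz[seq_len(min(5L, n_scans(run)))],
                        function(m) if (length(m) > 2) diff(m) else numeric(0)))
    if (length(sp) > 10 && stats::sd(sp) / mean(sp) < 0.5)
      warning(sprintf("%s: data may be profile mode (median %d peaks/scan, quasi-uniform spacing)",
                      path, med_peaks), call. = FALSE)
  }
  run
}

#' Write a centroid run as mzXML
#'
#' Writes MS1 scans with base64 network-byte-order peak blobs. 64-bit
#' encoding round-trips bit-exactly through [read_mzxml()].
#'
#' @param run A `centroid_run`.
#' @param path Output path.
#' @param precision 32 or 64 (bits per value).
#' @param compression `"none"` or `"zlib"`.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(run, path, precision = 64, compression = "none") {
  stopifnot(inherits(run, "centroid_run"), precision %in% c(32, 64),
            compression %in% c("none", "zlib"))
  n <- n_scans(run)
  scans <- character(n)
  for (i in seq_len(n)) {
    blob <- encode_peaks_blob(run$mz[[i]], run$intensity[[i]], precision, compression)
    scans[i] <- sprintf(
      paste0('  <scan num="%d" msLevel="1" peaksCount="%d" retentionTime="PT%.6fS"%s>\n',
             '   <peaks precision="%d" byteOrder="network" contentType="m/z-int"',
             ' compressionType="%s" compressedLen="0">%s</peaks>\n  </scan>'),
      i, length(run$mz[[i]]), run$rt[i],
      if (!is.na(run$polarity)) sprintf(' polarity="%s"', run$polarity) else "",
      precision, compression, blob)
  }
  xml <- paste0('<?xml version="1.0" encoding="ISO-8859-1"?>\n',
                sprintf('<mzXML xmlns="%s">\n <msRun scanCount="%d">\n', .MZXML_NS, n),
                paste(scans, collapse = "\n"),
                '\n </msRun>\n</mzXML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}
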