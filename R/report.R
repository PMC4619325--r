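# Coloured quality overview (HTML + CSV twin) and per-parameter plots.

.ZONE_FILL <- c(green = "#4caf50", yellow = "#ffeb3b", orange = "#ff9800",
                red = "#f44336", missing = "#bdbdbd")

#' Render the coloured quality overview
#'
#' Builds the features-by-files overview matrix: each cell shows the
#' measured tR (min), tR deviation, m/z, ppm, area and area bias of one
#' feature in one file, coloured by the worst of the three parameter
#' zones; per-feature averages are appended at the right margin.
#' Written as an HTML table and a machine-readable CSV twin carrying
#' the zone codes (identical cell-for-cell). Not-found cells are
#' rendered red with a missing marker; columns follow measurement
#' order.
#'
#' @param screen A `qc_screen` object from [run_screen()].
#' @param out_dir Output directory.
#' @return Invisibly, the two paths written (`overview.html`,
#'   `overview.csv`).
#' @export
render_overview <- function(screen, out_dir) {
  r <- screen$results
  files <- unique(r$file[order(r$file_order)])
  feats <- unique(r$feature)
  r$cell_zone <- cell_zone(r)

  # CSV twin: long format, one row per cell
  csv <- r[order(match(r$feature, feats), r$file_order),
           c("feature", "ion", "file", "sequence_id", "category", "found",
             "rt_s", "rt_dev_s", "mz", "ppm", "area", "area_bias_pct", "ria",
             "zone_rt", "zone_mz", "zone_area", "cell_zone")]
  csv$rt_min <- csv$rt_s / 60
  csv$rt_dev_min <- csv$rt_dev_s / 60
  csv_path <- file.path(out_dir, "overview.csv")
  utils::write.csv(csv[c("feature", "ion", "file", "sequence_id", "category",
                         "found", "rt_min", "rt_dev_min", "mz", "ppm", "area",
                         "area_bias_pct", "ria", "zone_rt", "zone_mz",
                         "zone_area", "cell_zone")],
                   csv_path, row.names = FALSE, na = "")

  fmt <- function(x, d) ifelse(is.na(x), "&#8211;", formatC(x, format = "f", digits = d))
  body <- character(0)
  for (ft in feats) {
    cells <- character(0)
    for (fl in files) {
      row <- r[r$feature == ft & r$file == fl, ][1, ]
      zl <- function(z) sprintf('<span class="z %s" title="%s"></span>', z, z)
      cells <- c(cells, sprintf(
        '<td class="cell %s">tR %s (%s) min %s<br/>m/z %s (%s ppm) %s<br/>A %s (%s%%) %s</td>',
        row$cell_zone,
        fmt(row$rt_s / 60, 2), fmt(row$rt_dev_s / 60, 2), zl(row$zone_rt),
        fmt(row$mz, 4), fmt(row$ppm, 2), zl(row$zone_mz),
        ifelse(is.na(row$area), "&#8211;", formatC(row$area, format = "e", digits = 2)),
        fmt(row$area_bias_pct, 1), zl(row$zone_area)))
    }
    st <- screen$stats
    msel <- st$feature == ft & st$grouping == "sequence"
    mrow <- function(p) {
      v <- st$mean[msel & st$parameter == p]
      if (length(v) == 0 || all(is.na(v))) "&#8211;"
      else paste(formatC(v, format = "g", digits = 4), collapse = " / ")
    }
    cells <- c(cells, sprintf(
      '<td class="cell summary">tR %s min<br/>m/z %s<br/>A %s</td>',
      mrow("rt_s"), mrow("mz"), mrow("area")))
    body <- c(body, sprintf('<tr><th class="feat">%s<br/><small>%s</small></th>%s</tr>',
                            ft, r$ion[r$feature == ft][1], paste(cells, collapse = "")))
  }
  header <- paste0("<th>", c("feature", files, "per-sequence mean"), "</th>",
                   collapse = "")
  css <- paste(
    "table{border-collapse:collapse;font:11px sans-serif}",
    "td,th{border:1px solid #999;padding:3px;text-align:left;vertical-align:top}",
    paste(sprintf(".cell.%s{background:%s%s}", names(.ZONE_FILL), .ZONE_FILL, "33"),
          collapse = " "),
    paste(sprintf(".z.%s{display:inline-block;width:9px;height:9px;background:%s;border:1px solid #555}",
                  names(.ZONE_FILL), .ZONE_FILL), collapse = " "),
    ".cell.summary{background:#eee}", sep = "\n")
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<title>Quality overview</title><style>", css, "</style></head><body>",
    "<h2>Coloured quality overview</h2>",
    "<p>Rows: target features; columns: data files in measurement order. ",
    "Cell colour = worst zone of tR / mass accuracy / area bias; ",
    "squares mark the per-parameter zones.</p>",
    "<table><tr>", header, "</tr>", paste(body, collapse = ""),
    "</table></body></html>")
  html_path <- file.path(out_dir, "overview.html")
  writeLines(html, html_path)
  invisible(c(html_path, csv_path))
}

# worst zone across the three parameters; not-found renders red
cell_zone <- function(r) {
  rank <- c(green = 1, yellow = 2, orange = 3, red = 4, missing = 5)
  z <- pmax(rank[r$zone_rt], rank[r$zone_mz], rank[r$zone_area])
  out <- names(rank)[z]
  out[!r$found] <- "missing"
  out
}

.zone_band_layers <- function(limits, ref = 0) {
  lims <- c(0, limits)
  fills <- c("#4caf50", "#ffeb3b", "#ff9800")
  bands <- lapply(seq_len(3), function(i)
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = c(ref - lims[i + 1], ref + lims[i]),
                      ymax = c(ref - lims[i], ref + lims[i + 1]),
                      fill = fills[i], alpha = 0.25))
  c(bands, list(ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                                  ymin = c(-Inf, ref + limits[3]),
                                  ymax = c(ref - limits[3], Inf),
                                  fill = "#f44336", alpha = 0.25)))
}

.save_plot <- function(p, path, image_format, width = 7, height = 4.5) {
  dev <- if (image_format == "svg") grDevices::svg else NULL
  ggplot2::ggsave(paste0(path, ".", image_format), p, device = dev,
                  width = width, height = height, dpi = 110)
  paste0(path, ".", image_format)
}

#' Render per-parameter plots
#'
#' For every target feature: (a) an EIC overlay across all files with a
#' file legend ("F<index> <filename>"); (b) feature area against
#' measurement order with zone bands around the area reference; (c)
#' retention time against order (ion species of the same group
#' overlaid); (d) mass accuracy (ppm) against order with zone bands and
#' mean plus/minus SD lines; plus per-category boxplots of area, tR and
#' ppm, and an isotopolog-ratio plot when RIA was measured. The x axis
#' is measurement order or acquisition time.
#'
#' @param screen A `qc_screen` object.
#' @param out_dir Output directory; plots land in `plots/`.
#' @param x_axis `"order"` or `"time"`.
#' @param image_format `"png"` or `"svg"`.
#' @return Invisibly, the written file paths.
#' @export
render_parameter_plots <- function(screen, out_dir,
                                   x_axis = c("order", "time"),
                                   image_format = c("png", "svg")) {
  x_axis <- match.arg(x_axis)
  image_format <- match.arg(image_format)
  pdir <- file.path(out_dir, "plots")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  r <- screen$results
  sch <- screen$scheme
  if (x_axis == "time" && !all(is.na(r$acquisition_time))) {
    r$x <- as.POSIXct(r$acquisition_time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    xlab <- "acquisition time"
  } else {
    r$x <- r$file_order
    xlab <- "measurement order"
  }
  written <- character(0)
  aes <- ggplot2::aes
  theme_qc <- ggplot2::theme_bw(base_size = 10)

  for (ft in unique(r$feature)) {
    d <- r[r$feature == ft, ]
    safe <- gsub("[^A-Za-z0-9._-]", "_", ft)

    # EIC overlay
    keys <- paste(ft, d$file, sep = "|")
    ed <- do.call(rbind, lapply(seq_along(keys), function(i) {
      e <- screen$eics[[keys[i]]]
      if (is.null(e)) return(NULL)
      data.frame(rt_min = e$rt / 60, intensity = e$intensity,
                 file = sprintf("F%d %s", d$file_order[i], d$file[i]))
    }))
    if (!is.null(ed) && nrow(ed) > 0) {
      p <- ggplot2::ggplot(ed, aes(x = rt_min, y = intensity, colour = file)) +
        ggplot2::geom_line(linewidth = 0.3) +
        ggplot2::labs(title = sprintf("EIC overlay: %s", ft),
                      x = "retention time (min)", y = "intensity (counts)") +
        theme_qc + ggplot2::theme(legend.text = ggplot2::element_text(size = 6))
      written <- c(written, .save_plot(p, file.path(pdir, paste0(safe, "_eic")),
                                       image_format, width = 9))
    }

    dfound <- d[d$found, ]
    if (nrow(dfound) > 0) {
      # area vs order with bias zone bands around the per-scope reference
      aref <- stats::median(dfound$area_ref, na.rm = TRUE)
      p <- ggplot2::ggplot(dfound, aes(x = x, y = area, colour = sequence_id))
      if (is.finite(aref) && aref > 0)
        p <- p + .zone_band_layers(sch$area_limits_pct / 100 * aref, ref = aref)
      p <- p + ggplot2::geom_point() + ggplot2::geom_line(linewidth = 0.2) +
        ggplot2::labs(title = sprintf("Feature area: %s", ft), x = xlab,
                      y = "area (counts · s)") + theme_qc
      written <- c(written, .save_plot(p, file.path(pdir, paste0(safe, "_area")),
                                       image_format))

      # tR vs order, same-group ion species overlaid
      grp <- d$group[1]
      dg <- r[r$group == grp & r$found, ]
      p <- ggplot2::ggplot(dg, aes(x = x, y = rt_s / 60, colour = ion,
                                   shape = sequence_id)) +
        .zone_band_layers(sch$rt_limits_s / 60, ref = d$expected_rt_s[1] / 60) +
        ggplot2::geom_point() +
        ggplot2::labs(title = sprintf("Retention time: %s", grp), x = xlab,
                      y = "tR (min)") + theme_qc
      written <- c(written, .save_plot(p, file.path(pdir, paste0(safe, "_tr")),
                                       image_format))

      # ppm vs order with zone bands and mean +/- sd
      mu <- mean(dfound$ppm, na.rm = TRUE)
      sdv <- stats::sd(dfound$ppm, na.rm = TRUE)
      p <- ggplot2::ggplot(dfound, aes(x = x, y = ppm, colour = sequence_id)) +
        .zone_band_layers(sch$ppm_limits, ref = 0) +
        ggplot2::geom_point() +
        ggplot2::geom_hline(yintercept = mu, linetype = 2) +
        ggplot2::labs(title = sprintf("Mass accuracy: %s", ft), x = xlab,
                      y = "mass accuracy (ppm)") + theme_qc
      if (is.finite(sdv))
        p <- p + ggplot2::geom_hline(yintercept = c(mu - sdv, mu + sdv),
                                     linetype = 3)
      written <- c(written, .save_plot(p, file.path(pdir, paste0(safe, "_ppm")),
                                       image_format))

      if (any(!is.na(dfound$ria))) {
        p <- ggplot2::ggplot(dfound, aes(x = x, y = ria, colour = sequence_id)) +
          ggplot2::geom_point() +
          ggplot2::geom_hline(yintercept = d$theoretical_ria[1], linetype = 2) +
          ggplot2::labs(title = sprintf("Isotopolog ratio M+1/M: %s", ft),
                        x = xlab, y = "RIA") + theme_qc
        written <- c(written, .save_plot(p, file.path(pdir, paste0(safe, "_ria")),
                                         image_format))
      }
    }
  }

  # per-category boxplots of area, tR and ppm
  rf <- r[r$found, ]
  if (nrow(rf) > 0) {
    box <- function(col, ylab, suffix) {
      p <- ggplot2::ggplot(rf, aes(x = category, y = .data[[col]])) +
        ggplot2::geom_boxplot(outlier.size = 0.8) +
        ggplot2::facet_wrap(~feature, scales = "free_y") +
        ggplot2::labs(x = "sample category", y = ylab) + theme_qc
      .save_plot(p, file.path(pdir, paste0("boxplot_", suffix)), image_format,
                 width = 8, height = 5)
    }
    rf$rt_min <- rf$rt_s / 60
    written <- c(written, box("area", "area (counts · s)", "area"),
                 box("rt_min", "tR (min)", "tr"),
                 box("ppm", "mass accuracy (ppm)", "ppm"))
  }
  invisible(written)
}
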