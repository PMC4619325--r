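# End-to-end screening pipeline, tabular output, overview and plots.

make_campaign <- function(dir, ...) {
  spec <- tiny_spec(...)
  cw <- write_campaign(spec, dir)
  list(spec = spec, cw = cw)
}

test_that("a clean campaign screens to all-green QC zones", {
  d <- withr::local_tempdir()
  camp <- make_campaign(d, seed = 31)
  out <- file.path(d, "out")
  suppressMessages(
    scr <- run_screen(camp$cw$sequence_csvs, camp$cw$targets_csv, out,
                      ppm = 8, rt_tol = 20, categories = "QCstd", plots = FALSE))
  r <- scr$results
  expect_true(all(r$found))
  expect_true(all(r$zone_rt == "green"))
  expect_true(all(r$zone_mz == "green"))
  expect_true(all(r$zone_area == "green"))
  # per-parameter CSVs: one row per (feature, file), none dropped
  tr <- read.csv(file.path(out, "tr.csv"))
  expect_equal(nrow(tr), nrow(camp$spec$features) * 2 * 4)  # 2 seq x 4 QCstd
  expect_true(file.exists(file.path(out, "summary.csv")))
  # summary means equal means recomputed from the detail rows
  ar <- read.csv(file.path(out, "area.csv"))
  st <- read.csv(file.path(out, "summary.csv"))
  for (s in c("S1", "S2")) {
    det <- mean(ar$area[ar$feature == "StdA" & ar$sequence_id == s])
    summ <- st$mean[st$feature == "StdA" & st$grouping == "sequence" &
                    st$group == s & st$parameter == "area"]
    expect_equal(summ, det, tolerance = 1e-9)
  }
})

test_that("overview HTML and CSV twin agree cell-for-cell on zones", {
  d <- withr::local_tempdir()
  camp <- make_campaign(d, seed = 32, mz_ppm_start = c(0, 4), mz_ppm_end = c(0, 4))
  out <- file.path(d, "out")
  suppressMessages(
    scr <- run_screen(camp$cw$sequence_csvs, camp$cw$targets_csv, out,
                      ppm = 8, rt_tol = 20, categories = "QCstd", plots = FALSE))
  ov <- read.csv(file.path(out, "overview.csv"))
  # cell count = features x files
  expect_equal(nrow(ov), nrow(camp$spec$features) * 8)
  html <- paste(readLines(file.path(out, "overview.html")), collapse = "\n")
  for (z in c("green", "yellow", "orange", "red", "missing")) {
    n_html <- lengths(regmatches(html, gregexpr(sprintf('class="cell %s"', z), html)))
    expect_equal(n_html, sum(ov$cell_zone == z), label = z)
  }
  # the injected +4 ppm sequence is flagged yellow on mass accuracy
  expect_true(all(ov$zone_mz[ov$sequence_id == "S2"] == "yellow"))
  expect_true(all(ov$zone_mz[ov$sequence_id == "S1"] == "green"))
})

test_that("a corrupt file is flagged missing without aborting the run", {
  d <- withr::local_tempdir()
  camp <- make_campaign(d, seed = 33)
  bad <- grep("QCstd_S1R03", camp$cw$mzxml_files, value = TRUE)
  writeLines("not xml at all", bad)
  out <- file.path(d, "out")
  suppressMessages(
    scr <- run_screen(camp$cw$sequence_csvs, camp$cw$targets_csv, out,
                      ppm = 8, rt_tol = 20, categories = "QCstd", plots = FALSE))
  r <- scr$results
  badcol <- r$file == basename(bad)
  expect_true(all(!r$found[badcol]))
  expect_true(all(r$found[!badcol]))
  # the column is retained in the overview, rendered as missing
  ov <- read.csv(file.path(out, "overview.csv"))
  expect_true(basename(bad) %in% ov$file)
  expect_true(all(ov$cell_zone[ov$file == basename(bad)] == "missing"))
})

test_that("screening output is deterministic for identical inputs", {
  d <- withr::local_tempdir()
  camp <- make_campaign(d, seed = 34)
  out1 <- file.path(d, "o1"); out2 <- file.path(d, "o2")
  for (o in c(out1, out2))
    suppressMessages(run_screen(camp$cw$sequence_csvs, camp$cw$targets_csv, o,
                                ppm = 8, rt_tol = 20, plots = FALSE))
  for (f in c("tr.csv", "mz.csv", "ppm.csv", "area.csv", "summary.csv",
              "overview.csv", "overview.html"))
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)),
                     label = f)
})

test_that("parameter plots are rendered and non-empty", {
  d <- withr::local_tempdir()
  camp <- make_campaign(d, seed = 35)
  out <- file.path(d, "out")
  suppressMessages(
    scr <- run_screen(camp$cw$sequence_csvs, camp$cw$targets_csv, out,
                      ppm = 8, rt_tol = 20, categories = "QCstd",
                      ria = TRUE, plots = TRUE))
  plots <- list.files(file.path(out, "plots"), full.names = TRUE)
  for (feat in camp$spec$features$name)
    for (kind in c("eic", "area", "tr", "ppm", "ria"))
      expect_true(any(grepl(sprintf("%s_%s\\.png$", feat, kind), plots)),
                  label = sprintf("%s %s plot", feat, kind))
  expect_true(all(file.size(plots) > 0))
  # RIA plot only when enabled
  out2 <- file.path(d, "out2")
  suppressMessages(run_screen(camp$cw$sequence_csvs, camp$cw$targets_csv, out2,
                              ppm = 8, rt_tol = 20, categories = "QCstd",
                              ria = FALSE, plots = TRUE))
  expect_false(any(grepl("_ria\\.png$", list.files(file.path(out2, "plots")))))
})

test_that("a target absent from every file yields missing rows, not an error", {
  d <- withr::local_tempdir()
  camp <- make_campaign(d, seed = 36)
  tt <- read.csv(file.path(d, "targets.csv"))
  tt <- rbind(tt, data.frame(name = "Ghost", formula = "C21H20O12", target_mz = NA,
                             ion = "[M+H]+", expected_tR_min = 2, group = "Ghost"))
  write.csv(tt, file.path(d, "targets.csv"), row.names = FALSE, na = "")
  suppressMessages(
    scr <- run_screen(camp$cw$sequence_csvs, file.path(d, "targets.csv"),
                      file.path(d, "out"), ppm = 8, rt_tol = 20,
                      categories = "QCstd", plots = FALSE))
  g <- scr$results[scr$results$feature == "Ghost", ]
  expect_true(all(!g$found))
  expect_true(all(g$zone_area == "missing"))
  expect_true(all(scr$results$found[scr$results$feature != "Ghost"]))
  # rows are present in the detail CSVs with missing markers
  ar <- read.csv(file.path(d, "out", "area.csv"))
  expect_equal(sum(ar$feature == "Ghost"), 8)
  expect_true(all(is.na(ar$area[ar$feature == "Ghost"])))
})

test_that("config files parse with CLI-style overrides taking precedence", {
  d <- withr::local_tempdir()
  p <- file.path(d, "run.cfg")
  writeLines(c("# run settings", "ppm = 6", "ppm_limits = 2,4,6", "ria = true"), p)
  cfg <- read_run_config(p)
  expect_equal(cfg$ppm, 6)
  expect_equal(cfg$ppm_limits, c(2, 4, 6))
  expect_true(cfg$ria)
  expect_equal(cfg$rt_tol, 30)  # untouched default
  cfg2 <- read_run_config(p, overrides = list(ppm = 3))
  expect_equal(cfg2$ppm, 3)
  writeLines("no_such_key = 1", p)
  expect_error(read_run_config(p), "unknown config key")
  expect_s3_class(config_scheme(cfg), "tolerance_scheme")
})
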