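# Quality parameters, four-zone classification and summaries.

test_that("ppm error is the signed relative deviation times 1e6", {
  expect_equal(round(ppm_error(211.1340, 211.1329), 2), 5.21)
  expect_equal(ppm_error(300, 300), 0)
  # antisymmetric to first order
  expect_equal(ppm_error(211.1340, 211.1329), -ppm_error(211.1329, 211.1340),
               tolerance = 1e-4)
})

test_that("retention-time deviation is a signed difference in seconds", {
  expect_equal(rt_deviation(1278, 1284), -6)   # -0.1 min
  expect_equal(rt_deviation(10, 10), 0)
})

test_that("area bias is the signed percent deviation from the reference", {
  areas <- c(1.0, 1.2, 0.8) * 1e5
  expect_equal(area_bias(areas, mean(areas)), c(0, 20, -20))
  expect_equal(area_bias(rep(5, 4), 5), rep(0, 4))
})

test_that("the four-zone classifier honours inclusive boundaries", {
  lim <- c(3, 5, 8)
  expect_equal(classify_zone(3.0, lim), "green")     # <= 3 is green
  expect_equal(classify_zone(-3.0, lim), "green")    # symmetric in sign
  expect_equal(classify_zone(4.2, lim), "yellow")
  expect_equal(classify_zone(5.0, lim), "yellow")
  expect_equal(classify_zone(5.21, lim), "orange")
  expect_equal(classify_zone(8.0, lim), "orange")
  expect_equal(classify_zone(8.0001, lim), "red")
  expect_equal(classify_zone(NA_real_, lim), "missing")
})

test_that("classification is monotone in |value|", {
  set.seed(9)
  lim <- sort(runif(3, 1, 20))
  rank <- c(green = 1, yellow = 2, orange = 3, red = 4)
  v <- sort(abs(rnorm(200, 0, 15)))
  z <- rank[classify_zone(v, lim)]
  expect_true(all(diff(z) >= 0))
})

test_that("evaluation assigns exactly one zone per parameter to found results", {
  res <- data.frame(
    feature = rep(c("A", "B"), each = 4),
    sequence_id = rep(c("S1", "S1", "S2", "S2"), 2),
    category = "QCstd",
    found = c(TRUE, TRUE, TRUE, FALSE, rep(TRUE, 4)),
    rt_s = c(100, 101, 99, NA, 200, 201, 199, 202),
    mz = c(211.1330, 211.1329, 211.1335, NA, 180.05, 180.05, 180.05, 180.05),
    area = c(1e5, 1.2e5, 0.8e5, NA, 2e5, 2e5, 2e5, 2e5),
    expected_rt_s = rep(c(100, 200), each = 4),
    theoretical_mz = rep(c(211.1329, 180.05), each = 4),
    stringsAsFactors = FALSE)
  ev <- evaluate_results(res, tolerance_scheme())
  found <- ev[ev$found, ]
  for (z in c("zone_rt", "zone_mz", "zone_area"))
    expect_true(all(found[[z]] %in% c("green", "yellow", "orange", "red")))
  nf <- ev[!ev$found, ]
  expect_true(all(nf$zone_rt == "missing" & nf$zone_mz == "missing" &
                  nf$zone_area == "missing"))
  expect_true(all(is.na(nf[c("rt_s", "mz", "area", "area_bias_pct")])))
})

test_that("data-mean area bias averages to zero within each scope", {
  set.seed(31)
  res <- data.frame(
    feature = "A", sequence_id = rep(c("S1", "S2"), each = 6),
    category = "QCstd", found = TRUE,
    rt_s = 100, mz = 200,
    area = c(runif(6, 0.9e5, 1.1e5), runif(6, 1.8e5, 2.2e5)),
    expected_rt_s = 100, theoretical_mz = 200, stringsAsFactors = FALSE)
  ev <- evaluate_results(res, tolerance_scheme())
  for (s in c("S1", "S2"))
    expect_equal(mean(ev$area_bias_pct[ev$sequence_id == s]), 0, tolerance = 1e-9)
  # per-sequence references differ by the sensitivity step
  refs <- tapply(ev$area_ref, ev$sequence_id, unique)
  expect_equal(refs[["S2"]] / refs[["S1"]], 2, tolerance = 0.15)
})

test_that("data-mean retention reference gives zero deviation for a single file", {
  res <- data.frame(feature = "A", sequence_id = "S1", category = "QCstd",
                    found = TRUE, rt_s = 123, mz = 200, area = 1e5,
                    expected_rt_s = 100, theoretical_mz = 200,
                    stringsAsFactors = FALSE)
  sch <- tolerance_scheme(reference = list(rt = "data_mean", mz = "fixed",
                                           area = "data_mean"))
  ev <- evaluate_results(res, sch)
  expect_equal(ev$rt_dev_s, 0)
})

test_that("summaries use the sample standard deviation and count missing separately", {
  res <- data.frame(
    feature = "A", sequence_id = "S1", category = "QCstd",
    found = c(TRUE, TRUE, FALSE),
    rt_s = c(100, 102, NA), mz = c(200, 200, NA), area = c(2, 4, NA),
    ria = NA_real_,
    expected_rt_s = 100, theoretical_mz = 200, stringsAsFactors = FALSE)
  ev <- evaluate_results(res, tolerance_scheme())
  st <- summarize_results(ev)
  a <- st[st$grouping == "sequence" & st$parameter == "area", ]
  expect_equal(a$n, 2L)
  expect_equal(a$n_missing, 1L)
  expect_equal(a$mean, 3)
  expect_equal(a$sd, sqrt(2))
  # RSD of a constant vector is zero
  m <- st[st$grouping == "sequence" & st$parameter == "mz", ]
  expect_equal(m$rsd_pct, 0)
  # a group of all not-found yields n = 0 and missing stats
  res$found <- FALSE
  res[c("rt_s", "mz", "area")] <- NA_real_
  st0 <- summarize_results(evaluate_results(res, tolerance_scheme()))
  a0 <- st0[st0$grouping == "sequence" & st0$parameter == "area", ]
  expect_equal(a0$n, 0L)
  expect_true(is.na(a0$mean))
})

test_that("tolerance schemes require strictly ascending positive limits", {
  expect_error(tolerance_scheme(ppm_limits = c(5, 3, 8)))
  expect_error(tolerance_scheme(rt_limits_s = c(0, 1, 2)))
  expect_silent(tolerance_scheme(ppm_limits = c(1, 2, 3)))
})
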