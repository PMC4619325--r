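# EIC extraction, CWT peak detection and area integration.

test_that("EIC picks up a single centroid at the target m/z", {
  run <- toy_run(1:3, list(list(mz = 200, intensity = 5),
                           list(mz = 300, intensity = 7),
                           list(mz = numeric(0), intensity = numeric(0))))
  e <- extract_eic(run, 200, 5)
  expect_equal(e$intensity, c(5, 0, 0))
  expect_equal(e$matched_mz, c(200, NA, NA))
})

test_that("the ppm window is closed: a centroid exactly at the boundary is included", {
  t <- 200
  ppm <- 5
  edge <- t + t * ppm / 1e6   # |edge - t|/t*1e6 == 5 exactly in doubles
  run <- toy_run(1, list(list(mz = edge, intensity = 3)))
  inside <- abs(edge - t) / t * 1e6 <= ppm
  e <- extract_eic(run, t, ppm)
  expect_equal(e$intensity, if (inside) 3 else 0)
  # and matches the brute-force filter on the same data either way
  expect_equal(e$intensity, brute_force_eic(run, t, ppm)$intensity)
})

test_that("windowed extraction is bit-identical to the brute-force filter", {
  set.seed(101)
  for (rep in 1:100) {
    run <- random_run(n_scans = 15, n_peaks = 40)
    t <- runif(1, 120, 480)
    ppm <- runif(1, 1, 500)
    e <- extract_eic(run, t, ppm)
    o <- brute_force_eic(run, t, ppm)
    expect_identical(e$intensity, o$intensity)
    expect_identical(e$matched_mz, o$matched_mz)
  }
})

test_that("enlarging the ppm window never decreases EIC intensity", {
  set.seed(7)
  run <- random_run(n_scans = 10, n_peaks = 50)
  prev <- rep(0, 10)
  for (ppm in c(1, 5, 20, 100, 1000)) {
    cur <- extract_eic(run, 250, ppm)$intensity
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("a noiseless Gaussian apex is located within one scan spacing", {
  rt <- seq(500, 700, by = 1)
  run <- gaussian_run(rt, mu = 600, sigma = 5, amplitude = 1e4)
  e <- extract_eic(run, 200, 5)
  pk <- detect_peak(e, expected_rt = 600, rt_tol = 30)
  expect_false(is.null(pk))
  expect_lte(abs(pk$apex_rt - 600), 1)
  expect_lt(pk$left_rt, pk$apex_rt)
  expect_gt(pk$right_rt, pk$apex_rt)
})

test_that("the candidate nearest the expected tR wins", {
  rt <- seq(500, 700, by = 1)
  y <- 1e4 * exp(-(rt - 580)^2 / (2 * 5^2)) + 8e3 * exp(-(rt - 615)^2 / (2 * 5^2))
  run <- toy_run(rt, lapply(y, function(v) list(mz = 200, intensity = v)))
  e <- extract_eic(run, 200, 5)
  pk <- detect_peak(e, expected_rt = 610, rt_tol = 30)
  # direct argmin oracle over the two true apexes
  expect_equal(which.min(abs(c(580, 615) - 610)), 2L)
  expect_lte(abs(pk$apex_rt - 615), 2)
  # with the expectation moved, the other peak is returned
  pk2 <- detect_peak(e, expected_rt = 585, rt_tol = 30)
  expect_lte(abs(pk2$apex_rt - 580), 2)
})

test_that("flat or empty traces yield a not-found result", {
  rt <- 1:50
  run <- toy_run(rt, lapply(rt, function(i) list(mz = numeric(0), intensity = numeric(0))))
  e <- extract_eic(run, 200, 5)
  expect_null(detect_peak(e, 25, 10))
})

test_that("no candidate inside the tR window yields not-found, not an error", {
  rt <- seq(0, 200, by = 1)
  run <- gaussian_run(rt, mu = 50, sigma = 5, amplitude = 1e4)
  e <- extract_eic(run, 200, 5)
  expect_null(detect_peak(e, expected_rt = 150, rt_tol = 20))
})

test_that("trapezoidal area matches closed forms", {
  # Gaussian: boundaries at +/-4 sigma capture essentially all of A*sigma*sqrt(2*pi)
  rt <- seq(0, 400, by = 1)
  sigma <- 8; A <- 5e3; mu <- 200
  run <- gaussian_run(rt, mu, sigma, A)
  e <- extract_eic(run, 200, 5)
  pk <- list(left_idx = which(rt == mu - 4 * sigma), right_idx = which(rt == mu + 4 * sigma))
  expect_equal(integrate_area(e, pk), A * sigma * sqrt(2 * pi), tolerance = 0.02)

  # rectangle of height h over w seconds
  rt2 <- seq(0, 10, by = 0.01)
  h <- 50
  run2 <- toy_run(rt2, lapply(rt2, function(t)
    if (t >= 2 && t <= 8) list(mz = 200, intensity = h) else list(mz = numeric(0), intensity = numeric(0))))
  e2 <- extract_eic(run2, 200, 5)
  pk2 <- list(left_idx = which.min(abs(rt2 - 2)), right_idx = which.min(abs(rt2 - 8)))
  expect_equal(integrate_area(e2, pk2), h * 6, tolerance = 0.01)

  # zero trace integrates to zero; degenerate boundaries warn
  e0 <- extract_eic(toy_run(1:10, lapply(1:10, function(i)
    list(mz = numeric(0), intensity = numeric(0)))), 200, 5)
  expect_equal(integrate_area(e0, list(left_idx = 2L, right_idx = 9L)), 0)
  expect_warning(a <- integrate_area(e0, list(left_idx = 3L, right_idx = 3L)),
                 "degenerate")
  expect_equal(a, 0)
})

test_that("apex and area recover over seeded noisy Gaussians (SNR >= 20)", {
  set.seed(202)
  n_ok_apex <- 0L
  rel_err <- numeric(0)
  n_cases <- 50
  for (i in seq_len(n_cases)) {
    sigma <- runif(1, 4, 10)
    A <- 10^runif(1, 3.5, 5)
    mu <- runif(1, 150, 250)
    rt <- seq(0, 400, by = 1)
    run <- gaussian_run(rt, mu, sigma, A, baseline_noise_sd = A / 200)
    e <- extract_eic(run, 200, 5)
    pk <- detect_peak(e, expected_rt = mu, rt_tol = 40)
    expect_false(is.null(pk), info = sprintf("case %d not found", i))
    if (abs(pk$apex_rt - mu) <= 1) n_ok_apex <- n_ok_apex + 1L
    rel_err <- c(rel_err, abs(pk$area - A * sigma * sqrt(2 * pi)) / (A * sigma * sqrt(2 * pi)))
  }
  expect_gte(n_ok_apex / n_cases, 0.95)
  expect_lte(max(rel_err), 0.05)
})

test_that("measured m/z and RIA recover generator ground truth", {
  spec <- tiny_spec(seed = 5, mz_ppm_start = 2, mz_ppm_end = 2, jitter_ppm_sd = 0.3)
  run <- simulate_run(spec, 1, 2)
  tg <- list(theoretical_mz = spec$features$theoretical_mz[1], expected_rt_s = 50,
             n_carbon = 12)
  m <- measure_feature(run, tg, ppm = 8, rt_tol = 20, ria = TRUE)
  expect_true(m$found)
  expect_equal(ppm_error(m$mz, tg$theoretical_mz), 2, tolerance = 0.1)
  expect_equal(m$ria, theoretical_ria("C12H18O3"), tolerance = 0.01)
})
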