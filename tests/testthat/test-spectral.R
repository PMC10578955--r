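test_that("window spectrum: tone peak, quadratic scaling, zero flag", {
  fs <- 40e6
  t <- (0:255) / fs
  tone <- matrix(sin(2 * pi * 5e6 * t), 256, 4)
  sp <- compute_window_spectrum(tone, fs)
  expect_equal(sp$freq_hz[which.max(sp$power)], 5e6, tolerance = fs / sp$nfft)
  # doubling amplitudes scales power by exactly 4
  sp2 <- compute_window_spectrum(2 * tone, fs)
  expect_equal(sp2$power, 4 * sp$power, tolerance = 1e-12)
  # all-zero window: flagged, not an error
  spz <- compute_window_spectrum(matrix(0, 64, 2), fs)
  expect_true(spz$flag_zero)
  expect_true(all(spz$power == 0))
  expect_error(compute_window_spectrum(matrix(0, 8, 2), fs), ">= 16")
})

test_that("white-noise spectrum matches a direct periodogram oracle", {
  fs <- 40e6
  set.seed(21)
  sigma <- 1.7
  x <- matrix(rnorm(128 * 1e4, 0, sigma), 128)
  sp <- compute_window_spectrum(x, fs)
  # oracle: direct per-line periodograms of the tapered lines
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:127) / 127)
  oracle <- rowMeans(abs(stats::mvfft(x * ham))^2)
  inb <- sp$freq_hz >= 3e6 & sp$freq_hz <= 8e6
  expect_equal(mean(sp$power[inb]),
               mean(oracle[seq_along(sp$power)][inb]), tolerance = 1e-10)
  # flat expectation: in-band mean equals E|FFT|^2 = sigma^2 sum(ham^2)
  expect_equal(mean(sp$power[inb]), sigma^2 * sum(ham^2), tolerance = 0.1)
})

test_that("normalization: identity, point-compensation rule, errors", {
  f <- seq(0, 20e6, by = 0.5e6)
  ps <- exp(-((f - 8e6) / 5e6)^2) + 0.1
  ns <- normalize_spectrum(ps, ps, f)
  expect_true(all(abs(ns$values_db) < 1e-12))
  # alpha = 0.5, d = 2 cm adds exactly 4*0.5*2*f dB (20 dB at 5 MHz)
  ns2 <- normalize_spectrum(ps, ps, f, atten_db_cm_mhz = 0.5, depth_cm = 2)
  expect_equal(ns2$values_db[f == 5e6], 20)
  expect_equal(ns2$values_db, 4 * 0.5 * 2 * f / 1e6, tolerance = 1e-12)
  expect_equal(attenuation_compensation_db(0.5, 5, 2), 20)
  expect_equal(attenuation_compensation_db(0, 5, 2), 0)
  expect_error(normalize_spectrum(ps, ps[-1], f), "must match")
  # nonpositive reference in band surfaces at fitting time
  bad <- ps; bad[f == 5e6] <- 0
  nsb <- normalize_spectrum(ps, bad, f)
  expect_true(is.na(nsb$values_db[f == 5e6]))
})

test_that("spectral line fit: exact lines and the MBF identity", {
  f <- seq(0, 20e6, by = 0.25e6)
  band <- analysis_band(3, 8)
  mk <- function(vals) normalize_spectrum(10^(vals / 10), rep(1, length(f)), f)
  # values exactly 2f + 4 dB -> SS = 2, SI = 4, MBF = 4 + 2 * 5.5 = 15
  fit <- fit_spectral_line(mk(2 * f / 1e6 + 4), band)
  expect_equal(fit$SS, 2, tolerance = 1e-10)
  expect_equal(fit$SI, 4, tolerance = 1e-10)
  expect_equal(fit$MBF, 15, tolerance = 1e-10)
  # constant -7 dB
  fit <- fit_spectral_line(mk(rep(-7, length(f))), band)
  expect_equal(fit$SS, 0, tolerance = 1e-12)
  expect_equal(fit$MBF, -7, tolerance = 1e-10)
  expect_equal(fit$SI, -7, tolerance = 1e-10)
  # identity MBF = SI + SS * f_center at machine precision on noisy input
  set.seed(2)
  for (i in 1:50) {
    fit <- fit_spectral_line(mk(rnorm(length(f), 0, 5)), band)
    expect_equal(fit$MBF, fit$SI + fit$SS * band$f_center,
                 tolerance = 1e-12)
  }
  expect_error(fit_spectral_line(mk(rep(1, length(f))), analysis_band(3, 3.1)),
               "fewer than 3")
})

test_that("noisy line: recovered slope is unbiased (OLS sampling check)", {
  set.seed(31)
  f <- seq(0, 20e6, by = 0.25e6)
  inb <- f / 1e6 >= 3 & f / 1e6 <= 8
  nrep <- 200
  slopes <- replicate(nrep, {
    vals <- -1.5 * f / 1e6 + 10 + rnorm(length(f), 0, 2)
    fit_spectral_line(
      normalize_spectrum(10^(vals / 10), rep(1, length(f)), f))$SS
  })
  se_theory <- 2 / sqrt(sum((f[inb] / 1e6 - mean(f[inb] / 1e6))^2)) /
    sqrt(nrep)
  expect_lt(abs(mean(slopes) - (-1.5)), 2 * se_theory)
})

test_that("Gaussian form factor: limits, monotonicity, closed form", {
  expect_equal(gaussian_form_factor(0, 80), 1)
  fs <- seq(1, 10, by = 1)
  expect_true(all(diff(gaussian_form_factor(fs, 80)) < 0))
  expect_true(all(gaussian_form_factor(5, c(40, 80, 120, 160)) ==
                    cummin(gaussian_form_factor(5, c(40, 80, 120, 160)))))
  # direct arithmetic oracle at (5 MHz, 80 um, 1540 m/s)
  k <- 2 * pi * 5e6 / 1540
  expect_equal(gaussian_form_factor(5, 80),
               exp(-0.827 * k^2 * (40e-6)^2), tolerance = 1e-14)
})

test_that("Anderson form factor: Rayleigh limit, scaling, truncation", {
  # ka -> 0: normalised form factor -> 1
  expect_equal(anderson_form_factor(0.01, 50), 1, tolerance = 1e-4)
  # unnormalised backscatter sum: |S|^2 ~ x^6 (Rayleigh) within 1% at ka<=0.1
  g <- 1.02; h <- 1.02
  s1 <- Mod(qusradiomics:::.anderson_sum(0.05, g, h))
  s2 <- Mod(qusradiomics:::.anderson_sum(0.10, g, h))
  expect_equal((s2 / s1)^2, 2^6, tolerance = 0.01)
  # equivalently the normalised form factor is within 1% of 1 at ka = 0.1
  c0 <- 1540; a <- 100e-6 / 2
  f_ka01 <- 0.1 / a * c0 / (2 * pi) / 1e6
  expect_equal(anderson_form_factor(f_ka01, 100), 1, tolerance = 0.01)
  # truncation: tightening the tolerance (more partial waves) changes the
  # sum by < 1e-8 relative at ka = 2
  sA <- qusradiomics:::.anderson_sum(2, g, h, tol = 1e-10)
  sB <- qusradiomics:::.anderson_sum(2, g, h, tol = 1e-16)
  expect_lt(Mod(sA - sB) / Mod(sB), 1e-8)
  expect_error(anderson_form_factor(200, 4000), "ka > 50")
})

test_that("form-factor fit: self-consistency, amplitude separation, scale", {
  f <- seq(3, 8, by = 0.25)
  band <- analysis_band()
  ref <- data.frame(f_mhz = seq(0.5, 15, by = 0.1),
                    bsc = 1e-4 * seq(0.5, 15, by = 0.1)^4)
  # synthesise a BSC curve exactly from the Gaussian model at ASD 100 um
  truth_db <- 10 * log10(3e-3 * f^4 * gaussian_form_factor(f, 100))
  ref_db <- 10 * log10(approx(ref$f_mhz, ref$bsc, f)$y)
  ns <- structure(list(freq_mhz = f, values_db = truth_db - ref_db,
                       window_depth_cm = 1), class = "normalized_spectrum")
  fit <- fit_form_factor(ns, ref, band, "gaussian")
  expect_equal(fit$ASD, 100, tolerance = 0.5)
  expect_lt(fit$residual, 1e-6)
  expect_false(fit$boundary)
  # multiplying the BSC by 10 raises AAC by exactly 10 dB, ASD unchanged
  ns10 <- ns; ns10$values_db <- ns$values_db + 10
  fit10 <- fit_form_factor(ns10, ref, band, "gaussian")
  expect_equal(fit10$ASD, fit$ASD)
  expect_equal(fit10$AAC - fit$AAC, 10, tolerance = 1e-10)
  # Anderson route runs and flags boundaries
  fa <- fit_form_factor(ns, ref, band, "anderson",
                        dict = form_factor_dictionary(f, "anderson",
                                                      seq(20, 60, 2)))
  expect_true(fa$boundary)   # optimum clipped at the narrow search bound
})

test_that("ASD estimates are invariant to RF amplitude scaling", {
  acq <- acquisition_spec()
  scat <- scatterer_spec(80, 16, 1, 0)
  fr <- suppressWarnings(simulate_rf_frame(acq, scat, 5, depth_cm = 1.2,
                                           n_lines = 40))
  ph <- suppressWarnings(simulate_reference_phantom(acq, 6, depth_cm = 1.2,
                                                    n_lines = 80))
  geo <- window_geometry(acq, sliding_window_config())
  r <- 150; cc <- 10
  run <- function(scale) {
    sw <- fr$rf[r:(r + geo$win_ax - 1), cc:(cc + geo$win_lat - 1)] * scale
    sp <- compute_window_spectrum(sw, acq$sampling_rate_hz)
    rp <- compute_window_spectrum(ph$rf[r:(r + geo$win_ax - 1), ],
                                  acq$sampling_rate_hz)
    ns <- normalize_spectrum(sp$power, rp$power, sp$freq_hz)
    fit_form_factor(ns, ph$reference_bsc, model = "gaussian")
  }
  f1 <- run(1); f3 <- run(3)
  expect_equal(f1$ASD, f3$ASD)                      # shape unchanged
  expect_equal(f3$AAC - f1$AAC, 20 * log10(3), tolerance = 1e-8)
})

test_that("Gaussian and Anderson ASD agree in rank over a diameter sweep", {
  # noiseless model curves generated from the Gaussian family at three
  # diameters; both parameterizations must rank them identically
  f <- seq(3, 8, by = 0.25)
  ref <- data.frame(f_mhz = seq(0.5, 15, by = 0.1),
                    bsc = 1e-4 * seq(0.5, 15, by = 0.1)^4)
  ref_db <- 10 * log10(approx(ref$f_mhz, ref$bsc, f)$y)
  dg <- form_factor_dictionary(f, "gaussian")
  da <- form_factor_dictionary(f, "anderson")
  est <- t(vapply(c(40, 80, 120), function(D) {
    y <- 10 * log10(1e-3 * f^4 * gaussian_form_factor(f, D))
    ns <- structure(list(freq_mhz = f, values_db = y - ref_db,
                         window_depth_cm = 1), class = "normalized_spectrum")
    c(fit_form_factor(ns, ref, model = "gaussian", dict = dg)$ASD,
      fit_form_factor(ns, ref, model = "anderson", dict = da)$ASD)
  }, numeric(2)))
  expect_equal(cor(est[, 1], est[, 2], method = "spearman"), 1)
})
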