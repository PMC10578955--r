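#' Analysis band for spectral fitting
#'
#' Default 3--8 MHz, the fixed fitting band; the band centre (5.5 MHz) is the
#' frequency at which the mid-band fit (MBF) is evaluated.
#'
#' @param f_low,f_high band edges in MHz.
#' @return list of class `analysis_band` with `f_low`, `f_high`, `f_center`.
#' @export
analysis_band <- function(f_low = 3, f_high = 8) {
  stopifnot(f_low < f_high, f_low >= 0)
  structure(list(f_low = f_low, f_high = f_high,
                 f_center = (f_low + f_high) / 2),
            class = "analysis_band")
}

#' Average power spectrum of an RF window
#'
#' Each scan line is tapered with a Hamming window, zero-padded to the next
#' power of two, Fourier transformed, and the squared magnitudes are averaged
#' across lines. The one-sided frequency grid is derived from the sampling
#' rate. An all-zero window returns an all-zero spectrum with `flag_zero`
#' set (not an error).
#'
#' @param window numeric matrix, axial samples x scan lines (>= 16 x 2).
#' @param sampling_rate sampling rate in Hz.
#' @return list with `freq_hz`, `power` (linear units), `nfft`, `flag_zero`.
#' @export
compute_window_spectrum <- function(window, sampling_rate) {
  window <- as.matrix(window)
  if (nrow(window) < 16 || ncol(window) < 2)
    stop("window must have >= 16 axial samples and >= 2 lines")
  n <- nrow(window)
  nfft <- 2^ceiling(log2(n))
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  tapered <- window * ham
  padded <- rbind(tapered, matrix(0, nfft - n, ncol(window)))
  X <- stats::mvfft(padded)
  ps <- rowMeans(Mod(X)^2)
  keep <- seq_len(nfft / 2 + 1)
  list(freq_hz = (keep - 1) * sampling_rate / nfft,
       power = ps[keep], nfft = nfft,
       flag_zero = all(window == 0))
}

#' Point-compensation attenuation term in dB
#'
#' Round-trip point compensation: the power spectrum is multiplied by
#' `10^(4 * alpha * f * d / 10)` at frequency `f` (MHz) and one-way depth `d`
#' (cm), i.e. `4 * alpha * f * d` dB are added. `alpha` is the attenuation
#' coefficient in dB/cm/MHz on the one-way amplitude (20 log10) convention.
#'
#' @param alpha_db_cm_mhz attenuation coefficient (dB/cm/MHz).
#' @param f_mhz frequency vector in MHz.
#' @param depth_cm one-way depth in cm.
#' @return compensation in dB (vector over `f_mhz`).
#' @export
attenuation_compensation_db <- function(alpha_db_cm_mhz, f_mhz, depth_cm) {
  stopifnot(alpha_db_cm_mhz >= 0, depth_cm >= 0)
  4 * alpha_db_cm_mhz * f_mhz * depth_cm
}

#' Normalize a sample power spectrum by a reference-phantom spectrum
#'
#' `values = 10*log10(sample/reference)` plus attenuation compensation for
#' the sample medium and (optionally, subtracted) for the phantom. Both
#' spectra must share one frequency grid. Bins where the reference is not
#' strictly positive are set to `NA`; fitting later errors if such bins fall
#' in the analysis band.
#'
#' @param sample_ps,reference_ps linear power spectra on a common grid.
#' @param freq_hz the common frequency grid (Hz).
#' @param atten_db_cm_mhz sample-medium attenuation coefficient.
#' @param depth_cm one-way depth of the window centre (cm).
#' @param phantom_atten_db_cm_mhz phantom attenuation (default 0).
#' @param phantom_depth_cm depth used for the phantom recording (defaults to
#'   `depth_cm`).
#' @return object of class `normalized_spectrum`: `freq_mhz`, `values_db`,
#'   `window_depth_cm`.
#' @export
normalize_spectrum <- function(sample_ps, reference_ps, freq_hz,
                               atten_db_cm_mhz = 0, depth_cm = 0,
                               phantom_atten_db_cm_mhz = 0,
                               phantom_depth_cm = depth_cm) {
  if (length(sample_ps) != length(reference_ps) ||
      length(sample_ps) != length(freq_hz))
    stop("sample, reference and frequency grids must match")
  f_mhz <- freq_hz / 1e6
  vals <- rep(NA_real_, length(freq_hz))
  ok <- reference_ps > 0 & sample_ps >= 0
  vals[ok] <- 10 * log10(pmax(sample_ps[ok], .Machine$double.xmin) /
                           reference_ps[ok])
  vals <- vals +
    attenuation_compensation_db(atten_db_cm_mhz, f_mhz, depth_cm) -
    attenuation_compensation_db(phantom_atten_db_cm_mhz, f_mhz,
                                phantom_depth_cm)
  structure(list(freq_mhz = f_mhz, values_db = vals,
                 window_depth_cm = depth_cm),
            class = "normalized_spectrum")
}

.in_band <- function(ns, band) {
  which(ns$freq_mhz >= band$f_low & ns$freq_mhz <= band$f_high &
          is.finite(ns$values_db))
}

#' Fit the spectral regression line: MBF, SS, SI
#'
#' Ordinary least squares of the normalized spectrum (dB) against frequency
#' (MHz) over the in-band bins. SI is the intercept at 0 MHz, SS the slope,
#' and MBF the fitted value at the band centre, so the identity
#' `MBF = SI + SS * f_center` holds exactly.
#'
#' @param ns a `normalized_spectrum`.
#' @param band an [analysis_band()].
#' @return list of class `spectral_fit`: `MBF` (dB), `SS` (dB/MHz), `SI`
#'   (dB), `band`.
#' @export
fit_spectral_line <- function(ns, band = analysis_band()) {
  idx <- .in_band(ns, band)
  if (length(idx) < 3) stop("fewer than 3 in-band frequency bins")
  f <- ns$freq_mhz[idx]
  y <- ns$values_db[idx]
  fm <- mean(f)
  ss <- sum((f - fm) * (y - mean(y))) / sum((f - fm)^2)
  si <- mean(y) - ss * fm
  structure(list(MBF = si + ss * band$f_center, SS = ss, SI = si,
                 band = band),
            class = "spectral_fit")
}

#' Gaussian form factor
#'
#' `F(f) = exp(-0.827 * k^2 * a^2)` with `k = 2 pi f / c` and `a` the
#' effective radius (half the effective scatterer diameter). Equals 1 in the
#' Rayleigh limit `f -> 0` and decreases monotonically in both frequency and
#' diameter.
#'
#' @param f_mhz frequency in MHz (vectorised).
#' @param diameter_um effective scatterer diameter in micrometres.
#' @param c_mps speed of sound (m/s).
#' @return dimensionless form factor in (0, 1].
#' @export
gaussian_form_factor <- function(f_mhz, diameter_um, c_mps = 1540) {
  stopifnot(diameter_um > 0)
  k <- 2 * pi * f_mhz * 1e6 / c_mps
  a <- diameter_um * 1e-6 / 2
  exp(-0.827 * k^2 * a^2)
}

# spherical Bessel j_n and y_n for orders 0..nmax at scalar x > 0.
# y_n by stable upward recurrence; j_n by downward (Miller) recurrence
# normalised with j_0.
.sph_bessel <- function(nmax, x) {
  stopifnot(x > 0)
  y <- numeric(nmax + 2)
  y[1] <- -cos(x) / x
  if (nmax + 1 >= 1) y[2] <- -cos(x) / x^2 - sin(x) / x
  if (nmax + 1 >= 2)
    for (n in 1:nmax) y[n + 2] <- (2 * n + 1) / x * y[n + 1] - y[n]
  nstart <- nmax + 15 + ceiling(x)
  jj <- numeric(nstart + 2)
  jj[nstart + 2] <- 0
  jj[nstart + 1] <- 1e-30
  for (n in nstart:1) jj[n] <- (2 * n + 1) / x * jj[n + 1] - jj[n + 2]
  j0 <- sin(x) / x
  scale <- j0 / jj[1]
  j <- jj[seq_len(nmax + 2)] * scale
  list(j = j[seq_len(nmax + 1)], y = y[seq_len(nmax + 1)],
       # derivatives f_n' = f_{n-1} - (n+1)/x f_n  (n >= 1); f_0' = -f_1
       jp = c(-j[2], j[seq_len(nmax)] - (2:(nmax + 1)) / x * j[2:(nmax + 1)]),
       yp = c(-y[2], y[seq_len(nmax)] - (2:(nmax + 1)) / x * y[2:(nmax + 1)]))
}

# backscatter partial-wave sum S(x) = sum (2n+1) (-1)^n b_n for a fluid
# sphere, x = ka; truncated when successive terms fall below 1e-10 of the
# running sum.
.anderson_sum <- function(x, g, h, tol = 1e-10, nmax_cap = 200L) {
  x1 <- x / h
  nmax <- min(nmax_cap, ceiling(x + 10 + 15))
  B <- .sph_bessel(nmax, x)
  B1 <- .sph_bessel(nmax, x1)
  S <- 0 + 0i
  for (n in 0:nmax) {
    jn <- B$j[n + 1]; jnp <- B$jp[n + 1]
    yn <- B$y[n + 1]; ynp <- B$yp[n + 1]
    hn <- complex(real = jn, imaginary = yn)
    hnp <- complex(real = jnp, imaginary = ynp)
    j1 <- B1$j[n + 1]; j1p <- B1$jp[n + 1]
    D <- j1p / (g * h * j1)
    bn <- (D * jn - jnp) / (hnp - D * hn)
    term <- (2 * n + 1) * (-1)^n * bn
    S <- S + term
    if (n >= 2 && Mod(term) < tol * Mod(S)) break
  }
  if (n == nmax && nmax == nmax_cap)
    stop("Anderson partial-wave series did not converge (ka = ", x, ")")
  S
}

#' Anderson (fluid-sphere) backscatter form factor
#'
#' Backscatter form factor of a fluid sphere with density ratio `g` and
#' sound-speed ratio `h` relative to the host medium, from the classical
#' partial-wave series in spherical Bessel functions, normalized to 1 in the
#' Rayleigh limit `ka -> 0`.
#'
#' @param f_mhz frequency in MHz (vectorised).
#' @param diameter_um sphere diameter in micrometres.
#' @param c_mps host speed of sound (m/s).
#' @param g,h density and sound-speed ratios (interior / host), both > 0.
#' @return dimensionless form factor (1 at `f = 0`).
#' @export
anderson_form_factor <- function(f_mhz, diameter_um, c_mps = 1540,
                                 g = 1.02, h = 1.02) {
  stopifnot(diameter_um > 0, g > 0, h > 0)
  a <- diameter_um * 1e-6 / 2
  x <- 2 * pi * f_mhz * 1e6 / c_mps * a
  if (any(x > 50)) stop("ka > 50: outside the validated series range")
  # Rayleigh normalisation: |S(x)| ~ K x^3 as x -> 0
  K <- Mod(.anderson_sum(1e-3, g, h)) / 1e-9
  vapply(x, function(xi) {
    if (xi <= 0) return(1)
    (Mod(.anderson_sum(xi, g, h)) / (K * xi^3))^2
  }, numeric(1))
}

#' Precompute a form-factor dictionary over a diameter grid
#'
#' Used by the map builder so thousands of window fits share one model
#' matrix. Columns are `10*log10(f^4 * FF(f, D))` curves.
#'
#' @param f_mhz in-band frequency grid (MHz).
#' @param model `"gaussian"` or `"anderson"`.
#' @param diameters_um diameter grid (micrometres).
#' @param c_mps speed of sound; `g`, `h` Anderson contrasts.
#' @param g,h Anderson fluid-sphere contrast ratios.
#' @return list with `diameters_um` and `model_db` (length(f) x length(D)).
#' @export
form_factor_dictionary <- function(f_mhz, model = c("gaussian", "anderson"),
                                   diameters_um = seq(10, 300, by = 0.5),
                                   c_mps = 1540, g = 1.02, h = 1.02) {
  model <- match.arg(model)
  ff <- vapply(diameters_um, function(D) {
    if (model == "gaussian") gaussian_form_factor(f_mhz, D, c_mps)
    else anderson_form_factor(f_mhz, D, c_mps, g, h)
  }, numeric(length(f_mhz)))
  list(model = model, diameters_um = diameters_um,
       model_db = 10 * log10(outer(f_mhz^4, rep(1, length(diameters_um))) *
                               ff))
}

#' Fit a backscatter form-factor model: ASD and AAC
#'
#' The sample backscatter coefficient is reconstructed as the reference
#' curve times the linear-scale normalized spectrum; the average scatterer
#' diameter (ASD) minimises the mean squared in-band deviation between the
#' measured `10*log10(BSC)` and `10*log10(AAC_lin * f^4 * FF(f, ASD))` over a
#' 0.5-um diameter grid (plus parabolic refinement); the average acoustic
#' concentration (AAC) is the best-fit amplitude in dB relative to an
#' arbitrary-but-fixed reference (only relative AAC values are meaningful).
#'
#' @param ns a `normalized_spectrum`.
#' @param reference_bsc data.frame with `f_mhz`, `bsc` (linear) — the known
#'   phantom backscatter curve.
#' @param band an [analysis_band()].
#' @param model `"gaussian"` or `"anderson"`.
#' @param dict optional precomputed [form_factor_dictionary()] on the band
#'   grid (must match the in-band bins of `ns`).
#' @param ... passed to [form_factor_dictionary()].
#' @return list of class `backscatter_fit`: `model`, `ASD` (um), `AAC`
#'   (dB/cm3, arbitrary fixed offset), `residual` (dB^2), `boundary` flag.
#' @export
fit_form_factor <- function(ns, reference_bsc, band = analysis_band(),
                            model = c("gaussian", "anderson"), dict = NULL,
                            ...) {
  model <- match.arg(model)
  idx <- .in_band(ns, band)
  if (length(idx) < 3) stop("fewer than 3 in-band frequency bins")
  f <- ns$freq_mhz[idx]
  ref <- stats::approx(reference_bsc$f_mhz, reference_bsc$bsc, xout = f)$y
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("reference BSC not positive/finite over the analysis band")
  bsc_db <- 10 * log10(ref) + ns$values_db[idx]
  if (any(!is.finite(bsc_db))) stop("non-finite BSC in band")
  if (is.null(dict)) dict <- form_factor_dictionary(f, model, ...)
  M <- dict$model_db
  ycen <- bsc_db - mean(bsc_db)
  Mcen <- sweep(M, 2, colMeans(M))
  rss <- colMeans((Mcen - ycen)^2)
  i <- which.min(rss)
  D <- dict$diameters_um
  # parabolic refinement on the discrete rss curve
  if (i > 1 && i < length(D)) {
    num <- rss[i - 1] - rss[i + 1]
    den <- rss[i - 1] - 2 * rss[i] + rss[i + 1]
    asd <- if (den > 0) D[i] + 0.5 * num / den * (D[2] - D[1]) else D[i]
  } else asd <- D[i]
  aac_db <- mean(bsc_db) - mean(M[, i])
  structure(list(model = model, ASD = asd, AAC = aac_db,
                 residual = rss[i],
                 boundary = (i == 1 || i == length(D))),
            class = "backscatter_fit")
}
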