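#' Acquisition geometry specification
#'
#' Defaults reproduce a clinical linear-array acquisition: 40 MHz sampling,
#' 256 scan lines over a 3.8 cm lateral field of view, up to 5 cm depth, a
#' pulse centred at 10 MHz with 110% fractional bandwidth (chosen so the
#' 3--8 MHz analysis band lies inside the -5 dB envelope of the pulse power
#' spectrum; a narrower pulse leaves the band edges dominated by spectral
#' leakage from the passband), and a fixed
#' soft-tissue speed of sound of 1540 m/s (used for the depth <-> sample
#' conversion; one axial sample spans `c / (2 fs)`).
#'
#' @param sampling_rate_hz RF sampling rate (Hz).
#' @param num_lines lateral scan lines.
#' @param lateral_fov_cm lateral field of view (cm).
#' @param max_depth_cm maximum imaging depth (cm).
#' @param pulse_center_hz pulse centre frequency (Hz).
#' @param pulse_fractional_bandwidth FWHM of the pulse amplitude spectrum
#'   divided by the centre frequency.
#' @param speed_of_sound_mps speed of sound (m/s).
#' @return list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_rate_hz = 40e6, num_lines = 256L,
                             lateral_fov_cm = 3.8, max_depth_cm = 5,
                             pulse_center_hz = 10e6,
                             pulse_fractional_bandwidth = 1.1,
                             speed_of_sound_mps = 1540) {
  stopifnot(num_lines >= 1, sampling_rate_hz > 0, lateral_fov_cm > 0,
            max_depth_cm > 0, pulse_fractional_bandwidth > 0)
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 num_lines = as.integer(num_lines),
                 lateral_fov_cm = lateral_fov_cm,
                 max_depth_cm = max_depth_cm,
                 pulse_center_hz = pulse_center_hz,
                 pulse_fractional_bandwidth = pulse_fractional_bandwidth,
                 speed_of_sound_mps = speed_of_sound_mps),
            class = "acquisition_spec")
}

#' Axial sample spacing and lateral line pitch (mm)
#' @param acq an [acquisition_spec()].
#' @return named vector `c(axial_mm, lateral_mm)`.
#' @export
pixel_pitch_mm <- function(acq) {
  c(axial_mm = acq$speed_of_sound_mps / (2 * acq$sampling_rate_hz) * 1e3,
    lateral_mm = acq$lateral_fov_cm * 10 / acq$num_lines)
}

#' Scatterer population specification
#'
#' Describes the random medium a simulated frame is built from: the effective
#' scatterer diameter (the ground truth that ASD estimators should recover),
#' the areal number density, the per-scatterer amplitude variance (the AAC
#' proxy: mean backscattered power scales with `variance * density`), and a
#' frequency-linear attenuation coefficient.
#'
#' @param effective_diameter_um ground-truth scatterer diameter (um), > 0.
#' @param number_density_mm2 scatterers per mm^2, > 0.
#' @param amplitude_variance variance of the zero-mean Gaussian scattering
#'   amplitudes (arbitrary units), >= 0.
#' @param attenuation_db_cm_mhz one-way amplitude attenuation (dB/cm/MHz),
#'   >= 0.
#' @return list of class `scatterer_spec`.
#' @export
scatterer_spec <- function(effective_diameter_um = 80,
                           number_density_mm2 = 16,
                           amplitude_variance = 1,
                           attenuation_db_cm_mhz = 0) {
  stopifnot(effective_diameter_um > 0, number_density_mm2 > 0,
            amplitude_variance >= 0, attenuation_db_cm_mhz >= 0)
  structure(list(effective_diameter_um = effective_diameter_um,
                 number_density_mm2 = number_density_mm2,
                 amplitude_variance = amplitude_variance,
                 attenuation_db_cm_mhz = attenuation_db_cm_mhz),
            class = "scatterer_spec")
}

# one-sided pulse amplitude spectrum on f (Hz)
.pulse_spectrum <- function(acq, f_hz) {
  sigma <- acq$pulse_fractional_bandwidth * acq$pulse_center_hz /
    (2 * sqrt(2 * log(2)))
  exp(-(f_hz - acq$pulse_center_hz)^2 / (2 * sigma^2))
}

#' Simulate one RF speckle frame from a random scatterer medium
#'
#' Lines are synthesised independently (delta lateral beam): scatterer
#' positions are drawn from a homogeneous Poisson process over each line's
#' lateral strip, amplitudes are zero-mean Gaussian, the size-dependent
#' Gaussian form factor shapes the per-scatterer spectrum (amplitude
#' `f^2 sqrt(FF(f))`, the Rayleigh-plus-form-factor response), the
#' Gaussian-modulated pulse is applied in the frequency domain, and depth-
#' and frequency-dependent attenuation multiplies each scatterer's echo by
#' `10^(-alpha f z / 5)` in amplitude — the exact counterpart of the
#' round-trip point-compensation rule (`4 alpha f z` dB in power).
#'
#' @param acq an [acquisition_spec()].
#' @param scat a [scatterer_spec()].
#' @param seed integer RNG seed; the same specs and seed give bit-identical
#'   frames.
#' @param depth_cm simulated depth (defaults to `acq$max_depth_cm`).
#' @param n_lines number of lines to simulate (defaults to `acq$num_lines`).
#' @param focal_depth_cm nominal focal depth recorded with the frame.
#' @return object of class `rf_frame`: `rf` (samples x lines), `acquisition`,
#'   `focal_depth_cm`, `attenuation_db_cm_mhz`, and `ground_truth` (the
#'   ASD/AAC-proxy/attenuation used, plus `low_density_warning` when the
#'   expected number of scatterers per resolution cell falls below 1).
#' @export
simulate_rf_frame <- function(acq, scat, seed, depth_cm = acq$max_depth_cm,
                              n_lines = acq$num_lines,
                              focal_depth_cm = 1.75) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(scat, "scatterer_spec"))
  set.seed(as.integer(seed))
  fs <- acq$sampling_rate_hz
  c0 <- acq$speed_of_sound_mps
  n_samp <- ceiling(2 * depth_cm * 1e-2 / c0 * fs)
  nfft <- 2^ceiling(log2(n_samp + 64))
  f_hz <- (0:(nfft / 2)) * fs / nfft
  f_mhz <- f_hz / 1e6
  pitch_mm <- pixel_pitch_mm(acq)[["lateral_mm"]]
  strip_area_mm2 <- pitch_mm * depth_cm * 10
  base <- .pulse_spectrum(acq, f_hz) * f_mhz^2 *
    sqrt(gaussian_form_factor(f_mhz, scat$effective_diameter_um,
                              c0))
  rf <- matrix(0, n_samp, n_lines)
  if (scat$amplitude_variance > 0) {
    for (l in seq_len(n_lines)) {
      ns <- rpois(1, scat$number_density_mm2 * strip_area_mm2)
      if (ns == 0) next
      z_cm <- runif(ns, 0, depth_cm)
      amp <- rnorm(ns, 0, sqrt(scat$amplitude_variance))
      tau <- 2 * z_cm * 1e-2 / c0
      att <- 10^(-scat$attenuation_db_cm_mhz *
                   outer(f_mhz, z_cm) / 5)
      ph <- exp(-2i * pi * outer(f_hz, tau))
      spec_half <- base * drop((att * ph) %*% amp)
      full <- c(spec_half, Conj(rev(spec_half[2:(nfft / 2)])))
      x <- Re(fft(full, inverse = TRUE)) / nfft
      rf[, l] <- x[seq_len(n_samp)]
    }
  }
  # resolution cell ~ pulse axial extent x nominal 1 mm elevation/beam width
  pulse_len_mm <- c0 / (2 * acq$pulse_fractional_bandwidth *
                          acq$pulse_center_hz) * 1e3
  per_cell <- scat$number_density_mm2 * pulse_len_mm * 1.0
  low_density <- per_cell < 1
  if (low_density)
    warning("fewer than 1 scatterer per resolution cell in expectation; ",
            "QUS estimator assumptions are violated", call. = FALSE)
  structure(list(rf = rf, acquisition = acq,
                 focal_depth_cm = focal_depth_cm,
                 attenuation_db_cm_mhz = scat$attenuation_db_cm_mhz,
                 ground_truth = list(
                   asd_um = scat$effective_diameter_um,
                   aac_proxy = scat$amplitude_variance *
                     scat$number_density_mm2,
                   attenuation_db_cm_mhz = scat$attenuation_db_cm_mhz,
                   scatterers_per_cell = per_cell,
                   low_density_warning = low_density)),
            class = "rf_frame")
}

#' Simulate the reference (calibration) phantom
#'
#' A fixed, documented scatterer population: 25 um Gaussian scatterers at
#' 16 / mm^2, unit amplitude variance, zero attenuation. The analytic
#' backscatter curve of that population over frequency is returned alongside
#' the RF frame: `bsc(f) = eta * f^4 * FF_gauss(f, 25 um)` with `eta` an
#' arbitrary-but-fixed calibration constant (absolute AAC calibration is
#' arbitrary; only relative values are used downstream).
#'
#' @param acq an [acquisition_spec()].
#' @param seed RNG seed.
#' @param depth_cm,n_lines frame extent (defaults: full geometry).
#' @param diameter_um,density_mm2,amplitude_variance phantom population.
#' @return an `rf_frame` with an extra `reference_bsc` data.frame
#'   (`f_mhz`, `bsc`).
#' @export
simulate_reference_phantom <- function(acq, seed,
                                       depth_cm = acq$max_depth_cm,
                                       n_lines = acq$num_lines,
                                       diameter_um = 25, density_mm2 = 16,
                                       amplitude_variance = 1) {
  scat <- scatterer_spec(diameter_um, density_mm2, amplitude_variance, 0)
  fr <- simulate_rf_frame(acq, scat, seed, depth_cm, n_lines)
  f_mhz <- seq(0.5, acq$sampling_rate_hz / 2e6, by = 0.05)
  fr$reference_bsc <- data.frame(
    f_mhz = f_mhz,
    bsc = 1e-4 * f_mhz^4 * gaussian_form_factor(f_mhz, diameter_um,
                                                acq$speed_of_sound_mps))
  fr$phantom_population <- scat
  fr
}
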