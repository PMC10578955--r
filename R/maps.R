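#' Construct a parametric map object
#'
#' @param parameter_id one of the seven QUS parameter ids (`MBF`, `SS`, `SI`,
#'   `ASD_gaussian`, `AAC_gaussian`, `ASD_anderson`, `AAC_anderson`) or a
#'   texture-feature id for texture-of-texture maps.
#' @param values numeric matrix (`NA` outside validity).
#' @param validity logical matrix, same shape.
#' @param pixel_spacing_mm `c(axial, lateral)` spacing in mm.
#' @param units physical units string.
#' @return object of class `parametric_map`.
#' @export
parametric_map <- function(parameter_id, values, validity,
                           pixel_spacing_mm = c(0.5, 0.5), units = "") {
  stopifnot(all(dim(values) == dim(validity)), all(pixel_spacing_mm > 0))
  if (any(validity & !is.finite(values)))
    stop("parametric_map: non-finite values inside the validity mask")
  structure(list(parameter_id = parameter_id, values = values,
                 validity = validity,
                 pixel_spacing_mm = pixel_spacing_mm, units = units),
            class = "parametric_map")
}

#' Sliding-window configuration for parametric maps
#'
#' Default: 2 x 2 mm window with 94.1% overlap between adjacent windows in
#' both directions. Window and step sizes are converted to integer samples
#' and lines by rounding half-up, with the step floored at 1; at the default
#' geometry this yields a step of 6 samples axially and 1 line laterally.
#'
#' @param window_mm window side (mm).
#' @param overlap_fraction overlap between adjacent windows, in [0, 1).
#' @param min_lines_per_window minimum lines for a spectral estimate.
#' @return list of class `sliding_window_config`.
#' @export
sliding_window_config <- function(window_mm = 2, overlap_fraction = 0.941,
                                  min_lines_per_window = 2L) {
  stopifnot(window_mm > 0, overlap_fraction >= 0, overlap_fraction < 1)
  structure(list(window_mm = window_mm,
                 overlap_fraction = overlap_fraction,
                 min_lines_per_window = as.integer(min_lines_per_window)),
            class = "sliding_window_config")
}

#' Integer window geometry for a given acquisition
#'
#' @param acq an [acquisition_spec()].
#' @param cfg a [sliding_window_config()].
#' @return list: `win_ax`, `win_lat` (window extent in samples / lines),
#'   `step_ax`, `step_lat`.
#' @export
window_geometry <- function(acq, cfg) {
  pitch <- pixel_pitch_mm(acq)
  win_ax <- max(2L, round_half_up(cfg$window_mm / pitch[["axial_mm"]]))
  win_lat <- max(cfg$min_lines_per_window,
                 round_half_up(cfg$window_mm / pitch[["lateral_mm"]]))
  list(win_ax = as.integer(win_ax), win_lat = as.integer(win_lat),
       step_ax = max(1L, as.integer(round_half_up(
         (1 - cfg$overlap_fraction) * win_ax))),
       step_lat = max(1L, as.integer(round_half_up(
         (1 - cfg$overlap_fraction) * win_lat))))
}

# window top-left positions along one axis (1-based), plus centre offsets
.window_positions <- function(extent, win, step) {
  if (extent < win) return(integer(0))
  seq.int(1L, extent - win + 1L, by = step)
}

#' Build the seven QUS parametric maps from an RF frame
#'
#' Slides the analysis window over the frame; every window whose centre
#' pixel lies inside the ROI mask is processed through the full spectral
#' chain (Hamming/FFT power spectrum, reference-phantom normalization with
#' attenuation compensation at the window-centre depth, spectral-line fit,
#' and backscatter form-factor fits under both models). The map lattice is
#' the window-step lattice over the frame.
#'
#' @param frame an `rf_frame`.
#' @param mask logical matrix on the RF grid (axial samples x lines).
#' @param phantom a phantom `rf_frame` from [simulate_reference_phantom()]
#'   (same geometry; its per-depth average spectrum is the reference).
#' @param cfg a [sliding_window_config()].
#' @param band an [analysis_band()].
#' @param atten_db_cm_mhz sample attenuation used for compensation
#'   (defaults to the frame's recorded coefficient).
#' @param asd_grid_um diameter search grid (um) shared by both models.
#' @return named list of 7 `parametric_map` objects, with attributes
#'   `n_windows` and `n_failed`.
#' @export
build_parametric_maps <- function(frame, mask, phantom,
                                  cfg = sliding_window_config(),
                                  band = analysis_band(),
                                  atten_db_cm_mhz =
                                    frame$attenuation_db_cm_mhz,
                                  asd_grid_um = seq(10, 300, by = 0.5)) {
  acq <- frame$acquisition
  rf <- frame$rf
  stopifnot(all(dim(mask) == dim(rf)))
  if (!any(mask)) stop("ROI too small: empty mask")
  geo <- window_geometry(acq, cfg)
  rows <- .window_positions(nrow(rf), geo$win_ax, geo$step_ax)
  cols <- .window_positions(ncol(rf), geo$win_lat, geo$step_lat)
  if (!length(rows) || !length(cols))
    stop("ROI too small: window does not fit inside the frame")
  ctr_r <- rows + (geo$win_ax - 1L) %/% 2L
  ctr_c <- cols + (geo$win_lat - 1L) %/% 2L
  inside <- mask[ctr_r, ctr_c, drop = FALSE]
  if (!any(inside)) stop("ROI too small: no window centre inside the mask")
  axial_mm <- pixel_pitch_mm(acq)[["axial_mm"]]
  params <- c("MBF", "SS", "SI", "ASD_gaussian", "AAC_gaussian",
              "ASD_anderson", "AAC_anderson")
  units <- c("dB", "dB/MHz", "dB", "um", "dB/cm3", "um", "dB/cm3")
  vals <- lapply(params, function(p)
    matrix(NA_real_, length(rows), length(cols)))
  names(vals) <- params
  # reference spectra per axial position, averaged over all phantom lines
  nfft <- 2^ceiling(log2(geo$win_ax))
  ref_cache <- new.env()
  ref_for_row <- function(r) {
    key <- as.character(r)
    if (!is.null(ref_cache[[key]])) return(ref_cache[[key]])
    rr <- min(r, nrow(phantom$rf) - geo$win_ax + 1L)
    s <- compute_window_spectrum(phantom$rf[rr:(rr + geo$win_ax - 1L), ,
                                            drop = FALSE],
                                 acq$sampling_rate_hz)
    ref_cache[[key]] <- s
    s
  }
  # model dictionaries on the in-band grid (shared across windows)
  f_grid <- (0:(nfft / 2)) * acq$sampling_rate_hz / nfft / 1e6
  inb <- which(f_grid >= band$f_low & f_grid <= band$f_high)
  dicts <- list(
    gaussian = form_factor_dictionary(f_grid[inb], "gaussian", asd_grid_um,
                                      acq$speed_of_sound_mps),
    anderson = form_factor_dictionary(f_grid[inb], "anderson", asd_grid_um,
                                      acq$speed_of_sound_mps))
  n_windows <- 0L; n_failed <- 0L
  for (i in seq_along(rows)) {
    ref <- NULL
    for (j in seq_along(cols)) {
      if (!inside[i, j]) next
      n_windows <- n_windows + 1L
      res <- tryCatch({
        if (is.null(ref)) ref <- ref_for_row(rows[i])
        win <- rf[rows[i]:(rows[i] + geo$win_ax - 1L),
                  cols[j]:(cols[j] + geo$win_lat - 1L), drop = FALSE]
        sp <- compute_window_spectrum(win, acq$sampling_rate_hz)
        depth <- (ctr_r[i] - 0.5) * axial_mm / 10
        ns <- normalize_spectrum(sp$power, ref$power, sp$freq_hz,
                                 atten_db_cm_mhz, depth)
        fit <- fit_spectral_line(ns, band)
        fg <- fit_form_factor(ns, phantom$reference_bsc, band, "gaussian",
                              dict = dicts$gaussian)
        fa <- fit_form_factor(ns, phantom$reference_bsc, band, "anderson",
                              dict = dicts$anderson)
        c(fit$MBF, fit$SS, fit$SI, fg$ASD, fg$AAC, fa$ASD, fa$AAC)
      }, error = function(e) NULL)
      if (is.null(res) || any(!is.finite(res))) {
        n_failed <- n_failed + 1L
        next
      }
      for (k in seq_along(params)) vals[[k]][i, j] <- res[k]
    }
  }
  spacing <- c(geo$step_ax * axial_mm,
               geo$step_lat * pixel_pitch_mm(acq)[["lateral_mm"]])
  maps <- lapply(seq_along(params), function(k)
    parametric_map(params[k], vals[[k]], is.finite(vals[[k]]),
                   spacing, units[k]))
  names(maps) <- params
  attr(maps, "n_windows") <- n_windows
  attr(maps, "n_failed") <- n_failed
  maps
}

#' Mean of a parametric map over its valid pixels
#' @param map a `parametric_map`.
#' @return scalar mean.
#' @export
roi_mean <- function(map) {
  v <- map$values[map$validity]
  if (!length(v)) stop("roi_mean: no valid pixels")
  mean(v)
}

#' Patient-level value: mean of the per-frame ROI means
#' @param frame_means numeric vector of per-frame ROI means.
#' @return scalar.
#' @export
patient_value <- function(frame_means) {
  stopifnot(length(frame_means) >= 1)
  mean(frame_means)
}

#' One-tailed pooled-variance two-sample comparison of group means
#'
#' Student's t with pooled variance. `direction = "greater"` tests whether
#' the CR mean exceeds the PR mean. Degenerate case: zero variance in both
#' groups with equal means gives p = 0.5 by convention.
#'
#' @param values_cr,values_pr numeric vectors (n >= 2 each).
#' @param direction `"greater"` or `"less"` (alternative for CR vs PR).
#' @return list of class `group_comparison`: `mean_cr`, `mean_pr`,
#'   `t`, `df`, `p_value_one_tail`.
#' @export
compare_groups <- function(values_cr, values_pr,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  n1 <- length(values_cr); n2 <- length(values_pr)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(values_cr); m2 <- mean(values_pr)
  sp2 <- ((n1 - 1) * var(values_cr) + (n2 - 1) * var(values_pr)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  if (se == 0) {
    tt <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else tt <- (m1 - m2) / se
  p <- if (direction == "greater") pt(tt, df, lower.tail = FALSE)
       else pt(tt, df)
  structure(list(mean_cr = m1, mean_pr = m2, t = tt, df = df,
                 p_value_one_tail = p),
            class = "group_comparison")
}
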