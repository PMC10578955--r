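#' Class-conditional map statistics for the synthetic cohort
#'
#' The stated world of the cohort generator. Per-parameter CR and PR means
#' default to the group means of a 72-patient head-and-neck cohort (25 CR /
#' 47 PR); the patient-level standard deviations are back-derived from the
#' one-tailed pooled t-test p-values reported alongside those means
#' (`sd = |mean_cr - mean_pr| / (t_(1-p, 70) * sqrt(1/25 + 1/47))`), so a
#' regenerated 25/47 cohort reproduces comparable group-difference
#' statistics. Responders additionally differ in the spatial correlation
#' length of their parametric maps (coarser texture in CR), which is what
#' makes the classes separable by min--max-invariant texture features.
#'
#' @param mean_cr,mean_pr named numeric vectors over the 7 parameters.
#' @param sd named patient-level standard deviations.
#' @param corr_length_cr,corr_length_pr Gaussian-field correlation lengths
#'   (map pixels) per class.
#' @return list of class `class_effect`.
#' @export
class_effect <- function(mean_cr = NULL, mean_pr = NULL, sd = NULL,
                         corr_length_cr = 3.5, corr_length_pr = 2.0) {
  params <- c("MBF", "SS", "SI", "ASD_gaussian", "AAC_gaussian",
              "ASD_anderson", "AAC_anderson")
  def_cr <- c(3.474, -2.172, 15.44, 82.82, 63.96, 142.9, 112.9)
  def_pr <- c(0.622, -2.050, 11.92, 77.98, 61.25, 136.7, 106.7)
  pvals <- c(0.020, 0.302, 0.026, 0.241, 0.304, 0.098, 0.049)
  names(def_cr) <- names(def_pr) <- names(pvals) <- params
  def_sd <- abs(def_cr - def_pr) /
    (qt(1 - pvals, df = 70) * sqrt(1 / 25 + 1 / 47))
  structure(list(parameters = params,
                 mean_cr = mean_cr %||% def_cr,
                 mean_pr = mean_pr %||% def_pr,
                 sd = sd %||% def_sd,
                 corr_length_cr = corr_length_cr,
                 corr_length_pr = corr_length_pr),
            class = "class_effect")
}

#' A class effect with no signal (null cohort)
#'
#' Both classes share the PR means and the PR correlation length; downstream
#' classification AUC on such a cohort must hover around 0.5.
#' @return a `class_effect`.
#' @export
null_class_effect <- function() {
  ce <- class_effect()
  ce$mean_cr <- ce$mean_pr
  ce$corr_length_cr <- ce$corr_length_pr
  ce
}

#' Cohort specification for the synthetic-data generator
#'
#' @param n_patients number of patients.
#' @param frames_per_patient frames (image planes) per patient; default 6.
#' @param class_fraction_cr proportion of complete responders (default
#'   0.347, i.e. 25 of 72).
#' @param class_effect a [class_effect()].
#' @param map_size map grid side in pixels.
#' @param pixel_spacing_mm map pixel spacing.
#' @param roi_axes_mm range of the full elliptical ROI axes (mm).
#' @param seed RNG seed; fixed seed gives a bit-identical cohort.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, frames_per_patient = 6L,
                        class_fraction_cr = 0.347,
                        class_effect = qusradiomics::class_effect(),
                        map_size = 32L, pixel_spacing_mm = 0.5,
                        roi_axes_mm = c(8, 16), seed = 1L) {
  stopifnot(n_patients >= 1, frames_per_patient >= 1,
            class_fraction_cr > 0, class_fraction_cr < 1)
  structure(list(n_patients = as.integer(n_patients),
                 frames_per_patient = as.integer(frames_per_patient),
                 class_fraction_cr = class_fraction_cr,
                 class_effect = class_effect,
                 map_size = as.integer(map_size),
                 pixel_spacing_mm = pixel_spacing_mm,
                 roi_axes_mm = roi_axes_mm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# unit-variance Gaussian random field via periodic convolution of white
# noise with a Gaussian kernel of the given correlation length (pixels)
.grf <- function(nr, nc, corr_len) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_len <= 0.5) return(z)
  kr <- exp(-0.5 * (pmin(0:(nr - 1), nr - 0:(nr - 1)) / corr_len)^2)
  kc <- exp(-0.5 * (pmin(0:(nc - 1), nc - 0:(nc - 1)) / corr_len)^2)
  ker <- outer(kr, kc)
  sm <- Re(fft(fft(z) * fft(ker), inverse = TRUE)) / (nr * nc)
  sm / sqrt(sum(ker^2))   # exact unit marginal variance
}

.ellipse_mask <- function(n, a_px, b_px, theta) {
  ctr <- (n + 1) / 2
  x <- outer(seq_len(n) - ctr, rep(1, n))
  y <- outer(rep(1, n), seq_len(n) - ctr)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  (xr / a_px)^2 + (yr / b_px)^2 <= 1
}

#' Generate a labeled synthetic cohort of QUS parametric maps
#'
#' For each patient, `frames_per_patient` sets of 7 parametric maps are drawn
#' from class-conditional Gaussian random fields: pixel field =
#' class mean + patient effect + frame effect + correlated field, with the
#' class-specific correlation length from the [class_effect()]. ROIs are
#' random ellipses; a degenerate ROI (fewer valid pixels than one 3 x 3
#' texture window) is rejected and regenerated. Variance split: patient
#' effect 0.95 sd, frame effect 0.3 sd, pixel field 1.0 sd, so the
#' patient-level mean (averaged over frames and pixels) has close to the
#' nominal patient-level sd.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `frames` (list of records with
#'   `patient_id`, `frame_index`, `label`, `maps` — 7 `parametric_map`s),
#'   `labels` (named by patient id), `manifest` (one row per frame), `spec`.
#' @export
generate_synthetic_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ce <- spec$class_effect
  n <- spec$n_patients
  n_cr <- max(1L, min(n - 1L, as.integer(round(spec$class_fraction_cr * n))))
  ids <- sprintf("P%03d", seq_len(n))
  labels <- rep("PR", n)
  labels[sample.int(n, n_cr)] <- "CR"
  names(labels) <- ids
  m <- spec$map_size
  units <- c(MBF = "dB", SS = "dB/MHz", SI = "dB", ASD_gaussian = "um",
             AAC_gaussian = "dB/cm3", ASD_anderson = "um",
             AAC_anderson = "dB/cm3")
  frames <- list()
  man <- list()
  axes_px <- spec$roi_axes_mm / spec$pixel_spacing_mm / 2  # semi-axes
  for (p in seq_len(n)) {
    lab <- labels[p]
    mu <- if (lab == "CR") ce$mean_cr else ce$mean_pr
    clen <- if (lab == "CR") ce$corr_length_cr else ce$corr_length_pr
    patient_eff <- rnorm(length(ce$parameters), 0, 0.95 * ce$sd)
    for (fr in seq_len(spec$frames_per_patient)) {
      frame_eff <- rnorm(length(ce$parameters), 0, 0.3 * ce$sd)
      mask <- NULL
      for (try in 1:20) {
        a <- runif(1, min(axes_px), max(axes_px))
        b <- runif(1, min(axes_px), max(axes_px))
        cand <- .ellipse_mask(m, min(a, (m - 2) / 2), min(b, (m - 2) / 2),
                              runif(1, 0, pi))
        if (sum(cand) >= 9) { mask <- cand; break }
        message("degenerate ROI rejected and regenerated (patient ", p,
                ", frame ", fr, ")")
      }
      if (is.null(mask)) stop("could not generate a non-degenerate ROI")
      maps <- list()
      for (k in seq_along(ce$parameters)) {
        field <- mu[k] + patient_eff[k] + frame_eff[k] +
          ce$sd[k] * .grf(m, m, clen)
        vals <- ifelse(mask, field, NA_real_)
        maps[[ce$parameters[k]]] <-
          parametric_map(ce$parameters[k], vals, mask,
                         rep(spec$pixel_spacing_mm, 2),
                         units[[ce$parameters[k]]])
      }
      rec <- list(patient_id = ids[p], frame_index = fr, label = lab,
                  maps = maps, roi_mask = mask)
      frames[[length(frames) + 1L]] <- rec
      man[[length(man) + 1L]] <- data.frame(
        patient_id = ids[p], frame_index = fr, label = lab,
        frame_id = sprintf("%s_f%d", ids[p], fr),
        n_roi_pixels = sum(mask))
    }
  }
  structure(list(frames = frames, labels = labels,
                 manifest = do.call(rbind, man), spec = spec),
            class = "synthetic_cohort")
}
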